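# Data model and I/O: sample-by-taxon abundance tables, environmental tables,
# validation, and sample-key alignment.
#
# On disk the canonical abundance format is long (site,date,taxon_id,
# abundance_cells_per_L) with a separate per-taxon metadata CSV; in memory the
# table is a dense sample x taxon matrix carried with its sample and taxon
# frames.

#' Construct a phytoplankton abundance table
#'
#' The central container of the package: a sample-by-taxon matrix of cell
#' densities (cells/L) together with the sample frame (site, date) and the
#' taxon metadata frame (name, phylum, mean cell volume, optional
#' functional-group code).
#'
#' @param samples `data.frame` with columns `site` (character) and `date`
#'   (`Date`); `(site, date)` pairs must be unique.
#' @param taxa `data.frame` with columns `taxon_id`, `name`, `phylum`,
#'   `cell_volume_um3` and optionally `fg_code`. `phylum` must be one of the
#'   seven freshwater phyla (Chlorophyta, Bacillariophyta, Cyanophyta,
#'   Dinophyta, Euglenophyta, Cryptophyta, Chrysophyta); `cell_volume_um3`
#'   must be positive.
#' @param abundance Numeric matrix, `nrow(samples)` x `nrow(taxa)`,
#'   non-negative cells/L; every sample must have at least one positive entry.
#' @return An object of class `phyto_abundance`.
#' @seealso [load_abundance()], [classify_taxa()], [compute_biomass()]
#' @export
phyto_abundance <- function(samples, taxa, abundance) {
  stopifnot(is.data.frame(samples), is.data.frame(taxa))
  require_columns(samples, c("site", "date"), "sample frame")
  require_columns(taxa, c("taxon_id", "name", "phylum", "cell_volume_um3"), "taxon frame")
  if (!inherits(samples$date, "Date")) samples$date <- parse_dates(samples$date)
  if (is.null(taxa$fg_code)) taxa$fg_code <- NA_character_
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"

  if (nrow(abundance) != nrow(samples) || ncol(abundance) != nrow(taxa)) {
    stop("abundance matrix is ", nrow(abundance), " x ", ncol(abundance),
         " but there are ", nrow(samples), " samples and ", nrow(taxa), " taxa",
         call. = FALSE)
  }
  keys <- sample_key(samples$site, samples$date)
  if (anyDuplicated(keys)) {
    stop("duplicated (site, date) sample keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(taxa$taxon_id)) {
    stop("duplicated taxon_id in taxon metadata", call. = FALSE)
  }
  if (anyNA(abundance) || any(abundance < 0)) {
    stop("abundance must be non-negative and complete (cells/L)", call. = FALSE)
  }
  if (nrow(abundance) > 0 && any(rowSums(abundance) <= 0)) {
    empty <- keys[rowSums(abundance) <= 0]
    stop("sample(s) with no positive abundance: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  bad_phy <- setdiff(unique(as.character(taxa$phylum)), PHYLA)
  if (length(bad_phy)) {
    stop("unknown phylum: ", paste(bad_phy, collapse = ", "),
         " (expected one of ", paste(PHYLA, collapse = ", "), ")", call. = FALSE)
  }
  if (any(!is.finite(taxa$cell_volume_um3) | taxa$cell_volume_um3 <= 0)) {
    bad <- taxa$taxon_id[!is.finite(taxa$cell_volume_um3) | taxa$cell_volume_um3 <= 0]
    stop("non-positive cell_volume_um3 for taxa: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rownames(abundance) <- keys
  colnames(abundance) <- taxa$taxon_id
  structure(
    list(samples = samples[, c("site", "date")], taxa = taxa, abundance = abundance),
    class = "phyto_abundance"
  )
}

#' @export
print.phyto_abundance <- function(x, ...) {
  cat("<phyto_abundance> ", nrow(x$samples), " samples x ", nrow(x$taxa), " taxa; ",
      length(unique(x$samples$site)), " site(s), ",
      format(min(x$samples$date)), " to ", format(max(x$samples$date)), "\n", sep = "")
  n_cls <- sum(!is.na(x$taxa$fg_code))
  cat("  functional-group codes assigned: ", n_cls, "/", nrow(x$taxa), "\n", sep = "")
  invisible(x)
}

#' Construct an environmental table
#'
#' Water-quality measurements aligned to the same `(site, date)` sample keys
#' as the abundance table. Variables: water temperature `WT` (deg C), `pH`,
#' dissolved oxygen `DO` (mg/L), Secchi depth `SD` (m), total nitrogen `TN`
#' (mg/L), total phosphorus `TP` (mg/L), ammonia nitrogen `NH3N` (mg/L) and
#' permanganate index `CODMn` (mg/L). Missing cells are allowed and kept as
#' `NA`; downstream statistics drop incomplete samples and report the count.
#'
#' @param samples `data.frame` with columns `site`, `date`.
#' @param env `data.frame` with the eight variable columns, one row per sample.
#' @return An object of class `phyto_env`.
#' @export
phyto_env <- function(samples, env) {
  require_columns(samples, c("site", "date"), "sample frame")
  require_columns(env, ENV_VARS, "environmental table")
  if (!inherits(samples$date, "Date")) samples$date <- parse_dates(samples$date)
  env <- as.data.frame(lapply(env[ENV_VARS], as.numeric))
  if (nrow(env) != nrow(samples)) {
    stop("environmental table has ", nrow(env), " rows for ", nrow(samples),
         " samples", call. = FALSE)
  }
  keys <- sample_key(samples$site, samples$date)
  if (anyDuplicated(keys)) {
    stop("duplicated (site, date) sample keys in environmental table", call. = FALSE)
  }
  ph_bad <- !is.na(env$pH) & (env$pH <= 0 | env$pH >= 14)
  if (any(ph_bad)) {
    stop("pH outside (0, 14) at: ", paste(keys[ph_bad], collapse = ", "), call. = FALSE)
  }
  for (v in setdiff(ENV_VARS, "pH")) {
    bad <- !is.na(env[[v]]) & env[[v]] < 0
    if (any(bad)) {
      stop("negative ", v, " at: ", paste(keys[bad], collapse = ", "), call. = FALSE)
    }
  }
  n_na <- sum(is.na(env))
  if (n_na > 0) {
    message("environmental table has ", n_na, " missing cell(s); kept as NA")
  }
  rownames(env) <- keys
  structure(list(samples = samples[, c("site", "date")], env = env),
            class = "phyto_env")
}

#' @export
print.phyto_env <- function(x, ...) {
  cat("<phyto_env> ", nrow(x$samples), " samples x ", ncol(x$env), " variables (",
      paste(ENV_VARS, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Load a long-format abundance CSV plus taxon metadata
#'
#' Reads the canonical on-disk representation: a long table with columns
#' `site,date,taxon_id,abundance_cells_per_L` (ISO dates) and a metadata CSV
#' with columns `taxon_id,name,phylum,cell_volume_um3,fg_code` (one row per
#' taxon; `fg_code` may be empty). Duplicate `(site, date, taxon)` rows are
#' summed with a warning; taxa present in the counts but absent from the
#' metadata are an error.
#'
#' @param path Path to the long-format abundance CSV/TSV.
#' @param taxon_meta_path Path to the taxon metadata CSV.
#' @return A validated [phyto_abundance] object.
#' @export
load_abundance <- function(path, taxon_meta_path) {
  stopifnot(file.exists(path), file.exists(taxon_meta_path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  long <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                            check.names = FALSE)
  require_columns(long, c("site", "date", "taxon_id", "abundance_cells_per_L"),
                  "abundance file")
  long$date <- parse_dates(long$date)
  ab <- suppressWarnings(as.numeric(long$abundance_cells_per_L))
  if (anyNA(ab)) {
    stop("non-numeric abundance in row(s): ",
         paste(utils::head(which(is.na(ab)), 10), collapse = ", "), call. = FALSE)
  }
  if (any(ab < 0)) {
    stop("negative abundance in row(s): ",
         paste(utils::head(which(ab < 0), 10), collapse = ", "), call. = FALSE)
  }
  long$abundance_cells_per_L <- ab

  meta <- utils::read.csv(taxon_meta_path, stringsAsFactors = FALSE)
  require_columns(meta, c("taxon_id", "name", "phylum", "cell_volume_um3"),
                  "taxon metadata")
  if (is.null(meta$fg_code)) meta$fg_code <- NA_character_
  meta$fg_code[!is.na(meta$fg_code) & !nzchar(meta$fg_code)] <- NA_character_

  orphans <- setdiff(unique(long$taxon_id), meta$taxon_id)
  if (length(orphans)) {
    stop("taxa present in counts but missing from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }

  key <- sample_key(long$site, long$date)
  dup <- duplicated(cbind(key, long$taxon_id))
  if (any(dup)) {
    warning(sum(dup), " duplicate (site, date, taxon) row(s) summed", call. = FALSE)
  }
  # drop taxa never observed in this file? keep all metadata rows that occur
  meta <- meta[meta$taxon_id %in% long$taxon_id, , drop = FALSE]
  ukey <- unique(key)
  samples <- data.frame(
    site = long$site[match(ukey, key)],
    date = long$date[match(ukey, key)],
    stringsAsFactors = FALSE
  )
  mat <- matrix(0, nrow = length(ukey), ncol = nrow(meta),
                dimnames = list(ukey, meta$taxon_id))
  idx <- cbind(match(key, ukey), match(long$taxon_id, meta$taxon_id))
  for (r in seq_len(nrow(long))) {
    mat[idx[r, 1], idx[r, 2]] <- mat[idx[r, 1], idx[r, 2]] + long$abundance_cells_per_L[r]
  }
  phyto_abundance(samples, meta, mat)
}

#' Write an abundance table back to the canonical long format
#'
#' Inverse of [load_abundance()]: zero cells are omitted so that
#' write-then-load round-trips values, sample order and taxon metadata.
#'
#' @param x A [phyto_abundance] object.
#' @param path Output CSV path for the long abundance table.
#' @param taxon_meta_path Output CSV path for the taxon metadata.
#' @return Invisibly, `x`.
#' @export
write_abundance <- function(x, path, taxon_meta_path) {
  stopifnot(inherits(x, "phyto_abundance"))
  nz <- which(x$abundance != 0 | col(x$abundance) == 1, arr.ind = TRUE)
  # keep at least the first taxon column per sample so empty-ish samples survive;
  # validation guarantees every sample has a positive entry anyway
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  long <- data.frame(
    site = x$samples$site[nz[, 1]],
    date = format(x$samples$date[nz[, 1]], "%Y-%m-%d"),
    taxon_id = x$taxa$taxon_id[nz[, 2]],
    abundance_cells_per_L = x$abundance[nz],
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE, quote = TRUE)
  utils::write.csv(x$taxa[, c("taxon_id", "name", "phylum", "cell_volume_um3", "fg_code")],
                   taxon_meta_path, row.names = FALSE, quote = TRUE, na = "")
  invisible(x)
}

#' Load an environmental CSV
#'
#' Wide format with columns `site,date,WT,pH,DO,SD,TN,TP,NH3N,CODMn`; dates
#' ISO-8601. Missing cells are permitted (kept as `NA` and counted in a
#' message); a pH outside (0, 14) or a negative concentration is an error.
#'
#' @param path Path to the CSV file.
#' @return A validated [phyto_env] object.
#' @export
load_env <- function(path) {
  stopifnot(file.exists(path))
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(wide, c("site", "date", ENV_VARS), "environmental file")
  samples <- data.frame(site = wide$site, date = parse_dates(wide$date),
                        stringsAsFactors = FALSE)
  phyto_env(samples, wide[ENV_VARS])
}

#' Write an environmental table to CSV
#'
#' @param x A [phyto_env] object.
#' @param path Output CSV path.
#' @return Invisibly, `x`.
#' @export
write_env <- function(x, path) {
  stopifnot(inherits(x, "phyto_env"))
  out <- cbind(site = x$samples$site, date = format(x$samples$date, "%Y-%m-%d"),
               x$env)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(x)
}

#' Restrict abundance and environmental tables to their common samples
#'
#' Both tables are subset to the intersection of `(site, date)` keys, in the
#' abundance table's order, so rows correspond one-to-one. Dropped keys are
#' reported; an empty intersection is an error. The operation is idempotent.
#'
#' @param a A [phyto_abundance] object.
#' @param e A [phyto_env] object.
#' @return A list with elements `abundance` and `env`.
#' @export
align_samples <- function(a, e) {
  stopifnot(inherits(a, "phyto_abundance"), inherits(e, "phyto_env"))
  ka <- sample_key(a$samples$site, a$samples$date)
  ke <- sample_key(e$samples$site, e$samples$date)
  common <- ka[ka %in% ke]
  if (length(common) == 0) {
    stop("abundance and environmental tables share no (site, date) samples",
         call. = FALSE)
  }
  dropped <- c(setdiff(ka, common), setdiff(ke, common))
  if (length(dropped)) {
    message("align_samples: dropped ", length(dropped), " unmatched sample(s)")
  }
  ia <- match(common, ka)
  ie <- match(common, ke)
  a2 <- phyto_abundance(a$samples[ia, , drop = FALSE], a$taxa,
                        a$abundance[ia, , drop = FALSE])
  e2 <- phyto_env(e$samples[ie, , drop = FALSE], e$env[ie, , drop = FALSE])
  list(abundance = a2, env = e2)
}
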