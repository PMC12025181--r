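# Reynolds/Padisak functional-group layer: the packaged trait catalog,
# species -> group classification, count -> biomass conversion, McNaughton
# dominance, dominant functional groups and habitat indication.

#' The packaged functional-group trait catalog
#'
#' Loads the 27-group trait table shipped with the package: group code,
#' habitat template, representative taxa, tolerance, susceptibility, and a
#' flag for the eight groups (B, D, L_O, P, S1, W1, W2, Y) that dominated the
#' reservoir survey the catalog describes. A species -> code lookup
#' (`species_map`) is derived from the representative-taxa column: full
#' species names first, then the leading (genus) token.
#'
#' @param path Optional path to an alternative catalog CSV with columns
#'   `code,habitat,representative_taxa,tolerance,susceptibility,dominant_in_study`
#'   (taxa separated by `;`). Defaults to the packaged catalog.
#' @return An object of class `fg_catalog`: the trait `data.frame` plus a
#'   `species_map` attribute (named character vector, lower-case name pattern
#'   -> code).
#' @export
#' @examples
#' cat27 <- fg_catalog()
#' nrow(cat27)            # 27 groups
#' sum(cat27$dominant_in_study)
fg_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fg_catalog.csv", package = "phytofg")
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(tab, c("code", "habitat", "representative_taxa", "tolerance",
                         "susceptibility", "dominant_in_study"), "catalog")
  if (anyDuplicated(tab$code)) stop("duplicated catalog codes", call. = FALSE)
  tab$dominant_in_study <- as.logical(tab$dominant_in_study)

  species <- character(0)
  for (i in seq_len(nrow(tab))) {
    pats <- trimws(strsplit(tab$representative_taxa[i], ";", fixed = TRUE)[[1]])
    pats <- pats[nzchar(pats)]
    # strip the "sp." suffix: entries like "Cyclotella sp." index the genus
    pats <- tolower(sub("\\s+sp\\.?$", "", pats))
    new <- stats::setNames(rep(tab$code[i], length(pats)), pats)
    species <- c(species, new[!(names(new) %in% names(species))])
  }
  structure(tab, species_map = species, class = c("fg_catalog", "data.frame"))
}

#' Assign functional-group codes to the taxa of an abundance table
#'
#' Each taxon is classified by, in order of precedence: (1) an explicit
#' non-missing `fg_code` already present in the taxon metadata; (2) a
#' case-insensitive full-name match against the catalog's representative
#' taxa; (3) a genus-level match on the leading token of the name. Taxa that
#' match nothing receive the sentinel code `"UNASSIGNED"` and are reported.
#'
#' @param table A [phyto_abundance] object.
#' @param catalog An [fg_catalog()] object.
#' @return The table with `taxa$fg_code` filled in for every taxon.
#' @export
classify_taxa <- function(table, catalog = fg_catalog()) {
  stopifnot(inherits(table, "phyto_abundance"), inherits(catalog, "fg_catalog"))
  map <- attr(catalog, "species_map")
  codes <- table$taxa$fg_code
  known <- c(catalog$code, "UNASSIGNED")
  bad_explicit <- !is.na(codes) & !(codes %in% known)
  if (any(bad_explicit)) {
    stop("taxon metadata carries fg_code(s) absent from the catalog: ",
         paste(unique(codes[bad_explicit]), collapse = ", "), call. = FALSE)
  }
  todo <- which(is.na(codes))
  for (i in todo) {
    nm <- tolower(trimws(table$taxa$name[i]))
    nm <- sub("\\s+sp\\.?$", "", nm)
    hit <- map[nm]
    if (is.na(hit)) {
      genus <- strsplit(nm, "\\s+")[[1]][1]
      hit <- map[genus]
      if (is.na(hit)) {
        # genus-level catalog entries may carry an epithet (e.g. full species
        # names); fall back to matching the pattern's own leading token
        lead <- vapply(strsplit(names(map), "\\s+"), `[`, "", 1)
        j <- match(genus, lead)
        hit <- if (is.na(j)) NA_character_ else unname(map[j])
      }
    }
    codes[i] <- if (is.na(hit)) "UNASSIGNED" else unname(hit)
  }
  unassigned <- table$taxa$name[codes == "UNASSIGNED"]
  message("classify_taxa: ", length(unassigned), " taxa unassigned",
          if (length(unassigned)) paste0(" (", paste(unassigned, collapse = ", "), ")"))
  table$taxa$fg_code <- codes
  table
}

#' Habitat indication for functional-group codes
#'
#' Returns the catalog's habitat, tolerance and susceptibility text for each
#' requested code, for interpretive reporting of what the dominant groups
#' indicate about trophic state. No automated verdict is computed.
#'
#' @param codes Character vector of functional-group codes (may be empty).
#' @param catalog An [fg_catalog()] object.
#' @return A `data.frame` with one row per code.
#' @export
habitat_indication <- function(codes, catalog = fg_catalog()) {
  stopifnot(inherits(catalog, "fg_catalog"))
  if (length(codes) == 0) {
    return(catalog[0, c("code", "habitat", "representative_taxa", "tolerance",
                        "susceptibility")])
  }
  i <- match(codes, catalog$code)
  if (anyNA(i)) {
    stop("unknown functional-group code(s): ", paste(codes[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  out <- catalog[i, c("code", "habitat", "representative_taxa", "tolerance",
                      "susceptibility")]
  rownames(out) <- NULL
  out
}

#' Convert cell counts to functional-group biomass
#'
#' Per-taxon biomass is `density (g/cm^3) x cell volume (um^3) x abundance
#' (cells/L) x 1e-9`, which for unit-density plankton gives mg/L directly
#' (1 um^3 of unit-density matter weighs 1e-9 mg). Taxon biomasses are then
#' summed within functional groups and each sample row is normalised to
#' relative biomass.
#'
#' @param table A [phyto_abundance] whose taxa all carry an `fg_code`
#'   (run [classify_taxa()] first) and a positive `cell_volume_um3`.
#' @param density Cell density in g/cm^3; the conventional value is 1.
#' @return An object of class `fg_biomass`: `samples`, `groups` (codes),
#'   `biomass` (sample x group, mg/L) and `relative` (rows summing to 1;
#'   `NA` for any all-zero biomass row, which is flagged).
#' @export
compute_biomass <- function(table, density = 1) {
  stopifnot(inherits(table, "phyto_abundance"), density > 0)
  if (anyNA(table$taxa$fg_code)) {
    stop("taxa without fg_code: ",
         paste(table$taxa$taxon_id[is.na(table$taxa$fg_code)], collapse = ", "),
         "; run classify_taxa() first", call. = FALSE)
  }
  if (anyNA(table$taxa$cell_volume_um3)) {
    stop("taxa without cell_volume_um3: ",
         paste(table$taxa$taxon_id[is.na(table$taxa$cell_volume_um3)], collapse = ", "),
         call. = FALSE)
  }
  per_taxon <- sweep(table$abundance, 2, density * table$taxa$cell_volume_um3 * 1e-9, `*`)
  groups <- sort(unique(table$taxa$fg_code))
  agg <- matrix(0, nrow(per_taxon), length(groups),
                dimnames = list(rownames(per_taxon), groups))
  for (g in groups) {
    cols <- which(table$taxa$fg_code == g)
    agg[, g] <- rowSums(per_taxon[, cols, drop = FALSE])
  }
  tot <- rowSums(agg)
  rel <- agg / tot
  if (any(tot == 0)) {
    message("compute_biomass: ", sum(tot == 0),
            " sample(s) with zero total biomass; relative biomass set to NA")
    rel[tot == 0, ] <- NA_real_
  }
  structure(list(samples = table$samples, groups = groups,
                 biomass = agg, relative = rel),
            class = "fg_biomass")
}

#' @export
print.fg_biomass <- function(x, ...) {
  cat("<fg_biomass> ", nrow(x$biomass), " samples x ", length(x$groups),
      " functional groups; total biomass ",
      signif(min(rowSums(x$biomass)), 3), "-", signif(max(rowSums(x$biomass)), 3),
      " mg/L\n", sep = "")
  invisible(x)
}

#' McNaughton dominance index
#'
#' For each taxon over an evaluation scope of samples: `Y = (Ni / N) * fi`,
#' where `Ni` is the taxon's summed abundance, `N` the all-taxa total and
#' `fi` the fraction of scope samples in which the taxon occurs (abundance
#' strictly positive). Taxa with `Y >= 0.02` are dominant; `Y > 0.1` marks
#' the absolute dominants.
#'
#' @param table A [phyto_abundance] object.
#' @param scope Samples defining the evaluation scope: a logical or integer
#'   index into the sample rows, or `NULL` (default) for all samples.
#' @return A `data.frame` with columns `taxon_id`, `name`, `Ni`, `share`
#'   (`Ni/N`), `fi`, `Y` and `status` (`none`/`dominant`/`absolute_dominant`),
#'   sorted by decreasing `Y`.
#' @export
dominance <- function(table, scope = NULL) {
  stopifnot(inherits(table, "phyto_abundance"))
  m <- table$abundance
  if (!is.null(scope)) m <- m[scope, , drop = FALSE]
  if (nrow(m) == 0) stop("empty dominance scope", call. = FALSE)
  N <- sum(m)
  if (N == 0) stop("zero total abundance over the dominance scope", call. = FALSE)
  Ni <- colSums(m)
  fi <- colMeans(m > 0)
  share <- Ni / N
  Y <- share * fi
  status <- ifelse(Y > 0.1, "absolute_dominant",
                   ifelse(Y >= 0.02, "dominant", "none"))
  out <- data.frame(taxon_id = table$taxa$taxon_id, name = table$taxa$name,
                    Ni = Ni, share = share, fi = fi, Y = Y,
                    status = factor(status, levels = c("none", "dominant",
                                                       "absolute_dominant")),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$Y), ]
}

#' Dominant functional groups of a sample stratum
#'
#' Group shares are computed on stratum-aggregated biomass (group biomass
#' summed over the stratum divided by total biomass over the stratum), not as
#' averages of per-sample shares. Groups whose share strictly exceeds
#' `threshold` are returned in decreasing order; the remainder is reported as
#' the `"others"` attribute.
#'
#' @param bm An [compute_biomass()] result (`fg_biomass`).
#' @param stratum Samples defining the stratum: logical or integer index into
#'   the sample rows, or `NULL` for all samples.
#' @param threshold Dominance cut-off on the share, default 0.05 (5.00%).
#' @return A `data.frame` with columns `code` and `share`, attribute
#'   `others` = 1 - sum(share).
#' @export
dominant_groups <- function(bm, stratum = NULL, threshold = 0.05) {
  stopifnot(inherits(bm, "fg_biomass"))
  m <- bm$biomass
  if (!is.null(stratum)) m <- m[stratum, , drop = FALSE]
  if (nrow(m) == 0) stop("empty stratum", call. = FALSE)
  tot <- sum(m)
  if (tot == 0) stop("zero total biomass over the stratum", call. = FALSE)
  share <- colSums(m) / tot
  keep <- share > threshold
  out <- data.frame(code = names(share)[keep], share = unname(share[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "others") <- 1 - sum(out$share)
  out
}

#' Per-phylum species composition summary
#'
#' Counts the distinct taxa per phylum (a taxon counts if its abundance is
#' positive anywhere in the table) and reports each phylum's percentage of
#' the total species count, rounded half-up to two decimals.
#'
#' @param table A [phyto_abundance] object.
#' @return A `data.frame` with columns `phylum`, `n_species`, `pct`, sorted
#'   by decreasing count; attribute `total` holds the species total.
#' @export
composition_summary <- function(table) {
  stopifnot(inherits(table, "phyto_abundance"))
  present <- colSums(table$abundance > 0) > 0
  phyla <- as.character(table$taxa$phylum[present])
  counts <- table(factor(phyla, levels = PHYLA))
  counts <- counts[counts > 0]
  total <- sum(counts)
  out <- data.frame(phylum = names(counts), n_species = as.integer(counts),
                    pct = round_half_up(as.integer(counts) / total * 100, 2),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_species), ]
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}
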