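# Community stability via the average variation degree (AVD): the mean
# absolute standardized deviation of per-group values across the samples of a
# stratum, normalised by (samples x groups). Lower AVD = more stable; 1 - AVD
# is reported as a stability score.

#' Average variation degree of a sample stratum
#'
#' For each functional group `i` with positive sample standard deviation
#' `delta_i` over the stratum, the per-sample variation degree is
#' `a_ij = |x_ij - xbar_i| / delta_i`; the AVD is the double sum of `a_ij`
#' over groups and samples divided by `k x n`, where `k` is the number of
#' samples and `n` the number of groups with nonzero variance. Groups with
#' zero variance carry no information about variability and are excluded from
#' both the numerator and `n` (and reported).
#'
#' @param x An `fg_biomass` object or a numeric sample x group matrix.
#' @param stratum Samples defining the stratum (logical or integer index), or
#'   `NULL` for all samples. At least 2 samples are required.
#' @param measure For `fg_biomass` input: `"biomass"` (default, mg/L),
#'   `"relative"`, or `"abundance"` is not available here - aggregate counts
#'   to groups yourself and pass a matrix to use abundances.
#' @param sd_denominator `"n-1"` (default, sample standard deviation) or
#'   `"n"` (population form).
#' @return An object of class `avd_result`: `k`, `n`, `avd`,
#'   `stability_score` (`1 - avd`), `per_group` (mean `a_ij` per retained
#'   group) and `excluded_groups`.
#' @export
#' @examples
#' m <- cbind(g1 = c(1, 3))  # one group, two samples: AVD = sqrt(2)/2
#' avd(m)$avd
avd <- function(x, stratum = NULL, measure = c("biomass", "relative"),
                sd_denominator = c("n-1", "n")) {
  measure <- match.arg(measure)
  sd_denominator <- match.arg(sd_denominator)
  if (inherits(x, "fg_biomass")) {
    m <- x[[if (measure == "biomass") "biomass" else "relative"]]
  } else {
    m <- as.matrix(x)
  }
  if (!is.null(stratum)) m <- m[stratum, , drop = FALSE]
  k <- nrow(m)
  if (k < 2) stop("AVD needs at least 2 samples in the stratum", call. = FALSE)
  if (anyNA(m)) stop("AVD input contains missing values", call. = FALSE)

  mu <- colMeans(m)
  dev <- sweep(m, 2, mu)
  ss <- colSums(dev^2)
  sdv <- sqrt(ss / if (sd_denominator == "n-1") (k - 1) else k)
  keep <- sdv > 0
  if (!any(keep)) {
    stop("all groups have zero variance over the stratum; AVD undefined",
         call. = FALSE)
  }
  a <- sweep(abs(dev[, keep, drop = FALSE]), 2, sdv[keep], `/`)
  n <- sum(keep)
  avd_val <- sum(a) / (k * n)
  structure(list(
    k = k, n = n, avd = avd_val, stability_score = 1 - avd_val,
    per_group = colMeans(a),
    excluded_groups = colnames(m)[!keep] %||% character(0)
  ), class = "avd_result")
}

#' @export
print.avd_result <- function(x, ...) {
  cat("<avd_result> k = ", x$k, " samples, n = ", x$n, " groups; AVD = ",
      signif(x$avd, 4), " (1 - AVD = ", signif(x$stability_score, 4), ")\n", sep = "")
  if (length(x$excluded_groups)) {
    cat("  zero-variance groups excluded: ",
        paste(x$excluded_groups, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' AVD per year or per site
#'
#' Computes one AVD per stratum: per calendar year (pooling all sites'
#' samples of that year) or per site (pooling all dates at that site). Strata
#' that fail the AVD preconditions are reported with a warning and omitted.
#'
#' @param bm An `fg_biomass` object.
#' @param by `"year"` or `"site"`.
#' @inheritParams avd
#' @return A `data.frame` with columns `stratum`, `k`, `n`, `avd`,
#'   `one_minus_avd`; the full `avd_result` objects are attached as the
#'   `"results"` attribute.
#' @export
avd_by <- function(bm, by = c("year", "site"), measure = c("biomass", "relative"),
                   sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(bm, "fg_biomass"))
  by <- match.arg(by)
  key <- switch(by,
                year = format(bm$samples$date, "%Y"),
                site = bm$samples$site)
  strata <- sort(unique(key))
  results <- list()
  rows <- list()
  for (s in strata) {
    res <- tryCatch(avd(bm, stratum = key == s, measure = measure,
                        sd_denominator = sd_denominator),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("stratum ", s, " skipped: ", conditionMessage(res), call. = FALSE)
      next
    }
    results[[s]] <- res
    rows[[s]] <- data.frame(stratum = s, k = res$k, n = res$n, avd = res$avd,
                            one_minus_avd = res$stability_score,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no stratum satisfied the AVD preconditions", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
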