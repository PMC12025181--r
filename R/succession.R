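# Functional-group succession rate: per-day total absolute change in
# relative biomass between two sampling occasions, and its monthly/annual/
# spatial aggregation.

#' Succession rate between two relative-biomass profiles
#'
#' `SR = sum_i |f_ib - f_ia| / (b - a)` in units of /day, where `f_ia`,
#' `f_ib` are the relative biomasses of functional group `i` at the two
#' occasions. Both profiles must be over the union of groups (name-matched if
#' named; a group absent at one time contributes its share at the other) and
#' each must sum to 1. Because the total variation distance between two
#' probability vectors is at most 2, `SR <= 2 / delta_days`.
#'
#' @param fa,fb Numeric vectors of relative biomass (each summing to 1 within
#'   `tol`). If named, they are aligned on the union of names with missing
#'   groups treated as 0.
#' @param delta_days Positive time difference `b - a` in days.
#' @param tol Tolerance on the unit-sum check.
#' @return The succession rate, per day.
#' @export
#' @examples
#' succession_rate(c(0.6, 0.4), c(0.4, 0.6), 10)  # 0.04 /d
succession_rate <- function(fa, fb, delta_days, tol = 1e-9) {
  if (!is.numeric(delta_days) || length(delta_days) != 1 || delta_days <= 0) {
    stop("delta_days must be a single positive number of days", call. = FALSE)
  }
  if (!is.null(names(fa)) && !is.null(names(fb))) {
    groups <- union(names(fa), names(fb))
    fa <- stats::setNames(fa[groups], groups)
    fb <- stats::setNames(fb[groups], groups)
    fa[is.na(fa)] <- 0
    fb[is.na(fb)] <- 0
  } else if (length(fa) != length(fb)) {
    stop("unnamed profiles must have equal length", call. = FALSE)
  }
  if (abs(sum(fa) - 1) > tol || abs(sum(fb) - 1) > tol) {
    stop("relative-biomass profiles must each sum to 1 (tolerance ", tol, ")",
         call. = FALSE)
  }
  sum(abs(fb - fa)) / delta_days
}

#' Succession-rate series for one site
#'
#' Orders the site's samples by date, recomputes relative biomass over the
#' selected groups, and evaluates the succession rate for every consecutive
#' pair of occasions, with the time step taken from the actual sampling dates
#' in calendar days.
#'
#' @param bm An `fg_biomass` object (see [compute_biomass()]).
#' @param site_id Site to extract; must have at least two sampling dates.
#' @param groups Optional subset of group codes to restrict the profiles to
#'   (shares renormalised); default all groups.
#' @return An object of class `succession_series`: `site_id`, `timepoints`,
#'   `profiles` (timepoint x group relative biomass) and `intervals`
#'   (`data.frame` with `a`, `b`, `delta_days`, `SR`).
#' @export
series_sr <- function(bm, site_id, groups = NULL) {
  stopifnot(inherits(bm, "fg_biomass"))
  rows <- which(bm$samples$site == site_id)
  if (length(rows) < 2) {
    stop("site ", site_id, " has fewer than 2 sampling occasions", call. = FALSE)
  }
  rows <- rows[order(bm$samples$date[rows])]
  dates <- bm$samples$date[rows]
  if (anyDuplicated(dates)) {
    stop("site ", site_id, " has duplicated sampling dates", call. = FALSE)
  }
  m <- bm$biomass[rows, , drop = FALSE]
  if (!is.null(groups)) {
    missing <- setdiff(groups, colnames(m))
    if (length(missing)) {
      stop("unknown group code(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- m[, groups, drop = FALSE]
  }
  tot <- rowSums(m)
  if (any(tot == 0)) {
    drop <- which(tot == 0)
    warning("dropping ", length(drop), " occasion(s) with zero biomass at site ",
            site_id, call. = FALSE)
    m <- m[-drop, , drop = FALSE]
    dates <- dates[-drop]
    tot <- tot[-drop]
    if (length(dates) < 2) stop("fewer than 2 usable occasions", call. = FALSE)
  }
  prof <- m / tot
  n <- nrow(prof)
  delta <- as.numeric(dates[-1] - dates[-n])
  sr <- vapply(seq_len(n - 1), function(i) {
    succession_rate(prof[i, ], prof[i + 1, ], delta[i])
  }, numeric(1))
  structure(list(
    site_id = site_id,
    timepoints = dates,
    profiles = prof,
    intervals = data.frame(a = dates[-n], b = dates[-1],
                           delta_days = delta, SR = sr)
  ), class = "succession_series")
}

#' @export
print.succession_series <- function(x, ...) {
  cat("<succession_series> site ", x$site_id, ": ", length(x$timepoints),
      " occasions, ", nrow(x$intervals), " intervals; mean SR ",
      format(round_half_up(mean(x$intervals$SR), 3), nsmall = 3), " /d\n", sep = "")
  invisible(x)
}

#' Aggregate succession rates by month, year or site
#'
#' Arithmetic mean of the interval succession rates, grouped by calendar
#' month (01-12), calendar year, or site. An interval is attributed to the
#' month/year of its endpoint `b`. Empty groups are omitted.
#'
#' @param series A `succession_series` or a list of them (typically one per
#'   site).
#' @param by One of `"month"`, `"year"`, `"site"`.
#' @return A `data.frame` with columns `group_key`, `mean_SR_per_day`,
#'   `n_intervals`. Means are exact; round with [round_half_up()] to the
#'   three decimals conventionally reported.
#' @export
aggregate_sr <- function(series, by = c("month", "year", "site")) {
  by <- match.arg(by)
  if (inherits(series, "succession_series")) series <- list(series)
  stopifnot(length(series) > 0,
            all(vapply(series, inherits, TRUE, "succession_series")))
  iv <- do.call(rbind, lapply(series, function(s) {
    cbind(s$intervals, site = s$site_id, stringsAsFactors = FALSE)
  }))
  key <- switch(by,
                month = format(iv$b, "%m"),
                year  = format(iv$b, "%Y"),
                site  = iv$site)
  agg <- stats::aggregate(iv$SR, by = list(group_key = key),
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(group_key = agg$group_key,
                    mean_SR_per_day = agg$x[, 1],
                    n_intervals = as.integer(agg$x[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$group_key), , drop = FALSE]
}
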