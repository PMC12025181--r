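# internal helpers shared across modules

PHYLA <- c("Chlorophyta", "Bacillariophyta", "Cyanophyta", "Dinophyta",
           "Euglenophyta", "Cryptophyta", "Chrysophyta")

ENV_VARS <- c("WT", "pH", "DO", "SD", "TN", "TP", "NH3N", "CODMn")

#' Round half up
#'
#' Decimal rounding where ties go away from zero (`0.005 -> 0.01`), the
#' convention used when reporting percentage shares, rather than the
#' banker's rounding of [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(45.265, 2.5), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

sample_key <- function(site, date) paste(site, format(date, "%Y-%m-%d"), sep = "@")

# parse ISO dates, erroring with the offending rows named
parse_dates <- function(x, what = "date") {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (any(is.na(d))) {
    rows <- if (length(bad)) bad else which(is.na(d))
    stop("unparseable ", what, " in row(s): ", paste(utils::head(rows, 10), collapse = ", "),
         " (expected ISO-8601 YYYY-MM-DD)", call. = FALSE)
  }
  d
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
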