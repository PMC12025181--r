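# Community-environment statistical layer: distance matrices, PCA with
# eigenvalue-share variance, permutation Mantel test, permutation analysis of
# multivariate dispersion, and hierarchical partitioning of RDA explained
# variance. Distance, Mantel and dispersion computations are delegated to
# vegan; the hierarchical partitioning is implemented here.

#' Pairwise sample distances
#'
#' Bray-Curtis (for community composition) or Euclidean (for environmental
#' variables) distances between sample rows.
#'
#' @param m A numeric sample x feature matrix, or an `fg_biomass` object (its
#'   biomass matrix is used).
#' @param metric `"bray_curtis"` or `"euclidean"`.
#' @return An object of class `phyto_dist`: `labels`, square symmetric
#'   matrix `d` with zero diagonal, and `metric`.
#' @export
community_distance <- function(m, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  if (inherits(m, "fg_biomass")) m <- m$biomass
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (metric == "bray_curtis") {
    if (any(m < 0)) stop("Bray-Curtis needs non-negative input", call. = FALSE)
    if (any(rowSums(m) == 0)) {
      stop("Bray-Curtis undefined for all-zero sample row(s): ",
           paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
    }
  }
  d <- vegan::vegdist(m, method = if (metric == "bray_curtis") "bray" else "euclidean")
  structure(list(labels = rownames(m), d = as.matrix(d), metric = metric),
            class = "phyto_dist")
}

#' @export
print.phyto_dist <- function(x, ...) {
  cat("<phyto_dist> ", length(x$labels), " samples, metric ", x$metric, "\n", sep = "")
  invisible(x)
}

#' Principal component analysis with eigenvalue-share variance
#'
#' Centered (optionally z-scored) PCA of a sample x feature matrix. The
#' variance explained by each component is its eigenvalue divided by the sum
#' of all eigenvalues, so the fractions sum to 1.
#'
#' @param m Numeric sample x feature matrix (>= 2 samples and features).
#' @param scale Standardise features to unit variance first? A constant
#'   feature with `scale = TRUE` is an error naming the feature.
#' @return A list with `scores`, `loadings`, `eigenvalues` and
#'   `variance_fraction`.
#' @export
pca_summary <- function(m, scale = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("PCA needs >= 2 samples and >= 2 features",
                                       call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (scale && any(sds == 0)) {
    nm <- colnames(m) %||% as.character(seq_len(ncol(m)))
    stop("constant feature(s) cannot be scaled: ",
         paste(nm[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = scale)
  ev <- fit$sdev^2
  list(scores = fit$x, loadings = fit$rotation, eigenvalues = ev,
       variance_fraction = ev / sum(ev))
}

#' Permutation Mantel test
#'
#' Pearson (or Spearman) correlation between the vectorised off-diagonal
#' entries of two distance matrices over the same samples, with a one-sided
#' permutation p-value: `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`,
#' permuting the row/column order of the second matrix jointly.
#'
#' @param d1,d2 `phyto_dist` objects with identical labels in identical order.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed controlling the permutations (required for
#'   reproducibility).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `mantel_result`: `r`, `p`, `n_perm`, `seed`,
#'   `method`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(d1, "phyto_dist"), inherits(d2, "phyto_dist"), n_perm >= 99)
  if (!identical(d1$labels, d2$labels)) {
    stop("distance matrices are over different samples or a different order",
         call. = FALSE)
  }
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(d1$d), stats::as.dist(d2$d),
                       method = method, permutations = n_perm)
  structure(list(r = unname(fit$statistic), p = fit$signif,
                 n_perm = n_perm, seed = seed, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("<mantel_result> r = ", signif(x$r, 4), ", p = ", signif(x$p, 4),
      " (", x$method, ", ", x$n_perm, " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Permutation test of multivariate dispersion homogeneity
#'
#' Embeds the distance matrix by principal coordinates (with the standard
#' correction for negative eigenvalues), measures each sample's distance to
#' its own group centroid, and tests the one-way ANOVA F statistic on those
#' distances against permutations of the group labels.
#'
#' @param d A `phyto_dist` object.
#' @param groups Group membership: factor/character vector of
#'   `length(d$labels)`, or named with the labels. At least 2 groups, each
#'   with at least 2 members.
#' @param n_perm Number of permutations.
#' @param seed Integer seed (required).
#' @return An object of class `dispersion_result`: `group_means` (mean
#'   distance to centroid per group), `F`, `p`, `n_perm`, `seed`.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed) {
  stopifnot(inherits(d, "phyto_dist"))
  if (!is.null(names(groups))) groups <- groups[d$labels]
  groups <- factor(groups)
  if (length(groups) != length(d$labels) || anyNA(groups)) {
    stop("groups must cover every sample label", call. = FALSE)
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("singleton group(s): ",
         paste(names(which(table(groups) < 2)), collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  mod <- vegan::betadisper(stats::as.dist(d$d), groups, type = "centroid")
  pt <- vegan::permutest(mod, permutations = n_perm)
  structure(list(
    group_means = tapply(mod$distances, groups, mean),
    distances = mod$distances,
    F = unname(pt$tab[1, "F"]),
    p = pt$tab[1, "Pr(>F)"],
    n_perm = n_perm, seed = seed
  ), class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("<dispersion_result> F = ", signif(x$F, 4), ", p = ", signif(x$p, 4),
      " (", x$n_perm, " permutations, seed ", x$seed, ")\n", sep = "")
  print(round(x$group_means, 4))
  invisible(x)
}

# R^2 of the multivariate linear model of (transformed, centered) Y on the
# predictor subset S; explained sum of squares over total sum of squares,
# the RDA explained-variance fraction.
rda_r2 <- function(Y, X, subset_idx) {
  if (length(subset_idx) == 0) return(0)
  Xs <- as.matrix(X[, subset_idx, drop = FALSE])
  qrx <- qr(cbind(1, Xs))
  fitted <- qr.fitted(qrx, Y)
  # Y is column-centered, so fitted values of the intercept-only model are 0
  sum(fitted^2) / sum(Y^2)
}

#' Hierarchical partitioning of RDA explained variance
#'
#' Quantifies each environmental predictor's contribution to the variance of
#' a (transformed) community matrix explained by redundancy analysis. For
#' every subset `S` of predictors, `R2(S)` is the explained-variance fraction
#' of the multivariate linear model of the transformed response on `S`; the
#' individual contribution of predictor `j` is the average, over all
#' orderings of the predictors, of the `R2` increment when `j` enters
#' (Chevan-Sutherland hierarchical partitioning). The individual
#' contributions sum exactly to `R2` of the full model. Joint contribution
#' `= R2({j}) - individual(j)`; individual contributions can be slightly
#' negative, which is reported, not truncated.
#'
#' @param response Sample x group matrix (biomass or abundance), or an
#'   `fg_biomass` object.
#' @param predictors `data.frame` of numeric environmental predictors (at
#'   most 12; all-subsets enumeration is `2^p`), or a `phyto_env` object
#'   (its eight variables). Rows with missing values are dropped with a
#'   message; rows must align with the response.
#' @param transform Community transformation before the fit: `"hellinger"`
#'   (default; square root of relative abundance), `"log1p"` or `"none"`.
#' @return An object of class `hier_part`: `predictors`, `total_r2`,
#'   `individual`, `joint`, `residual` (`1 - total_r2`) and
#'   `negative_individual` flag.
#' @export
hierarchical_partition <- function(response, predictors,
                                   transform = c("hellinger", "log1p", "none")) {
  transform <- match.arg(transform)
  if (inherits(response, "fg_biomass")) response <- response$biomass
  Y <- as.matrix(response)
  if (inherits(predictors, "phyto_env")) predictors <- predictors$env
  X <- as.data.frame(predictors)
  if (!all(vapply(X, is.numeric, TRUE))) {
    stop("predictors must all be numeric", call. = FALSE)
  }
  if (nrow(X) != nrow(Y)) stop("response and predictors have different row counts",
                               call. = FALSE)
  p <- ncol(X)
  if (p < 1) stop("need at least one predictor", call. = FALSE)
  if (p > 12) stop("at most 12 predictors supported (all-subsets is 2^p)",
                   call. = FALSE)

  cc <- stats::complete.cases(X)
  if (!all(cc)) {
    message("hierarchical_partition: dropped ", sum(!cc),
            " incomplete sample(s)")
    X <- X[cc, , drop = FALSE]
    Y <- Y[cc, , drop = FALSE]
  }
  if (nrow(Y) <= p + 1) stop("too few complete samples for ", p, " predictors",
                             call. = FALSE)

  Y <- switch(transform,
              hellinger = {
                if (any(Y < 0)) stop("hellinger needs non-negative response",
                                     call. = FALSE)
                rs <- rowSums(Y)
                if (any(rs == 0)) stop("hellinger undefined for all-zero rows",
                                       call. = FALSE)
                sqrt(Y / rs)
              },
              log1p = log1p(Y),
              none = Y)
  Y <- scale(Y, center = TRUE, scale = FALSE)

  # singularity screen on the full design
  qrf <- qr(cbind(1, scale(as.matrix(X))))
  if (qrf$rank < p + 1) {
    aliased <- colnames(X)[qrf$pivot[seq(qrf$rank + 1, p + 1)] - 1]
    stop("collinear-to-singularity design; aliased predictor(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  # R2 for every subset, indexed by bitmask
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    r2[mask + 1] <- rda_r2(Y, X, idx)
  }
  total <- r2[2^p]

  # Chevan-Sutherland weights: |S|! (p-|S|-1)! / p!
  fact <- factorial(0:p)
  individual <- numeric(p)
  for (j in seq_len(p)) {
    bit <- 2^(j - 1)
    inc <- 0
    for (mask in 0:(2^p - 1)) {
      if (bitwAnd(mask, bit) > 0) next
      s <- sum(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
      w <- fact[s + 1] * fact[p - s] / fact[p + 1]
      inc <- inc + w * (r2[mask + bit + 1] - r2[mask + 1])
    }
    individual[j] <- inc
  }
  names(individual) <- colnames(X)
  marginal <- vapply(seq_len(p), function(j) r2[2^(j - 1) + 1], numeric(1))
  joint <- stats::setNames(marginal - individual, colnames(X))

  structure(list(
    predictors = colnames(X), total_r2 = total,
    individual = individual, joint = joint,
    residual = 1 - total,
    negative_individual = any(individual < 0)
  ), class = "hier_part")
}

#' @export
print.hier_part <- function(x, ...) {
  cat("<hier_part> total R2 = ", signif(x$total_r2, 4), " over ",
      length(x$predictors), " predictors; residual ", signif(x$residual, 4),
      "\n", sep = "")
  tab <- data.frame(individual = round(x$individual, 4),
                    joint = round(x$joint, 4))
  print(tab)
  if (x$negative_individual) {
    cat("  note: negative individual contribution(s) reported as-is\n")
  }
  invisible(x)
}

#' Share of the total explained variance carried by selected predictors
#'
#' Report formatter for hierarchical-partitioning outputs: the percentage of
#' the total interpretation rate accounted for by a set of per-predictor
#' rates, rounded half-up to two decimals. Both arguments are on the same
#' scale (fractions or percents).
#'
#' @param rates Per-predictor contribution rates.
#' @param total Total interpretation rate.
#' @return `sum(rates) / total * 100`, rounded half-up to 2 decimals.
#' @export
#' @examples
#' hp_contribution_share(c(8.82, 8.78, 3.94), 30.90)  # 69.71
hp_contribution_share <- function(rates, total) {
  stopifnot(is.numeric(rates), is.numeric(total), length(total) == 1, total > 0)
  round_half_up(sum(rates) / total * 100, 2)
}
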