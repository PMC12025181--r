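# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written as plain loops over definitions,
# sharing no code with R/.

oracle_sr <- function(fa, fb, delta_days) {
  tot <- 0
  for (i in seq_along(fa)) tot <- tot + abs(fb[[i]] - fa[[i]])
  tot / delta_days
}

oracle_avd <- function(m, denom = "n-1") {
  k <- nrow(m)
  tot <- 0
  n <- 0
  per_group <- c()
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    mu <- sum(x) / k
    ss <- 0
    for (v in x) ss <- ss + (v - mu)^2
    dl <- sqrt(ss / if (denom == "n-1") (k - 1) else k)
    if (dl == 0) next
    n <- n + 1
    for (v in x) tot <- tot + abs(v - mu) / dl
  }
  if (n == 0) stop("oracle: no variable groups")
  tot / (k * n)
}

oracle_dominance_Y <- function(m) {
  N <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) N <- N + m[i, j]
  Y <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    Ni <- 0
    pres <- 0
    for (i in seq_len(nrow(m))) {
      Ni <- Ni + m[i, j]
      if (m[i, j] > 0) pres <- pres + 1
    }
    Y[j] <- (Ni / N) * (pres / nrow(m))
  }
  Y
}

oracle_bray <- function(x, y) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# distances to own-group centroid in raw coordinate space (valid oracle for
# Euclidean distance matrices), then the classical one-way ANOVA F on them
oracle_permdisp_F <- function(coords, groups) {
  groups <- as.character(groups)
  d <- numeric(nrow(coords))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cen <- colMeans(coords[idx, , drop = FALSE])
    for (i in idx) d[i] <- sqrt(sum((coords[i, ] - cen)^2))
  }
  k <- length(unique(groups))
  N <- length(d)
  gm <- mean(d)
  ssb <- 0
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    mg <- mean(d[idx])
    ssb <- ssb + length(idx) * (mg - gm)^2
    for (i in idx) ssw <- ssw + (d[i] - mg)^2
  }
  (ssb / (k - 1)) / (ssw / (N - k))
}

# hierarchical partitioning by explicit enumeration of all p! orderings,
# with subset R^2 from stats::lm on the centered response
oracle_hp_individual <- function(Y, X) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  p <- ncol(X)
  tss <- sum(Y^2)
  r2_of <- function(idx) {
    if (length(idx) == 0) return(0)
    fit <- stats::lm(Y ~ ., data = X[, idx, drop = FALSE])
    1 - sum(stats::residuals(fit)^2) / tss
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  ind <- numeric(p)
  all_ord <- perms(seq_len(p))
  for (ord in all_ord) {
    sofar <- integer(0)
    for (j in ord) {
      ind[j] <- ind[j] + r2_of(c(sofar, j)) - r2_of(sofar)
      sofar <- c(sofar, j)
    }
  }
  stats::setNames(ind / length(all_ord), colnames(X))
}

# random unit-sum composition vector
rand_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}
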