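test_that("distances match definitions and reject degenerate input", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(0, 0, 5))
  d <- community_distance(m, "bray_curtis")
  expect_equal(d$d["a", "b"], 0)
  # disjoint support -> Bray-Curtis 1
  m2 <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 2, 2))
  expect_equal(community_distance(m2, "bray_curtis")$d["a", "b"], 1)
  expect_error(community_distance(rbind(c(1, 1), c(0, 0)), "bray_curtis"),
               "all-zero")

  set.seed(21)
  for (rep in 1:100) {
    m <- matrix(rexp(20), 5, 4)
    d <- community_distance(m, "bray_curtis")$d
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(d[i, j], oracle_bray(m[i, ], m[j, ]), tolerance = 1e-12)
      expect_equal(d[i, j], d[j, i])
    }
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("PCA variance fractions are eigenvalue shares", {
  # two perfectly correlated features: PC1 carries everything
  x <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  p <- pca_summary(x)
  expect_equal(p$variance_fraction[1], 1)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)

  set.seed(8)
  m <- matrix(rnorm(12), 4, 3)
  p2 <- pca_summary(m)
  # eigenvalues of the covariance matrix, independently
  ev <- sort(eigen(cov(m), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(unname(p2$eigenvalues), ev, tolerance = 1e-9)
  expect_equal(sum(p2$variance_fraction), 1, tolerance = 1e-9)

  # feature reordering leaves the spectrum alone
  p3 <- pca_summary(m[, c(3, 1, 2)])
  expect_equal(p3$eigenvalues, p2$eigenvalues, tolerance = 1e-9)

  m_const <- cbind(m, k = 1)
  expect_error(pca_summary(m_const, scale = TRUE), "k")
})

test_that("mantel_test recovers identity and affine relationships", {
  set.seed(31)
  m <- matrix(rnorm(30), 10, 3)
  d1 <- community_distance(m, "euclidean")
  r_self <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(r_self$r, 1, tolerance = 1e-12)
  expect_lte(r_self$p, 0.05)

  d2 <- d1
  d2$d <- 0.3 * d1$d + 2
  diag(d2$d) <- 0
  expect_equal(mantel_test(d1, d2, n_perm = 99, seed = 1)$r, 1,
               tolerance = 1e-9)

  d3 <- d1
  d3$labels <- rev(d3$labels)
  expect_error(mantel_test(d1, d3, n_perm = 99, seed = 1), "different")

  # p-value floor respected and result reproducible under the same seed
  p1 <- mantel_test(d1, d1, n_perm = 99, seed = 42)
  p2 <- mantel_test(d1, d1, n_perm = 99, seed = 42)
  expect_identical(p1$p, p2$p)
  expect_gte(p1$p, 1 / 100)
})

test_that("permdisp F equals the classical ANOVA on centroid distances", {
  set.seed(13)
  for (rep in 1:100) {
    n_per <- sample(3:5, 3, replace = TRUE)
    groups <- rep(c("g1", "g2", "g3"), n_per)
    coords <- matrix(rnorm(length(groups) * 3), ncol = 3)
    rownames(coords) <- paste0("s", seq_along(groups))
    d <- community_distance(coords, "euclidean")
    res <- permdisp(d, setNames(groups, rownames(coords)), n_perm = 19, seed = rep)
    expect_equal(res$F, oracle_permdisp_F(coords, groups), tolerance = 1e-9)
  }
})

test_that("permdisp handles degenerate groups as specified", {
  # a group collapsed onto a single point has zero mean distance to centroid
  coords <- rbind(matrix(rnorm(12), 4, 3),
                  matrix(rep(c(5, 5, 5), 4), 4, 3, byrow = TRUE))
  rownames(coords) <- paste0("s", 1:8)
  d <- community_distance(coords, "euclidean")
  g <- rep(c("spread", "point"), each = 4)
  res <- permdisp(d, g, n_perm = 99, seed = 2)
  expect_equal(unname(res$group_means["point"]), 0, tolerance = 1e-9)

  expect_error(permdisp(d, c(rep("a", 7), "b"), n_perm = 99, seed = 2),
               "singleton")
})

test_that("hierarchical partitioning decomposes R2 exactly", {
  set.seed(17)
  # single predictor: individual contribution is the whole R2
  X1 <- data.frame(a = rnorm(20))
  Y <- matrix(rnorm(40), 20, 2) + cbind(X1$a, -X1$a)
  hp1 <- hierarchical_partition(Y, X1, transform = "none")
  expect_equal(unname(hp1$individual["a"]), hp1$total_r2, tolerance = 1e-12)

  # orthogonal predictors: individual = marginal R2, joint = 0
  a <- rep(c(-1, 1), each = 10)
  b <- rep(c(-1, 1), times = 10)
  Xo <- data.frame(a = a, b = b)
  Yo <- matrix(rnorm(40, sd = 0.1), 20, 2) + cbind(a + b, a - b)
  hpo <- hierarchical_partition(Yo, Xo, transform = "none")
  m_a <- hierarchical_partition(Yo, Xo["a"], transform = "none")$total_r2
  m_b <- hierarchical_partition(Yo, Xo["b"], transform = "none")$total_r2
  expect_equal(unname(hpo$individual["a"]), m_a, tolerance = 1e-9)
  expect_equal(unname(hpo$individual["b"]), m_b, tolerance = 1e-9)
  expect_equal(unname(hpo$joint), c(0, 0), tolerance = 1e-9)

  # individual contributions match the all-orderings oracle
  for (rep in 1:20) {
    X <- as.data.frame(matrix(rnorm(45), 15, 3))
    Y <- matrix(rnorm(60), 15, 4) + X[[1]] %o% rnorm(4)
    hp <- hierarchical_partition(Y, X, transform = "none")
    expect_equal(hp$individual, oracle_hp_individual(Y, X), tolerance = 1e-9)
    expect_equal(sum(hp$individual), hp$total_r2, tolerance = 1e-9)
  }

  # the decomposition identity holds for p = 4 too
  X4 <- as.data.frame(matrix(rnorm(100), 25, 4))
  Y4 <- matrix(rnorm(75), 25, 3)
  hp4 <- hierarchical_partition(Y4, X4, transform = "none")
  expect_equal(sum(hp4$individual), hp4$total_r2, tolerance = 1e-9)

  # collinear design is rejected with the aliased predictor named
  Xc <- data.frame(a = rnorm(20))
  Xc$b <- 2 * Xc$a
  expect_error(hierarchical_partition(matrix(rnorm(40), 20, 2), Xc,
                                      transform = "none"), "b")
})

test_that("hellinger transform is applied before partitioning", {
  set.seed(23)
  comm <- matrix(rexp(60), 20, 3)
  X <- data.frame(a = rnorm(20))
  hp_h <- hierarchical_partition(comm, X)  # default hellinger
  hp_manual <- hierarchical_partition(sqrt(comm / rowSums(comm)), X,
                                      transform = "none")
  expect_equal(hp_h$total_r2, hp_manual$total_r2, tolerance = 1e-12)
  expect_error(hierarchical_partition(-comm, X), "non-negative")
})

test_that("explained-variance shares are formatted half-up", {
  expect_equal(hp_contribution_share(c(10), 40), 25)
  expect_equal(hp_contribution_share(c(1, 1, 1), 3), 100)
})
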