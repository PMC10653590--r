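test_that("PCA matches the two-variable closed form and conserves
          variance", {
  Z <- with_seed(4, MASS::mvrnorm(200, c(0, 0),
                                  matrix(c(1, 0.6, 0.6, 1), 2),
                                  empirical = TRUE))
  dimnames(Z) <- list(paste0("r", 1:200), c("a", "b"))
  pc <- pca_families(Z)
  expect_equal(pc$var_explained[1], 100 * (1 + 0.6) / 2,
               tolerance = 1e-9)
  expect_equal(sum(pc$var_explained), 100, tolerance = 1e-9)
})

test_that("PCA loadings are orthonormal, sign-fixed, and reconstruct the
          scaled data", {
  M <- with_seed(5, matrix(stats::rnorm(20 * 6), 20, 6,
                           dimnames = list(paste0("s", 1:20),
                                           paste0("f", 1:6))))
  pc <- pca_families(M)
  expect_equal(crossprod(pc$loadings), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (j in seq_len(6)) {
    l <- pc$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  recon <- pc$scores %*% t(pc$loadings)
  expect_equal(recon, scale(M), tolerance = 1e-9, ignore_attr = TRUE)
  M0 <- M; M0[, 3] <- 1
  expect_error(pca_families(M0), "f3")
})

test_that("ancestral states equal closed forms and the brute-force GLS
          oracle", {
  t2 <- ape::read.tree(text = "(a:2,b:3);")
  a2 <- ancestral_states(t2, c(a = 1, b = 4))
  expect_equal(a2$estimate, (1 / 2 + 4 / 3) / (1 / 2 + 1 / 3),
               tolerance = 1e-12)
  # constant trait: every node estimate equals the constant
  t8 <- with_seed(18, ape::rtree(8))
  ac <- ancestral_states(t8, stats::setNames(rep(2.5, 8),
                                             t8$tip.label))
  expect_equal(ac$estimate, rep(2.5, t8$Nnode), tolerance = 1e-10)
  # random trees up to 10 tips against the matrix oracle
  for (s in 18:20) {
    tr <- with_seed(s, ape::rtree(sample(4:10, 1)))
    x <- with_seed(s + 100,
                   stats::setNames(stats::rnorm(length(tr$tip.label)),
                                   tr$tip.label))
    a <- ancestral_states(tr, x)
    expect_equal(a$estimate, anc_oracle(tr, x), tolerance = 1e-8)
    expect_true(all(a$variance >= 0))
  }
  skip_if_not_installed("phytools")
  x8 <- with_seed(3, stats::setNames(stats::rnorm(8), t8$tip.label))
  fa <- phytools::fastAnc(t8, x8)
  expect_equal(ancestral_states(t8, x8)$estimate, as.numeric(fa),
               tolerance = 1e-8)
})

test_that("the correlation audit reproduces textbook Pearson values", {
  x <- c(1, 2, 4, 5, 7, 8, 9, 11, 12, 15)
  expect_equal(qc_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  # constructed orthogonal pair
  y <- x^2
  y <- y - mean(y) - stats::cov(x, y) / stats::var(x) * (x - mean(x))
  expect_equal(qc_correlation(x, y)$r, 0, tolerance = 1e-12)
  # textbook formula on a fixed 10-point set
  y2 <- c(2.1, 2.6, 3.1, 4.9, 6.0, 7.2, 8.1, 9.3, 11.8, 13.2)
  r_formula <- sum((x - mean(x)) * (y2 - mean(y2))) /
    sqrt(sum((x - mean(x))^2) * sum((y2 - mean(y2))^2))
  out <- qc_correlation(x, y2)
  expect_equal(out$r, r_formula, tolerance = 1e-12)
  expect_equal(out$t, r_formula * sqrt(8 / (1 - r_formula^2)),
               tolerance = 1e-10)
  expect_error(qc_correlation(x, rep(1, 10)), "variance")
  expect_error(qc_correlation(1:2, 1:2), "3")
})
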