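test_that("on a star tree the contrasts equal the OLS Tukey-type
          oracle", {
  st <- ape::stree(15, "star")
  st$edge.length <- rep(1, 15)
  st$tip.label <- paste0("s", 1:15)
  g <- stats::setNames(rep(c("g1", "g2", "g3"), each = 5), st$tip.label)
  y <- with_seed(2, stats::setNames(stats::rnorm(15) +
                                      (g == "g2") * 1.5, st$tip.label))
  pt <- phylo_tukey(st, y, g, adjust = "holm")
  # textbook OLS oracle: group means, pooled variance, all-pairs SEs
  means <- tapply(y, g, mean)
  s2 <- sum((y - means[g])^2) / (15 - 3)
  se <- sqrt(s2 * (1 / 5 + 1 / 5))
  est_oracle <- c(means["g2"] - means["g1"], means["g3"] - means["g1"],
                  means["g3"] - means["g2"])
  expect_equal(pt$estimate, unname(est_oracle), tolerance = 1e-10)
  expect_equal(pt$se, rep(se, 3), tolerance = 1e-10)
  z_oracle <- unname(est_oracle) / se
  expect_equal(pt$z, z_oracle, tolerance = 1e-10)
  expect_equal(pt$p_adj,
               stats::p.adjust(2 * stats::pnorm(-abs(z_oracle)), "holm"),
               tolerance = 1e-10)
})

test_that("single-step adjustment dominates raw p and tracks an external
          max-|t| implementation", {
  tr <- fx_tree24()
  g <- fx_groups24()
  x <- simulate_traits(tr, "BM", seed = 3)[, 1]
  pt <- phylo_tukey(tr, x, g, adjust = "single-step", nsim = 50000,
                    seed = 1)
  expect_true(all(pt$p_adj >= pt$p_raw - 1e-12))
  expect_true(all(pt$p_adj <= 1 & pt$p_raw >= 0))
  skip_if_not_installed("multcomp")
  # GLS == OLS after whitening by the Brownian covariance
  C <- ape::vcv(tr)[names(x), names(x)]
  L <- chol(C)
  yw <- backsolve(L, x, transpose = TRUE)
  Xw <- backsolve(L, stats::model.matrix(~ 0 + factor(g[names(x)])),
                  transpose = TRUE)
  fit <- stats::lm(yw ~ 0 + Xw)
  K <- matrix(c(-1, 1, 0, -1, 0, 1, 0, -1, 1), 3, byrow = TRUE)
  s <- summary(multcomp::glht(fit, linfct = K))
  expect_equal(unname(s$test$coefficients), pt$estimate,
               tolerance = 1e-8)
  expect_equal(unname(s$test$sigma), pt$se, tolerance = 1e-8)
  # multcomp uses max-|t| (df = 21) vs our max-|z|: same ordering, close p
  expect_equal(order(as.numeric(s$test$pvalues)), order(pt$p_adj))
  expect_lt(max(abs(as.numeric(s$test$pvalues) - pt$p_adj)), 0.05)
})

test_that("a planted group shift is the most significant contrast", {
  tr <- fx_tree24()
  g <- fx_groups24()
  sdp <- sqrt(mean(diag(ape::vcv(tr))))
  hits <- 0L
  for (r in 1:100) {
    x <- simulate_traits(tr, "BM", seed = 1500 + r)[, 1]
    x[g[names(x)] == "b"] <- x[g[names(x)] == "b"] + 2 * sdp
    pt <- phylo_tukey(tr, x, g, adjust = "holm")
    hits <- hits + grepl("b", pt$contrast[which.min(pt$p_adj)])
  }
  expect_gte(hits, 80L)
  expect_error(phylo_tukey(tr, simulate_traits(tr, "BM", seed = 1)[, 1],
                           stats::setNames(rep("a", 24),
                                           tr$tip.label)),
               "2 groups")
})

test_that("multivariate fits reduce to the univariate fits for a single
          trait", {
  tr <- fx_tree64()
  preds <- data.frame(lifestyle = rep(c("terrestrial", "fossorial"), 32),
                      row.names = tr$tip.label)
  x <- simulate_traits(tr, "BM", seed = 10)
  mc <- fit_multivariate(tr, x, preds, c("BM", "OU:lifestyle"))
  expect_equal(mc$fits$BM$logLik, fit_bm(tr, x[, 1])$logLik,
               tolerance = 1e-6)
  reg <- stats::setNames(preds$lifestyle, rownames(preds))
  expect_equal(mc$fits[["OU:lifestyle"]]$logLik,
               fit_ou(tr, x[, 1], reg)$logLik, tolerance = 1e-4)
  expect_identical(mc$criterion, "AICc")
  expect_true(all(c("pillai", "chi2", "p_value") %in%
                    names(mc$manova)))
  # p >= n rejected
  bigY <- with_seed(44, matrix(stats::rnorm(64 * 70), 64, 70,
                               dimnames = list(tr$tip.label, NULL)))
  expect_error(fit_multivariate(tr, bigY, preds, "BM"), "p >= n")
})
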