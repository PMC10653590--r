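test_that("lambda ML matches the grid oracle and an external
          implementation on BM data", {
  tr <- fx_tree64()
  x <- simulate_traits(tr, "BM", sigma2 = 1, seed = 11)[, 1]
  pl <- pagel_lambda(tr, x)
  orc <- grid_lambda_oracle(tr, x)
  expect_gte(pl$lambda, 0.9)
  expect_lt(pl$p_value, 0.05)
  expect_lte(abs(pl$lambda - orc$lambda), orc$spacing)
  skip_if_not_installed("phytools")
  ps <- phytools::phylosig(tr, x, method = "lambda", test = TRUE)
  expect_equal(pl$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(pl$loglik, ps$logL, tolerance = 1e-6)
})

test_that("permuting trait values across tips destroys the signal", {
  tr <- fx_tree64()
  x <- simulate_traits(tr, "BM", sigma2 = 1, seed = 11)[, 1]
  lams <- vapply(1:20, function(s) {
    xp <- with_seed(s, stats::setNames(x[sample(64)], names(x)))
    pagel_lambda(tr, xp)$lambda
  }, numeric(1))
  expect_lte(stats::median(lams), 0.1)
})

test_that("lambda endpoints collapse to iid-normal and BM likelihoods", {
  tr <- fx_tree64()
  x <- simulate_traits(tr, "BM", sigma2 = 1, seed = 11)[, 1]
  pl <- pagel_lambda(tr, x)
  # lambda = 1 is the BM likelihood
  expect_equal(pl$loglik1, fit_bm(tr, x)$logLik, tolerance = 1e-9)
  # lambda = 0 on a unit-depth tree is the iid normal MLE likelihood
  mu <- mean(x); s2 <- mean((x - mu)^2)
  ll_iid <- sum(stats::dnorm(x, mu, sqrt(s2), log = TRUE))
  # tree depth is 6, so rescale to unit depth for the iid comparison
  tr1 <- tr; tr1$edge.length <- tr$edge.length / 6
  expect_equal(pagel_lambda(tr1, x)$loglik0, ll_iid, tolerance = 1e-9)
  # affine invariance of the estimate
  expect_equal(pagel_lambda(tr, 3 + 2 * x)$lambda, pl$lambda,
               tolerance = 1e-6)
  expect_error(pagel_lambda(tr, stats::setNames(rep(1, 64),
                                                tr$tip.label)),
               "variance")
})

test_that("BM MLEs match the two-taxon closed form and are unbiased in
          rate", {
  t2 <- ape::read.tree(text = "(a:2,b:3);")
  xb <- c(a = 1, b = 4)
  f <- fit_bm(t2, xb)
  expect_equal(f$params$root, (1 / 2 * 1 + 1 / 3 * 4) / (1 / 2 + 1 / 3),
               tolerance = 1e-12)
  expect_equal(f$params$sigma2, (1 - 4)^2 / (2 * (2 + 3)),
               tolerance = 1e-12)
  expect_equal(f$AIC, 2 * 2 - 2 * f$logLik, tolerance = 1e-12)
  # constant trait: rate at the zero boundary, flagged
  fc <- fit_bm(t2, c(a = 2, b = 2))
  expect_true(fc$details$sigma2_at_zero)
  # relative bias of sigma2 over 200 replicates below 5%
  tr <- fx_tree64()
  X <- simulate_traits(tr, "BM", sigma2 = 1, reps = 200, seed = 21)
  s2 <- apply(X, 2, function(xx)
    fit_bm(tr, stats::setNames(xx, rownames(X)))$params$sigma2)
  expect_lt(abs(mean(s2) - 1), 0.05)
})

test_that("OU with two regimes recovers the optima and outranks BM on OU
          data", {
  tr <- fx_tree64()
  reg <- stats::setNames(rep(c("A", "B"), each = 32), tr$tip.label)
  th <- matrix(0, 100, 2); wins <- 0L
  for (r in 1:100) {
    x <- simulate_traits(tr, "OU", sigma2 = 10, alpha = 5,
                         theta = c(A = 0, B = 3), regimes = reg,
                         seed = 1300 + r)[, 1]
    fo <- fit_ou(tr, x, reg)
    th[r, ] <- fo$params$theta
    wins <- wins + (fo$AIC < fit_bm(tr, x)$AIC)
  }
  expect_lt(max(abs(colMeans(th) - c(0, 3))), 0.3)
  expect_gte(wins, 90L)
  # non-ultrametric trees are rejected with guidance
  bad <- ape::read.tree(text = "((a:1,b:2):1,c:1);")
  expect_error(fit_ou(bad, c(a = 1, b = 2, c = 3)), "ultrametric")
})
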