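# Phylogenetic signal and univariate evolutionary model fits: Pagel's
# lambda by maximum likelihood with a likelihood-ratio test, and BM / OU
# (with regimes) fits returning "phylofit" objects.

# Align a named trait vector (or factor) to tree tips after underscore
# normalization; mismatches are errors, never silent drops.
match_tips <- function(tree, x, what = "trait") {
  tips <- tree$tip.label
  norm <- function(s) gsub("\\s+", "_", trimws(s))
  nm <- norm(names(x))
  if (is.null(names(x))) {
    if (length(x) != length(tips))
      stop(what, " has no names and wrong length")
    names(x) <- tips
    return(x)
  }
  idx <- match(norm(tips), nm)
  if (anyNA(idx))
    stop(what, " missing for tips: ",
         paste(tips[is.na(idx)], collapse = ", "))
  out <- x[idx]
  names(out) <- tips
  out
}

# GLS with covariance V: profiled mean coefficients and ML variance.
.gls_core <- function(y, V, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  R <- chol(V)
  ys <- backsolve(R, y, transpose = TRUE)
  Xs <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  resid <- ys - Xs %*% beta
  rss <- sum(resid^2)
  logdetV <- 2 * sum(log(diag(R)))
  sigma2 <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  list(beta = drop(beta), sigma2_ml = sigma2, rss = rss,
       loglik = loglik, logdetV = logdetV, XtX = XtX, n = n, p = ncol(X))
}

#' Pagel's lambda by maximum likelihood with a likelihood-ratio test
#'
#' The off-diagonal entries of the phylogenetic covariance are scaled by
#' lambda in `[0, 1]`; the diffusion rate and root state are profiled out
#' analytically and lambda is optimized by golden-section search with
#' endpoint refinement. The LRT compares the ML fit against lambda = 0
#' (chi-square, 1 df); lambda = 1 recovers the Brownian-motion
#' likelihood.
#'
#' @param tree an `ape::phylo` tree.
#' @param trait named numeric vector (names matched to tip labels).
#' @return object of class `pagel_lambda`: lambda, loglik, loglik0,
#'   loglik1, lrt_stat, p_value, sigma2, root, at_boundary.
#' @export
pagel_lambda <- function(tree, trait) {
  x <- match_tips(tree, trait)
  n <- length(x)
  if (n < 4L) stop("need at least 4 species")
  if (stats::var(x) <= 0) stop("trait has zero variance")
  C <- ape::vcv(tree)
  dC <- diag(C)
  Vl <- function(l) l * C + diag((1 - l) * dC, n)
  ll <- function(l) .gls_core(x, Vl(l))$loglik
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE,
                         tol = .Machine$double.eps^0.35)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, ll(0)), c(1, ll(1)))
  best <- cand[which.max(cand[, 2L]), ]
  lam <- best[1L]; llhat <- best[2L]
  ll0 <- cand[2L, 2L]
  stat <- max(0, 2 * (llhat - ll0))
  fit <- .gls_core(x, Vl(lam))
  structure(list(lambda = lam, loglik = llhat, loglik0 = ll0,
                 loglik1 = cand[3L, 2L],
                 lrt_stat = stat,
                 p_value = stats::pchisq(stat, df = 1L,
                                         lower.tail = FALSE),
                 sigma2 = fit$sigma2_ml, root = unname(fit$beta),
                 at_boundary = lam %in% c(0, 1), n = n),
            class = "pagel_lambda")
}

#' @export
print.pagel_lambda <- function(x, ...) {
  cat(sprintf("Pagel's lambda: %.4f%s  logLik %.3f  LRT vs lambda=0: %.3f (P = %.3g)\n",
              x$lambda, if (x$at_boundary) " [boundary]" else "",
              x$loglik, x$lrt_stat, x$p_value))
  invisible(x)
}

.phylofit <- function(model, params, loglik, k, n, details = list()) {
  structure(list(model = model, params = params, logLik = loglik,
                 k = k, AIC = 2 * k - 2 * loglik, n = n,
                 details = details),
            class = "phylofit")
}

#' @export
print.phylofit <- function(x, ...) {
  cat("phylofit:", x$model, "\n  parameters:\n")
  for (nm in names(x$params)) {
    v <- x$params[[nm]]
    cat("   ", nm, "=", paste(signif(v, 5), collapse = ", "), "\n")
  }
  cat(sprintf("  logLik %.4f  k %d  AIC %.4f  (n = %d)\n",
              x$logLik, x$k, x$AIC, x$n))
  invisible(x)
}

#' @export
logLik.phylofit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
coef.phylofit <- function(object, ...) {
  unlist(object$params[intersect(c("root", "theta"),
                                 names(object$params))])
}

#' Fit Brownian motion to a continuous trait (ML)
#'
#' Closed-form GLS: the root state is the inverse-covariance-weighted
#' mean and the rate is the ML variance of the whitened residuals.
#'
#' @inheritParams pagel_lambda
#' @return a `phylofit` (model "BM", k = 2: sigma2 and root).
#' @export
fit_bm <- function(tree, trait) {
  x <- match_tips(tree, trait)
  C <- ape::vcv(tree)
  fit <- .gls_core(x, C)
  boundary <- fit$sigma2_ml < .Machine$double.eps * max(diag(C))
  .phylofit("BM",
            list(sigma2 = fit$sigma2_ml, root = unname(fit$beta)),
            fit$loglik, k = 2L, n = fit$n,
            details = list(sigma2_at_zero = boundary))
}

# Root-conditioned OU correlation structure (sigma2 factored out):
# V0_ij = exp(-alpha d_ij) (1 - exp(-2 alpha t_ij)) / (2 alpha),
# with t_ij the shared path length and d_ij the patristic distance.
# Continuous in alpha: V0 -> t_ij (the BM covariance) as alpha -> 0.
.ou_v0 <- function(alpha, C, D) {
  if (alpha < 1e-9) return(C)
  exp(-alpha * D) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
}

#' Fit an Ornstein-Uhlenbeck model (ML), optionally with regimes
#'
#' Root-conditioned OU covariance on a dated (ultrametric) tree:
#' `V_ij = sigma2/(2 alpha) * exp(-alpha d_ij) (1 - exp(-2 alpha t_ij))`
#' with `d_ij` the patristic distance and `t_ij` the shared path length,
#' so the model reduces to BM as `alpha -> 0`. Tip means are the optima
#' of the tip regimes; optima and rate are profiled analytically and
#' alpha is optimized on a log scale.
#'
#' @inheritParams pagel_lambda
#' @param regimes optional factor/character named by species mapping each
#'   tip to a selective regime; NULL fits a single optimum.
#' @return a `phylofit` (model "OU", k = 2 + number of regimes);
#'   parameters include alpha, sigma2 and the stationary variance
#'   `sigma2 / (2 alpha)`.
#' @export
fit_ou <- function(tree, trait, regimes = NULL) {
  x <- match_tips(tree, trait)
  if (!ape::is.ultrametric(tree, option = 2))
    stop("the OU fit expects an ultrametric (dated) tree; ",
         "rescale branch lengths to time first")
  n <- length(x)
  C <- ape::vcv(tree)
  D <- stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
  if (is.null(regimes)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "theta"))
  } else {
    reg <- factor(match_tips(tree, regimes, "regimes"))
    X <- stats::model.matrix(~ 0 + reg)
    colnames(X) <- levels(reg)
  }
  Tmax <- max(D) / 2
  llfun <- function(loga) .gls_core(x, .ou_v0(exp(loga), C, D), X)$loglik
  lo <- log(1e-4 / Tmax); hi <- log(1e3 / Tmax)
  opt <- stats::optimize(llfun, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  alpha <- exp(opt$maximum)
  fit <- .gls_core(x, .ou_v0(alpha, C, D), X)
  theta <- stats::setNames(as.numeric(fit$beta), colnames(X))
  at_bound <- abs(opt$maximum - lo) < 1e-3 || abs(opt$maximum - hi) < 1e-3
  .phylofit("OU",
            list(alpha = alpha, sigma2 = fit$sigma2_ml,
                 sigma2_stat = fit$sigma2_ml / (2 * alpha),
                 theta = theta),
            fit$loglik, k = 2L + ncol(X), n = n,
            details = list(alpha_at_boundary = at_bound,
                           regimes = colnames(X)))
}
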