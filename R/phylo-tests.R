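# Group comparisons under phylogenetic covariance: all-pairs Tukey-type
# contrasts from a phylogenetic GLS, and multivariate phylogenetic model
# comparison (BM vs OU regime models) with a Pillai-type MANOVA.

#' Phylogenetic Tukey contrasts (all pairwise group differences)
#'
#' Fits a cell-means GLS under Brownian covariance (`sigma2 * C`),
#' forms all pairwise group-mean contrasts with their GLS standard
#' errors, and adjusts family-wise either by single-step max-|z| (seeded
#' Monte Carlo on the contrast correlation matrix) or by Holm.
#'
#' @param tree an `ape::phylo` tree.
#' @param trait named numeric vector.
#' @param groups factor/character named by species.
#' @param adjust "single-step" (default) or "holm".
#' @param nsim Monte Carlo draws for the single-step adjustment.
#' @param seed seed for the Monte Carlo draws.
#' @return data.frame of class `phylo_tukey`: contrast, estimate, se, z,
#'   p_raw, p_adj; attributes `method`, `sigma2`, `group_means`.
#' @export
phylo_tukey <- function(tree, trait, groups,
                        adjust = c("single-step", "holm"),
                        nsim = 50000L, seed = 1L) {
  adjust <- match.arg(adjust)
  x <- match_tips(tree, trait)
  g <- factor(match_tips(tree, groups, "groups"))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L))
    stop("each group needs at least 2 species: ",
         paste(levels(g)[table(g) < 2L], collapse = ", "))
  n <- length(x)
  C <- ape::vcv(tree)
  X <- stats::model.matrix(~ 0 + g)
  colnames(X) <- levels(g)
  fit <- .gls_core(x, C, X)
  df_resid <- n - ncol(X)
  sigma2 <- fit$rss / df_resid
  cov_beta <- sigma2 * solve(fit$XtX)

  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  K <- matrix(0, ncol(pairs), nlevels(g),
              dimnames = list(paste(pairs[2L, ], "-", pairs[1L, ]), lv))
  for (i in seq_len(ncol(pairs))) {
    K[i, pairs[1L, i]] <- -1
    K[i, pairs[2L, i]] <- 1
  }
  est <- drop(K %*% fit$beta)
  covK <- K %*% cov_beta %*% t(K)
  se <- sqrt(diag(covK))
  z <- est / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  if (adjust == "single-step") {
    # pairwise contrasts are linearly dependent, so draw in the
    # (full-rank) group-mean space and project through K
    B <- with_seed(seed,
                   rmvn_chol(nsim, rep(0, ncol(cov_beta)), cov_beta))
    Zd <- (K %*% B) / se
    maxabs <- apply(abs(Zd), 2L, max)
    p_adj <- vapply(abs(z), function(zz) mean(maxabs >= zz), numeric(1))
    p_adj <- pmin(1, pmax(p_adj, p_raw))
  } else {
    p_adj <- stats::p.adjust(p_raw, "holm")
  }
  out <- data.frame(contrast = rownames(K), estimate = est, se = se,
                    z = z, p_raw = p_raw, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("phylo_tukey", "data.frame")
  attr(out, "method") <- adjust
  attr(out, "sigma2") <- sigma2
  attr(out, "group_means") <- stats::setNames(as.numeric(fit$beta), lv)
  out
}

#' @export
print.phylo_tukey <- function(x, ...) {
  cat("phylo_tukey contrasts (", attr(x, "method"), " adjustment)\n",
      sep = "")
  print.data.frame(cbind(x[1L], lapply(x[-1L], signif, 4)))
  invisible(x)
}

# Multivariate GLS log-likelihood with trait covariance profiled out:
# Y ~ MN(X B, V, S), S_hat = E' V^-1 E / n.
.mv_gls <- function(Y, V, X) {
  n <- nrow(Y); p <- ncol(Y)
  R <- chol(V)
  Ys <- backsolve(R, Y, transpose = TRUE)
  Xs <- backsolve(R, X, transpose = TRUE)
  B <- solve(crossprod(Xs), crossprod(Xs, Ys))
  E <- Ys - Xs %*% B
  S <- crossprod(E) / n
  ldS <- determinant(S, logarithm = TRUE)$modulus
  ldV <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * p * log(2 * pi) + p * ldV + n * ldS + n * p)
  list(B = B, S = S, loglik = as.numeric(ll), E = E, Xs = Xs, Ys = Ys)
}

.regime_design <- function(tree, predictors, spec) {
  if (spec == "all") {
    f <- stats::as.formula(paste("~", paste(names(predictors),
                                            collapse = " + ")))
    X <- stats::model.matrix(f, data = predictors)
  } else {
    g <- factor(predictors[[spec]])
    X <- stats::model.matrix(~ 0 + g)
    colnames(X) <- levels(g)
  }
  X
}

#' Compare multivariate phylogenetic models of trait-matrix evolution
#'
#' Fits multivariate BM and stationary-OU models (one optimum set per
#' level of an ecological predictor, or an additive design over all
#' predictors) to a species x traits matrix by ML, with the among-trait
#' covariance profiled analytically and a single OU pull strength
#' optimized per model. Models are ranked by information criterion:
#' the default is the small-sample corrected AICc (penalty
#' `2k(k+1)/(np - k - 1)` on the `n x p` observations), which guards
#' against the overfitting of regime models that plain AIC shows at
#' these problem sizes; plain AIC is also reported. For each regime
#' model a Pillai-trace MANOVA on the GLS-whitened data tests the regime
#' effect (large-sample chi-square approximation, df = p * q).
#'
#' @param tree an `ape::phylo` tree (ultrametric for OU models).
#' @param traits species x traits numeric matrix (rownames = species).
#' @param predictors data.frame of ecological factors, rownames =
#'   species (e.g. lifestyle, diet, activity).
#' @param models character: "BM" and/or "OU:<predictor>" / "OU:all".
#' @param criterion "AICc" (default) or "AIC".
#' @return object of class `mv_model_comparison`: `fits` (named list of
#'   `phylofit`), `ranking` (data.frame sorted by criterion), `manova`
#'   (data.frame), `criterion`.
#' @export
fit_multivariate <- function(tree, traits,
                             predictors = NULL,
                             models = c("BM",
                                        paste0("OU:",
                                               names(predictors))),
                             criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  Y <- as.matrix(traits)
  if (is.null(rownames(Y))) stop("traits must have species rownames")
  ord <- match(tree$tip.label, gsub("\\s+", "_", rownames(Y)))
  if (anyNA(ord))
    stop("traits missing for tips: ",
         paste(tree$tip.label[is.na(ord)], collapse = ", "))
  Y <- Y[ord, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  if (p >= n)
    stop("p >= n: more traits than species; regularized fitting is not ",
         "supported")
  if (!is.null(predictors)) {
    pidx <- match(tree$tip.label, gsub("\\s+", "_", rownames(predictors)))
    if (anyNA(pidx)) stop("predictors missing for some tips")
    predictors <- predictors[pidx, , drop = FALSE]
  }
  C <- ape::vcv(tree)
  D <- stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
  Tmax <- max(D) / 2
  ones <- matrix(1, n, 1L)

  fits <- list()
  manova_rows <- list()
  for (m in models) {
    if (m == "BM") {
      f <- .mv_gls(Y, C, ones)
      k <- p + p * (p + 1) / 2
      fits[[m]] <- .phylofit("mvBM", list(mean = drop(f$B)),
                             f$loglik, k = k, n = n,
                             details = list(S = f$S))
    } else {
      spec <- sub("^OU:", "", m)
      if (is.null(predictors)) stop("OU models need predictors")
      if (!ape::is.ultrametric(tree, option = 2))
        stop("the OU models expect an ultrametric tree")
      X <- .regime_design(tree, predictors, spec)
      llfun <- function(loga)
        .mv_gls(Y, .ou_v0(exp(loga), C, D), X)$loglik
      opt <- stats::optimize(llfun,
                             interval = log(c(1e-4, 1e3) / Tmax),
                             maximum = TRUE, tol = 1e-7)
      alpha <- exp(opt$maximum)
      V <- .ou_v0(alpha, C, D)
      f <- .mv_gls(Y, V, X)
      q <- ncol(X)
      k <- q * p + p * (p + 1) / 2 + 1
      fits[[m]] <- .phylofit(paste0("mvOU(", spec, ")"),
                             list(alpha = alpha, theta = f$B),
                             f$loglik, k = k, n = n,
                             details = list(S = f$S, design = colnames(X)))
      # Pillai MANOVA of the regime effect on V-whitened data
      f0 <- .mv_gls(Y, V, ones)
      Efull <- crossprod(f$E)
      Enull <- crossprod(f0$E)
      H <- Enull - Efull
      pillai <- sum(diag(H %*% solve(H + Efull)))
      df_h <- qr(cbind(ones, X))$rank - 1L
      chi2 <- n * pillai
      manova_rows[[m]] <- data.frame(
        model = m, pillai = pillai, chi2 = chi2, df = p * df_h,
        p_value = stats::pchisq(chi2, p * df_h, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  kk <- vapply(fits, `[[`, 0, "k")
  ll <- vapply(fits, `[[`, 0, "logLik")
  N <- n * p
  ranking <- data.frame(
    model = names(fits), logLik = ll, k = kk,
    AIC = 2 * kk - 2 * ll,
    AICc = 2 * kk - 2 * ll + 2 * kk * (kk + 1) / pmax(1, N - kk - 1),
    stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking[[criterion]]), , drop = FALSE]
  ranking$delta <- ranking[[criterion]] - ranking[[criterion]][1L]
  rownames(ranking) <- NULL
  manova <- if (length(manova_rows)) do.call(rbind, manova_rows)
            else NULL
  if (!is.null(manova)) rownames(manova) <- NULL
  structure(list(fits = fits, ranking = ranking, manova = manova,
                 criterion = criterion),
            class = "mv_model_comparison")
}

#' @export
print.mv_model_comparison <- function(x, ...) {
  cat("Multivariate phylogenetic model comparison (criterion:",
      x$criterion, ")\n")
  print.data.frame(cbind(x$ranking[1L],
                         lapply(x$ranking[-1L], signif, 6)))
  if (!is.null(x$manova)) {
    cat("MANOVA (Pillai, chi-square approximation):\n")
    print.data.frame(cbind(x$manova[1L], lapply(x$manova[-1L], signif, 4)))
  }
  invisible(x)
}
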