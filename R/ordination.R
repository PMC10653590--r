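# Ordination of normalized family proportions, ML ancestral states under
# BM, and the plain correlation check used for assembly-quality audits.

#' PCA of normalized family proportions
#'
#' Centered (and by default unit-variance scaled) principal component
#' analysis; per-component variance percentages sum to 100. Component
#' signs are fixed by making each loading column's largest-magnitude
#' entry positive, so results are reproducible across platforms.
#'
#' @param norm_matrix species x families numeric matrix (e.g. from
#'   [normalize_families()]).
#' @param center,scale logicals passed to the decomposition.
#' @return object of class `or_pca`: `scores` (species x components),
#'   `loadings` (families x components, orthonormal columns),
#'   `var_explained` (percent), `center`, `scale`.
#' @export
pca_families <- function(norm_matrix, center = TRUE, scale = TRUE) {
  M <- as.matrix(norm_matrix)
  if (nrow(M) < 3L) stop("need at least 3 species")
  v <- apply(M, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance family column: ",
         paste(colnames(M)[v == 0], collapse = ", "))
  pr <- stats::prcomp(M, center = center, scale. = scale)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    l <- pr$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  pr$rotation <- sweep(pr$rotation, 2L, flip, "*")
  pr$x <- sweep(pr$x, 2L, flip, "*")
  structure(list(scores = pr$x, loadings = pr$rotation,
                 var_explained = 100 * pr$sdev^2 / sum(pr$sdev^2),
                 center = center, scale = scale),
            class = "or_pca")
}

#' @export
print.or_pca <- function(x, ...) {
  cat("or_pca:", nrow(x$scores), "species,", ncol(x$loadings),
      "components\n  % variance:",
      paste(signif(x$var_explained[seq_len(min(5,
        length(x$var_explained)))], 4), collapse = ", "), "...\n")
  invisible(x)
}

#' ML ancestral states of a continuous trait under Brownian motion
#'
#' GLS estimates for every internal node: the conditional expectation of
#' the node state given the tips under the fitted BM model, with
#' estimation variances that account for root-state uncertainty.
#'
#' @param tree an `ape::phylo` tree.
#' @param trait named numeric vector.
#' @return data.frame of class `ancestral_states`: node (ape node id),
#'   estimate, variance. The root row equals the GLS root state.
#' @export
ancestral_states <- function(tree, trait) {
  x <- match_tips(tree, trait)
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  d <- ape::dist.nodes(tree)
  root <- nt + 1L
  depth <- d[root, ]
  ids <- seq_len(nt + nn)
  # shared path length from the root for every pair of nodes
  S <- outer(depth[ids], depth[ids], "+") - d[ids, ids]
  S <- S / 2
  C <- S[seq_len(nt), seq_len(nt)]
  Cinv <- solve(C)
  one <- rep(1, nt)
  denom <- sum(Cinv)
  mu <- sum(Cinv %*% x) / denom
  sigma2 <- drop(crossprod(x - mu, Cinv %*% (x - mu))) / nt
  nodes <- nt + seq_len(nn)
  est <- numeric(nn); vr <- numeric(nn)
  for (i in seq_len(nn)) {
    k <- nodes[i]
    ck <- S[seq_len(nt), k]
    w <- Cinv %*% ck
    est[i] <- mu + drop(crossprod(w, x - mu))
    vr[i] <- sigma2 * (S[k, k] - drop(crossprod(ck, w)) +
                         (1 - sum(w))^2 / denom)
  }
  out <- data.frame(node = nodes, estimate = est, variance = pmax(0, vr))
  class(out) <- c("ancestral_states", "data.frame")
  attr(out, "sigma2") <- sigma2
  attr(out, "root_state") <- mu
  out
}

#' Pearson correlation with t-test (assembly-quality audit)
#'
#' @param x,y paired finite numeric vectors, length >= 3.
#' @return list: r, t, df, p_value.
#' @export
qc_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value)
}
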