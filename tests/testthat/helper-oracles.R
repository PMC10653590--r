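# Independent oracles shared across test files.

# 1,001-point grid-search likelihood oracle for Pagel's lambda, written
# directly from the profiled GLS likelihood.
grid_lambda_oracle <- function(tree, x, npts = 1001L) {
  C <- ape::vcv(tree); dC <- diag(C); n <- length(x)
  ll <- function(l) {
    V <- l * C + diag((1 - l) * dC, n)
    R <- chol(V)
    ys <- backsolve(R, x, transpose = TRUE)
    Xs <- backsolve(R, rep(1, n), transpose = TRUE)
    b <- sum(Xs * ys) / sum(Xs^2)
    s2 <- sum((ys - Xs * b)^2) / n
    -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n)
  }
  grid <- seq(0, 1, length.out = npts)
  vals <- vapply(grid, ll, 1)
  list(lambda = grid[which.max(vals)], loglik = max(vals),
       spacing = grid[2] - grid[1])
}

# Brute-force GLS oracle for ancestral states: conditional mean of each
# internal node given the tips, with the shared-path covariance over all
# nodes assembled from MRCA depths (explicit matrix inversion).
anc_oracle <- function(tree, x) {
  nt <- length(tree$tip.label)
  ids <- seq_len(nt + tree$Nnode)
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  S <- matrix(depth[M], length(ids), length(ids))
  C <- S[seq_len(nt), seq_len(nt)]
  Ci <- solve(C)
  mu <- sum(Ci %*% x[tree$tip.label]) / sum(Ci)
  nodes <- nt + seq_len(tree$Nnode)
  vapply(nodes, function(k)
    mu + drop(S[k, seq_len(nt)] %*% Ci %*% (x[tree$tip.label] - mu)),
    numeric(1))
}
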