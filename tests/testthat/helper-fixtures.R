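# Shared fixtures, built once per test run (all generated in code).

.fx <- new.env(parent = emptyenv())

fx_seeds <- function() {
  if (is.null(.fx$seeds)) .fx$seeds <- make_seed_set()
  .fx$seeds
}

fx_profiles <- function() {
  if (is.null(.fx$profiles)) .fx$profiles <- build_family_profiles(fx_seeds())
  .fx$profiles
}

fx_panel <- function() {
  if (is.null(.fx$panel)) .fx$panel <- make_reference_panel()
  .fx$panel
}

# balanced 64-tip unit-branch tree used for simulation-based checks
fx_tree64 <- function() {
  if (is.null(.fx$tree64)) {
    tr <- ape::stree(64, "balanced")
    tr$edge.length <- rep(1, nrow(tr$edge))
    tr$tip.label <- paste0("t", 1:64)
    .fx$tree64 <- tr
  }
  .fx$tree64
}

# random dated 24-tip tree with three balanced groups
fx_tree24 <- function() {
  if (is.null(.fx$tree24)) {
    .fx$tree24 <- with_seed(99, {
      tr <- ape::rcoal(24)
      tr$tip.label <- paste0("t", 1:24)
      tr
    })
  }
  .fx$tree24
}

fx_groups24 <- function() {
  stats::setNames(rep(c("a", "b", "c"), 8), fx_tree24()$tip.label)
}

# run expr with a local RNG seed (mirror of the package-internal helper)
with_seed <- ormine:::with_seed
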