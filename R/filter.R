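# Phylogenetic non-OR filter: each candidate is placed on a
# neighbor-joining tree together with the verified OR / non-OR GPCR
# reference panel; candidates whose nearest reference clade contains only
# non-OR references are removed. Surviving candidates are assigned to the
# best-scoring family profile.

.aa_submat <- NULL
.get_blosum62 <- function() {
  if (is.null(.aa_submat)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    utils::assignInMyNamespace(".aa_submat",
                               get("BLOSUM62", envir = environment()))
  }
  .aa_submat
}

# p-distance from a pairwise global alignment: mismatches / aligned
# residue pairs. Vectorized over `patterns`.
.aa_pdist_to <- function(patterns, subject) {
  al <- Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject,
    substitutionMatrix = .get_blosum62(),
    gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT, type = "global")
  nm <- Biostrings::nmatch(al)
  mm <- Biostrings::nmismatch(al)
  mm / pmax(1L, nm + mm)
}

# Symmetric p-distance matrix for a named protein vector.
.aa_dist_matrix <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    d <- .aa_pdist_to(seqs[(i + 1L):n], seqs[[i]])
    D[i, (i + 1L):n] <- d
    D[(i + 1L):n, i] <- d
  }
  D
}

#' Assemble a reference panel object
#'
#' @param or_refs OR reference proteins (FASTA path, XStringSet, or named
#'   character vector).
#' @param nonor_refs non-OR GPCR reference proteins (same forms).
#' @return list of class `reference_panel` with `or_refs`, `nonor_refs`,
#'   `labels`.
#' @export
reference_panel <- function(or_refs, nonor_refs) {
  or_refs <- as_seq_vector(or_refs, "AA")
  nonor_refs <- as_seq_vector(nonor_refs, "AA")
  if (length(intersect(names(or_refs), names(nonor_refs))))
    stop("OR and non-OR reference ids overlap")
  structure(list(
    or_refs = or_refs, nonor_refs = nonor_refs,
    labels = c(stats::setNames(rep("OR", length(or_refs)), names(or_refs)),
               stats::setNames(rep("NONOR", length(nonor_refs)),
                               names(nonor_refs)))),
    class = "reference_panel")
}

#' Phylogenetic filter against the OR / non-OR reference panel
#'
#' For each candidate protein, a neighbor-joining tree is inferred from
#' pairwise amino-acid p-distances of the candidate plus the full panel,
#' rooted on the non-OR references. Walking up from the candidate tip, the
#' smallest clade containing at least one reference decides the verdict:
#' the candidate is kept iff that clade contains at least one OR-labelled
#' reference.
#'
#' @param candidates candidate proteins (named character vector, FASTA
#'   path, or XStringSet). Stops (`*`) are treated as X.
#' @param panel a `reference_panel` (or a list with or_refs/nonor_refs,
#'   e.g. from [make_reference_panel()]).
#' @return data.frame of class `filter_verdicts`: candidate_id, keep,
#'   nearest_reference_id, sister_group (label set of the attachment
#'   clade).
#' @export
phylo_filter <- function(candidates, panel) {
  if (!inherits(panel, "reference_panel"))
    panel <- reference_panel(panel$or_refs, panel$nonor_refs)
  cands <- as_seq_vector(candidates, "AA")
  cands <- vapply(cands, function(s) gsub("*", "X", s, fixed = TRUE),
                  character(1))
  short <- nchar(cands) < 50L
  if (any(short))
    stop("candidate shorter than 50 aa: ",
         paste(names(cands)[short], collapse = ", "))
  only_x <- vapply(cands, function(s)
    all(strsplit(s, "")[[1]] %in% c("X", "-")), logical(1))
  if (any(only_x))
    stop("candidate has only ambiguous residues: ",
         paste(names(cands)[only_x], collapse = ", "))
  refs <- c(panel$or_refs, panel$nonor_refs)
  if (length(refs) + 1L < 4L) stop("need at least 4 sequences for a tree")
  if (any(names(cands) %in% names(refs)))
    stop("candidate ids collide with panel ids")
  Dref <- .aa_dist_matrix(refs)
  nonor <- names(panel$nonor_refs)

  rows <- lapply(seq_along(cands), function(i) {
    id <- names(cands)[i]
    dc <- .aa_pdist_to(refs, cands[[i]])
    D <- rbind(cbind(Dref, dc), c(dc, 0))
    dimnames(D) <- list(c(names(refs), id), c(names(refs), id))
    tr <- ape::nj(stats::as.dist(D))
    # root on the non-OR reference farthest (patristic) from the
    # candidate: a non-OR rooting that can never sit on the candidate's
    # own attachment edge
    pd <- stats::cophenetic(tr)
    out_tip <- nonor[which.max(pd[id, nonor])]
    tr <- ape::root(tr, outgroup = out_tip, resolve.root = TRUE)
    tip <- match(id, tr$tip.label)
    node <- tip
    verdict <- NA
    sister <- character(0)
    repeat {
      parent <- tr$edge[tr$edge[, 2L] == node, 1L]
      if (!length(parent)) break
      tips <- tr$tip.label[phangorn::Descendants(tr, parent, "tips")[[1]]]
      in_clade <- setdiff(tips, id)
      if (length(in_clade)) {
        lab <- panel$labels[in_clade]
        verdict <- any(lab == "OR")
        sister <- sort(unique(lab))
        break
      }
      node <- parent
    }
    if (is.na(verdict)) verdict <- FALSE
    data.frame(candidate_id = id, keep = verdict,
               nearest_reference_id = names(refs)[which.min(dc)],
               sister_group = paste(sister, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("filter_verdicts", "data.frame")
  out
}

#' Assign a candidate protein to an OR family
#'
#' Scores the candidate against every family profile ([profile_score()]);
#' the highest score wins, ties broken by lexicographic family id. A best
#' score below `floor` yields `family_id = "unassigned"` (flagged, not
#' dropped).
#'
#' @param candidate protein (character scalar) or named vector of
#'   proteins.
#' @param profiles a `family_profile_set`.
#' @param floor minimum acceptable best score (log-odds nats).
#' @return data.frame of class `family_calls`: candidate_id, family_id,
#'   best_family (ignoring the floor), score, margin.
#' @export
assign_family <- function(candidate, profiles, floor = 0) {
  stopifnot(inherits(profiles, "family_profile_set"))
  cands <- as_seq_vector(candidate, "AA")
  fams <- vapply(profiles, `[[`, "", "family_id")
  rows <- lapply(seq_along(cands), function(i) {
    sc <- vapply(profiles, function(p)
      profile_score(cands[[i]], p), numeric(1))
    names(sc) <- fams
    o <- order(-sc, fams)
    best <- fams[o[1L]]
    margin <- if (length(sc) > 1L) sc[o[1L]] - sc[o[2L]] else sc[o[1L]]
    data.frame(candidate_id = names(cands)[i],
               family_id = if (sc[o[1L]] < floor) "unassigned" else best,
               best_family = best, score = unname(sc[o[1L]]),
               margin = unname(margin), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("family_calls", "data.frame")
  out
}
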