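# Greedy incremental identity clustering of candidate loci (CD-HIT-style
# redundancy merge at 98% identity, to collapse alleles and assembly
# duplicates).

# Global-alignment identity: matches / alignment length (gaps included).
.nt_submat <- NULL
.get_nt_submat <- function() {
  if (is.null(.nt_submat)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
    utils::assignInMyNamespace(".nt_submat", m)
  }
  .nt_submat
}

#' Pairwise global nucleotide identity
#'
#' Needleman-Wunsch alignment; identity is matches divided by the full
#' alignment length (gap columns count against identity).
#'
#' @param a,b nucleotide sequences (character scalars).
#' @return identity fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, substitutionMatrix = .get_nt_submat(),
    gapOpening = 5, gapExtension = 2, type = "global")
  Biostrings::nmatch(al) /
    nchar(as.character(Biostrings::alignedPattern(al)))
}

#' Merge redundant candidate loci by greedy identity clustering
#'
#' Sequences are visited longest-first (ties by (contig, start) for
#' `genome_hits` input, by name otherwise); each joins the first earlier
#' representative whose global identity reaches the threshold, else founds
#' a new cluster. Deterministic given the input.
#'
#' @param hits a `genome_hits` data.frame or a named character vector of
#'   nucleotide sequences.
#' @param threshold identity fraction in (0, 1]; default 0.98, the
#'   allele-collapsing threshold.
#' @return list of class `clustering_result`: `representatives` (ids, in
#'   founding order), `member_map` (named vector input id -> representative
#'   id), `identity_threshold`, and `hits` (the representative subset, for
#'   `genome_hits` input).
#' @export
dedup_cluster <- function(hits, threshold = 0.98) {
  stopifnot(threshold > 0, threshold <= 1)
  is_df <- is.data.frame(hits)
  if (is_df) {
    seqs <- hit_sequences(hits)
    ord <- order(-nchar(seqs), hits$contig, hits$start)
  } else {
    seqs <- as_seq_vector(hits, "DNA")
    ord <- order(-nchar(seqs), names(seqs))
  }
  ids <- names(seqs)[ord]
  sq <- unname(seqs[ord])
  reps <- character(0)
  rep_seq <- character(0)
  member_map <- character(0)
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (abs(nchar(sq[i]) - nchar(rep_seq[r])) >
          (1 - threshold) * 2 * nchar(rep_seq[r]) + 10) next
      if (global_identity(sq[i], rep_seq[r]) >= threshold) {
        member_map[ids[i]] <- reps[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      rep_seq <- c(rep_seq, sq[i])
      member_map[ids[i]] <- ids[i]
    }
  }
  out <- list(representatives = reps, member_map = member_map,
              identity_threshold = threshold)
  if (is_df) {
    rn <- names(seqs)
    out$hits <- hits[match(reps, rn), , drop = FALSE]
  }
  class(out) <- "clustering_result"
  out
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("clustering_result:", length(x$member_map), "sequences ->",
      length(x$representatives), "representatives at identity >=",
      x$identity_threshold, "\n")
  invisible(x)
}
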