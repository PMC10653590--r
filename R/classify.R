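# Functional classification of candidate OR loci: premature-stop and
# frameshift detection against a reference coding sequence, the 650-bp
# minimum coding length, and a hydropathy-based transmembrane-helix count
# (a deterministic stand-in for neural TM predictors; pluggable).

TM_WINDOW <- 19L       # hydropathy window (residues)
TM_THRESHOLD <- 1.6    # mean Kyte-Doolittle hydropathy to call a window
TM_MERGE_GAP <- 5L     # merge helix segments separated by < this
TM_MIN_LEN <- 15L      # minimum helix length
MIN_FUNCTIONAL_NT <- 650L  # minimum nt length to code seven TM domains

#' Detect pseudogene features against a reference coding sequence
#'
#' The candidate nucleotides are locally aligned to the best-matching
#' reference CDS (reference-anchored frame). Any coding-region indel whose
#' length is not divisible by 3 is a frameshift; a premature stop is any
#' in-frame stop codon (read in the reference frame, between indels)
#' before the reference's final codon. If alignment identity falls below
#' `min_identity` the evidence is marked unanchored and the stop check
#' falls back to the longest-ORF frame.
#'
#' @param nt_sequence candidate nucleotide sequence (strand-corrected).
#' @param reference_cds reference coding nucleotide sequence (in frame,
#'   terminal stop included), e.g. a family profile's `ref_cds`.
#' @param reference_id label carried into the evidence.
#' @param min_identity anchoring threshold (default 0.30).
#' @return list: `has_premature_stop`, `frameshift` (list with
#'   `reference_id`, `positions`, `lengths`, `has_frameshift`),
#'   `length_nt`, `anchored`, `identity`.
#' @export
detect_pseudogene_features <- function(nt_sequence, reference_cds,
                                       reference_id = "reference",
                                       min_identity = 0.30) {
  s <- toupper(nt_sequence)
  len <- nchar(s)
  al <- Biostrings::pairwiseAlignment(
    pattern = s, subject = toupper(reference_cds),
    substitutionMatrix = .get_nt_submat(),
    gapOpening = 8, gapExtension = 2, type = "local")
  nm <- Biostrings::nmatch(al)
  mm <- Biostrings::nmismatch(al)
  identity <- nm / max(1L, nm + mm)
  # anchoring needs both identity and coverage: a short spurious local
  # alignment of unrelated sequence can be locally near-identical
  coverage <- (nm + mm) / min(len, nchar(reference_cds))
  if (identity < min_identity || coverage < min_identity) {
    return(list(
      has_premature_stop = .longest_orf_stop(s),
      frameshift = list(reference_id = reference_id,
                        positions = integer(0), lengths = integer(0),
                        has_frameshift = FALSE),
      length_nt = len, anchored = FALSE, identity = identity))
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ref_off <- Biostrings::start(Biostrings::subject(al)) - 1L
  ref_len <- nchar(reference_cds)
  final_codon <- ref_len %/% 3L

  # indels: runs of gaps in either row
  gap_runs <- function(isgap, refpos) {
    r <- rle(isgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(col = starts[keep], len = r$lengths[keep],
               refpos = refpos[starts[keep]])
  }
  refpos <- ref_off + cumsum(sa != "-")  # ref coordinate at each column
  dels <- gap_runs(pa == "-", refpos)
  ins <- gap_runs(sa == "-", refpos)
  indels <- rbind(dels, ins)
  fs_lens <- indels$len[indels$len %% 3L != 0L]
  fs_pos <- indels$refpos[indels$len %% 3L != 0L]

  # premature stops: complete, gap-free reference codons read from the
  # candidate row
  has_stop <- FALSE
  cod_cols <- split(seq_along(sa)[sa != "-"],
                    (refpos[sa != "-"] - 1L) %/% 3L + 1L)
  for (ci in names(cod_cols)) {
    cols <- cod_cols[[ci]]
    if (length(cols) != 3L) next
    if (any(pa[cols] == "-")) next
    if (max(cols) - min(cols) != 2L) next  # insertion inside the codon
    codon <- paste0(pa[cols], collapse = "")
    if (codon %in% STOP_CODONS && as.integer(ci) < final_codon) {
      has_stop <- TRUE
      break
    }
  }
  list(has_premature_stop = has_stop,
       frameshift = list(reference_id = reference_id,
                         positions = as.integer(fs_pos),
                         lengths = as.integer(fs_lens),
                         has_frameshift = length(fs_lens) > 0L),
       length_nt = len, anchored = TRUE, identity = identity)
}

# Longest-ORF fallback stop check: in the frame with the longest open
# reading frame, is there a stop before the final codon?
.longest_orf_stop <- function(s) {
  best_frame <- 0L
  best_orf <- -1L
  for (f in 0:2) {
    aa <- translate_nt(s, f)
    runs <- rle(strsplit(aa, "")[[1]] == "*")
    orf <- if (any(!runs$values)) max(runs$lengths[!runs$values]) else 0L
    if (orf > best_orf) { best_orf <- orf; best_frame <- f }
  }
  aa <- translate_nt(s, best_frame)
  pos <- which(strsplit(aa, "")[[1]] == "*")
  length(pos) > 0L && any(pos < nchar(aa))
}

#' Count transmembrane helices by hydropathy
#'
#' Sliding-window Kyte-Doolittle scan: residues covered by any window of
#' `TM_WINDOW` residues with mean hydropathy above `TM_THRESHOLD` form
#' helix segments; segments separated by fewer than `TM_MERGE_GAP`
#' residues are merged and segments shorter than `TM_MIN_LEN` are
#' dropped. A deterministic stand-in for trained TM-topology predictors;
#' callers can substitute any predictor returning the same shape.
#'
#' @param protein character scalar (>= 100 residues; at most 10%
#'   non-standard residues).
#' @param window,threshold,merge_gap,min_len scan parameters.
#' @return list of class `tm_topology`: `helices` (data.frame start, end;
#'   0-based half-open) and `tm_count`.
#' @export
count_tm_domains <- function(protein, window = TM_WINDOW,
                             threshold = TM_THRESHOLD,
                             merge_gap = TM_MERGE_GAP,
                             min_len = TM_MIN_LEN) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 100L) stop("protein shorter than 100 residues")
  nonstd <- !(ch %in% names(KD_SCALE))
  if (mean(nonstd) > 0.10)
    stop("more than 10% non-standard residues")
  h <- KD_SCALE[ch]
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  k <- n - window + 1L
  wmean <- (cs[(window + 1L):(n + 1L)] - cs[1:k]) / window
  pass <- which(wmean > threshold)
  helices <- data.frame(start = integer(0), end = integer(0))
  if (length(pass)) {
    cover <- logical(n)
    for (p in pass) cover[p:(p + window - 1L)] <- TRUE
    r <- rle(cover)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    iv <- cbind(starts[r$values], ends[r$values])
    # merge segments separated by < merge_gap
    merged <- iv[1L, , drop = FALSE]
    if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
      if (iv[i, 1L] - merged[nrow(merged), 2L] - 1L < merge_gap) {
        merged[nrow(merged), 2L] <- iv[i, 2L]
      } else merged <- rbind(merged, iv[i, ])
    }
    keep <- (merged[, 2L] - merged[, 1L] + 1L) >= min_len
    merged <- merged[keep, , drop = FALSE]
    helices <- data.frame(start = merged[, 1L] - 1L, end = merged[, 2L])
  }
  structure(list(helices = helices, tm_count = nrow(helices)),
            class = "tm_topology")
}

#' @export
print.tm_topology <- function(x, ...) {
  cat("tm_topology:", x$tm_count, "helices\n")
  if (x$tm_count) print.data.frame(x$helices)
  invisible(x)
}

#' Classify a candidate's status from its evidence
#'
#' Rules: pseudogene iff premature stop, frameshift, or length < 650 nt;
#' otherwise sub7TM if the helix count differs from seven; otherwise
#' functional. The 650-nt bound is inclusive: a 650-nt sequence passes
#' the length rule.
#'
#' @param has_premature_stop,has_frameshift logicals.
#' @param length_nt candidate length in nucleotides.
#' @param tm_count helix count (may be NA when not applicable; NA with
#'   clean evidence and sufficient length is treated as sub7TM only if
#'   `tm_count` is non-NA and != 7 — NA yields "functional" with a
#'   missing-TM flag never raised here; callers should supply tm_count).
#' @return one of "functional", "sub7TM", "pseudogene".
#' @export
classify_status <- function(has_premature_stop, has_frameshift, length_nt,
                            tm_count = NA_integer_) {
  if (isTRUE(has_premature_stop) || isTRUE(has_frameshift) ||
      length_nt < MIN_FUNCTIONAL_NT) return("pseudogene")
  if (!is.na(tm_count) && tm_count != 7L) return("sub7TM")
  "functional"
}

#' Remove alignment columns with excess missing data
#'
#' A column is kept iff its fraction of missing characters (gaps `-`/`.`,
#' `?`, and unknowns N/X, case-insensitive) is at most
#' `max_missing_fraction`; the boundary fraction itself is kept. Row
#' order and count are preserved; the operation is idempotent.
#'
#' @param alignment character vector of equal-length aligned sequences
#'   (possibly named), a character matrix, or an XStringSet.
#' @param max_missing_fraction maximum tolerated missing fraction.
#' @return the trimmed alignment, same representation as the input
#'   (matrix in, matrix out; otherwise character vector).
#' @export
trim_alignment <- function(alignment, max_missing_fraction = 0.8) {
  was_matrix <- is.matrix(alignment)
  if (was_matrix) M <- alignment
  else {
    if (!length(alignment)) stop("empty alignment")
    v <- as_seq_vector(alignment, "AA")
    if (!length(v) || any(!nchar(v))) stop("empty alignment")
    w <- unique(nchar(v))
    if (length(w) != 1L) stop("alignment is not rectangular")
    M <- do.call(rbind, strsplit(v, "", fixed = TRUE))
    rownames(M) <- names(v)
  }
  if (!nrow(M) || !ncol(M)) stop("empty alignment")
  missing <- matrix(toupper(M) %in% c("-", ".", "?", "N", "X"),
                    nrow = nrow(M))
  keep <- colMeans(missing) <= max_missing_fraction
  M2 <- M[, keep, drop = FALSE]
  if (was_matrix) return(M2)
  out <- apply(M2, 1L, paste0, collapse = "")
  if (!ncol(M2)) out <- stats::setNames(rep("", nrow(M2)), rownames(M2))
  out
}
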