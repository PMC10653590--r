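# Per-family profile models: position-specific scoring matrices (log-odds
# PSSMs) built from the aligned amino-acid translations of seed coding
# sequences. One profile per OR family; the same profiles drive both the
# translated genome scan and family assignment.

.BG_AA <- stats::setNames(rep(1 / 20, 20), AA20)
.STOP_SCORE <- -8  # emission for '*' at any column
.GAP_OPEN <- 10
.GAP_EXT <- 0.5

# Translate a seed CDS, dropping the terminal stop; error on internal stops.
.translate_seed <- function(cds, id) {
  if (nchar(cds) %% 3L != 0L)
    stop("seed ", id, ": length not divisible by 3")
  aa <- translate_nt(cds)
  aa <- sub("\\*$", "", aa)
  if (grepl("*", aa, fixed = TRUE))
    stop("seed ", id, ": internal stop codon in translation")
  aa
}

# Center-star multiple alignment of proteins onto the longest sequence;
# returns per-center-column residue counts (insertions relative to the
# center are ignored; deletions contribute nothing).
.column_counts <- function(proteins) {
  L <- max(nchar(proteins))
  center <- proteins[[which.max(nchar(proteins))]]
  counts <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  for (p in proteins) {
    if (identical(p, center)) {
      ch <- strsplit(p, "", fixed = TRUE)[[1]]
      idx <- cbind(match(ch, AA20), seq_len(L))
      idx <- idx[!is.na(idx[, 1L]), , drop = FALSE]
      counts[idx] <- counts[idx] + 1
      next
    }
    al <- Biostrings::pairwiseAlignment(
      pattern = p, subject = center, substitutionMatrix = B62,
      gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT, type = "global")
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    col <- cumsum(sa != "-")
    keep <- sa != "-" & pa != "-" & pa %in% AA20
    idx <- cbind(match(pa[keep], AA20), col[keep])
    counts[idx] <- counts[idx] + 1
  }
  counts
}

#' Build one profile model per OR family
#'
#' Seed coding sequences are translated, multiply aligned per family
#' (center-star onto the longest seed), and converted to a log-odds
#' position-specific scoring matrix against a uniform residue background
#' with background-proportional pseudocounts. Stops score a fixed strong
#' penalty; X scores 0 at every column.
#'
#' @param seeds a seed set as returned by [make_seed_set()] (data.frame
#'   with columns family, gene, cds), or a named list
#'   `family -> named character vector of CDS`.
#' @param pseudocount total pseudocount mass added per column.
#' @return named list of `family_profile` objects (one per family), class
#'   `family_profile_set`.
#' @export
build_family_profiles <- function(seeds, pseudocount = 1) {
  if (is.data.frame(seeds)) {
    fam_split <- split(stats::setNames(seeds$cds, seeds$gene), seeds$family)
  } else {
    fam_split <- seeds
  }
  empty <- names(fam_split)[vapply(fam_split, length, 1L) == 0L]
  if (length(empty))
    stop("family with no seed sequences: ", paste(empty, collapse = ", "))
  profiles <- lapply(names(fam_split), function(fam) {
    cds <- fam_split[[fam]]
    prots <- vapply(seq_along(cds), function(i)
      .translate_seed(cds[[i]], names(cds)[i] %||% paste0(fam, ":", i)),
      character(1))
    counts <- .column_counts(prots)
    L <- ncol(counts)
    tot <- colSums(counts)
    probs <- sweep(counts + pseudocount * .BG_AA,
                   2L, tot + pseudocount, "/")
    emis <- log(probs / .BG_AA)
    emis <- rbind(emis,
                  X = rep(0, L),
                  `*` = rep(.STOP_SCORE, L))
    rownames(emis) <- AA_ALPHABET
    consensus <- paste0(AA20[apply(counts + pseudocount * .BG_AA, 2L,
                                   which.max)], collapse = "")
    ref_i <- which.max(nchar(cds))
    structure(list(family_id = fam, model_length = L, emissions = emis,
                   background = .BG_AA, consensus = consensus,
                   seed_count = length(cds),
                   ref_cds = unname(cds[[ref_i]]),
                   ref_id = names(cds)[ref_i]),
              class = "family_profile")
  })
  names(profiles) <- names(fam_split)
  structure(profiles, class = c("family_profile_set", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.family_profile <- function(x, ...) {
  cat("family_profile: family", x$family_id, "|", x$model_length,
      "match columns |", x$seed_count, "seeds\n")
  invisible(x)
}

#' @export
print.family_profile_set <- function(x, ...) {
  cat("family_profile_set with", length(x), "profiles:",
      paste(vapply(x, `[[`, "", "family_id"), collapse = ", "), "\n")
  invisible(x)
}

#' Score a protein against a profile
#'
#' The profile is split into contiguous column chunks (as in the genome
#' scan); each chunk is slid along the protein independently and its best
#' placement score, clamped at zero, contributes to the total. Chunked
#' scoring keeps the score informative for disrupted sequences
#' (frameshifts, truncations) whose intact parts still match a subset of
#' columns. With `chunked = FALSE` the classic single best ungapped
#' full-profile placement is returned.
#'
#' @param protein character scalar.
#' @param profile a `family_profile`.
#' @param chunked use per-chunk best placements (default).
#' @return numeric scalar score in nats of log-odds.
#' @export
profile_score <- function(protein, profile, chunked = TRUE) {
  L <- profile$model_length
  idx <- aa_index(protein)
  n <- length(idx)
  idxp <- c(rep.int(21L, L), idx, rep.int(21L, L))
  na <- n + L - 1L
  E <- profile$emissions
  if (!chunked) {
    sc <- numeric(na)
    for (j in seq_len(L)) sc <- sc + E[cbind(idxp[(j + 1L):(j + na)], j)]
    return(max(sc))
  }
  bounds <- .chunk_bounds(L)
  run <- numeric(na)
  prev <- numeric(na)
  bi <- 1L
  total <- 0
  for (j in seq_len(L)) {
    run <- run + E[cbind(idxp[(j + 1L):(j + na)], j)]
    if (j == bounds[bi, "end"]) {
      total <- total + max(0, run - prev)
      prev <- run
      bi <- bi + 1L
    }
  }
  total
}

#' Serialize / load a profile set
#'
#' Profiles round-trip bit-identically through RDS (version 3, xz off).
#'
#' @param profiles a `family_profile_set`.
#' @param path file path.
#' @return `path` invisibly / the reloaded `family_profile_set`.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "family_profile_set"))
  saveRDS(profiles, path, version = 3, compress = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  p <- readRDS(path)
  stopifnot(inherits(p, "family_profile_set"))
  p
}
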