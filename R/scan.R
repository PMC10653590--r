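# Six-frame translated scan of genome assemblies against the family
# profiles. Each profile is split into contiguous column chunks (~50 aa);
# chunk scores are computed for every profile placement in every frame in
# a single pass over the profile columns. Chunks that clear the
# significance threshold become locus votes spanning their matched
# columns; votes on the same contig+strand within a small gap are chained
# into one locus, so disrupted genes (premature stops, frameshifts,
# truncations) are still recovered from their intact chunks while a
# truncated gene's locus stays confined to the matched region. A locus
# whose match reaches the final profile column is extended by one codon
# to include the terminal stop.

# Chunk column boundaries: k roughly equal chunks of >= 40 columns.
.chunk_bounds <- function(L, target = 52L) {
  k <- max(1L, round(L / target))
  b <- as.integer(round(seq(0L, L, length.out = k + 1L)))
  cbind(start = b[-length(b)] + 1L, end = b[-1L])
}

#' Scan a genome for candidate OR loci
#'
#' @param profiles a `family_profile_set` from [build_family_profiles()].
#' @param genome FASTA path, `DNAStringSet`, or named character vector of
#'   contigs (IUPAC alphabet; ambiguity codes translate to X).
#' @param evalue significance threshold: a chunk must score at least
#'   `log(db_size / evalue)` nats, where `db_size` is the number of
#'   amino-acid positions scanned across all six frames.
#' @param chunk_cols target chunk width in profile columns.
#' @param chain_gap maximum nt gap between chained chunk votes.
#' @return data.frame of class `genome_hits` with columns contig, start,
#'   end (0-based half-open, forward-strand), strand, family, score,
#'   evalue, seq (strand-corrected nucleotide sequence). Hits are
#'   non-overlapping per (contig, strand) and sorted by (contig, start).
#' @export
scan_genome <- function(profiles, genome, evalue = 1e-10,
                        chunk_cols = 52L, chain_gap = 200L) {
  stopifnot(inherits(profiles, "family_profile_set"))
  contigs <- as_seq_vector(genome, "DNA")
  db_size <- max(1, 2 * sum(nchar(contigs)))
  score_min <- log(db_size / evalue)

  all_hits <- list()
  for (ci in seq_along(contigs)) {
    cname <- names(contigs)[ci]
    fwd <- toupper(contigs[[ci]])
    Lc <- nchar(fwd)
    if (Lc < 3L) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      votes <- list()  # scanning-strand nt coordinates
      for (f in 0:2) {
        prot <- translate_nt(s, f)
        n <- nchar(prot)
        if (n < 10L) next
        idx <- aa_index(prot)
        for (pr in profiles) {
          L <- pr$model_length
          idxp <- c(rep.int(21L, L), idx, rep.int(21L, L))
          na <- n + L - 1L  # placements a = (2 - L) .. n
          E <- pr$emissions
          bounds <- .chunk_bounds(L, chunk_cols)
          run <- numeric(na)
          prev <- numeric(na)
          bi <- 1L
          for (j in seq_len(L)) {
            run <- run + E[cbind(idxp[(j + 1L):(j + na)], j)]
            if (j == bounds[bi, "end"]) {
              cs <- run - prev
              hit <- which(cs >= score_min)
              if (length(hit)) {
                a <- hit - (L - 1L)          # placement in protein coords
                i0 <- a + bounds[bi, "start"] - 1L  # chunk aa start
                nt0 <- f + 3L * (i0 - 1L)
                clen <- bounds[bi, "end"] - bounds[bi, "start"] + 1L
                votes[[length(votes) + 1L]] <- data.frame(
                  start = unname(pmax(0L, nt0)),
                  end = unname(pmin(Lc, nt0 + 3L * clen)),
                  family = pr$family_id, chunk_score = unname(cs[hit]),
                  c_end = unname(bounds[bi, "end"]), model_len = L,
                  stringsAsFactors = FALSE)
              }
              prev <- run
              bi <- bi + 1L
            }
          }
        }
      }
      if (!length(votes)) next
      v <- do.call(rbind, votes)
      # chain votes within chain_gap into loci
      v <- v[order(v$start, v$end), , drop = FALSE]
      grp <- integer(nrow(v))
      g <- 0L; cur_end <- -Inf
      for (i in seq_len(nrow(v))) {
        if (v$start[i] > cur_end + chain_gap) { g <- g + 1L }
        cur_end <- max(cur_end, v$end[i])
        grp[i] <- g
      }
      for (gi in unique(grp)) {
        vg <- v[grp == gi, , drop = FALSE]
        fam_scores <- tapply(vg$chunk_score, vg$family, sum)
        best <- names(fam_scores)[which.max(fam_scores)]
        vb <- vg[vg$family == best, , drop = FALSE]
        st <- min(vb$start); en <- max(vb$end)
        # include the terminal stop codon when the match reaches the
        # final profile column
        if (max(vb$c_end) == vb$model_len[1L]) en <- min(Lc, en + 3L)
        if (strand == "-") { tmp <- st; st <- Lc - en; en <- Lc - tmp }
        all_hits[[length(all_hits) + 1L]] <- data.frame(
          contig = cname, start = st, end = en, strand = strand,
          family = best, score = unname(max(fam_scores)),
          evalue = db_size * exp(-max(vg$chunk_score)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(all_hits)) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      family = character(0), score = numeric(0),
                      evalue = numeric(0), seq = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("genome_hits", "data.frame")
    return(out)
  }
  h <- do.call(rbind, all_hits)

  # final non-overlap pass per (contig, strand): union intervals, keep
  # the best-scoring family (multi-profile overlap rule)
  out <- list()
  for (key in unique(paste(h$contig, h$strand))) {
    hk <- h[paste(h$contig, h$strand) == key, , drop = FALSE]
    hk <- hk[order(hk$start, hk$end), , drop = FALSE]
    i <- 1L
    while (i <= nrow(hk)) {
      j <- i
      en <- hk$end[i]
      while (j < nrow(hk) && hk$start[j + 1L] < en) {
        j <- j + 1L
        en <- max(en, hk$end[j])
      }
      blk <- hk[i:j, , drop = FALSE]
      top <- which.max(blk$score)
      rec <- blk[top, , drop = FALSE]
      rec$start <- min(blk$start); rec$end <- en
      rec$evalue <- min(blk$evalue)
      out[[length(out) + 1L]] <- rec
      i <- j + 1L
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res$seq <- vapply(seq_len(nrow(res)), function(i) {
    sub <- substr(contigs[[res$contig[i]]], res$start[i] + 1L, res$end[i])
    if (res$strand[i] == "-") revcomp(sub) else sub
  }, character(1))
  class(res) <- c("genome_hits", "data.frame")
  attr(res, "params") <- list(evalue = evalue, db_size = db_size,
                              score_min = score_min)
  res
}

#' @export
print.genome_hits <- function(x, ...) {
  cat("genome_hits:", nrow(x), "loci on",
      length(unique(x$contig)), "contig(s)\n")
  if (nrow(x)) print.data.frame(utils::head(
    x[, c("contig", "start", "end", "strand", "family", "score")], 20))
  invisible(x)
}

#' Write hits as BED6
#'
#' name = best family, score column = profile score (rounded), 0-based
#' half-open coordinates.
#'
#' @param hits a `genome_hits` data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$contig, hits$start, hits$end, hits$family,
                    round(hits$score, 1), hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extracted candidate sequences as a named vector
#'
#' Names follow `contig:start-end:strand`.
#'
#' @param hits a `genome_hits` data.frame.
#' @return named character vector of strand-corrected sequences.
#' @export
hit_sequences <- function(hits) {
  stats::setNames(hits$seq, sprintf("%s:%d-%d:%s", hits$contig,
                                    hits$start, hits$end, hits$strand))
}
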