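# End-to-end mining pipeline: scan -> dedup -> phylogenetic non-OR filter
# -> family assignment -> functional classification, producing one
# classified record per deduplicated candidate locus.

# Best translation of a candidate locus: the forward frame whose best
# profile score is highest. Returns the protein (stops kept as '*') and
# the winning frame/score.
candidate_translation <- function(seq, profiles) {
  best <- list(frame = 0L, score = -Inf, protein = "")
  for (f in 0:2) {
    prot <- translate_nt(seq, f)
    if (nchar(prot) < 10L) next
    sc <- max(vapply(profiles, function(p) profile_score(prot, p),
                     numeric(1)))
    if (sc > best$score) best <- list(frame = f, score = sc,
                                      protein = prot)
  }
  best
}

#' Mine and classify the OR repertoire of one genome assembly
#'
#' Runs the full pipeline: profile scan ([scan_genome()]), redundancy
#' merge ([dedup_cluster()]), per-representative phylogenetic non-OR
#' filter ([phylo_filter()], verdicts propagate to cluster members),
#' family assignment ([assign_family()]), and functional classification
#' (stop/frameshift/length rules via [detect_pseudogene_features()] and
#' the TM count via [count_tm_domains()]).
#'
#' @param genome FASTA path / DNAStringSet / named character contigs.
#' @param profiles a `family_profile_set`.
#' @param panel a `reference_panel` (or list with or_refs/nonor_refs).
#' @param species species label attached to every record.
#' @param evalue scan significance threshold.
#' @param dedup_threshold identity threshold for the redundancy merge.
#' @return data.frame of class `or_records`, one row per deduplicated
#'   candidate: id, species, contig, start, end, strand, status
#'   (functional / sub7TM / pseudogene / removed_nonOR), family,
#'   length_nt, has_premature_stop, has_frameshift, tm_count, score,
#'   margin, nearest_reference, n_members, seq.
#' @export
mine_or_repertoire <- function(genome, profiles, panel,
                               species = "species", evalue = 1e-10,
                               dedup_threshold = 0.98) {
  hits <- scan_genome(profiles, genome, evalue = evalue)
  if (!nrow(hits)) return(.empty_records())
  cl <- dedup_cluster(hits, threshold = dedup_threshold)
  reps <- cl$hits
  ids <- names(hit_sequences(reps))
  n_members <- table(cl$member_map)[ids]

  trans <- lapply(reps$seq, candidate_translation, profiles = profiles)
  prots <- vapply(trans, `[[`, "", "protein")
  names(prots) <- ids
  verdicts <- phylo_filter(prots, panel)
  calls <- assign_family(prots, profiles)

  rows <- lapply(seq_along(ids), function(i) {
    keep <- verdicts$keep[i]
    fam <- calls$family_id[i]
    ref_fam <- calls$best_family[i]
    feat <- detect_pseudogene_features(
      reps$seq[i], profiles[[ref_fam]]$ref_cds,
      reference_id = profiles[[ref_fam]]$ref_id)
    tm <- NA_integer_
    status <- if (!keep) "removed_nonOR" else {
      pre <- classify_status(feat$has_premature_stop,
                             feat$frameshift$has_frameshift,
                             feat$length_nt)
      if (pre == "pseudogene") "pseudogene" else {
        prot_clean <- gsub("\\*.*$", "", sub("^X+", "", prots[i]))
        tm <- if (nchar(prot_clean) >= 100L)
          count_tm_domains(prot_clean)$tm_count else 0L
        classify_status(FALSE, FALSE, feat$length_nt, tm)
      }
    }
    data.frame(id = ids[i], species = species,
               contig = reps$contig[i], start = reps$start[i],
               end = reps$end[i], strand = reps$strand[i],
               status = status, family = fam,
               length_nt = feat$length_nt,
               has_premature_stop = feat$has_premature_stop,
               has_frameshift = feat$frameshift$has_frameshift,
               tm_count = tm, score = calls$score[i],
               margin = calls$margin[i],
               nearest_reference = verdicts$nearest_reference_id[i],
               n_members = as.integer(n_members[i]),
               seq = reps$seq[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("or_records", "data.frame")
  out
}

.empty_records <- function() {
  out <- data.frame(id = character(0), species = character(0),
                    contig = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    status = character(0), family = character(0),
                    length_nt = integer(0),
                    has_premature_stop = logical(0),
                    has_frameshift = logical(0), tm_count = integer(0),
                    score = numeric(0), margin = numeric(0),
                    nearest_reference = character(0),
                    n_members = integer(0), seq = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("or_records", "data.frame")
  out
}

#' @export
print.or_records <- function(x, ...) {
  cat("or_records:", nrow(x), "classified loci\n")
  if (nrow(x)) print(table(x$status))
  invisible(x)
}

#' Compare mined records against a synthetic truth table
#'
#' Matches each truth plant to the mined record whose interval overlaps
#' it most (same contig), and reports the fraction of plants whose mined
#' status equals the intended status. Intact (intended-functional)
#' plants must additionally be covered over at least `min_overlap` of
#' their planted length; operator-bearing plants only need to be
#' detected, since truncations legitimately shrink the mined locus.
#'
#' @param records an `or_records` data.frame.
#' @param truth the `truth` table from [make_genome()].
#' @param min_overlap minimum overlap fraction for intact plants.
#' @return list: `agreement` (fraction), `table` (per-plant detail).
#' @export
score_against_truth <- function(records, truth, min_overlap = 0.9) {
  detail <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    cand <- records[records$contig == tr$contig, , drop = FALSE]
    ov <- pmax(0L, pmin(cand$end, tr$end) - pmax(cand$start, tr$start))
    ok <- which(ov > 0L)
    j <- if (length(ok)) ok[which.max(ov[ok])] else NA_integer_
    data.frame(
      name = tr$name, intended = tr$intended_status,
      observed = if (is.na(j)) "missing" else cand$status[j],
      overlap = if (is.na(j)) 0 else ov[j] / (tr$end - tr$start),
      strand_ok = if (is.na(j)) NA else cand$strand[j] == tr$strand,
      family_ok = if (is.na(j)) NA else cand$family[j] == tr$family,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, detail)
  need <- ifelse(truth$intended_status == "functional", min_overlap, 0)
  agree <- tab$observed == tab$intended & tab$overlap > 0 &
    tab$overlap >= need
  list(agreement = mean(agree), table = tab)
}
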