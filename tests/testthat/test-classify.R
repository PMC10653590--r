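# three-frame oracle for frameshift detection: translate both halves of
# the candidate in all three frames, find which ABSOLUTE reading frame
# best matches the reference protein in each half (allowing one codon of
# positional slop), and call a frameshift iff the frame switches
three_frame_oracle <- function(nt, ref_protein) {
  match_frac <- function(aa_part, ref_part) {
    a <- strsplit(aa_part, "")[[1]]; b <- strsplit(ref_part, "")[[1]]
    best <- 0
    for (s in -1:1) {
      aa <- if (s >= 0) a[seq_len(length(a) - s) + s] else a
      bb <- if (s < 0) b[seq_len(length(b) + s) - s] else b
      m <- min(length(aa), length(bb))
      best <- max(best, mean(aa[seq_len(m)] == bb[seq_len(m)]))
    }
    best
  }
  n <- nchar(nt)
  cut <- n %/% 2
  ref1 <- substr(ref_protein, 1, nchar(ref_protein) %/% 2)
  ref2 <- substr(ref_protein, nchar(ref_protein) %/% 2 + 1,
                 nchar(ref_protein))
  f1 <- which.max(vapply(0:2, function(f)
    match_frac(translate_nt(substr(nt, 1, cut), f), ref1), 1)) - 1L
  f2 <- which.max(vapply(0:2, function(f)
    match_frac(translate_nt(substr(nt, cut + 1, n), f), ref2), 1)) - 1L
  abs1 <- f1 %% 3L
  abs2 <- (cut + f2) %% 3L
  abs1 != abs2
}

test_that("pseudogene features are detected against the reference CDS", {
  ref <- or_template_cds("4")
  ref_aa <- sub("[*]$", "", translate_nt(ref))
  # clean input
  f0 <- detect_pseudogene_features(ref, ref)
  expect_false(f0$has_premature_stop)
  expect_false(f0$frameshift$has_frameshift)
  expect_identical(f0$length_nt, 933L)
  # codon 10 mutated to TGA
  stopped <- paste0(substr(ref, 1, 27), "TGA", substr(ref, 31, 933))
  fs <- detect_pseudogene_features(stopped, ref)
  expect_true(fs$has_premature_stop)
  # one base deleted at position 300: frameshift of length 1
  del <- paste0(substr(ref, 1, 299), substr(ref, 301, 933))
  fd <- detect_pseudogene_features(del, ref)
  expect_true(fd$frameshift$has_frameshift)
  expect_true(1L %in% fd$frameshift$lengths)
  expect_true(three_frame_oracle(del, ref_aa))
  expect_false(three_frame_oracle(ref, ref_aa))
  # in-frame 3-nt deletion is not a frameshift
  del3 <- paste0(substr(ref, 1, 299), substr(ref, 303, 933))
  expect_false(detect_pseudogene_features(del3,
                                          ref)$frameshift$has_frameshift)
})

test_that("unanchored candidates fall back to the longest-ORF stop
          check", {
  ref <- or_template_cds("4")
  junk <- with_seed(13, paste0(sample(c("A", "C", "G", "T"), 900,
                                      replace = TRUE), collapse = ""))
  f <- detect_pseudogene_features(junk, ref)
  expect_false(f$anchored)
})

test_that("hydropathy scan counts planted helices", {
  # moderately hydrophobic 21-mers (Ala, KD 1.8) with 10-residue polar
  # loops: only windows fully inside a block clear the 1.6 threshold
  hydro <- strrep("A", 21)
  polar <- strrep("N", 10)
  prot7 <- paste0(rep(c(hydro, polar), 7), collapse = "")
  expect_identical(count_tm_domains(prot7)$tm_count, 7L)
  # replace one hydrophobic block by polar residues -> six helices
  prot6 <- paste0(c(rep(c(hydro, polar), 3), strrep("N", 31),
                    rep(c(hydro, polar), 3)), collapse = "")
  expect_identical(count_tm_domains(prot6)$tm_count, 6L)
  expect_identical(count_tm_domains(strrep("S", 300))$tm_count, 0L)
  # strongly hydrophobic template architecture (22-mers, 19-loops)
  expect_identical(count_tm_domains(or_template_protein("4"))$tm_count,
                   7L)
  # helices are ordered and non-overlapping
  tm <- count_tm_domains(prot7)
  expect_true(all(diff(tm$helices$start) > 0))
  expect_true(all(tm$helices$end[-7] <= tm$helices$start[-1]))
  expect_error(count_tm_domains(strrep("L", 50)), "100")
  expect_error(count_tm_domains(paste0(strrep("B", 50),
                                       strrep("L", 150))),
               "non-standard")
})

test_that("the status rules apply the 650-nt and seven-helix
          boundaries", {
  expect_identical(classify_status(FALSE, FALSE, 649L, 7L), "pseudogene")
  expect_identical(classify_status(FALSE, FALSE, 650L, 7L), "functional")
  expect_identical(classify_status(FALSE, FALSE, 933L, 7L), "functional")
  expect_identical(classify_status(FALSE, FALSE, 933L, 6L), "sub7TM")
  expect_identical(classify_status(TRUE, FALSE, 933L, 7L), "pseudogene")
  expect_identical(classify_status(FALSE, TRUE, 933L, 7L), "pseudogene")
})

test_that("pseudogenization operators flip status; none leaves it
          functional", {
  for (fam in c("51", "2-13", "14")) {
    cds <- or_template_cds(fam)
    aa <- sub("[*]$", "", translate_nt(cds))
    tm <- count_tm_domains(aa)$tm_count
    f <- detect_pseudogene_features(cds, cds)
    expect_identical(classify_status(f$has_premature_stop,
                                     f$frameshift$has_frameshift,
                                     f$length_nt, tm), "functional")
    for (op in c("premature_stop", "frameshift_indel", "truncate")) {
      mut <- apply_operator(cds, op, seed = 11L,
                            len = if (op == "truncate") 600L else 1L)
      fm <- detect_pseudogene_features(mut, cds)
      expect_identical(classify_status(fm$has_premature_stop,
                                       fm$frameshift$has_frameshift,
                                       fm$length_nt, 7L), "pseudogene")
    }
  }
})

test_that("alignment trimming removes columns above 80% missing and is
          idempotent", {
  # 10-row toy: one column with 9 gaps (0.9 missing) is removed
  rows <- c(paste0("A", "A"), rep(paste0("A", "-"), 9))
  out <- trim_alignment(rows)
  expect_identical(unname(nchar(out)), rep(1L, 10))
  # gap-free alignment unchanged
  clean <- rep("ACDEF", 4)
  expect_identical(unname(trim_alignment(clean)), clean)
  # column missing fractions {0, 0.2, 0.8, 0.81, 1.0} -> 3 retained
  M <- matrix("A", nrow = 100, ncol = 5)
  M[seq_len(20), 2] <- "-"
  M[seq_len(80), 3] <- "-"
  M[seq_len(81), 4] <- "-"
  M[, 5] <- "-"
  out2 <- trim_alignment(M)
  expect_identical(ncol(out2), 3L)
  expect_identical(trim_alignment(out2), out2)
  expect_error(trim_alignment(character(0)), "empty")
})
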