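mk_records <- function(species, status, family) {
  data.frame(species = species, status = status, family = family,
             stringsAsFactors = FALSE)
}

test_that("repertoire aggregation computes exact counts and fractions", {
  expect_identical(nrow(summarize_repertoire(
    mk_records(character(0), character(0), character(0)))), 0L)
  rec <- mk_records("sp1",
                    c("functional", "functional", "functional",
                      "pseudogene"),
                    c("4", "4", "6", "4"))
  tab <- summarize_repertoire(rec)
  expect_identical(tab$n_functional, 3L)
  expect_identical(tab$fam_4, 2L)
  expect_identical(tab$fam_6, 1L)
  expect_identical(tab$pseudogene, 1L)
  expect_identical(tab$fraction_functional, 0.75)
  expect_error(summarize_repertoire(
    mk_records("sp1", "sometimes", "4")), "unknown status")
  # count conservation over a random record set
  rec2 <- with_seed(31, mk_records(
    sample(c("sp1", "sp2", "sp3"), 200, replace = TRUE),
    sample(c("functional", "sub7TM", "pseudogene"), 200, replace = TRUE),
    sample(or_families(), 200, replace = TRUE)))
  tab2 <- summarize_repertoire(rec2)
  expect_identical(sum(tab2$n_total), 200L)
  expect_identical(tab2$n_functional,
                   as.integer(rowSums(tab2[, paste0("fam_",
                     gsub("-", "_", or_families()))])))
})

test_that("family normalization gives row-sum-1 proportions and
          column-mean-1 rescaling", {
  counts <- with_seed(32, matrix(rpois(5 * 13, 30) + 1L, 5, 13))
  tab <- as_repertoire_table(data.frame(
    species = paste0("sp", 1:5),
    stats::setNames(as.data.frame(counts), or_families()),
    check.names = FALSE))
  P <- normalize_families(tab)
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
  # proportions stage is idempotent
  expect_equal(sweep(P, 1L, rowSums(P), "/"), P, tolerance = 1e-15)
  R <- normalize_families(tab, rescale_columns = TRUE)
  expect_equal(unname(colMeans(R)), rep(1, 13), tolerance = 1e-12)
  # two species with family-4 proportions 0.1 / 0.3 rescale to 0.5 / 1.5
  t2 <- as_repertoire_table(data.frame(
    species = c("u", "v"),
    stats::setNames(as.data.frame(rbind(c(10, rep(7.5, 12)),
                                        c(90, rep(17.5, 12)))),
                    c("4", setdiff(or_families(), "4"))),
    check.names = FALSE))
  P2 <- normalize_families(t2)
  expect_equal(unname(P2[, "4"]), c(0.1, 0.3), tolerance = 1e-12)
  R2 <- normalize_families(t2, rescale_columns = TRUE)
  expect_equal(unname(R2[, "4"]), c(0.5, 1.5), tolerance = 1e-12)
  # single species: every rescaled entry is 1
  R1 <- normalize_families(t2[1, ], rescale_columns = TRUE)
  expect_equal(unname(R1[1, ]), rep(1, 13), tolerance = 1e-12)
})

test_that("table statistics match a sort-based median oracle", {
  # per-species functional totals 370 (gundi-like minimum), 780, 1737
  # (agouti-like maximum), built from family counts that sum exactly
  mk_counts <- function(total) c(total - 12L, rep(1L, 12))
  tab <- as_repertoire_table(data.frame(
    species = c("gundi", "median_sp", "agouti"),
    stats::setNames(as.data.frame(rbind(mk_counts(370L),
                                        mk_counts(780L),
                                        mk_counts(1737L))),
                    or_families()),
    check.names = FALSE))
  st <- repertoire_stats(tab)
  row <- st[st$column == "n_functional", ]
  expect_equal(row$median, 780)
  expect_equal(row$min, 370)
  expect_equal(row$max, 1737)
  expect_identical(row$argmin_species, "gundi")
  expect_identical(row$argmax_species, "agouti")
  # mid-mean median for even n, against a sort oracle
  x <- c(370L, 780L, 1737L, 512L)
  tab2 <- as_repertoire_table(data.frame(
    species = paste0("s", 1:4),
    stats::setNames(as.data.frame(t(vapply(x, mk_counts,
                                           integer(13)))),
                    or_families()),
    check.names = FALSE))
  st2 <- repertoire_stats(tab2)
  s <- sort(x)
  expect_equal(st2$median[st2$column == "n_functional"],
               mean(s[2:3]))
})

test_that("pre-counted tables round-trip through TSV", {
  counts <- with_seed(34, matrix(rpois(3 * 13, 50), 3, 13))
  df <- data.frame(species = c("a", "b", "c"),
                   stats::setNames(as.data.frame(counts), or_families()),
                   pseudogene = c(5L, 10L, 20L), check.names = FALSE)
  tab <- as_repertoire_table(df)
  expect_identical(tab$n_total, tab$n_functional + tab$pseudogene)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire(tab, path)
  back <- read_repertoire(path)
  expect_equal(back$n_functional, tab$n_functional)
  expect_equal(back$fraction_functional, tab$fraction_functional)
})
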