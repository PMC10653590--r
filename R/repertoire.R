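# Per-species repertoire tables: per-family functional counts, sub-7TM
# and pseudogene counts, totals and fractions, plus the family-proportion
# normalizations used for ordination and multivariate model fitting.

.fam_col <- function(f) paste0("fam_", gsub("-", "_", f))

#' Aggregate classified records into a per-species repertoire table
#'
#' @param records an `or_records` data.frame (or any data.frame with
#'   columns species, status, family).
#' @return data.frame of class `repertoire_table`, one row per species
#'   (sorted): 13 per-family functional counts, sub7TM, pseudogene,
#'   removed_nonOR, n_functional, n_total (= functional + sub7TM +
#'   pseudogene), fraction_functional (functional / n_total),
#'   fraction_functional_fp (functional / (functional + pseudogene),
#'   the sub-7TM-free convention), class1_fraction.
#' @export
summarize_repertoire <- function(records) {
  stopifnot(all(c("species", "status", "family") %in% names(records)))
  bad <- setdiff(unique(records$status),
                 c("functional", "sub7TM", "pseudogene", "removed_nonOR"))
  if (length(bad)) stop("unknown status: ", paste(bad, collapse = ", "))
  species <- sort(unique(records$species))
  rows <- lapply(species, function(sp) {
    r <- records[records$species == sp, , drop = FALSE]
    fun <- r[r$status == "functional", , drop = FALSE]
    famc <- vapply(OR_FAMILIES, function(f) sum(fun$family == f),
                   integer(1))
    n_func <- sum(famc)
    n_sub <- sum(r$status == "sub7TM")
    n_pse <- sum(r$status == "pseudogene")
    n_rem <- sum(r$status == "removed_nonOR")
    n_tot <- n_func + n_sub + n_pse
    out <- c(list(species = sp),
             stats::setNames(as.list(famc), .fam_col(OR_FAMILIES)),
             list(sub7TM = n_sub, pseudogene = n_pse,
                  removed_nonOR = n_rem, n_functional = n_func,
                  n_total = n_tot,
                  fraction_functional =
                    if (n_tot > 0) n_func / n_tot else NA_real_,
                  fraction_functional_fp =
                    if (n_func + n_pse > 0) n_func / (n_func + n_pse)
                    else NA_real_,
                  class1_fraction = if (n_func > 0)
                    sum(famc[CLASS_I_FAMILIES]) / n_func else NA_real_))
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(OR_FAMILIES) + 9L)),
      c("species", .fam_col(OR_FAMILIES), "sub7TM", "pseudogene",
        "removed_nonOR", "n_functional", "n_total",
        "fraction_functional", "fraction_functional_fp",
        "class1_fraction"))
  rownames(tab) <- NULL
  class(tab) <- c("repertoire_table", "data.frame")
  tab
}

#' Build a repertoire table from pre-counted per-species data
#'
#' Ingests a table (e.g. a published per-species count table) with one
#' row per species, 13 per-family functional count columns named after
#' the families (any of "51", "fam_51", "OR51" styles), and optional
#' sub7TM / pseudogene count columns.
#'
#' @param counts data.frame or TSV path.
#' @param species_col name of the species column.
#' @return a `repertoire_table`.
#' @export
as_repertoire_table <- function(counts, species_col = "species") {
  if (is.character(counts) && length(counts) == 1L)
    counts <- utils::read.delim(counts, stringsAsFactors = FALSE,
                                check.names = FALSE)
  norm_name <- function(x) gsub("[-_/]", "", sub("^(fam|or)", "",
                                                 tolower(x)))
  want <- norm_name(OR_FAMILIES)
  hit <- match(want, norm_name(names(counts)))
  if (anyNA(hit))
    stop("missing family count columns: ",
         paste(OR_FAMILIES[is.na(hit)], collapse = ", "))
  famM <- as.matrix(counts[, hit, drop = FALSE])
  colnames(famM) <- .fam_col(OR_FAMILIES)
  aux <- function(nm) {
    j <- match(nm, tolower(names(counts)))
    if (is.na(j)) rep(0L, nrow(counts)) else as.integer(counts[[j]])
  }
  tab <- data.frame(species = counts[[species_col]], famM,
                    sub7TM = aux("sub7tm"), pseudogene = aux("pseudogene"),
                    removed_nonOR = 0L, stringsAsFactors = FALSE)
  tab$n_functional <- as.integer(rowSums(famM))
  tab$n_total <- tab$n_functional + tab$sub7TM + tab$pseudogene
  tab$fraction_functional <- ifelse(tab$n_total > 0,
                                    tab$n_functional / tab$n_total, NA)
  tab$fraction_functional_fp <- ifelse(
    tab$n_functional + tab$pseudogene > 0,
    tab$n_functional / (tab$n_functional + tab$pseudogene), NA)
  tab$class1_fraction <- rowSums(famM[, .fam_col(CLASS_I_FAMILIES),
                                      drop = FALSE]) /
    pmax(1L, tab$n_functional)
  tab <- tab[order(tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("repertoire_table", "data.frame")
  tab
}

#' Normalize family counts to proportions (and optional column rescaling)
#'
#' Each species' 13 family counts are divided by its total functional
#' count, so rows sum to 1. With `rescale_columns = TRUE`, every family
#' column is then divided by its mean, so each family column has mean 1
#' (the heatmap normalization).
#'
#' @param table a `repertoire_table`.
#' @param rescale_columns logical.
#' @return numeric matrix species x 13 families, with attribute
#'   `rescaled`.
#' @export
normalize_families <- function(table, rescale_columns = FALSE) {
  M <- as.matrix(table[, .fam_col(OR_FAMILIES), drop = FALSE])
  rownames(M) <- table$species
  colnames(M) <- OR_FAMILIES
  nf <- rowSums(M)
  zero <- table$species[nf == 0]
  if (length(zero))
    stop("species with no functional genes: ",
         paste(zero, collapse = ", "))
  P <- sweep(M, 1L, nf, "/")
  if (rescale_columns) P <- sweep(P, 2L, colMeans(P), "/")
  attr(P, "rescaled") <- rescale_columns
  P
}

#' Column summary statistics of a repertoire table
#'
#' Median (mid-mean for even n), mean, min, max per numeric column, with
#' the species attaining the extremes.
#'
#' @param table a `repertoire_table`.
#' @return data.frame: column, median, mean, min, max, argmin_species,
#'   argmax_species.
#' @export
repertoire_stats <- function(table) {
  stopifnot(nrow(table) >= 1L)
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  rows <- lapply(num, function(cn) {
    x <- table[[cn]]
    data.frame(column = cn, median = stats::median(x), mean = mean(x),
               min = min(x), max = max(x),
               argmin_species = table$species[which.min(x)],
               argmax_species = table$species[which.max(x)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a repertoire table as TSV
#' @param table a `repertoire_table`.
#' @param path file path.
#' @return `path` invisibly / the reloaded table.
#' @export
write_repertoire <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_repertoire
#' @export
read_repertoire <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(tab) <- c("repertoire_table", "data.frame")
  tab
}
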