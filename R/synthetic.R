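# Ground-truthed synthetic data: OR-like templates with seven planted
# transmembrane blocks, pseudogenization operators, genomes with planted
# genes and non-OR GPCR decoys, and traits simulated under BM/lambda/OU.
#
# Templates are deterministic functions of the family label, so the seed
# sets, reference panel, and planted genes all derive from the same
# underlying gene models.

.HYDROPHOBIC <- c("I", "L", "V", "F")
# strongly polar loop residues, so helix boundaries stay sharp under the
# hydropathy scan even after moderate sequence divergence
.POLAR <- c("N", "Q", "E", "D", "K", "R", "H", "P")

# Non-OR GPCR decoy lineages (the real pipeline's escapees were
# melanocortin-1 receptor, TAAR2, and 5-HT1A -type sequences).
NONOR_LINEAGES <- c("MC1R-like", "TAAR2-like", "HTR1A-like")

# Reverse genetic code: codons per amino acid (stops excluded).
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
})

.template_seed <- function(label) {
  7000L + match(label, c(OR_FAMILIES, NONOR_LINEAGES))
}

#' Synthetic OR template protein for one family
#'
#' A 310-residue seven-transmembrane architecture: a 20-residue N-terminal
#' loop, seven 22-residue strongly hydrophobic helices separated by
#' 19-residue polar loops, and a 22-residue C-terminal tail. Residues are
#' drawn from hydrophobic/polar pools with a family-specific seed, so
#' different families are unrelated outside the shared architecture.
#'
#' @param family family label (one of [or_families()] or a decoy lineage).
#' @return character scalar, 310-aa protein.
#' @export
or_template_protein <- function(family) {
  seed <- .template_seed(family)
  if (is.na(seed)) stop("unknown template label: ", family)
  with_seed(seed, {
    block <- function(n, pool) paste0(sample(pool, n, replace = TRUE),
                                      collapse = "")
    parts <- character(0)
    parts <- c(parts, block(20, .POLAR))
    for (k in 1:7) {
      parts <- c(parts, block(22, .HYDROPHOBIC))
      if (k < 7) parts <- c(parts, block(19, .POLAR))
    }
    parts <- c(parts, block(22, .POLAR))
    paste0(parts, collapse = "")
  })
}

#' Back-translate a protein to a coding sequence
#'
#' Codons are sampled uniformly among the synonymous codons of each
#' residue, reproducibly for a given seed. A TAA terminal stop is appended.
#'
#' @param protein character scalar (no stops).
#' @param seed integer seed for codon choice.
#' @return character scalar CDS (length `3 * nchar(protein) + 3`).
#' @export
backtranslate <- function(protein, seed = 1L) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), names(.codons_by_aa))
  if (length(bad)) stop("cannot back-translate residues: ",
                        paste(bad, collapse = ", "))
  with_seed(seed, {
    codons <- vapply(ch, function(a) {
      cs <- .codons_by_aa[[a]]
      cs[sample.int(length(cs), 1L)]
    }, character(1))
    paste0(paste0(codons, collapse = ""), "TAA")
  })
}

#' Template coding sequence for one family
#' @inheritParams or_template_protein
#' @return 933-nt CDS (930 coding + terminal TAA).
#' @export
or_template_cds <- function(family) {
  backtranslate(or_template_protein(family), seed = .template_seed(family))
}

#' Mutate a coding sequence by random substitutions
#'
#' Substitutes a `rate` fraction of positions uniformly to another base.
#' With `avoid_stops = TRUE` (default) any substitution that would create
#' an in-frame stop codon before the terminal codon is resampled, so the
#' mutated sequence keeps its intended (functional) reading frame at any
#' divergence. The terminal stop codon is never touched.
#'
#' @param cds character scalar coding sequence (length divisible by 3).
#' @param rate substitution fraction in `[0, 1)`.
#' @param seed integer seed.
#' @param avoid_stops logical; resample substitutions creating in-frame
#'   stops.
#' @return mutated sequence, same length.
#' @export
mutate_cds <- function(cds, rate, seed = 1L, avoid_stops = TRUE) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("coding sequence length not divisible by 3")
  if (rate <= 0) return(cds)
  with_seed(seed, {
    ch <- strsplit(toupper(cds), "", fixed = TRUE)[[1]]
    mutable <- seq_len(n - 3L)  # keep the terminal stop codon
    k <- round(rate * n)
    k <- min(k, length(mutable))
    pos <- sort(sample(mutable, k))
    bases <- c("A", "C", "G", "T")
    for (p in pos) {
      alt <- setdiff(bases, ch[p])
      repeat {
        new <- sample(alt, 1L)
        old <- ch[p]
        ch[p] <- new
        if (!avoid_stops) break
        cod_start <- 3L * ((p - 1L) %/% 3L) + 1L
        codon <- paste0(ch[cod_start:(cod_start + 2L)], collapse = "")
        if (!(codon %in% STOP_CODONS)) break
        ch[p] <- old
        alt <- setdiff(alt, new)
        if (!length(alt)) break
      }
    }
    paste0(ch, collapse = "")
  })
}

#' Mutate a protein by random substitutions
#' @param protein character scalar.
#' @param rate substitution fraction.
#' @param seed integer seed.
#' @return mutated protein.
#' @export
mutate_protein <- function(protein, rate, seed = 1L) {
  if (rate <= 0) return(protein)
  with_seed(seed, {
    ch <- strsplit(protein, "", fixed = TRUE)[[1]]
    k <- round(rate * length(ch))
    pos <- sample(seq_along(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
    paste0(ch, collapse = "")
  })
}

#' Build a seed set of coding sequences for profile construction
#'
#' For each family, the template CDS plus `n_per_family - 1` mutated
#' copies at the given divergence, labelled with synthetic species names.
#'
#' @param families family labels (default all 13).
#' @param n_per_family sequences per family.
#' @param divergence nucleotide substitution fraction for the non-template
#'   seeds.
#' @param seed integer seed.
#' @return data.frame with columns family, gene, species, cds.
#' @export
make_seed_set <- function(families = or_families(), n_per_family = 4,
                          divergence = 0.05, seed = 101L) {
  rows <- list()
  for (fi in seq_along(families)) {
    fam <- families[fi]
    cds0 <- or_template_cds(fam)
    for (j in seq_len(n_per_family)) {
      s <- if (j == 1L) cds0 else
        mutate_cds(cds0, divergence, seed = seed + 1000L * fi + j)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam,
        gene = sprintf("OR%s_g%d", gsub("-", "", fam), j),
        species = sprintf("species_%d", j),
        cds = s, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build a synthetic OR / non-OR reference panel
#'
#' Emulates the verified panel used by the phylogenetic non-OR filter:
#' two OR reference proteins per family (26 total) and 11 non-OR GPCR
#' proteins derived from three decoy lineages that sit at roughly 35%
#' amino-acid divergence from their nearest OR family.
#'
#' @param or_divergence amino-acid divergence of panel ORs from the family
#'   templates.
#' @param seed integer seed.
#' @return list with elements `or_refs`, `nonor_refs` (named character
#'   vectors of proteins) and `labels` (named "OR"/"NONOR" vector).
#' @export
make_reference_panel <- function(or_divergence = 0.04, seed = 202L) {
  or_refs <- character(0)
  for (fi in seq_along(OR_FAMILIES)) {
    fam <- OR_FAMILIES[fi]
    tpl <- or_template_protein(fam)
    for (j in 1:2) {
      nm <- sprintf("ORref_%s_%d", gsub("-", "", fam), j)
      or_refs[nm] <- mutate_protein(tpl, or_divergence,
                                    seed = seed + 100L * fi + j)
    }
  }
  nonor_refs <- character(0)
  per <- c(4L, 4L, 3L)
  for (li in seq_along(NONOR_LINEAGES)) {
    tpl <- nonor_template_protein(NONOR_LINEAGES[li])
    for (j in seq_len(per[li])) {
      nm <- sprintf("NONOR_%s_%d", sub("-like", "", NONOR_LINEAGES[li]), j)
      nonor_refs[nm] <- mutate_protein(tpl, 0.05,
                                       seed = seed + 9000L + 50L * li + j)
    }
  }
  labels <- c(stats::setNames(rep("OR", length(or_refs)), names(or_refs)),
              stats::setNames(rep("NONOR", length(nonor_refs)),
                              names(nonor_refs)))
  list(or_refs = or_refs, nonor_refs = nonor_refs, labels = labels)
}

#' Non-OR GPCR decoy template protein
#'
#' Each decoy lineage is a heavily diverged (35% amino-acid) derivative of
#' one class II OR family template: homologous enough that the profile
#' scan picks it up, but phylogenetically outside the OR references.
#'
#' @param lineage one of `r paste(NONOR_LINEAGES, collapse = ", ")`.
#' @return character scalar protein.
#' @export
nonor_template_protein <- function(lineage) {
  src <- c("MC1R-like" = "1-3-7", "TAAR2-like" = "6", "HTR1A-like" = "10")
  fam <- src[[lineage]]
  mutate_protein(or_template_protein(fam), 0.35,
                 seed = .template_seed(lineage))
}

#' Apply a pseudogenization operator to a coding sequence
#'
#' Operators mirror the inactivating lesions used to call pseudogenes:
#' `premature_stop` mutates one mid-sequence codon to TGA;
#' `frameshift_indel` inserts or deletes `len` bases at a random internal
#' position; `truncate` keeps the first `len` bases;
#' `reverse_complement` reverse-complements; `none` is the identity.
#'
#' @param seq coding sequence.
#' @param operator operator name.
#' @param seed integer seed.
#' @param len indel length (frameshift_indel) or kept length (truncate).
#' @return mutated sequence.
#' @export
apply_operator <- function(seq,
                           operator = c("none", "premature_stop",
                                        "frameshift_indel", "truncate",
                                        "reverse_complement"),
                           seed = 1L, len = 1L) {
  operator <- match.arg(operator)
  n <- nchar(seq)
  switch(operator,
    none = seq,
    reverse_complement = revcomp(seq),
    premature_stop = with_seed(seed, {
      ncod <- n %/% 3L
      cod <- sample(seq(max(2L, round(ncod * 0.2)), round(ncod * 0.8)), 1L)
      paste0(substr(seq, 1L, 3L * (cod - 1L)), "TGA",
             substr(seq, 3L * cod + 1L, n))
    }),
    frameshift_indel = with_seed(seed, {
      pos <- sample(seq(round(n * 0.2), round(n * 0.8)), 1L)
      if (stats::runif(1) < 0.5) {
        ins <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
        paste0(substr(seq, 1L, pos), ins, substr(seq, pos + 1L, n))
      } else {
        paste0(substr(seq, 1L, pos), substr(seq, pos + len + 1L, n))
      }
    }),
    truncate = {
      if (len >= n) stop("truncate length (", len,
                         ") must be shorter than the sequence (", n, ")")
      substr(seq, 1L, len)
    })
}

# Intended classification status implied by a plant's operator.
.intended_status <- function(operator, len) {
  if (operator == "nonor_decoy") return("removed_nonOR")
  if (operator == "premature_stop") return("pseudogene")
  if (operator == "frameshift_indel")
    return(if (len %% 3L != 0L) "pseudogene" else "functional")
  if (operator == "truncate") return(if (len < 650L) "pseudogene"
                                     else "functional")
  "functional"
}

#' Plant specification table for [make_genome()]
#'
#' @param family family label per plant (decoy plants use a decoy lineage
#'   via `operator = "nonor_decoy"` and ignore this label's profile role).
#' @param operator one of none, premature_stop, frameshift_indel, truncate,
#'   reverse_complement, nonor_decoy.
#' @param divergence per-plant substitution fraction applied before the
#'   operator.
#' @param len operator length argument (indel length / truncation length).
#' @param start 0-based plant start, or NA to auto-place evenly.
#' @return data.frame of class "plant_spec".
#' @export
plant_spec <- function(family, operator = "none", divergence = 0,
                       len = NA_integer_, start = NA_integer_) {
  k <- length(family)
  df <- data.frame(family = rep_len(family, k),
                   operator = rep_len(operator, k),
                   divergence = rep_len(divergence, k),
                   len = rep_len(as.integer(len), k),
                   start = rep_len(as.integer(start), k),
                   stringsAsFactors = FALSE)
  class(df) <- c("plant_spec", "data.frame")
  df
}

#' Generate a synthetic genome with planted OR genes and a truth table
#'
#' The background is iid nucleotide sequence at the given GC content;
#' each plant overwrites the background at its (recorded) interval.
#' Coordinates are 0-based half-open on the forward strand; plants with
#' `operator = "reverse_complement"` (or `strand = "-"`) are inserted as
#' the reverse complement and recorded with strand "-".
#'
#' @param plants a [plant_spec()] data.frame (may have 0 rows).
#' @param background_length total contig length in nt.
#' @param gc background GC fraction.
#' @param seed integer seed (background, per-plant mutation, operators).
#' @param contig contig name.
#' @return list with `genome` (named character vector, one contig) and
#'   `truth` (data.frame: name, contig, start, end, strand, family,
#'   operator, divergence, intended_status, cds).
#' @export
make_genome <- function(plants = plant_spec(character(0)),
                        background_length = 100000L, gc = 0.4, seed = 1L,
                        contig = "synthetic_contig_1") {
  plants <- as.data.frame(plants)
  np <- nrow(plants)
  bg <- with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste0(sample(names(p), background_length, replace = TRUE, prob = p),
           collapse = "")
  })
  truth <- data.frame(name = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), family = character(0),
                      operator = character(0), divergence = numeric(0),
                      intended_status = character(0), cds = character(0),
                      stringsAsFactors = FALSE)
  if (np == 0L) {
    return(list(genome = stats::setNames(bg, contig), truth = truth))
  }

  # Build plant sequences.
  seqs <- character(np)
  strands <- character(np)
  fams <- character(np)
  for (i in seq_len(np)) {
    op <- plants$operator[i]
    fam <- plants$family[i]
    if (op == "nonor_decoy") {
      lineage <- if (fam %in% NONOR_LINEAGES) fam else NONOR_LINEAGES[1L]
      base <- backtranslate(nonor_template_protein(lineage),
                            seed = .template_seed(lineage) + 1L)
      fams[i] <- lineage
    } else {
      base <- or_template_cds(fam)
      fams[i] <- fam
    }
    s <- mutate_cds(base, plants$divergence[i], seed = seed + 31L * i)
    if (op %in% c("premature_stop", "frameshift_indel", "truncate")) {
      s <- apply_operator(s, op, seed = seed + 57L * i,
                          len = if (is.na(plants$len[i])) 1L
                                else plants$len[i])
    }
    strands[i] <- if (op == "reverse_complement") "-" else "+"
    seqs[i] <- s
  }

  # Place plants: given starts or evenly spaced with margins.
  lens <- nchar(seqs)
  starts <- plants$start
  if (anyNA(starts)) {
    gap <- (background_length - sum(lens)) %/% (np + 1L)
    if (gap < 100L) stop("background too short for ", np, " plants")
    pos <- integer(np)
    cur <- gap
    for (i in seq_len(np)) { pos[i] <- cur; cur <- cur + lens[i] + gap }
    starts <- ifelse(is.na(starts), pos, starts)
  }
  ends <- starts + lens
  if (any(starts < 0L) || any(ends > background_length))
    stop("plant interval outside genome bounds")
  o <- order(starts)
  if (np > 1L && any(starts[o][-1L] < ends[o][-np]))
    stop("overlapping plant intervals: ",
         paste(which(starts[o][-1L] < ends[o][-np]), collapse = ", "))

  genome <- bg
  for (i in seq_len(np)) {
    ins <- if (strands[i] == "-") revcomp(seqs[i]) else seqs[i]
    substr(genome, starts[i] + 1L, ends[i]) <- ins
  }
  truth <- data.frame(
    name = sprintf("plant_%02d", seq_len(np)),
    contig = contig, start = starts, end = ends, strand = strands,
    family = fams, operator = plants$operator,
    divergence = plants$divergence,
    intended_status = vapply(seq_len(np), function(i)
      .intended_status(plants$operator[i],
                       if (is.na(plants$len[i])) 1L else plants$len[i]),
      character(1)),
    cds = seqs, stringsAsFactors = FALSE)
  list(genome = stats::setNames(genome, contig), truth = truth)
}

#' Simulate continuous traits on a tree under BM, lambda-BM, or OU
#'
#' Exact multivariate-normal sampling from the model covariance.
#' BM: `V = sigma2 * C_lambda` where `C_lambda` scales the off-diagonal
#' entries of the phylogenetic covariance by `lambda`.
#' OU (root-conditioned, dated trees): `V_ij = sigma2/(2 alpha) *
#' exp(-alpha d_ij) (1 - exp(-2 alpha t_ij))` with `d_ij` the patristic
#' distance and `t_ij` the shared path length; tip means are the regime
#' optima `theta`. The model reduces to BM as `alpha -> 0`.
#'
#' @param tree an `ape::phylo` tree.
#' @param model "BM" or "OU".
#' @param sigma2 diffusion rate.
#' @param lambda Pagel's lambda (BM only).
#' @param alpha OU pull strength.
#' @param theta OU optima: scalar, or named by regime level.
#' @param regimes factor/character of regime labels named by tip.
#' @param root root state (BM mean).
#' @param reps number of replicate traits.
#' @param seed integer seed.
#' @return matrix tips x reps with tip labels as rownames.
#' @export
simulate_traits <- function(tree, model = c("BM", "OU"), sigma2 = 1,
                            lambda = 1, alpha = 1, theta = 0,
                            regimes = NULL, root = 0, reps = 1,
                            seed = NULL) {
  model <- match.arg(model)
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips")
  if (model == "BM") {
    C <- ape::vcv(tree)
    V <- sigma2 * (lambda * C + (1 - lambda) * diag(diag(C), n))
    mu <- rep(root, n)
  } else {
    C <- ape::vcv(tree)
    D <- stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
    V <- sigma2 * .ou_v0(alpha, C, D)
    if (is.null(regimes)) {
      mu <- rep(theta[1L], n)
    } else {
      reg <- as.character(regimes[tree$tip.label])
      if (anyNA(reg)) stop("regimes missing for some tips")
      mu <- theta[reg]
      if (anyNA(mu)) stop("theta missing for some regime levels")
    }
  }
  if (sigma2 == 0) {
    X <- matrix(rep(mu, reps), nrow = n,
                dimnames = list(tree$tip.label,
                                paste0("rep", seq_len(reps))))
    return(X)
  }
  ok <- tryCatch({ chol(V); TRUE }, error = function(e) FALSE)
  if (!ok) stop("model covariance is not positive definite")
  X <- with_seed(seed, rmvn_chol(reps, mu, V))
  rownames(X) <- tree$tip.label
  colnames(X) <- paste0("rep", seq_len(reps))
  X
}

#' The standard 20-plant validation genome
#'
#' A fixed layout exercising every classification outcome: 10 intact
#' genes (one per family for 10 families), 4 stop-disrupted, 3
#' frameshifted (indel lengths 1, 2, 4), 2 truncated below 650 nt, and 1
#' non-OR GPCR decoy. Families that occur more than once carry a 5%
#' base divergence so distinct paralogs stay below the 98% allele-merge
#' threshold; `divergence` is added on top of the base for every plant
#' (a sweep dial for recovery-vs-divergence checks).
#'
#' @param divergence extra per-plant substitution fraction.
#' @param background_length,seed passed to [make_genome()].
#' @return list(genome, truth) as from [make_genome()].
#' @export
make_validation_genome <- function(divergence = 0,
                                   background_length = 120000L,
                                   seed = 1L) {
  fams <- OR_FAMILIES
  spec <- plant_spec(
    family = c(fams[1:10],                      # intact, one per family
               "11", "12", "14", "51",          # premature stops
               "1-3-7", "6", "10",              # frameshifts
               "4", "12",                       # truncations
               "TAAR2-like"),                   # non-OR decoy
    operator = c(rep("none", 10), rep("premature_stop", 4),
                 rep("frameshift_indel", 3), rep("truncate", 2),
                 "nonor_decoy"),
    divergence = divergence +
      c(rep(0, 10), 0, 0, 0, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0),
    len = c(rep(NA, 14), 1L, 2L, 4L, 600L, 500L, NA))
  make_genome(spec, background_length = background_length, seed = seed)
}

#' The 13 OR family labels
#' @return character vector (class I: 51, 52, 55, 56; class II: the rest).
#' @export
or_families <- function() OR_FAMILIES
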