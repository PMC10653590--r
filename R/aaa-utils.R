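# Shared constants and low-level helpers.

# The 13 monophyletic OR gene families conserved across mammals.
# Families 51/52/55/56 form class I; the remaining nine form class II.
OR_FAMILIES <- c("51", "52", "55", "56",
                 "1-3-7", "2-13", "4", "5-8-9", "6", "10", "11", "12", "14")
CLASS_I_FAMILIES <- c("51", "52", "55", "56")

# Amino-acid alphabet used for profile scoring: 20 standard residues,
# X (unknown/ambiguous, scored 0) and * (stop, strongly penalized).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA20, "X", "*")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
              L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Run code with a private, restored RNG state
#'
#' Evaluates `expr` after `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded internals never perturb user-level streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Codon -> amino acid lookup (standard code, table 1). Codons containing
# ambiguity codes translate to X unless all completions agree.
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  aa <- as.character(gc)
  names(aa) <- names(gc)
  aa
})

#' Translate a nucleotide string in a given frame
#'
#' Standard genetic code; stop codons become `*`; codons with ambiguity
#' codes become `X`. The trailing partial codon is dropped.
#'
#' @param nt character scalar, nucleotide sequence.
#' @param frame 0, 1, or 2: offset of the first codon.
#' @return character scalar amino-acid sequence (may contain `*`/`X`).
#' @export
translate_nt <- function(nt, frame = 0) {
  stopifnot(length(nt) == 1L, frame %in% 0:2)
  s <- toupper(gsub("U", "T", nt))
  n <- nchar(s)
  start <- frame + 1L
  ncod <- (n - frame) %/% 3L
  if (ncod <= 0L) return("")
  pos <- start + 3L * (seq_len(ncod) - 1L)
  codons <- substring(s, pos, pos + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# Map a protein string to integer indices into AA_ALPHABET (X for unknown).
aa_index <- function(protein) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  i <- match(ch, AA_ALPHABET)
  i[is.na(i)] <- match("X", AA_ALPHABET)
  i
}

#' Reverse complement of a nucleotide string
#' @param nt character scalar.
#' @return character scalar.
#' @export
revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# Deterministic multivariate-normal sampler: mu + t(chol(V)) %*% z.
# Returns an n x reps matrix (columns are replicates).
rmvn_chol <- function(reps, mu, V) {
  n <- length(mu)
  L <- chol(V)
  Z <- matrix(stats::rnorm(n * reps), nrow = n, ncol = reps)
  sweep(crossprod(L, Z), 1L, mu, "+")
}

# Read a FASTA file (or pass through an XStringSet / named character vector)
# into a named character vector of sequences.
as_seq_vector <- function(x, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- if (type == "DNA") Biostrings::readDNAStringSet(x)
           else Biostrings::readAAStringSet(x)
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(set))
    return(out)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot interpret input as sequences (FASTA path, XStringSet, ",
       "or named character vector expected)")
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param type "DNA" or "AA".
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
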