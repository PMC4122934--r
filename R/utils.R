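# Shared internal helpers: alphabets, substitution matrix, RNG, formatting.

# 20 canonical amino acids; X is tolerated everywhere and scored 0.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

# Background amino-acid frequencies (BLOSUM62 marginals, Robinson-Robinson
# style); used to draw decoy proteins and root sequences.
AA_BACKGROUND <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
  G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
  M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
  S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)

.pkg_cache <- new.env(parent = emptyenv())

# BLOSUM62 restricted to the 20 canonical residues plus X, with X scored 0
# against everything (design choice: ambiguity is neutral, never rewarded).
blosum62x <- function() {
  if (is.null(.pkg_cache$blosum62x)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .pkg_cache$blosum62x <- m
  }
  .pkg_cache$blosum62x
}

genetic_code_11 <- function() {
  if (is.null(.pkg_cache$gc11)) {
    .pkg_cache$gc11 <- Biostrings::getGeneticCode("11")
  }
  .pkg_cache$gc11
}

# aa -> list of codons under translation table 11
codon_table_11 <- function() {
  if (is.null(.pkg_cache$codons11)) {
    gc <- genetic_code_11()
    .pkg_cache$codons11 <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons11
}

check_protein <- function(x, what = "protein sequence") {
  bad <- !grepl(AA_REGEX, x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside the 20-letter amino-acid alphabet (+X): %s",
      what, paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

# deterministic number formatting for Newick / reports
fmt_num <- function(x) sprintf("%.10g", x)

# run expr under a temporary seed when seed is non-NULL
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# split equal-length gapped rows into a character matrix (rows = sequences)
rows_to_matrix <- function(rows) {
  stopifnot(length(unique(nchar(rows))) == 1)
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

matrix_to_rows <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

# longest common subsequence length between two character vectors
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb + 1)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1)
    for (j in seq_len(nb)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1]
}

translate_protein <- function(dna, strand = "+") {
  s <- Biostrings::DNAString(dna)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(s, genetic.code = genetic_code_11(),
                          if.fuzzy.codon = "X", no.init.codon = TRUE)))
  sub("\\*$", "", aa)
}

# protein -> coding DNA with a uniformly drawn synonymous codon per residue
# and a TAA stop; only used so generated records are self-consistent.
reverse_translate <- function(protein) {
  ct <- codon_table_11()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aa, function(a) {
    cs <- ct[[a]]
    if (is.null(cs)) cs <- names(genetic_code_11()) # X: any codon
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Draw a random protein from background amino-acid frequencies
#'
#' Residues are i.i.d. draws from BLOSUM62-style background frequencies.
#' Used for decoy genes and for root sequences of simulated families.
#'
#' @param length Number of residues.
#' @param seed Optional integer seed (the global RNG is left untouched).
#' @return A single amino-acid string.
#' @export
random_protein <- function(length, seed = NULL) {
  with_seed_opt(seed, paste(
    sample(AA20, length, replace = TRUE, prob = AA_BACKGROUND),
    collapse = ""))
}
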