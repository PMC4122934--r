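# Shared fixtures and independent oracles used across test files.

# memoised expensive fixtures (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, maker) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- maker()
  .fixture_env[[name]]
}

# a small complete dataset: 5 taxa, 20 decoys, partial cluster of 9
small_dataset <- function() {
  fixture("small_dataset", function() {
    simulate_plts_dataset(simulation_config(
      n_taxa = 5, decoys = 20, partial_cluster_core = 9, seed = 42))
  })
}

small_seeds <- function() {
  fixture("small_seeds", function() seed_set_from_dataset(small_dataset()))
}

# a toy genome built directly from protein strings (3 nt per residue + stop)
toy_genome <- function(prots, starts = NULL, contig = "c1", strand = "+",
                       genome_id = "toy") {
  n <- length(prots)
  if (is.null(names(prots))) names(prots) <- sprintf("g%02d", seq_len(n))
  strand <- rep(strand, length.out = n)
  lens <- 3L * (nchar(prots) + 1L)
  if (is.null(starts)) starts <- cumsum(c(100L, head(lens, -1) + 200L))
  genes <- tibble::tibble(
    gene_id = names(prots), contig_id = contig, start = starts,
    end = starts + lens, strand = strand, protein_seq = unname(prots),
    product = "test protein")
  annotated_genome(genome_id, genes,
                   contigs = stats::setNames(max(genes$end) + 500, contig))
}

# --- independent oracles ----------------------------------------------------

# brute-force optimal local alignment score with affine gaps
# (gap of length L costs open + ext * L); exponential, tiny inputs only
brute_local_score <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  h <- function(i, j, state) {
    key <- paste(i, j, state)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    best <- 0
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, mat[av[i], bv[j]] + h(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {
      best <- max(best, -(if (state == "X") ext else open + ext) +
                    h(i + 1, j, "X"))
    }
    if (j <= length(bv)) {
      best <- max(best, -(if (state == "Y") ext else open + ext) +
                    h(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      best <- max(best, mat[av[i], bv[j]] + h(i + 1, j + 1, "M"))
    }
  }
  best
}

# plain recursive longest-common-subsequence length
lcs_oracle <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  if (a[1] == b[1]) return(1L + lcs_oracle(a[-1], b[-1]))
  max(lcs_oracle(a[-1], b), lcs_oracle(a, b[-1]))
}

# random protein over the full alphabet using the ambient RNG
rand_prot <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}

# random additive distance matrix from a random topology with branch
# lengths in [lo, hi]; returns list(D, tree)
random_additive <- function(n_taxa, lo = 0.05, hi = 1.0) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, lo, hi))
  list(D = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label], tree = tr)
}

rf_oracle <- function(a, b) {
  as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b)))
}
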