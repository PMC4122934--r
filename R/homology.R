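# Seeded homology scanning: Smith-Waterman local alignment under
# BLOSUM62 with affine gaps, length-normalized score thresholds, and
# reciprocal-best-hit confirmation against the seed genome.
#
# The external database search the analysis replaces reported E-values;
# here significance is proxied by raw score divided by the shorter
# sequence length, which is deterministic and database-size independent.

#' Scoring parameters for the homology scan
#'
#' @param matrix Named substitution matrix (default BLOSUM62 with X scored
#'   0 against everything).
#' @param gap_open Affine gap opening penalty (a gap of length L costs
#'   `gap_open + gap_extend * L`).
#' @param gap_extend Affine gap extension penalty.
#' @param min_score_per_length Retention threshold on raw score divided by
#'   the shorter sequence length.
#' @param min_identity Retention threshold on the fraction of identical
#'   alignment columns.
#' @param min_raw_score Absolute raw-score floor.  The length-normalized
#'   threshold alone over-calls very short seeds on random sequence (their
#'   denominator is small while the null local-score tail is not); the
#'   floor plays the role of a bit-score cutoff and completes the
#'   empirical-null calibration of the defaults.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           min_score_per_length = 0.5, min_identity = 0.25,
                           min_raw_score = 80) {
  if (is.null(matrix)) matrix <- blosum62x()
  if (gap_extend > gap_open) abort("gap_extend must not exceed gap_open")
  if (min_score_per_length < 0 || min_identity < 0 || min_identity > 1 ||
      min_raw_score < 0) {
    abort("thresholds must be non-negative (identity in [0,1])")
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 min_score_per_length = min_score_per_length,
                 min_identity = min_identity,
                 min_raw_score = min_raw_score),
            class = "scoring_params")
}

#' Optimal local protein alignment
#'
#' Smith-Waterman local alignment with affine gaps.  Scores are clamped at
#' zero (an empty local alignment).  Identity is the fraction of identical
#' columns over the full local alignment length.
#'
#' @param a,b Protein sequences (20-letter alphabet plus X).
#' @param params A [scoring_params()].
#' @return A list with `raw_score`, `identity`, and the aligned spans of
#'   each sequence as 0-based half-open intervals (`a_span`, `b_span`).
#' @export
local_align <- function(a, b, params = scoring_params()) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  check_protein(c(a, b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = params$matrix, gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  list(
    raw_score = max(0, Biostrings::score(al)),
    identity = Biostrings::pid(al, type = "PID1") / 100,
    a_span = c(Biostrings::start(Biostrings::pattern(al)) - 1L,
               Biostrings::end(Biostrings::pattern(al))),
    b_span = c(Biostrings::start(Biostrings::subject(al)) - 1L,
               Biostrings::end(Biostrings::subject(al))))
}

#' Scan a genome with a seed set
#'
#' For each family, every gene is aligned locally against that family's
#' seed proteins; per (family, gene) pair the best raw score across seeds
#' is kept and the hit is retained when both the length-normalized score
#' and the identity thresholds are met.  A gene may hit several families;
#' disambiguation happens in [assign_families()].
#'
#' @param seeds A [seed_set()].
#' @param genome An [annotated_genome()].
#' @param params A [scoring_params()].
#' @return A `plts_hits` tibble (one row per retained family/gene pair)
#'   with `reciprocal_ok` set to `NA` until [confirm_reciprocal()] runs.
#' @export
search_genome <- function(seeds, genome, params = scoring_params()) {
  genes <- genome$genes
  prots <- Biostrings::AAStringSet(setNames(genes$protein_seq, genes$gene_id))
  glen <- nchar(genes$protein_seq)
  out <- list()
  for (fam in unique(seeds$entries$family)) {
    ent <- seeds$entries[seeds$entries$family == fam, ]
    best <- rep(-Inf, length(prots))
    best_seed <- rep(NA_integer_, length(prots))
    for (k in seq_len(nrow(ent))) {
      sc <- Biostrings::pairwiseAlignment(
        prots, Biostrings::AAString(ent$protein_seq[k]), type = "local",
        substitutionMatrix = params$matrix, gapOpening = params$gap_open,
        gapExtension = params$gap_extend, scoreOnly = TRUE)
      upd <- sc > best
      best[upd] <- sc[upd]
      best_seed[upd] <- k
    }
    best <- pmax(best, 0)
    norm <- best / pmin(glen, nchar(ent$protein_seq)[best_seed])
    cand <- which(norm >= params$min_score_per_length &
                    best >= params$min_raw_score)
    if (!length(cand)) next
    for (k in unique(best_seed[cand])) {
      idx <- cand[best_seed[cand] == k]
      al <- Biostrings::pairwiseAlignment(
        prots[idx], Biostrings::AAString(ent$protein_seq[k]), type = "local",
        substitutionMatrix = params$matrix, gapOpening = params$gap_open,
        gapExtension = params$gap_extend)
      ident <- Biostrings::pid(al, type = "PID1") / 100
      keep <- ident >= params$min_identity
      if (!any(keep)) next
      out[[length(out) + 1]] <- tibble(
        genome_id = genome$genome_id,
        gene_id = genes$gene_id[idx][keep],
        family = fam,
        seed_id = ent$source_locus[k],
        raw_score = pmax(0, Biostrings::score(al))[keep],
        normalized_score = norm[idx][keep],
        identity = ident[keep],
        gene_start = (Biostrings::start(Biostrings::pattern(al)) - 1L)[keep],
        gene_end = Biostrings::end(Biostrings::pattern(al))[keep],
        seed_start = (Biostrings::start(Biostrings::subject(al)) - 1L)[keep],
        seed_end = Biostrings::end(Biostrings::subject(al))[keep],
        reciprocal_ok = NA)
    }
  }
  res <- if (length(out)) bind_rows(out) else tibble(
    genome_id = character(), gene_id = character(), family = character(),
    seed_id = character(), raw_score = numeric(),
    normalized_score = numeric(), identity = numeric(),
    gene_start = integer(), gene_end = integer(), seed_start = integer(),
    seed_end = integer(), reciprocal_ok = logical())
  res <- arrange(res, .data$family, match(.data$gene_id, genes$gene_id))
  class(res) <- c("plts_hits", class(res))
  res
}

seed_targets <- function(seeds) {
  sg <- seeds$seed_genome$genes
  Biostrings::AAStringSet(setNames(sg$protein_seq, sg$gene_id))
}

# best-scoring seed-genome gene for a query protein; ties resolved by
# genome gene order (deterministic).
reverse_best_gene <- function(protein, seeds, params,
                              targets = seed_targets(seeds)) {
  sg <- seeds$seed_genome$genes
  sc <- Biostrings::pairwiseAlignment(
    targets, Biostrings::AAString(protein), type = "local",
    substitutionMatrix = params$matrix, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, scoreOnly = TRUE)
  i <- which.max(sc)
  list(gene_id = sg$gene_id[i], score = max(0, sc[i]),
       protein = sg$protein_seq[i])
}

seed_family_of <- function(seeds) seeds$locus_families

#' Confirm hits by reciprocal best hit against the seed genome
#'
#' A hit is confirmed when its gene's best-scoring gene in the seed genome
#' lies within the seed cluster locus and belongs to the same family as
#' the forward hit.
#'
#' @param hits A `plts_hits` tibble from [search_genome()].
#' @param genome The scanned [annotated_genome()] (provides the proteins).
#' @param seeds The [seed_set()] (must carry the seed genome).
#' @param params A [scoring_params()].
#' @return `hits` with `reciprocal_ok` filled in.
#' @export
confirm_reciprocal <- function(hits, genome, seeds, params = scoring_params()) {
  if (!nrow(hits)) return(hits)
  fam_of <- seed_family_of(seeds)
  prot_of <- setNames(genome$genes$protein_seq, genome$genes$gene_id)
  targets <- seed_targets(seeds)
  best_of <- lapply(
    setNames(nm = unique(hits$gene_id)),
    function(gid) reverse_best_gene(prot_of[[gid]], seeds, params, targets))
  ok <- vapply(seq_len(nrow(hits)), function(i) {
    b <- best_of[[hits$gene_id[i]]]
    b$gene_id %in% seeds$cluster_gene_ids &&
      identical(unname(fam_of[b$gene_id]), hits$family[i])
  }, logical(1))
  hits$reciprocal_ok <- ok
  hits
}

#' Reciprocal-best-hit test for a single hit
#'
#' @param hit A one-row `plts_hits` tibble.
#' @inheritParams confirm_reciprocal
#' @return `TRUE` iff the hit is reciprocally confirmed.
#' @export
reciprocal_best_hit <- function(hit, genome, seeds, params = scoring_params()) {
  stopifnot(nrow(hit) == 1)
  confirm_reciprocal(hit, genome, seeds, params)$reciprocal_ok
}

#' Resolve each gene to a single family
#'
#' Each gene receives the family of its maximum `normalized_score` hit
#' among reciprocally confirmed hits; ties are broken by higher identity,
#' then by the lexicographically smaller family name.  Genes with only
#' unconfirmed hits are absent from the result.
#'
#' @param hits A confirmed `plts_hits` tibble.
#' @return A tibble with columns `gene_id`, `family`.
#' @export
assign_families <- function(hits) {
  if (!nrow(hits)) return(tibble(gene_id = character(), family = character()))
  hits |>
    filter(.data$reciprocal_ok %in% TRUE) |>
    arrange(.data$gene_id, desc(.data$normalized_score),
            desc(.data$identity), .data$family) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", "family")
}
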