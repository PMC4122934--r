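# Cluster detection: grouping of family-assigned genes into candidate
# loci, the >=10-core-gene retention rule, iterated 4-kb boundary
# extension with reverse-search confirmation, baseplate synteny scoring,
# and architecture typing.

make_cluster <- function(genome, genes, profile, status = "candidate") {
  genes <- arrange(as_tibble(genes), .data$start)
  cl <- structure(list(
    genome_id = genome$genome_id,
    contig_id = genes$contig_id[1],
    genes = genes,
    span = c(min(genes$start), max(genes$end)),
    core_count = sum(genes$family %in% core_families(profile), na.rm = TRUE),
    synteny_score = NA_real_,
    status = status), class = "plts_cluster")
  cl$synteny_score <- synteny_score(cl, profile)
  cl
}

#' @export
print.plts_cluster <- function(x, ...) {
  cat(sprintf(
    "<plts_cluster> %s %s [%d,%d): %d genes, core %d, synteny %.3f, %s\n",
    x$genome_id, x$contig_id, x$span[1], x$span[2], nrow(x$genes),
    x$core_count, x$synteny_score, x$status))
  invisible(x)
}

plts_clusters <- function(x) structure(x, class = "plts_clusters")

#' @export
print.plts_clusters <- function(x, ...) {
  cat(sprintf("<plts_clusters> %d cluster(s)\n", length(x)))
  for (cl in x) print(cl)
  invisible(x)
}

#' @export
`[.plts_clusters` <- function(x, i) plts_clusters(unclass(x)[i])

#' Group family-assigned genes into candidate clusters
#'
#' Maximal runs of assigned genes on one contig in which consecutive
#' assigned genes are separated by at most `max_gap_genes` unassigned genes
#' and at most `max_gap_bp` nucleotides.  Unassigned genes interior to a
#' run are carried along with family `NA`.  Runs never span contigs.
#'
#' @param assignments A tibble (`gene_id`, `family`) from
#'   [assign_families()].
#' @param genome The scanned [annotated_genome()].
#' @param max_gap_genes Maximum number of intervening unassigned genes.
#' @param max_gap_bp Maximum nucleotide gap between consecutive assigned
#'   genes.
#' @param profile A [plts_profile()].
#' @return A `plts_clusters` list of candidate clusters.
#' @export
group_hits <- function(assignments, genome, max_gap_genes = 3L,
                       max_gap_bp = 5000L, profile = plts_profile()) {
  g <- genome$genes
  g$family <- assignments$family[match(g$gene_id, assignments$gene_id)]
  clusters <- list()
  for (ctg in unique(g$contig_id)) {
    gc <- arrange(g[g$contig_id == ctg, ], .data$start)
    hit_idx <- which(!is.na(gc$family))
    if (!length(hit_idx)) next
    run_start <- hit_idx[1]
    prev <- hit_idx[1]
    flush <- function(first, last) {
      clusters[[length(clusters) + 1]] <<-
        make_cluster(genome, gc[first:last, ], profile)
    }
    for (i in hit_idx[-1]) {
      n_between <- i - prev - 1L
      bp_gap <- gc$start[i] - gc$end[prev]
      if (n_between > max_gap_genes || bp_gap > max_gap_bp) {
        flush(run_start, prev)
        run_start <- i
      }
      prev <- i
    }
    flush(run_start, prev)
  }
  plts_clusters(clusters)
}

#' Apply the core-gene retention threshold
#'
#' Clusters with at least `min_core` genes assigned to core families are
#' marked `retained`; the rest are marked `rejected` but kept for
#' reporting.  Paralog copies each count toward the threshold when
#' `count_by = "genes"` (the default); `count_by = "families"` counts
#' distinct core families instead.
#'
#' @param clusters A `plts_clusters` list.
#' @param min_core Retention threshold (default 10).
#' @param count_by `"genes"` or `"families"`.
#' @param profile A [plts_profile()].
#' @return The clusters with `status` updated.
#' @export
filter_clusters <- function(clusters, min_core = 10L,
                            count_by = c("genes", "families"),
                            profile = plts_profile()) {
  count_by <- match.arg(count_by)
  if (min_core < 1) abort("min_core must be at least 1")
  out <- lapply(clusters, function(cl) {
    n <- if (count_by == "genes") cl$core_count else
      length(unique(cl$genes$family[cl$genes$family %in%
                                      core_families(profile)]))
    cl$status <- if (n >= min_core) "retained" else "rejected"
    cl
  })
  plts_clusters(out)
}

# Distance from a gene to the cluster span (0 when overlapping).
gene_cluster_distance <- function(start, end, span) {
  pmax(0L, pmax(start - span[2], span[1] - end))
}

# Reverse-search confirmation used during extension: the candidate's best
# hit in the seed genome must land inside the seed cluster locus and pass
# the scan thresholds.  Genes matching a locus member without a seed
# family label are annotated "associated".
reverse_confirm <- function(protein, seeds, params,
                            targets = seed_targets(seeds)) {
  b <- reverse_best_gene(protein, seeds, params, targets)
  if (!(b$gene_id %in% seeds$cluster_gene_ids)) {
    return(list(ok = FALSE, family = NA_character_))
  }
  norm <- b$score / min(nchar(protein), nchar(b$protein))
  if (norm < params$min_score_per_length ||
      b$score < params$min_raw_score) {
    return(list(ok = FALSE, family = NA_character_))
  }
  al <- local_align(protein, b$protein, params)
  if (al$identity < params$min_identity) {
    return(list(ok = FALSE, family = NA_character_))
  }
  fam <- seed_family_of(seeds)[b$gene_id]
  list(ok = TRUE,
       family = if (is.na(fam)) "associated" else unname(fam))
}

#' Extend a retained cluster into its flanking windows
#'
#' Every gene within `window_bp` of the cluster boundary (boundary to near
#' gene edge, inclusive) is tested by reverse search against the seed
#' genome; confirmed genes are merged, the span grows, and the window is
#' re-examined from the new boundary until a fixpoint is reached.
#' Intervening unconfirmed genes inside the grown span are carried with
#' family `NA`.
#'
#' @param cluster A retained `plts_cluster`.
#' @param genome The scanned [annotated_genome()].
#' @param seeds The [seed_set()].
#' @param params A [scoring_params()].
#' @param window_bp Extension window in nucleotides (default 4000).
#' @param profile A [plts_profile()].
#' @return The extended cluster (idempotent at its fixpoint).
#' @export
extend_cluster <- function(cluster, genome, seeds, params = scoring_params(),
                           window_bp = 4000L, profile = plts_profile()) {
  g <- genome$genes[genome$genes$contig_id == cluster$contig_id, ]
  fam_in <- setNames(cluster$genes$family, cluster$genes$gene_id)
  member <- setNames(rep(FALSE, nrow(g)), g$gene_id)
  member[names(fam_in)] <- TRUE
  fams <- setNames(rep(NA_character_, nrow(g)), g$gene_id)
  fams[names(fam_in)] <- fam_in
  tested <- new.env(parent = emptyenv())
  targets <- seed_targets(seeds)
  span <- cluster$span
  repeat {
    dist <- gene_cluster_distance(g$start, g$end, span)
    cand <- which(!member & dist <= window_bp)
    added <- FALSE
    for (i in cand) {
      gid <- g$gene_id[i]
      res <- tested[[gid]]
      if (is.null(res)) {
        res <- reverse_confirm(g$protein_seq[i], seeds, params, targets)
        tested[[gid]] <- res
      }
      if (res$ok) {
        member[gid] <- TRUE
        fams[gid] <- res$family
        span <- c(min(span[1], g$start[i]), max(span[2], g$end[i]))
        added <- TRUE
      }
    }
    if (!added) break
  }
  # interior unconfirmed genes become family-NA members
  interior <- g$start >= span[1] & g$end <= span[2]
  keep <- member | interior
  genes <- g[keep, ]
  genes$family <- unname(fams[genes$gene_id])
  out <- make_cluster(genome, genes, profile, status = cluster$status)
  out
}

#' Baseplate synteny score
#'
#' The observed order of baseplate-family genes (read 5' to 3' on the
#' cluster's majority strand) is compared with the consensus baseplate
#' order by longest common subsequence, normalized by the consensus length.
#' Clusters without baseplate genes score 0.
#'
#' @param cluster A `plts_cluster`.
#' @param profile A [plts_profile()].
#' @return A number in `[0, 1]`.
#' @export
synteny_score <- function(cluster, profile = plts_profile()) {
  g <- cluster$genes
  bp <- g$family[g$family %in% profile$baseplate_order]
  if (!length(bp)) return(0)
  strands <- g$strand[!is.na(g$family)]
  if (!length(strands)) strands <- g$strand
  if (mean(strands == "-") > 0.5) bp <- rev(bp)
  lcs_length(bp, profile$baseplate_order) / length(profile$baseplate_order)
}

#' Architecture features of a cluster
#'
#' Per-family copy counts and the lineage-diagnostic layout flags: a split
#' VgrG (GPD and baseV on separate ORFs), PAAR presence, and the
#' head-to-tail AAA+ ATPase / gp3-like (DUF4255) tandem.
#'
#' @param cluster A `plts_cluster`.
#' @param profile A [plts_profile()].
#' @return A list of class `plts_architecture`.
#' @export
architecture_features <- function(cluster, profile = plts_profile()) {
  fams <- cluster$genes$family
  cnt <- function(f) sum(fams %in% f)
  genes <- arrange(cluster$genes, .data$start)
  tandem <- FALSE
  ia <- which(genes$family %in% "AAA_ATPase")
  ig <- which(genes$family %in% "Gp3like")
  for (i in ia) for (j in ig) {
    if (abs(i - j) == 1 && genes$strand[i] == genes$strand[j]) tandem <- TRUE
  }
  structure(list(
    sheath_copies = cnt("Sheath"),
    tube_copies = cnt("Gp19"),
    vgrg_split = cnt("VgrG_GPD") > 0 && cnt("VgrG_baseV") > 0 &&
      cnt("VgrG") == 0,
    paar_present = cnt("PAAR") > 0,
    baseplatej_copies = cnt("BaseplateJ"),
    atpase_duf4255_head_to_tail = tandem), class = "plts_architecture")
}

#' Scan one genome end to end
#'
#' Runs the full detection stage: seeded search, reciprocal confirmation,
#' family assignment, grouping, core-count retention, and (optionally)
#' boundary extension of retained clusters, plus synteny scoring.
#'
#' @param genome An [annotated_genome()].
#' @param seeds A [seed_set()].
#' @param params A [scoring_params()].
#' @param profile A [plts_profile()].
#' @param min_core Retention threshold.
#' @param window_bp Extension window; `0` disables extension.
#' @param max_gap_genes,max_gap_bp Grouping gap rules.
#' @param count_by Core counting mode, see [filter_clusters()].
#' @return A `plts_scan` object with elements `hits`, `assignments`,
#'   `clusters`.
#' @export
scan_genome <- function(genome, seeds, params = scoring_params(),
                        profile = plts_profile(), min_core = 10L,
                        window_bp = 4000L, max_gap_genes = 3L,
                        max_gap_bp = 5000L, count_by = "genes") {
  hits <- search_genome(seeds, genome, params)
  hits <- confirm_reciprocal(hits, genome, seeds, params)
  assignments <- assign_families(hits)
  clusters <- group_hits(assignments, genome, max_gap_genes, max_gap_bp,
                         profile)
  clusters <- filter_clusters(clusters, min_core, count_by, profile)
  if (window_bp > 0) {
    clusters <- plts_clusters(lapply(clusters, function(cl) {
      if (cl$status == "retained") {
        extend_cluster(cl, genome, seeds, params, window_bp, profile)
      } else cl
    }))
  }
  structure(list(genome_id = genome$genome_id, hits = hits,
                 assignments = assignments, clusters = clusters,
                 profile = profile),
            class = "plts_scan")
}

#' @export
print.plts_scan <- function(x, ...) {
  nret <- sum(vapply(x$clusters, function(cl) cl$status == "retained",
                     logical(1)))
  cat(sprintf("<plts_scan> %s: %d hits, %d assigned genes, %d cluster(s), %d retained\n",
              x$genome_id, nrow(x$hits), nrow(x$assignments),
              length(x$clusters), nret))
  invisible(x)
}

#' Pick each family's best cluster copy for phylogeny
#'
#' For a retained cluster, returns one protein per requested family: the
#' member gene with the highest normalized hit score (multi-copy families
#' contribute their single best-scoring copy).
#'
#' @param scan A `plts_scan` object.
#' @param families Families to extract.
#' @return A named character vector (family -> protein), omitting families
#'   absent from the retained clusters.
#' @export
cluster_family_sequences <- function(scan,
                                     families = c("Sheath", "Gp25",
                                                  "BaseplateJ", "LysM",
                                                  "VgrG")) {
  ret <- Filter(function(cl) cl$status == "retained", scan$clusters)
  if (!length(ret)) return(setNames(character(0), character(0)))
  genes <- bind_rows(lapply(ret, function(cl) cl$genes))
  score_of <- scan$hits |>
    filter(.data$reciprocal_ok %in% TRUE) |>
    group_by(.data$gene_id) |>
    summarise(score = max(.data$normalized_score), .groups = "drop")
  genes <- left_join(genes, score_of, by = "gene_id")
  genes$score[is.na(genes$score)] <- -Inf
  out <- character()
  for (f in families) {
    gf <- genes[genes$family %in% f, ]
    if (!nrow(gf)) next
    gf <- arrange(gf, desc(.data$score), .data$gene_id)
    out[f] <- gf$protein_seq[1]
  }
  out
}
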