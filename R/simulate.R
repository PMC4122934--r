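# Synthetic-data generator: Yule species trees, family sequences evolved
# along a (possibly horizontally transferred) gene tree, and annotated
# genomes with planted clusters, partial clusters, decoys and optional
# conserved flanking genes -- all with recorded ground truth and full
# determinism under (config, seed).

DEFAULT_FAMILY_LENGTHS <- c(
  LysM = 150L, VgrG = 400L, PAAR = 100L, Gp25 = 130L, BaseplateJ = 280L,
  P2I = 160L, Gp19 = 170L, Sheath = 350L, Gp3like = 190L, AAA_ATPase = 380L)

# layout used for planted clusters: consensus baseplate order, then tube /
# sheath genes, then the gp3-like + ATPase head-to-tail pair; entries past
# position 10 are the paralog expansion order used for core-count sweeps.
CORE_LAYOUT <- c("LysM", "VgrG", "PAAR", "Gp25", "BaseplateJ", "P2I",
                 "Gp19", "Sheath", "Gp3like", "AAA_ATPase",
                 "BaseplateJ", "P2I", "Gp19", "Sheath", "Sheath", "Gp19")

#' Configuration of the synthetic dataset generator
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' clusters of 13-16 genes in the consensus order, sequence divergence
#' that keeps planted homologs at or above roughly 50% identity to the
#' seeds, 100 decoy genes per genome, and an optional partial cluster
#' below the retention threshold.
#'
#' @param n_taxa Number of taxa (>= 4).
#' @param birth_rate Yule birth rate.
#' @param divergence_scale Mean root-to-tip depth of the scaled species
#'   tree, in expected substitutions per site.
#' @param family_lengths Named integer vector of per-family root sequence
#'   lengths (residues).
#' @param hgt_events List of `c(donor, recipient)` taxon-label pairs
#'   applied in order to derive the gene tree.
#' @param decoys Number of random decoy genes per genome.
#' @param decoy_length Length range (residues) of decoy proteins.
#' @param partial_cluster_core If positive (at most 9), every genome also
#'   carries a partial cluster with this many core genes on a second
#'   contig.
#' @param cluster_core Optional per-taxon override of the main cluster's
#'   core gene count (recycled; `NA` = natural 13-16 draw).
#' @param flank_bp Optional per-taxon distance (bp, recycled) at which one
#'   conserved flanking gene is placed beyond the cluster's 3' boundary;
#'   `NA` disables the flank for that taxon.
#' @param seed_taxon Index of the taxon whose genome and cluster serve as
#'   the seed set.
#' @param seed Integer master seed; `(config, seed)` fully determines every
#'   generated byte.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 12L, birth_rate = 1,
                              divergence_scale = 0.3,
                              family_lengths = DEFAULT_FAMILY_LENGTHS,
                              hgt_events = NULL, decoys = 100L,
                              decoy_length = c(120L, 300L),
                              partial_cluster_core = 0L,
                              cluster_core = NULL, flank_bp = NULL,
                              seed_taxon = 1L, seed = 1L) {
  if (n_taxa < 4) abort("n_taxa must be at least 4")
  if (birth_rate <= 0 || divergence_scale <= 0) {
    abort("rates and scales must be positive")
  }
  if (partial_cluster_core > 9) {
    abort("partial_cluster_core must be at most 9 (below the retention threshold)")
  }
  for (ev in hgt_events %||% list()) {
    if (ev[1] == ev[2]) abort("hgt donor and recipient must differ")
  }
  structure(list(
    n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
    divergence_scale = divergence_scale, family_lengths = family_lengths,
    hgt_events = hgt_events, decoys = as.integer(decoys),
    decoy_length = as.integer(decoy_length),
    partial_cluster_core = as.integer(partial_cluster_core),
    cluster_core = cluster_core, flank_bp = flank_bp,
    seed_taxon = as.integer(seed_taxon), seed = as.integer(seed)),
    class = "simulation_config")
}

#' Simulate a Yule species tree
#'
#' Pure-birth process: two lineages at time zero, exponential waiting
#' times with rate (number of lineages x birth rate), a uniformly chosen
#' lineage splitting at each event, and one final waiting interval after
#' the n-th lineage appears.  All tips are contemporaneous, so the
#' root-to-tip depth has expectation `sum_{k=2}^{n} 1/(birth_rate * k)`.
#'
#' @param n_taxa Number of leaves (>= 4); labels `tax01`, `tax02`, ...
#' @param birth_rate Positive birth rate.
#' @param seed Optional seed (global RNG untouched).
#' @return A binary `ape::phylo` tree with branch lengths.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  stopifnot(n_taxa >= 4, birth_rate > 0)
  with_seed_opt(seed, {
    parent <- c(0L, 0L); birth <- c(0, 0); death <- c(NA_real_, NA_real_)
    active <- c(1L, 2L); t <- 0
    while (length(active) < n_taxa) {
      k <- length(active)
      t <- t + rexp(1, k * birth_rate)
      pick <- active[sample.int(k, 1)]
      death[pick] <- t
      id1 <- length(parent) + 1L
      parent <- c(parent, pick, pick)
      birth <- c(birth, t, t)
      death <- c(death, NA_real_, NA_real_)
      active <- c(setdiff(active, pick), id1, id1 + 1L)
    }
    death[active] <- t + rexp(1, n_taxa * birth_rate)
    leaves <- sort(active)
    lab <- setNames(sprintf("tax%02d", seq_along(leaves)),
                    as.character(leaves))
    build <- function(id) {
      ch <- which(parent == id)
      len <- fmt_num(death[id] - birth[id])
      if (!length(ch)) paste0(lab[[as.character(id)]], ":", len)
      else sprintf("(%s,%s):%s", build(ch[1]), build(ch[2]), len)
    }
    ch0 <- which(parent == 0L)
    ape::read.tree(text = sprintf("(%s,%s);", build(ch0[1]), build(ch0[2])))
  })
}

# rescale branch lengths so the mean root-to-tip depth equals mean_depth
scale_tree_depth <- function(tree, mean_depth) {
  d <- ape::node.depth.edgelength(tree)
  tipd <- mean(d[seq_along(tree$tip.label)])
  tree$edge.length <- tree$edge.length * mean_depth / tipd
  tree
}

#' Evolve one family's sequences along a tree
#'
#' Two modes with disjoint guarantees.  `"eventwise"` (general trees):
#' each branch receives `Poisson(d * L)` substitution events, each
#' replacing a uniformly chosen site with a uniformly chosen different
#' residue -- realistic multi-branch evolution for topology tests.
#' `"bernoulli_pairstar"` (star trees only): each site of each tip differs
#' from the root with probability `1 - exp(-d)` -- the exact generative
#' model of the Poisson-corrected distance estimator, used for
#' estimator-recovery tests.
#'
#' @param tree `ape::phylo` with branch lengths in expected
#'   substitutions/site.
#' @param root_seq Root protein sequence.
#' @param mode `"eventwise"` or `"bernoulli_pairstar"`.
#' @param seed Optional seed.
#' @return Named character vector, taxon -> sequence.
#' @export
evolve_family_sequences <- function(tree, root_seq,
                                    mode = c("eventwise",
                                             "bernoulli_pairstar"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  if (!nzchar(root_seq)) abort("root_seq must be non-empty")
  L <- nchar(root_seq)
  root_chars <- strsplit(root_seq, "", fixed = TRUE)[[1]]
  n <- length(tree$tip.label)
  with_seed_opt(seed, {
    if (mode == "bernoulli_pairstar") {
      if (tree$Nnode != 1) {
        abort(paste("bernoulli_pairstar requires a star tree;",
                    "its distance guarantee is invalid otherwise"))
      }
      out <- vapply(seq_len(n), function(i) {
        len <- tree$edge.length[tree$edge[, 2] == i]
        flip <- runif(L) < (1 - exp(-len))
        s <- root_chars
        for (site in which(flip)) {
          s[site] <- sample(setdiff(AA20, s[site]), 1)
        }
        paste(s, collapse = "")
      }, character(1))
      return(setNames(out, tree$tip.label))
    }
    seqs <- vector("list", n + tree$Nnode)
    seqs[[n + 1L]] <- root_chars
    eo <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(eo$edge))) {
      p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
      s <- seqs[[p]]
      nev <- rpois(1, eo$edge.length[k] * L)
      if (nev > 0) {
        for (site in sample.int(L, nev, replace = TRUE)) {
          s[site] <- sample(setdiff(AA20, s[site]), 1)
        }
      }
      seqs[[ch]] <- s
    }
    setNames(vapply(seq_len(n), function(i) paste(seqs[[i]], collapse = ""),
                    character(1)), tree$tip.label)
  })
}

#' Derive a gene tree by one horizontal transfer
#'
#' The recipient leaf is pruned and regrafted onto the donor's terminal
#' edge at a uniformly drawn attachment point; the recipient's pendant
#' branch equals the attachment-to-tip distance, so the tree stays
#' positively weighted.
#'
#' @param species_tree `ape::phylo`.
#' @param donor,recipient Distinct leaf labels.
#' @param seed Optional seed.
#' @return The gene `phylo` tree.
#' @export
apply_hgt <- function(species_tree, donor, recipient, seed = NULL) {
  if (donor == recipient) abort("donor and recipient must differ")
  stopifnot(all(c(donor, recipient) %in% species_tree$tip.label))
  with_seed_opt(seed, {
    tr <- ape::drop.tip(species_tree, recipient)
    di <- which(tr$tip.label == donor)
    el <- tr$edge.length[tr$edge[, 2] == di]
    pos <- runif(1) * el
    phytools::bind.tip(tr, recipient, edge.length = pos, where = di,
                       position = pos)
  })
}

perturb_protein <- function(seq, rate) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  flip <- which(runif(length(s)) < rate)
  for (site in flip) s[site] <- sample(setdiff(AA20, s[site]), 1)
  paste(s, collapse = "")
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# draw per-cluster copy numbers until the total lands in the consensus
# 13-16 gene range
draw_cluster_layout <- function() {
  repeat {
    copies <- c(BaseplateJ = sample(1:2, 1), P2I = sample(1:2, 1),
                Gp19 = sample(1:2, 1), Sheath = sample(1:3, 1))
    if (10 + sum(copies - 1L) >= 13) break
  }
  fams <- c("LysM", "VgrG", "PAAR", "Gp25",
            rep("BaseplateJ", copies["BaseplateJ"]),
            rep("P2I", copies["P2I"]),
            rep("Gp19", copies["Gp19"]),
            rep("Sheath", copies["Sheath"]),
            "Gp3like", "AAA_ATPase")
  fams
}

layout_with_core <- function(k) CORE_LAYOUT[seq_len(k)]

# lay out one gene run starting at `pos`; returns rows + next position
place_genes <- function(fams, seqs, pos, strand, role) {
  rows <- list()
  order_idx <- if (strand == "-") rev(seq_along(fams)) else seq_along(fams)
  for (i in order_idx) {
    len_nt <- 3L * (nchar(seqs[[i]]) + 1L)
    rows[[length(rows) + 1]] <- tibble(
      family = fams[i], protein_seq = seqs[[i]], start = pos,
      end = pos + len_nt, strand = strand, role = role)
    pos <- pos + len_nt + sample(50:500, 1)
  }
  list(rows = bind_rows(rows), pos = pos)
}

#' Plant annotated genomes around simulated family sequences
#'
#' Per taxon: one planted cluster laid out in the consensus order
#' (baseplate subcluster, tube and sheath genes, then the gp3-like +
#' ATPase pair on one strand), seeded intergenic spacers of 50-500 bp, a
#' random whole-cluster strand, `decoys` background genes, optionally one
#' conserved flanking gene at a configured distance and one partial
#' cluster on a second contig.  Ground truth records every placement.
#'
#' @param family_seqs List family -> named character vector
#'   (taxon -> protein); must cover every profile family for every taxon.
#' @param profile A [plts_profile()].
#' @param config A [simulation_config()]; uses the ambient RNG (seed it or
#'   call via [simulate_plts_dataset()]).
#' @return A list with `genomes` (named list of [annotated_genome()]) and
#'   `truth` (a tibble of planted gene placements).
#' @export
plant_genomes <- function(family_seqs, profile, config) {
  taxa <- names(family_seqs[[1]])
  need <- unique(CORE_LAYOUT)
  for (f in need) {
    missing <- setdiff(taxa, names(family_seqs[[f]] %||% character(0)))
    if (is.null(family_seqs[[f]]) || length(missing)) {
      abort(sprintf("missing family sequence for (%s, %s)",
                    paste(missing, collapse = "/"), f))
    }
  }
  flank_bp <- if (is.null(config$flank_bp)) rep(NA_integer_, length(taxa))
              else as.integer(rep(config$flank_bp, length.out = length(taxa)))
  core_override <- if (is.null(config$cluster_core))
    rep(NA_integer_, length(taxa))
  else as.integer(rep(config$cluster_core, length.out = length(taxa)))
  genomes <- list()
  truth <- list()
  for (ti in seq_along(taxa)) {
    tx <- taxa[ti]
    fams <- if (is.na(core_override[ti])) draw_cluster_layout()
            else layout_with_core(core_override[ti])
    copy_idx <- stats::ave(seq_along(fams), fams, FUN = seq_along)
    seqs <- vapply(seq_along(fams), function(i) {
      s <- family_seqs[[fams[i]]][[tx]]
      if (copy_idx[i] > 1) s <- perturb_protein(s, 0.08)
      s
    }, character(1))
    strand <- sample(c("+", "-"), 1)
    placed <- place_genes(fams, seqs, pos = 2000L, strand, role = "cluster")
    rows <- placed$rows
    cluster_end <- max(rows$end)
    # conserved flanking gene (reverse-confirmable, not in the seed set)
    if (!is.na(flank_bp[ti])) {
      fseq <- family_seqs[["Afp15"]][[tx]]
      fstart <- cluster_end + flank_bp[ti]
      rows <- bind_rows(rows, tibble(
        family = NA_character_, protein_seq = fseq, start = fstart,
        end = fstart + 3L * (nchar(fseq) + 1L), strand = "+",
        role = "flank"))
    }
    # decoy genes well clear of the cluster/flank region
    pos <- max(rows$end) + 1500L
    for (k in seq_len(config$decoys)) {
      len <- sample(config$decoy_length[1]:config$decoy_length[2], 1)
      dseq <- paste(sample(AA20, len, replace = TRUE, prob = AA_BACKGROUND),
                    collapse = "")
      rows <- bind_rows(rows, tibble(
        family = NA_character_, protein_seq = dseq, start = pos,
        end = pos + 3L * (len + 1L), strand = sample(c("+", "-"), 1),
        role = "decoy"))
      pos <- pos + 3L * (len + 1L) + sample(100:2000, 1)
    }
    rows$contig_id <- "contig1"
    # optional partial cluster on its own contig
    if (config$partial_cluster_core > 0) {
      pf <- layout_with_core(config$partial_cluster_core)
      pseqs <- vapply(pf, function(f) {
        perturb_protein(family_seqs[[f]][[tx]], 0.08)
      }, character(1))
      pplaced <- place_genes(pf, pseqs, pos = 1000L,
                             sample(c("+", "-"), 1), role = "partial")
      prows <- pplaced$rows
      prows$contig_id <- "contig2"
      rows <- bind_rows(rows, prows)
    }
    rows <- arrange(rows, .data$contig_id, .data$start)
    rows$gene_id <- sprintf("%s_g%03d", tx, seq_len(nrow(rows)))
    contigs <- vapply(split(rows$end, rows$contig_id), max, numeric(1)) + 500
    contig_seqs <- vapply(names(contigs), function(ctg) {
      chars <- strsplit(random_dna(contigs[[ctg]]), "", fixed = TRUE)[[1]]
      sub <- rows[rows$contig_id == ctg, ]
      for (i in seq_len(nrow(sub))) {
        cds <- reverse_translate(sub$protein_seq[i])
        if (sub$strand[i] == "-") cds <- revcomp(cds)
        chars[(sub$start[i] + 1):sub$end[i]] <- strsplit(cds, "",
                                                         fixed = TRUE)[[1]]
      }
      paste(chars, collapse = "")
    }, character(1))
    genomes[[tx]] <- annotated_genome(
      genome_id = tx,
      taxon_name = paste("Synthetic taxon", tx),
      lineage = c("Synthetica", tx),
      genes = tibble(
        gene_id = rows$gene_id, contig_id = rows$contig_id,
        start = rows$start, end = rows$end, strand = rows$strand,
        protein_seq = rows$protein_seq,
        product = ifelse(is.na(rows$family),
                         ifelse(rows$role == "flank",
                                "conserved cluster-associated protein",
                                "hypothetical protein"),
                         paste(rows$family, "family protein"))),
      contigs = contigs, contig_seqs = contig_seqs)
    rows$genome_id <- tx
    truth[[tx]] <- select(rows, "genome_id", "contig_id", "gene_id",
                          "family", "role", "start", "end", "strand")
  }
  list(genomes = genomes, truth = bind_rows(truth))
}

#' Simulate a complete synthetic dataset
#'
#' Species tree, gene tree (after any horizontal transfers), family
#' sequences evolved eventwise along the gene tree, and planted annotated
#' genomes.  `(config, seed)` determines every byte of the result.
#'
#' @param config A [simulation_config()].
#' @return An object of class `plts_sim` with elements `species_tree`,
#'   `gene_tree`, `family_seqs`, `genomes`, `truth`, `config`.
#' @export
simulate_plts_dataset <- function(config = simulation_config()) {
  profile <- plts_profile()
  with_seed_opt(config$seed, {
    sp <- simulate_species_tree(config$n_taxa, config$birth_rate)
    sp <- scale_tree_depth(sp, config$divergence_scale)
    gt <- sp
    for (ev in config$hgt_events %||% list()) {
      gt <- apply_hgt(gt, ev[1], ev[2])
    }
    fam_lengths <- config$family_lengths
    if (!is.null(config$flank_bp)) {
      fam_lengths <- c(fam_lengths, Afp15 = 260L)
    }
    family_seqs <- lapply(fam_lengths, function(L) {
      root <- paste(sample(AA20, L, replace = TRUE, prob = AA_BACKGROUND),
                    collapse = "")
      evolve_family_sequences(gt, root, mode = "eventwise")
    })
    pg <- plant_genomes(family_seqs, profile, config)
    structure(list(config = config, species_tree = sp, gene_tree = gt,
                   family_seqs = family_seqs, genomes = pg$genomes,
                   truth = pg$truth),
              class = "plts_sim")
  })
}

#' @export
print.plts_sim <- function(x, ...) {
  cat(sprintf("<plts_sim> %d genomes, %d planted genes, seed %d\n",
              length(x$genomes), nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Build the seed set from a simulated dataset
#'
#' Seed entries are the designated seed taxon's planted cluster genes (one
#' copy per family by default); the seed cluster locus additionally
#' includes the conserved flanking gene when present, so reverse searches
#' during extension can confirm it.
#'
#' @param dataset A `plts_sim`.
#' @param taxon Seed taxon label (default from the config).
#' @param include_paralogs Keep paralog copies as extra seed entries.
#' @param profile A [plts_profile()].
#' @return A [seed_set()].
#' @export
seed_set_from_dataset <- function(dataset, taxon = NULL,
                                  include_paralogs = FALSE,
                                  profile = plts_profile()) {
  taxon <- taxon %||% names(dataset$genomes)[dataset$config$seed_taxon]
  g <- dataset$genomes[[taxon]]
  tr <- dataset$truth[dataset$truth$genome_id == taxon, ]
  cl <- tr[tr$role == "cluster", ]
  if (!include_paralogs) {
    cl <- cl[!duplicated(cl$family), ]
  }
  prot <- setNames(g$genes$protein_seq, g$genes$gene_id)
  entries <- tibble(family = cl$family, protein_seq = unname(prot[cl$gene_id]),
                    source_locus = cl$gene_id)
  # the seed genome's partial cluster is a second genuine PLTS locus:
  # reverse hits landing there are confirmations too
  locus <- tr$gene_id[tr$role %in% c("cluster", "flank", "partial")]
  all_cl <- tr[tr$role %in% c("cluster", "partial"), ]
  seed_set(entries, g, cluster_gene_ids = locus,
           locus_families = setNames(all_cl$family, all_cl$gene_id),
           profile = profile)
}

#' Write a simulated dataset to disk
#'
#' Per genome: GFF3 + genomic FASTA and a GenBank flat file.  Plus the
#' species and gene trees (Newick), the seed protein FASTA and family map,
#' and the ground truth as JSON.  Byte-identical for identical
#' `(config, seed)`.
#'
#' @param dataset A `plts_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tx in names(dataset$genomes)) {
    g <- dataset$genomes[[tx]]
    write_annotated_genome(g, file.path(dir, paste0(tx, ".gff3")),
                           format = "gff3",
                           fasta = file.path(dir, paste0(tx, ".fna")))
    write_annotated_genome(g, file.path(dir, paste0(tx, ".gbk")),
                           format = "genbank")
  }
  write_newick(dataset$species_tree, file.path(dir, "species_tree.nwk"))
  write_newick(dataset$gene_tree, file.path(dir, "gene_tree.nwk"))
  seeds <- seed_set_from_dataset(dataset)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(seeds$entries$protein_seq,
                                     seeds$entries$source_locus)),
    file.path(dir, "seeds.faa"), width = 70L)
  write.table(
    data.frame(seed_id = seeds$entries$source_locus,
               family = seeds$entries$family),
    file.path(dir, "seed_families.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(species_tree = ape::write.tree(dataset$species_tree),
         gene_tree = ape::write.tree(dataset$gene_tree),
         truth = dataset$truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
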