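# Grouping, retention, extension, synteny and architecture typing.

# a cluster built directly from a family layout (no scanning involved)
layout_cluster <- function(fams, strand = "+", profile = plts_profile(),
                           reverse_coords = FALSE) {
  prots <- stats::setNames(replicate(length(fams), rand_prot(40)),
                           sprintf("g%02d", seq_along(fams)))
  g <- toy_genome(prots, strand = strand)
  genes <- g$genes
  genes$family <- if (reverse_coords) rev(fams) else fams
  pltscan:::make_cluster(g, genes, profile)
}

test_that("grouping respects gene-gap, bp-gap and contig boundaries", {
  withr::with_seed(10, {
    prots <- stats::setNames(replicate(30, rand_prot(40)),
                             sprintf("g%02d", 1:30))
  })
  g <- toy_genome(prots)  # ~320 bp intergenic spacing
  fams <- rep(c("Sheath", "Gp19"), length.out = 13)
  asg <- tibble::tibble(gene_id = sprintf("g%02d", 1:13), family = fams)
  cl <- group_hits(asg, g)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$genes), 13)
  # two runs separated by > 3 unassigned genes split
  asg2 <- tibble::tibble(gene_id = sprintf("g%02d", c(1:7, 12:17)),
                         family = "Sheath")
  cl2 <- group_hits(asg2, g)
  expect_length(cl2, 2)
  expect_equal(vapply(cl2, function(x) nrow(x$genes), integer(1)),
               c(7L, 6L))
  # interior unassigned genes ride along with family NA
  asg3 <- tibble::tibble(gene_id = c("g01", "g03"), family = "Sheath")
  cl3 <- group_hits(asg3, g)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$genes$gene_id, c("g01", "g02", "g03"))
  expect_true(is.na(cl3[[1]]$genes$family[2]))
  # a wide bp gap splits even with few intervening genes
  g_far <- toy_genome(prots[1:4], starts = c(100L, 500L, 20000L, 20500L))
  asg4 <- tibble::tibble(gene_id = sprintf("g%02d", 1:4), family = "Sheath")
  expect_length(group_hits(asg4, g_far), 2)
  # runs never span contigs
  genes <- g$genes[1:10, ]
  genes$contig_id <- rep(c("c1", "c2"), each = 5)
  g_two <- annotated_genome("two", genes,
                            contigs = c(c1 = 30000, c2 = 30000))
  asg5 <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                         family = "Sheath")
  expect_length(group_hits(asg5, g_two), 2)
})

test_that("retention keeps clusters with >= 10 core genes, counting paralogs", {
  withr::with_seed(11, {
    cls <- lapply(5:12, function(k) {
      layout_cluster(pltscan:::layout_with_core(k))
    })
  })
  out <- filter_clusters(pltscan:::plts_clusters(cls))
  status <- vapply(out, function(cl) cl$status, character(1))
  expect_equal(status, ifelse(5:12 >= 10, "retained", "rejected"))
  # paralog copies count individually: 8 families, double Sheath + Gp19
  withr::with_seed(12, {
    cl10 <- layout_cluster(c("LysM", "VgrG", "PAAR", "Gp25", "BaseplateJ",
                             "P2I", "Gp19", "Gp19", "Sheath", "Sheath"))
  })
  expect_equal(cl10$core_count, 10)
  expect_equal(filter_clusters(pltscan:::plts_clusters(list(cl10)))[[1]]$status,
               "retained")
  # distinct-family counting mode demotes the same cluster
  expect_equal(filter_clusters(pltscan:::plts_clusters(list(cl10)),
                               count_by = "families")[[1]]$status,
               "rejected")
  expect_length(filter_clusters(pltscan:::plts_clusters(list())), 0)
  expect_error(filter_clusters(pltscan:::plts_clusters(list()),
                               min_core = 0), "at least 1")
})

test_that("core_count is invariant under permutation of gene order", {
  withr::with_seed(13, {
    fams <- pltscan:::layout_with_core(12)
    cl <- layout_cluster(fams)
    prots <- stats::setNames(cl$genes$protein_seq, cl$genes$gene_id)
    g <- toy_genome(prots)
    perm <- sample(nrow(cl$genes))
    genes <- cl$genes[perm, ]
    cl2 <- pltscan:::make_cluster(g, genes, plts_profile())
    expect_equal(cl2$core_count, cl$core_count)
  })
})

test_that("synteny scoring reads the majority strand and uses the LCS", {
  prof <- plts_profile()
  consensus <- c("LysM", "VgrG", "PAAR", "Gp25", "BaseplateJ", "P2I")
  withr::with_seed(14, {
    expect_equal(layout_cluster(consensus)$synteny_score, 1.0)
    # same cluster gene-for-gene on the minus strand, coordinates reversed
    expect_equal(layout_cluster(consensus, strand = "-",
                                reverse_coords = TRUE)$synteny_score, 1.0)
    # one swap drops the LCS to 5
    swapped <- c("VgrG", "LysM", "PAAR", "Gp25", "BaseplateJ", "P2I")
    expect_equal(layout_cluster(swapped)$synteny_score, 5 / 6)
    # zero baseplate genes scores 0
    expect_equal(layout_cluster(c("Sheath", "Gp19"))$synteny_score, 0)
    # LCS backbone agrees with a recursive oracle on random family orders
    for (rep in 1:20) {
      obs <- sample(consensus, sample(3:6, 1))
      expect_equal(pltscan:::lcs_length(obs, consensus),
                   lcs_oracle(obs, consensus))
    }
  })
})

test_that("architecture typing reads copy numbers and layout flags", {
  withr::with_seed(15, {
    entero <- layout_cluster(c("LysM", "VgrG", "PAAR", "Gp25", "BaseplateJ",
                               "P2I", "Gp19", "Sheath", "Sheath", "Sheath",
                               "Gp3like", "AAA_ATPase"))
    arch <- architecture_features(entero)
    expect_equal(arch$sheath_copies, 3)
    expect_true(arch$paar_present)
    expect_false(arch$vgrg_split)
    expect_true(arch$atpase_duf4255_head_to_tail)
    # PAAR-less (Deinococcus-style) cluster
    noPaar <- layout_cluster(c("LysM", "VgrG", "Gp25", "BaseplateJ", "P2I",
                               "Gp19", "Sheath", "Gp3like", "AAA_ATPase"))
    expect_false(architecture_features(noPaar)$paar_present)
    # split VgrG on separate ORFs
    split <- layout_cluster(c("LysM", "VgrG_GPD", "VgrG_baseV", "PAAR",
                              "Gp25", "BaseplateJ", "P2I"))
    expect_true(architecture_features(split)$vgrg_split)
    # ATPase and gp3-like on opposite strands are not head-to-tail
    prots <- stats::setNames(replicate(2, rand_prot(40)), c("a", "b"))
    g <- toy_genome(prots, strand = c("+", "-"))
    genes <- g$genes
    genes$family <- c("Gp3like", "AAA_ATPase")
    opp <- pltscan:::make_cluster(g, genes, plts_profile())
    expect_false(architecture_features(opp)$atpase_duf4255_head_to_tail)
  })
})

test_that("extension merges confirmed flanking genes and is idempotent", {
  ds <- fixture("flank_dataset", function() {
    simulate_plts_dataset(simulation_config(
      n_taxa = 4, decoys = 15, flank_bp = c(300, 3000, 3000, 5000),
      seed = 21))
  })
  seeds <- fixture("flank_seeds", function() seed_set_from_dataset(ds))
  taxa <- names(ds$genomes)
  # flank at 3 kb merges; at 5 kb it does not
  sc3 <- scan_genome(ds$genomes[[taxa[2]]], seeds)
  ret3 <- Filter(function(cl) cl$status == "retained", sc3$clusters)[[1]]
  fid3 <- ds$truth$gene_id[ds$truth$genome_id == taxa[2] &
                             ds$truth$role == "flank"]
  expect_true(fid3 %in% ret3$genes$gene_id)
  expect_equal(ret3$genes$family[ret3$genes$gene_id == fid3], "associated")
  sc5 <- scan_genome(ds$genomes[[taxa[4]]], seeds)
  ret5 <- Filter(function(cl) cl$status == "retained", sc5$clusters)[[1]]
  fid5 <- ds$truth$gene_id[ds$truth$genome_id == taxa[4] &
                             ds$truth$role == "flank"]
  expect_false(fid5 %in% ret5$genes$gene_id)
  # applying extension to an already-extended cluster changes nothing
  again <- extend_cluster(ret3, ds$genomes[[taxa[2]]], seeds)
  expect_equal(again$genes$gene_id, ret3$genes$gene_id)
  expect_equal(again$span, ret3$span)
  # no flanking homologs: immediate fixpoint
  same <- extend_cluster(ret5, ds$genomes[[taxa[4]]], seeds)
  expect_equal(same$span, ret5$span)
})

test_that("extension iterates from the grown boundary (two-step merge)", {
  # flank A at 3 kb from the cluster, flank B 4 kb beyond A's far edge:
  # B is outside the original window and only merges after A grows it
  ds <- fixture("flank_dataset", function() {
    simulate_plts_dataset(simulation_config(
      n_taxa = 4, decoys = 15, flank_bp = c(300, 3000, 3000, 5000),
      seed = 21))
  })
  seeds <- fixture("flank_seeds", function() seed_set_from_dataset(ds))
  tx <- names(ds$genomes)[3]
  g <- ds$genomes[[tx]]
  tr <- ds$truth[ds$truth$genome_id == tx, ]
  fidA <- tr$gene_id[tr$role == "flank"]
  rowA <- g$genes[g$genes$gene_id == fidA, ]
  protB <- ds$family_seqs[["Afp15"]][[tx]]
  startB <- rowA$end + 4000L
  genes <- dplyr::bind_rows(g$genes, tibble::tibble(
    gene_id = "flankB", contig_id = rowA$contig_id, start = startB,
    end = startB + 3L * (nchar(protB) + 1L), strand = "+",
    protein_seq = protB, product = "conserved cluster-associated protein"))
  contigs <- g$contigs
  contigs[rowA$contig_id] <- max(contigs[rowA$contig_id],
                                 startB + 3L * (nchar(protB) + 1L) + 500)
  g2 <- annotated_genome(g$genome_id, genes, contigs,
                         taxon_name = g$taxon_name)
  sc <- scan_genome(g2, seeds)
  ret <- Filter(function(cl) cl$status == "retained", sc$clusters)[[1]]
  expect_true(all(c(fidA, "flankB") %in% ret$genes$gene_id))
  cl_end <- max(tr$end[tr$role == "cluster"])
  expect_gt(startB - cl_end, 4000)  # B alone was out of reach
})
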