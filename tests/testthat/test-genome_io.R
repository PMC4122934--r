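# File formats and the coordinate convention.

test_that("GenBank 1-based inclusive coordinates map to 0-based half-open", {
  gb <- c(
    "LOCUS       ctgA  1200 bp    DNA     linear   BCT 01-JAN-2014",
    "DEFINITION  Toy organism.",
    "SOURCE      Toy organism",
    "  ORGANISM  Toy organism",
    "            Synthetica; Toy.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1200",
    "     CDS             101..200",
    "                     /locus_tag=\"geneA\"",
    "                     /product=\"thing\"",
    sprintf("                     /translation=\"%s\"",
            strrep("M", 33)),
    "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, path)
  g <- read_annotated_genome(path, format = "genbank")
  expect_equal(g$genes$start, 100L)
  expect_equal(g$genes$end, 200L)
  expect_equal(g$genes$strand, "+")
  expect_equal(g$genes$gene_id, "geneA")
  expect_equal(unname(g$contigs["ctgA"]), 1200)
  expect_equal(g$taxon_name, "Toy organism")
})

test_that("generated genomes round-trip through GFF3+FASTA and GenBank", {
  ds <- small_dataset()
  g <- ds$genomes[[2]]
  expect_gte(nrow(g$genes), 30)
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "g.gff3"); fna <- file.path(dir, "g.fna")
  write_annotated_genome(g, gff, format = "gff3", fasta = fna)
  g2 <- read_annotated_genome(gff, format = "gff3", fasta = fna,
                              genome_id = g$genome_id)
  expect_equal(g2$genes[, c("gene_id", "contig_id", "start", "end",
                            "strand", "protein_seq")],
               g$genes[, c("gene_id", "contig_id", "start", "end",
                           "strand", "protein_seq")])
  expect_equal(as.numeric(g2$contigs[names(g$contigs)]),
               as.numeric(g$contigs))
  gbk <- file.path(dir, "g.gbk")
  write_annotated_genome(g, gbk, format = "genbank")
  g3 <- read_annotated_genome(gbk, format = "genbank",
                              genome_id = g$genome_id)
  expect_equal(g3$genes[, c("gene_id", "contig_id", "start", "end",
                            "strand", "protein_seq")],
               g$genes[, c("gene_id", "contig_id", "start", "end",
                           "strand", "protein_seq")])
  # translations derived from ORIGIN agree with the /translation qualifier
  gb_lines <- readLines(gbk)
  gb_no_tr <- gb_lines[!grepl("/translation=|^                     [A-Z\"]",
                              gb_lines)]
  path2 <- file.path(dir, "g_notr.gbk")
  writeLines(gb_no_tr, path2)
  g4 <- read_annotated_genome(path2, format = "genbank",
                              genome_id = g$genome_id)
  expect_equal(g4$genes$protein_seq, g$genes$protein_seq)
})

test_that("malformed and empty inputs raise parse errors", {
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(character(0), path)
  expect_error(read_annotated_genome(path, format = "genbank"), "LOCUS")
  expect_error(read_annotated_genome(tempfile(), format = "genbank"),
               "not found")
  # CDS with neither /translation nor ORIGIN names the gene
  gb <- c("LOCUS       ctgA  900 bp    DNA     linear   BCT 01-JAN-2014",
          "FEATURES             Location/Qualifiers",
          "     CDS             10..90",
          "                     /locus_tag=\"orphan\"",
          "//")
  writeLines(gb, path)
  expect_error(read_annotated_genome(path, format = "genbank"), "orphan")
})

test_that("annotated_genome enforces its invariants", {
  genes <- tibble::tibble(
    gene_id = "g1", contig_id = "c1", start = 10L, end = 40L, strand = "+",
    protein_seq = "MKLV", product = "p")
  expect_s3_class(annotated_genome("x", genes, c(c1 = 100)),
                  "annotated_genome")
  expect_error(annotated_genome("x", genes, c(c1 = 30)), "beyond")
  bad <- genes; bad$end <- 10L
  expect_error(annotated_genome("x", bad, c(c1 = 100)), "start < end")
  dup <- dplyr::bind_rows(genes, genes)
  expect_error(annotated_genome("x", dup, c(c1 = 100)), "unique")
  amb <- genes; amb$protein_seq <- "MKB"  # B not allowed
  expect_error(annotated_genome("x", amb, c(c1 = 100)), "alphabet")
})

test_that("seed sets count entries, keep paralogs, and check vocabulary", {
  ds <- small_dataset()
  seeds <- seed_set_from_dataset(ds, include_paralogs = TRUE)
  expect_equal(length(unique(seeds$entries$family)), 10)
  expect_gte(nrow(seeds$entries), 13)  # paralog copies retained
  expect_true(any(duplicated(seeds$entries$family)))
  # unknown family name is rejected
  bad <- seeds$entries
  bad$family[1] <- "Capsid"
  expect_error(seed_set(bad, seeds$seed_genome), "Capsid")
  # FASTA ids absent from the family map are listed
  dir <- withr::local_tempdir()
  ds_dir <- file.path(dir, "ds")
  write_dataset(ds, ds_dir)
  fam <- read.delim(file.path(ds_dir, "seed_families.tsv"))
  fam <- fam[-1, ]
  fmap <- file.path(dir, "broken.tsv")
  write.table(fam, fmap, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    read_seed_set(file.path(ds_dir, "seeds.faa"), fmap,
                  seeds$seed_genome),
    "missing from family map")
  # the round-trip through files reproduces the in-memory seed set
  seeds2 <- read_seed_set(file.path(ds_dir, "seeds.faa"),
                          file.path(ds_dir, "seed_families.tsv"),
                          seeds$seed_genome)
  base <- seed_set_from_dataset(ds)
  expect_equal(seeds2$entries$protein_seq, base$entries$protein_seq)
  expect_equal(seeds2$entries$family, base$entries$family)
})

test_that("cluster reports round-trip with one row per gene plus a summary", {
  ds <- small_dataset()
  seeds <- small_seeds()
  scan <- fixture("scan_tax3", function() {
    scan_genome(ds$genomes[[3]], seeds)
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_report(scan$clusters, path)
  rep <- read_cluster_report(path)
  n_genes <- sum(vapply(scan$clusters, function(cl) nrow(cl$genes),
                        integer(1)))
  expect_equal(sum(rep$record == "gene"), n_genes)
  expect_equal(sum(rep$record == "summary"), length(scan$clusters))
  summ <- rep[rep$record == "summary", ]
  expect_setequal(summ$status, c("retained", "rejected"))
  for (i in seq_along(scan$clusters)) {
    cl <- scan$clusters[[i]]
    expect_equal(summ$core_count[i], cl$core_count)
    expect_equal(summ$span_start[i], cl$span[1])
    expect_equal(summ$span_end[i], cl$span[2])
    expect_identical(summ$synteny_score[i], cl$synteny_score)
  }
  # empty cluster list -> header-only file
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_report(pltscan:::plts_clusters(list()), path2)
  expect_equal(nrow(read_cluster_report(path2)), 0)
  expect_equal(length(readLines(path2)), 1)
})

test_that("Newick I/O preserves topology, lengths and supports", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):1,(c:1,d:1):1);", path)
  tr <- read_newick(path)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(ape::Nnode(ape::unroot(tr)), 2)  # one internal edge
  # supports written as node labels survive a round trip
  ds <- small_dataset()
  sm <- fixture("small_supermatrix", function() {
    fams <- c("Sheath", "Gp25", "BaseplateJ", "LysM", "VgrG")
    concatenate_alignments(lapply(fams, function(f) {
      align_family(ds$family_seqs[[f]], family = f)
    }))
  })
  bs <- bootstrap_support(sm, n_reps = 50, seed = 5)
  write_newick(bs, path)
  bs2 <- read_newick(path)
  expect_equal(rf_distance(bs, bs2)$rf, 0)
  keys1 <- pltscan:::node_bipartition_keys(bs)
  keys2 <- pltscan:::node_bipartition_keys(bs2)
  sup1 <- stats::setNames(bs$node.label, keys1)
  sup2 <- stats::setNames(bs2$node.label, keys2)
  common <- stats::na.omit(keys1)
  expect_equal(as.numeric(sup1[common]), as.numeric(sup2[common]))
  # degenerate inputs
  writeLines("((a,b),(a,c));", path)
  expect_error(read_newick(path), "duplicate")
  writeLines("((a,b),(c,d);", path)
  expect_error(read_newick(path), "unbalanced")
})
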