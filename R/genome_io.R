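# Genome, seed-set and tree I/O.  Internal coordinates are 0-based
# half-open; GenBank/GFF3 files use 1-based inclusive coordinates and the
# conversion happens only at the file boundary.

#' Construct an annotated genome
#'
#' The central substrate of the scan: one or more contigs plus
#' coordinate-anchored protein-coding genes.  Gene coordinates are 0-based
#' half-open (`end - start` is the span length in nucleotides).
#'
#' @param genome_id Short unique identifier.
#' @param genes A data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`+`/`-`), `protein_seq`, `product`.
#' @param contigs Named numeric vector of contig lengths.
#' @param taxon_name Organism name (free text).
#' @param lineage Character vector of taxonomy labels, phylum to genus.
#' @param contig_seqs Optional named character vector of contig DNA
#'   sequences (required to write GFF3+FASTA output).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, genes, contigs,
                             taxon_name = genome_id,
                             lineage = character(),
                             contig_seqs = NULL) {
  genes <- as_tibble(genes)
  need <- c("gene_id", "contig_id", "start", "end", "strand",
            "protein_seq", "product")
  if (!all(need %in% names(genes))) {
    abort(paste("genes is missing columns:",
                paste(setdiff(need, names(genes)), collapse = ", ")))
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  for (col in names(genes)) genes[[col]] <- unname(genes[[col]])
  if (anyDuplicated(genes$gene_id)) {
    abort("gene_ids must be unique within a genome")
  }
  if (any(genes$start >= genes$end)) {
    abort("every gene must satisfy start < end (0-based half-open)")
  }
  if (any(genes$end - genes$start < 3)) {
    abort("gene spans must be at least 3 nucleotides")
  }
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (!all(genes$contig_id %in% names(contigs))) {
    abort("every gene must lie on a declared contig")
  }
  over <- genes$end > contigs[genes$contig_id]
  if (any(over)) {
    abort(paste("gene(s) extend beyond their contig:",
                paste(genes$gene_id[over], collapse = ", ")))
  }
  if (any(!nzchar(genes$protein_seq))) {
    abort("protein_seq must be non-empty for every gene")
  }
  check_protein(genes$protein_seq, "gene protein_seq")
  genes <- arrange(genes, .data$contig_id, .data$start)
  structure(
    list(genome_id = genome_id, taxon_name = taxon_name,
         lineage = lineage, contigs = contigs, genes = genes,
         contig_seqs = contig_seqs),
    class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s (%s): %d contig(s), %d genes\n",
              x$genome_id, x$taxon_name, length(x$contigs), nrow(x$genes)))
  invisible(x)
}

#' Read an annotated genome from GenBank or GFF3+FASTA
#'
#' File coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention.  Protein translations are taken from the
#' `/translation` qualifier when present, otherwise derived from the CDS
#' span of the genomic sequence under translation table 11.
#'
#' @param path GenBank flat file or GFF3 file.
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta Genomic FASTA path (required for `"gff3"`).
#' @param genome_id Identifier; defaults to the file base name.
#' @return An [annotated_genome()].
#' @export
read_annotated_genome <- function(path, format = c("genbank", "gff3"),
                                  fasta = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("file not found:", path))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "genbank") {
    read_genbank_genome(path, genome_id)
  } else {
    if (is.null(fasta)) abort("format 'gff3' needs the genomic FASTA via `fasta`")
    read_gff3_genome(path, fasta, genome_id)
  }
}

read_gff3_genome <- function(path, fasta, genome_id) {
  gr <- rtracklayer::import(path)
  if (length(gr) == 0) abort(paste("no features parsed from", path))
  dna <- Biostrings::readDNAStringSet(fasta)
  names(dna) <- sub("\\s.*$", "", names(dna))
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) abort(paste("no CDS features in", path))
  contig <- as.character(GenomicRanges::seqnames(cds))
  missing_ctg <- setdiff(unique(contig), names(dna))
  if (length(missing_ctg)) {
    abort(paste("contigs absent from FASTA:", paste(missing_ctg, collapse = ", ")))
  }
  start1 <- GenomicRanges::start(cds)
  end1 <- GenomicRanges::end(cds)
  strand <- as.character(GenomicRanges::strand(cds))
  ids <- cds$ID
  if (is.null(ids) || anyNA(ids)) abort("every CDS needs an ID attribute")
  prot <- vapply(seq_along(cds), function(i) {
    seg <- as.character(Biostrings::subseq(dna[[contig[i]]], start1[i], end1[i]))
    translate_protein(seg, strand[i])
  }, character(1))
  prod <- if (!is.null(cds$product)) as.character(cds$product) else
    rep("hypothetical protein", length(cds))
  prod[is.na(prod)] <- "hypothetical protein"
  annotated_genome(
    genome_id = genome_id,
    genes = tibble(gene_id = as.character(ids), contig_id = contig,
                   start = start1 - 1L, end = end1, strand = strand,
                   protein_seq = prot, product = prod),
    contigs = setNames(Biostrings::width(dna), names(dna)),
    contig_seqs = setNames(as.character(dna), names(dna)))
}

#' Write an annotated genome
#'
#' @param genome An [annotated_genome()].
#' @param path Output path (GenBank flat file, or GFF3 when
#'   `format = "gff3"`).
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta FASTA output path for `format = "gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotated_genome <- function(genome, path, format = c("genbank", "gff3"),
                                   fasta = NULL) {
  format <- match.arg(format)
  if (format == "genbank") {
    write_genbank_genome(genome, path)
  } else {
    if (is.null(fasta)) abort("format 'gff3' needs a FASTA output path")
    write_gff3_genome(genome, path, fasta)
  }
  invisible(path)
}

write_gff3_genome <- function(genome, path, fasta) {
  if (is.null(genome$contig_seqs)) {
    abort("GFF3+FASTA output needs contig_seqs on the genome")
  }
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(genome$contigs), as.integer(genome$contigs)),
             sprintf("%s\tpltscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
                     g$contig_id, g$start + 1L, g$end, g$strand, g$gene_id,
                     gsub("[;=\t]", "_", g$product)))
  writeLines(lines, path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contig_seqs), fasta, width = 70L)
  invisible(path)
}

# --- GenBank flat file (reader/writer) -------------------------------------
# No installed R package parses GenBank flat files offline, so the dialect
# used here is implemented directly: LOCUS/DEFINITION/SOURCE headers, CDS
# features with locus_tag/product/translation qualifiers, optional ORIGIN.

write_genbank_genome <- function(genome, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  wrap_qualifier <- function(text, width = 58) {
    substring(text, seq(1, nchar(text), width),
              pmin(seq(1, nchar(text), width) + width - 1, nchar(text)))
  }
  for (ctg in names(genome$contigs)) {
    len <- as.integer(genome$contigs[[ctg]])
    writeLines(sprintf(
      "LOCUS       %-17s %d bp    DNA     linear   BCT 01-JAN-2014",
      ctg, len), con)
    writeLines(sprintf("DEFINITION  %s, contig %s.", genome$taxon_name, ctg), con)
    writeLines(sprintf("SOURCE      %s", genome$taxon_name), con)
    writeLines(sprintf("  ORGANISM  %s", genome$taxon_name), con)
    lin <- if (length(genome$lineage)) paste(genome$lineage, collapse = "; ")
           else "Unclassified"
    writeLines(sprintf("            %s.", lin), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", len), con)
    writeLines(sprintf("                     /organism=\"%s\"", genome$taxon_name), con)
    g <- genome$genes[genome$genes$contig_id == ctg, ]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", g$gene_id[i]), con)
      writeLines(sprintf("                     /product=\"%s\"",
                         gsub("\"", "'", g$product[i])), con)
      tr <- wrap_qualifier(paste0("/translation=\"", g$protein_seq[i], "\""))
      writeLines(paste0("                     ", tr), con)
    }
    if (!is.null(genome$contig_seqs)) {
      writeLines("ORIGIN", con)
      s <- tolower(genome$contig_seqs[[ctg]])
      pos <- seq(1, nchar(s), 60)
      for (p in pos) {
        chunk <- substring(s, p, min(p + 59, nchar(s)))
        blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                            pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
        writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

read_genbank_genome <- function(path, genome_id) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    abort(paste("not a GenBank flat file (no LOCUS record):", path))
  }
  rec_starts <- grep("^LOCUS", lines)
  rec_ends <- grep("^//\\s*$", lines)
  if (length(rec_ends) < length(rec_starts)) {
    abort(paste("GenBank record not terminated by // in", path))
  }
  contigs <- numeric()
  contig_seqs <- character()
  gene_rows <- list()
  taxon <- genome_id
  lineage <- character()
  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    locus <- strsplit(trimws(sub("^LOCUS\\s+", "", rec[1])), "\\s+")[[1]]
    ctg <- locus[1]
    len <- suppressWarnings(as.integer(locus[2]))
    if (is.na(len)) abort(sprintf("cannot parse LOCUS length (record %d)", r))
    contigs[ctg] <- len
    org <- grep("^  ORGANISM", rec)
    if (length(org)) {
      taxon <- trimws(sub("^  ORGANISM", "", rec[org[1]]))
      j <- org[1] + 1
      lin <- character()
      while (j <= length(rec) && grepl("^\\s{10,}\\S", rec[j]) &&
             !grepl("^FEATURES", rec[j])) {
        lin <- c(lin, trimws(rec[j])); j <- j + 1
      }
      if (length(lin)) {
        lineage <- strsplit(sub("\\.$", "", paste(lin, collapse = " ")),
                            ";\\s*")[[1]]
      }
    }
    # ORIGIN sequence
    ori <- grep("^ORIGIN", rec)
    seq_chr <- NA_character_
    if (length(ori)) {
      body <- rec[(ori[1] + 1):(length(rec) - 1)]
      seq_chr <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
      contig_seqs[ctg] <- seq_chr
    }
    # features
    fstart <- grep("^FEATURES", rec)
    if (!length(fstart)) next
    fend <- if (length(ori)) ori[1] - 1 else length(rec) - 1
    feat <- rec[(fstart[1] + 1):fend]
    keys <- grep("^ {5}\\S", feat)
    for (ki in seq_along(keys)) {
      line1 <- feat[keys[ki]]
      key <- sub("^\\s+", "", substr(line1, 1, 20))
      key <- sub("\\s.*$", "", key)
      if (key != "CDS") next
      blk_end <- if (ki < length(keys)) keys[ki + 1] - 1 else length(feat)
      blk <- feat[keys[ki]:blk_end]
      loc <- trimws(substr(blk[1], 21, nchar(blk[1])))
      j <- 2
      while (j <= length(blk) && !grepl("^\\s{21}/", blk[j])) {
        loc <- paste0(loc, trimws(blk[j])); j <- j + 1
      }
      if (grepl("join|order", loc)) {
        abort(sprintf("compound CDS locations are not supported: %s", loc))
      }
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
      if (length(m) != 3) {
        abort(sprintf("cannot parse CDS location '%s' in record %d", loc, r))
      }
      start1 <- as.integer(m[2]); end1 <- as.integer(m[3])
      # qualifiers (joined continuation lines)
      qlines <- blk[j:length(blk)]
      qtext <- paste(trimws(qlines), collapse = "\n")
      quals <- strsplit(qtext, "\n/")[[1]]
      quals <- sub("^/", "", quals)
      getq <- function(name) {
        hit <- grep(paste0("^", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        v <- sub(paste0("^", name, "="), "", hit[1])
        gsub("\n", "", gsub("^\"|\"$", "", v))
      }
      gid <- getq("locus_tag")
      if (is.na(gid)) gid <- getq("gene")
      if (is.na(gid)) gid <- sprintf("%s_cds%03d", ctg, ki)
      prod <- getq("product")
      if (is.na(prod)) prod <- "hypothetical protein"
      prot <- getq("translation")
      if (is.na(prot)) {
        if (is.na(seq_chr)) {
          abort(sprintf(
            "CDS %s has no /translation and the record has no ORIGIN sequence",
            gid))
        }
        prot <- translate_protein(substr(seq_chr, start1, end1), strand)
      }
      gene_rows[[length(gene_rows) + 1]] <- tibble(
        gene_id = gid, contig_id = ctg, start = start1 - 1L, end = end1,
        strand = strand, protein_seq = prot, product = prod)
    }
  }
  if (!length(gene_rows)) abort(paste("no CDS features found in", path))
  annotated_genome(
    genome_id = genome_id, genes = bind_rows(gene_rows), contigs = contigs,
    taxon_name = taxon, lineage = lineage,
    contig_seqs = if (length(contig_seqs)) contig_seqs else NULL)
}

# --- seed sets --------------------------------------------------------------

#' Construct a seed set
#'
#' The seed set carries the query proteins (labeled by family) and the seed
#' genome used for reciprocal confirmation, together with the identifiers of
#' the genes that make up the seed cluster locus.
#'
#' @param entries Data frame with columns `family`, `protein_seq`,
#'   `source_locus` (gene id in the seed genome).
#' @param seed_genome An [annotated_genome()] containing the seed cluster.
#' @param cluster_gene_ids Gene ids of the seed cluster locus (defaults to
#'   the `source_locus` values).  Reverse hits must land here to count as
#'   reciprocal confirmation.
#' @param locus_families Optional named character vector mapping seed
#'   cluster gene ids to families (covering paralog copies that are not
#'   themselves seed entries); defaults to the map implied by `entries`.
#' @param profile Family vocabulary, a [plts_profile()].
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(entries, seed_genome,
                     cluster_gene_ids = unique(entries$source_locus),
                     locus_families = NULL,
                     profile = plts_profile()) {
  entries <- as_tibble(entries)
  stopifnot(all(c("family", "protein_seq", "source_locus") %in% names(entries)))
  vocab <- profile$families$family
  unknown <- setdiff(unique(entries$family), vocab)
  if (length(unknown)) {
    abort(paste("seed families outside the profile vocabulary:",
                paste(unknown, collapse = ", ")))
  }
  check_protein(entries$protein_seq, "seed protein")
  missing_locus <- setdiff(cluster_gene_ids, seed_genome$genes$gene_id)
  if (length(missing_locus)) {
    abort(paste("seed genome lacks annotated cluster gene(s):",
                paste(missing_locus, collapse = ", ")))
  }
  if (is.null(locus_families)) {
    locus_families <- setNames(entries$family, entries$source_locus)
    locus_families <- locus_families[!duplicated(names(locus_families))]
  }
  structure(list(entries = entries, seed_genome = seed_genome,
                 cluster_gene_ids = cluster_gene_ids,
                 locus_families = locus_families),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d seeds across %d families; seed genome %s\n",
              nrow(x$entries), length(unique(x$entries$family)),
              x$seed_genome$genome_id))
  invisible(x)
}

#' Read a seed set from FASTA plus a family map
#'
#' @param fasta_path Multi-FASTA of seed proteins; identifiers must appear
#'   in the family map and name genes of the seed genome.
#' @param family_map Path to a two-column TSV (`seed_id`, `family`) or an
#'   equivalent data frame.
#' @param seed_genome An [annotated_genome()] or a GenBank path.
#' @param profile Family vocabulary ([plts_profile()]).
#' @inheritParams seed_set
#' @return A [seed_set()].
#' @export
read_seed_set <- function(fasta_path, family_map, seed_genome,
                          cluster_gene_ids = NULL,
                          profile = plts_profile()) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  fm <- if (is.character(family_map) && length(family_map) == 1) {
    read.delim(family_map, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  } else as.data.frame(family_map)
  names(fm)[1:2] <- c("seed_id", "family")
  missing_ids <- setdiff(ids, fm$seed_id)
  if (length(missing_ids)) {
    abort(paste("FASTA ids missing from family map:",
                paste(missing_ids, collapse = ", ")))
  }
  if (is.character(seed_genome)) {
    seed_genome <- read_annotated_genome(seed_genome, format = "genbank")
  }
  entries <- tibble(
    family = fm$family[match(ids, fm$seed_id)],
    protein_seq = unname(as.character(aa)),
    source_locus = ids)
  seed_set(entries, seed_genome,
           cluster_gene_ids = cluster_gene_ids %||% unique(ids),
           profile = profile)
}

# --- cluster report ---------------------------------------------------------

CLUSTER_REPORT_COLS <- c(
  "record", "genome_id", "contig_id", "cluster_id", "gene_id", "start",
  "end", "strand", "family", "status", "n_genes", "core_count",
  "span_start", "span_end", "synteny_score", "sheath_copies", "tube_copies",
  "vgrg_split", "paar_present", "baseplatej_copies",
  "atpase_duf4255_head_to_tail")

#' Write a tab-separated cluster report
#'
#' One `gene` row per member gene plus one `summary` row per cluster
#' carrying the retention status, core count, span, synteny score and
#' architecture flags.  An empty cluster list yields a header-only file.
#'
#' @param clusters A `plts_clusters` list (or a single `plts_cluster`).
#' @param path Output path.
#' @param profile Profile used for architecture typing.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path, profile = plts_profile()) {
  if (inherits(clusters, "plts_cluster")) clusters <- plts_clusters(list(clusters))
  rows <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    cid <- sprintf("%s_cluster%02d", cl$genome_id, i)
    g <- cl$genes
    rows[[length(rows) + 1]] <- tibble(
      record = "gene", genome_id = cl$genome_id, contig_id = cl$contig_id,
      cluster_id = cid, gene_id = g$gene_id, start = g$start, end = g$end,
      strand = g$strand, family = ifelse(is.na(g$family), ".", g$family),
      status = cl$status, n_genes = NA_integer_, core_count = NA_integer_,
      span_start = NA_integer_, span_end = NA_integer_,
      synteny_score = NA_character_, sheath_copies = NA_integer_,
      tube_copies = NA_integer_, vgrg_split = NA,
      paar_present = NA, baseplatej_copies = NA_integer_,
      atpase_duf4255_head_to_tail = NA)
    arch <- architecture_features(cl, profile)
    rows[[length(rows) + 1]] <- tibble(
      record = "summary", genome_id = cl$genome_id, contig_id = cl$contig_id,
      cluster_id = cid, gene_id = ".", start = NA_integer_, end = NA_integer_,
      strand = ".", family = ".", status = cl$status,
      n_genes = nrow(g), core_count = cl$core_count,
      span_start = cl$span[1], span_end = cl$span[2],
      synteny_score = sprintf("%.17g", cl$synteny_score),
      sheath_copies = arch$sheath_copies, tube_copies = arch$tube_copies,
      vgrg_split = arch$vgrg_split, paar_present = arch$paar_present,
      baseplatej_copies = arch$baseplatej_copies,
      atpase_duf4255_head_to_tail = arch$atpase_duf4255_head_to_tail)
  }
  out <- if (length(rows)) bind_rows(rows) else
    as_tibble(setNames(rep(list(character(0)), length(CLUSTER_REPORT_COLS)),
                       CLUSTER_REPORT_COLS))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read back a cluster report
#'
#' @param path A TSV written by [write_cluster_report()].
#' @return A tibble with one row per report line.
#' @export
read_cluster_report <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA", colClasses = "character")
  df <- as_tibble(df)
  for (col in c("start", "end", "n_genes", "core_count", "span_start",
                "span_end", "sheath_copies", "tube_copies",
                "baseplatej_copies")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$synteny_score <- as.numeric(df$synteny_score)
  for (col in c("vgrg_split", "paar_present", "atpase_duf4255_head_to_tail")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

# --- Newick -----------------------------------------------------------------

#' Read a Newick tree
#'
#' Wraps `ape::read.tree` with a balanced-parenthesis pre-check (reporting
#' the character position of the first imbalance) and a duplicate-leaf check.
#'
#' @param path Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (depth < 0) abort(sprintf("unbalanced ')' at position %d", i))
  }
  if (depth != 0) {
    abort(sprintf("unbalanced parentheses: %d '(' left open", depth))
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) abort(paste("cannot parse Newick in", path))
  if (anyDuplicated(tr$tip.label)) {
    abort(paste("duplicate leaf labels:",
                paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                      collapse = ", ")))
  }
  tr
}

#' Write a Newick tree
#'
#' Branch lengths and internal support labels round-trip through
#' [read_newick()] with identical bipartition sets.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
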