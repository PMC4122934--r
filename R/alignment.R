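# Progressive multiple alignment: pairwise k-mer distances, a
# neighbor-joining guide tree, and profile-profile global alignment with
# affine gaps, merged in guide-tree join order.

#' Parameters for the progressive aligner
#'
#' @param gap_open,gap_extend Affine gap penalties of the profile-profile
#'   alignment (a gap of length L costs `gap_open + gap_extend * L`).
#' @param kmer Word size of the guide-tree distance (fraction of shared
#'   k-mers).
#' @param matrix Substitution matrix; default BLOSUM62 with X scored 0.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(gap_open = 10, gap_extend = 0.5, kmer = 3L,
                             matrix = NULL) {
  if (is.null(matrix)) matrix <- blosum62x()
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 kmer = as.integer(kmer), matrix = matrix),
            class = "alignment_params")
}

kmer_dist <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(table(character(0)))
    table(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  nk <- pmax(nchar(seqs) - k + 1, 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(names(counts[[i]]), names(counts[[j]]))
      common <- sum(pmin(counts[[i]][shared], counts[[j]][shared]))
      denom <- min(nk[i], nk[j])
      d[i, j] <- d[j, i] <- if (denom > 0) 1 - common / denom else 1
    }
  }
  d
}

# column frequency profile over the matrix alphabet; gaps contribute 0
profile_freq <- function(A, syms) {
  f <- vapply(seq_len(ncol(A)),
              function(j) tabulate(match(A[, j], syms), length(syms)),
              numeric(length(syms)))
  matrix(f, nrow = length(syms)) / nrow(A)
}

merge_profiles <- function(A, B, params) {
  syms <- rownames(params$matrix)
  S <- t(profile_freq(A, syms)) %*% params$matrix %*% profile_freq(B, syms)
  path <- nw_affine_path(S, params$gap_open, params$gap_extend)
  L <- length(path$a)
  newA <- matrix("-", nrow(A), L, dimnames = list(rownames(A), NULL))
  newA[, path$a > 0] <- A[, path$a[path$a > 0], drop = FALSE]
  newB <- matrix("-", nrow(B), L, dimnames = list(rownames(B), NULL))
  newB[, path$b > 0] <- B[, path$b[path$b > 0], drop = FALSE]
  rbind(newA, newB)
}

#' Multiple alignment container
#'
#' @param rows Named character vector of equal-length gapped rows.
#' @param family Optional family label.
#' @return An object of class `plts_alignment`.
#' @export
plts_alignment <- function(rows, family = NA_character_) {
  if (length(unique(nchar(rows))) != 1) {
    abort("all alignment rows must have equal length")
  }
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    abort("rows must carry unique taxon names")
  }
  structure(list(taxa = names(rows), rows = rows, family = family),
            class = "plts_alignment")
}

#' @export
print.plts_alignment <- function(x, ...) {
  cat(sprintf("<plts_alignment> %s: %d taxa x %d columns\n",
              x$family %||% "?", length(x$rows), nchar(x$rows[[1]])))
  invisible(x)
}

#' Align one family progressively
#'
#' Pairwise fractional-common-k-mer distances feed a neighbor-joining
#' guide tree; profiles are merged by global profile-profile alignment
#' with affine gaps, in guide-tree join order.  Deterministic for a given
#' input order.
#'
#' @param seqs Named character vector (taxon -> protein), length >= 2.
#' @param params An [alignment_params()].
#' @param family Family label carried on the result.
#' @return A [plts_alignment()]; ungapping any row reproduces its input.
#' @export
align_family <- function(seqs, params = alignment_params(),
                         family = NA_character_) {
  if (length(seqs) < 2) {
    abort("need at least 2 sequences; skip alignment for singletons")
  }
  if (any(!nzchar(seqs))) abort("sequences must be non-empty")
  check_protein(seqs)
  if (is.null(names(seqs))) abort("seqs must be named by taxon")
  prof <- lapply(seqs, function(s) {
    matrix(strsplit(s, "", fixed = TRUE)[[1]], nrow = 1)
  })
  for (i in seq_along(prof)) rownames(prof[[i]]) <- names(seqs)[i]
  if (length(seqs) == 2) {
    M <- merge_profiles(prof[[1]], prof[[2]], params)
  } else {
    plan <- nj_joins(kmer_dist(seqs, params$kmer))
    for (jn in plan$joins) {
      prof[[jn$node]] <- merge_profiles(prof[[jn$a]], prof[[jn$b]], params)
      prof[[jn$a]] <- NULL
      prof[[jn$b]] <- NULL
    }
    fl <- plan$final$labels
    M <- merge_profiles(prof[[fl[1]]], prof[[fl[2]]], params)
    if (length(fl) == 3) M <- merge_profiles(M, prof[[fl[3]]], params)
  }
  rows <- matrix_to_rows(M)[names(seqs)]
  plts_alignment(rows, family = family)
}

#' Concatenate per-family alignments into a supermatrix
#'
#' @param alignments List of [plts_alignment()] objects.
#' @param taxa_policy `"intersect"` keeps only taxa present in every
#'   family (the default); `"gap_fill"` keeps the union, filling missing
#'   family blocks with gaps.
#' @return A `plts_supermatrix` with a partition map (`family`, `start`,
#'   `end`; 0-based half-open column intervals).
#' @export
concatenate_alignments <- function(alignments,
                                   taxa_policy = c("intersect", "gap_fill")) {
  taxa_policy <- match.arg(taxa_policy)
  stopifnot(length(alignments) >= 1)
  taxa_per <- lapply(alignments, function(a) a$taxa)
  if (taxa_policy == "intersect") {
    taxa <- Reduce(intersect, taxa_per)
    if (length(taxa) < 2) {
      all_taxa <- unique(unlist(taxa_per))
      miss <- unlist(lapply(alignments, function(a) {
        m <- setdiff(all_taxa, a$taxa)
        if (length(m)) paste0("(", m, ", ", a$family, ")") else character(0)
      }))
      abort(paste("fewer than 2 taxa shared by all families; missing:",
                  paste(miss, collapse = " ")))
    }
  } else {
    taxa <- unique(unlist(taxa_per))
  }
  widths <- vapply(alignments, function(a) nchar(a$rows[[1]]), integer(1))
  offsets <- cumsum(c(0L, widths))
  rows <- setNames(rep("", length(taxa)), taxa)
  for (a in alignments) {
    block <- setNames(rep(strrep("-", nchar(a$rows[[1]])), length(taxa)),
                      taxa)
    present <- intersect(taxa, a$taxa)
    block[present] <- a$rows[present]
    rows <- paste0(rows, block)
  }
  names(rows) <- taxa
  partitions <- tibble(
    family = vapply(alignments, function(a) a$family, character(1)),
    start = offsets[-length(offsets)],
    end = offsets[-1])
  structure(list(taxa = taxa, rows = rows, partitions = partitions),
            class = "plts_supermatrix")
}

#' @export
print.plts_supermatrix <- function(x, ...) {
  cat(sprintf("<plts_supermatrix> %d taxa x %d columns, %d partition(s): %s\n",
              length(x$taxa), nchar(x$rows[[1]]), nrow(x$partitions),
              paste(x$partitions$family, collapse = ", ")))
  invisible(x)
}

#' Write an alignment or supermatrix as aligned FASTA
#'
#' For a supermatrix the partition map is written as a sidecar TSV
#' (`family`, `start`, `end`) next to the FASTA.
#'
#' @param x A `plts_alignment` or `plts_supermatrix`.
#' @param path FASTA output path.
#' @param partitions_path Optional TSV path for the partition map.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(x, path, partitions_path = NULL) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x$rows), path,
                              width = 70L)
  if (!is.null(partitions_path) && inherits(x, "plts_supermatrix")) {
    write.table(x$partitions, partitions_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
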