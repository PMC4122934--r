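# Distance phylogenetics from scratch: p-distances with complete or
# pairwise gap deletion, Poisson correction d = -ln(1 - p), Saitou-Nei
# neighbor joining under the Studier-Keppler Q-criterion, and a
# column-resampling bootstrap.

#' Proportion of differing sites between two gapped rows
#'
#' Columns gapped in either row are excluded (for two rows, complete and
#' pairwise deletion coincide; matrix-wide complete deletion is applied by
#' [distance_matrix()]).
#'
#' @param a,b Equal-length gapped strings.
#' @param deletion `"pairwise"` or `"complete"` (identical for two rows).
#' @return p in `[0, 1]`, or `NA` when no comparable columns remain.
#' @export
p_distance <- function(a, b, deletion = c("pairwise", "complete")) {
  match.arg(deletion)
  if (nchar(a) != nchar(b)) abort("rows must have equal length")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  comp <- av != "-" & bv != "-"
  if (!any(comp)) return(NA_real_)
  mean(av[comp] != bv[comp])
}

#' Poisson correction of a p-distance
#'
#' `d = -ln(1 - p)` under a Poisson substitution model with uniform rates
#' across sites.  `p >= 1` is flagged as undefined (`NA`), not an error.
#'
#' @param p Proportion(s) of differing sites in `[0, 1]`.
#' @return Corrected distance(s); `NA` where undefined.
#' @export
poisson_correct <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p must lie in [0, 1]")
  ifelse(is.na(p) | p >= 1, NA_real_, -log1p(-p))
}

dist_from_char_matrix <- function(M, deletion, model) {
  if (deletion == "complete") {
    keep <- colSums(M == "-") == 0
    M <- M[, keep, drop = FALSE]
  }
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      comp <- M[i, ] != "-" & M[j, ] != "-"
      p <- if (!any(comp)) NA_real_ else mean(M[i, comp] != M[j, comp])
      d[i, j] <- d[j, i] <-
        if (model == "poisson") poisson_correct(p) else p
    }
  }
  attr(d, "undefined") <- is.na(d)
  d
}

#' Pairwise distance matrix from an alignment or supermatrix
#'
#' @param x A `plts_alignment`, `plts_supermatrix`, or named character
#'   vector of equal-length gapped rows.
#' @param deletion `"complete"` drops every column containing a gap in any
#'   row before any pair is compared (the default); `"pairwise"` drops
#'   columns per pair.
#' @param model `"poisson"` (corrected, the default) or `"p"` (raw).
#' @return A symmetric matrix with zero diagonal; undefined entries are
#'   `NA` and flagged in `attr(, "undefined")`.
#' @export
distance_matrix <- function(x, deletion = c("complete", "pairwise"),
                            model = c("poisson", "p")) {
  deletion <- match.arg(deletion)
  model <- match.arg(model)
  rows <- if (is.character(x)) x else x$rows
  dist_from_char_matrix(rows_to_matrix(rows), deletion, model)
}

# Agglomeration order shared by nj_tree() and the aligner's guide tree.
# Ties in Q are broken by the smallest (i, j) pair in the current
# ordering; new nodes are appended at the end.
nj_joins <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  joins <- list()
  k_new <- 0
  while (n > 3) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    w <- which(Q == min(Q), arr.ind = TRUE)
    w <- w[w[, 1] < w[, 2], , drop = FALSE]
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    i <- w[1, 1]; j <- w[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    k_new <- k_new + 1
    new_lab <- paste0("__njnode", k_new)
    joins[[length(joins) + 1]] <-
      list(a = labels[i], b = labels[j], la = li, lb = lj, node = new_lab)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    labels <- c(labels[keep], new_lab)
    dimnames(d) <- list(labels, labels)
    n <- n - 1
  }
  final <- if (n == 3) {
    list(labels = labels,
         lengths = c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
                     (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
                     (d[1, 3] + d[2, 3] - d[1, 2]) / 2))
  } else {
    list(labels = labels, lengths = rep(d[1, 2] / 2, 2))
  }
  list(joins = joins, final = final)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining: iteratively join the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with
#' branch lengths by the usual formulas.  Negative branch-length estimates
#' are clamped to zero (the number of clamped branches is recorded in
#' `attr(tree, "nj_negative_branches")`).  Q-ties are broken by the
#' smallest pair in the current taxon ordering, so the result is
#' deterministic in the input order.  The last three lineages are joined
#' at a single (unrooted) trifurcation.
#'
#' @param D Symmetric distance matrix with row/column names (>= 3 taxa),
#'   all entries finite: undefined distances must be resolved upstream.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (is.null(rownames(D))) abort("D needs taxon row/column names")
  if (nrow(D) < 3) abort("neighbor joining needs at least 3 taxa")
  if (anyNA(D)) {
    bad <- unique(rownames(D)[which(is.na(D), arr.ind = TRUE)[, 1]])
    abort(paste("distance matrix has undefined entries involving:",
                paste(bad, collapse = ", ")))
  }
  if (max(abs(D - t(D))) > 1e-8) abort("distance matrix must be symmetric")
  if (any(D < 0)) abort("distances must be non-negative")
  if (any(diag(D) != 0)) abort("diagonal must be zero")
  plan <- nj_joins(D)
  n_neg <- 0L
  frag <- setNames(as.list(rownames(D)), rownames(D))
  brl <- function(x) {
    if (x < 0) n_neg <<- n_neg + 1L
    fmt_num(max(0, x))
  }
  for (jn in plan$joins) {
    frag[[jn$node]] <- sprintf("(%s:%s,%s:%s)", frag[[jn$a]], brl(jn$la),
                               frag[[jn$b]], brl(jn$lb))
  }
  fl <- plan$final
  txt <- paste0("(", paste(sprintf("%s:%s", unlist(frag[fl$labels]),
                                   vapply(fl$lengths, brl, character(1))),
                           collapse = ","), ");")
  tr <- ape::read.tree(text = txt)
  attr(tr, "nj_negative_branches") <- n_neg
  tr
}

#' Resolve undefined distances
#'
#' Greedily drops the taxon with the most undefined entries until the
#' matrix is fully defined.
#'
#' @param D Distance matrix with possible `NA` entries.
#' @param action `"error"` (default) or `"drop"`.
#' @return A fully defined distance matrix.
#' @export
resolve_undefined <- function(D, action = c("error", "drop")) {
  action <- match.arg(action)
  while (anyNA(D)) {
    if (action == "error") {
      bad <- unique(rownames(D)[which(is.na(D), arr.ind = TRUE)[, 1]])
      abort(paste("undefined distances involving:",
                  paste(bad, collapse = ", ")))
    }
    worst <- which.max(rowSums(is.na(D)))
    D <- D[-worst, -worst, drop = FALSE]
    if (nrow(D) < 3) abort("fewer than 3 taxa left after dropping")
  }
  D
}

#' Column-resampling bootstrap supports
#'
#' Columns of the supermatrix are resampled with replacement over the full
#' width; each replicate is turned into distances and a neighbor-joining
#' tree, and the support of each internal edge of the full-data tree is
#' the fraction of replicate trees containing its bipartition.  Replicates
#' with undefined distances are dropped and counted (a warning fires when
#' more than 5% drop).  Identical `(seed, input)` gives identical
#' supports.  Trivial (leaf) bipartitions have support 1 by convention and
#' carry no label.
#'
#' @param M A `plts_supermatrix` (or `plts_alignment`).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling RNG.
#' @param deletion,model Passed to [distance_matrix()].
#' @return The full-data `phylo` tree with `node.label` holding supports
#'   in `[0, 1]`; attributes `n_replicates` (requested) and
#'   `n_replicates_used`.
#' @export
bootstrap_support <- function(M, n_reps = 1000L, seed = NULL,
                              deletion = c("complete", "pairwise"),
                              model = c("poisson", "p")) {
  deletion <- match.arg(deletion)
  model <- match.arg(model)
  if (n_reps < 1) abort("n_reps must be at least 1")
  C <- rows_to_matrix(M$rows)
  full_D <- dist_from_char_matrix(C, deletion, model)
  full_D <- resolve_undefined(full_D, "error")
  tree <- nj_tree(full_D)
  counts <- new.env(parent = emptyenv())
  width <- ncol(C)
  used <- 0L
  with_seed_opt(seed %||% NULL, {
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(width, width, replace = TRUE)
      D <- dist_from_char_matrix(C[, idx, drop = FALSE], deletion, model)
      if (anyNA(D)) next
      used <- used + 1L
      for (key in tree_bipartitions(nj_tree(D))) {
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  })
  if (used < 0.95 * n_reps) {
    warning(sprintf("%d of %d bootstrap replicates dropped (undefined distances)",
                    n_reps - used, n_reps))
  }
  keys <- node_bipartition_keys(tree)
  support <- vapply(keys, function(k) {
    if (is.na(k)) NA_real_ else (counts[[k]] %||% 0L) / used
  }, numeric(1))
  tree$node.label <- ifelse(is.na(support), "", fmt_num(support))
  attr(tree, "support") <- support
  attr(tree, "n_replicates") <- as.integer(n_reps)
  attr(tree, "n_replicates_used") <- used
  attr(tree, "nj_negative_branches") <- NULL
  tree
}
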