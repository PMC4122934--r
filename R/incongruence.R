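# Gene-tree vs species-tree incongruence: bipartition machinery,
# Robinson-Foulds distance, leave-one-out displacement ranking of
# horizontal-transfer candidates, and monophyly checks.

# tip label sets below every node, by node id (own post-order traversal)
node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# canonical key of the bipartition induced by a clade: the sorted side not
# containing the alphabetically first leaf
bipart_key <- function(clade, all_tips) {
  ref <- sort(all_tips)[1]
  side <- if (ref %in% clade) setdiff(all_tips, clade) else clade
  paste(sort(side), collapse = "\r")
}

# canonical keys of one tree's non-trivial bipartitions (unique set)
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  sets <- node_tip_sets(tree)
  keys <- character(0)
  for (node in (n + 1):(n + tree$Nnode)) {
    sz <- length(sets[[node]])
    if (sz >= 2 && sz <= n - 2) {
      keys <- c(keys, bipart_key(sets[[node]], tips))
    }
  }
  unique(keys)
}

# per internal node (in node.label order): its bipartition key, or NA for
# the root / trivial bipartitions
node_bipartition_keys <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  sets <- node_tip_sets(tree)
  root <- n + 1L
  vapply((n + 1):(n + tree$Nnode), function(node) {
    sz <- length(sets[[node]])
    if (node == root || sz < 2 || sz > n - 2) NA_character_
    else bipart_key(sets[[node]], tips)
  }, character(1))
}

#' Restrict a gene tree and a species tree to their shared taxa
#'
#' Gene-tree leaves are first renamed through the taxon map (used when a
#' strain is represented by a congeneric proxy in the species tree); both
#' trees are then pruned to the shared leaf set, suppressing degree-2
#' nodes and summing branch lengths across them.
#'
#' @param gene_tree,species_tree `ape::phylo` trees.
#' @param taxon_map Optional named character vector or two-column data
#'   frame mapping gene-tree leaf -> species-tree leaf; must be injective.
#' @return A list with pruned `gene` and `species` trees.
#' @export
restrict_to_shared <- function(gene_tree, species_tree, taxon_map = NULL) {
  if (!is.null(taxon_map)) {
    if (is.data.frame(taxon_map)) {
      taxon_map <- setNames(as.character(taxon_map[[2]]),
                            as.character(taxon_map[[1]]))
    }
    if (anyDuplicated(unname(taxon_map))) {
      abort("taxon map must be injective")
    }
    hit <- gene_tree$tip.label %in% names(taxon_map)
    gene_tree$tip.label[hit] <- unname(taxon_map[gene_tree$tip.label[hit]])
    if (anyDuplicated(gene_tree$tip.label)) {
      abort("taxon map produces duplicate gene-tree leaves")
    }
  }
  shared <- intersect(gene_tree$tip.label, species_tree$tip.label)
  if (length(shared) < 4) {
    abort(sprintf("only %d shared leaves; need at least 4", length(shared)))
  }
  list(gene = ape::keep.tip(gene_tree, shared),
       species = ape::keep.tip(species_tree, shared))
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets,
#' normalized by `2 (n - 3)`.  Multifurcating trees are compared by their
#' bipartition sets directly; the normalization (derived for binary trees)
#' is then conservative.
#'
#' @param a,b `ape::phylo` trees on the same leaf set (>= 4 leaves).
#' @return A list with `rf` (even, non-negative) and `rf_normalized`.
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) {
    abort("trees must share an identical leaf set")
  }
  n <- length(a$tip.label)
  if (n < 4) abort("need at least 4 leaves")
  ka <- tree_bipartitions(a)
  kb <- tree_bipartitions(b)
  rf <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  list(rf = rf, rf_normalized = rf / (2 * (n - 3)))
}

#' Rank taxa whose removal most reduces tree incongruence
#'
#' For each leaf x the drop in Robinson-Foulds distance after pruning x
#' from both trees is computed; leaves with a positive reduction are
#' returned sorted by (reduction desc, name asc).  Taxa at the top are
#' horizontal-transfer candidates: their placement alone explains much of
#' the disagreement.
#'
#' @param a,b Trees on the same leaf set (>= 5 leaves).
#' @param max_rank Truncate the ranking (default all).
#' @return A tibble (`taxon`, `rf_reduction`), empty when the trees agree.
#' @export
displaced_taxa <- function(a, b, max_rank = Inf) {
  if (!setequal(a$tip.label, b$tip.label)) {
    abort("trees must share an identical leaf set")
  }
  if (length(a$tip.label) < 5) abort("need at least 5 leaves")
  base <- rf_distance(a, b)$rf
  if (base == 0) return(tibble(taxon = character(), rf_reduction = integer()))
  red <- vapply(sort(a$tip.label), function(x) {
    base - rf_distance(ape::drop.tip(a, x), ape::drop.tip(b, x))$rf
  }, numeric(1))
  out <- tibble(taxon = names(red), rf_reduction = as.integer(red)) |>
    filter(.data$rf_reduction > 0) |>
    arrange(desc(.data$rf_reduction), .data$taxon)
  head(out, max_rank)
}

#' Is a leaf set monophyletic on an unrooted tree?
#'
#' True iff some bipartition of the tree separates exactly `leaves` from
#' the rest.  Single leaves and complements of monophyletic sets are
#' monophyletic by the trivial/symmetric bipartition.
#'
#' @param tree An `ape::phylo` tree.
#' @param leaves Proper non-empty subset of the tree's leaves.
#' @return `TRUE` or `FALSE`.
#' @export
check_monophyly <- function(tree, leaves) {
  tips <- tree$tip.label
  leaves <- unique(leaves)
  if (!all(leaves %in% tips)) {
    abort(paste("unknown leaves:",
                paste(setdiff(leaves, tips), collapse = ", ")))
  }
  if (length(leaves) < 1 || length(leaves) >= length(tips)) {
    abort("leaves must be a proper non-empty subset of the tips")
  }
  k <- length(leaves)
  if (k == 1 || k == length(tips) - 1) return(TRUE)
  bipart_key(leaves, tips) %in% tree_bipartitions(tree)
}

#' Full gene-tree vs species-tree incongruence report
#'
#' Prunes to the shared taxa (through an optional taxon map), computes the
#' Robinson-Foulds incongruence, ranks displaced taxa as
#' horizontal-transfer candidates, and tests named monophyly claims on the
#' pruned gene tree.
#'
#' @inheritParams restrict_to_shared
#' @param monophyly_groups Named list of leaf sets to test (on the gene
#'   tree after mapping/pruning).
#' @param max_rank Truncation of the displacement ranking.
#' @return An object of class `incongruence_report`.
#' @export
incongruence_report <- function(gene_tree, species_tree, taxon_map = NULL,
                                monophyly_groups = list(), max_rank = Inf) {
  pr <- restrict_to_shared(gene_tree, species_tree, taxon_map)
  rf <- rf_distance(pr$gene, pr$species)
  displaced <- if (length(pr$gene$tip.label) >= 5) {
    displaced_taxa(pr$gene, pr$species, max_rank)
  } else tibble(taxon = character(), rf_reduction = integer())
  mono <- lapply(monophyly_groups, function(grp) {
    grp <- intersect(grp, pr$gene$tip.label)
    if (length(grp) < 1 || length(grp) >= length(pr$gene$tip.label)) NA
    else check_monophyly(pr$gene, grp)
  })
  structure(list(
    shared_leaf_count = length(pr$gene$tip.label),
    rf = rf$rf, rf_normalized = rf$rf_normalized,
    displaced = displaced, monophyly_results = mono,
    gene_tree = pr$gene, species_tree = pr$species),
    class = "incongruence_report")
}

#' @export
print.incongruence_report <- function(x, ...) {
  cat(sprintf("<incongruence_report> %d shared leaves; RF = %d (normalized %.3f)\n",
              x$shared_leaf_count, x$rf, x$rf_normalized))
  if (nrow(x$displaced)) {
    cat("horizontal-transfer candidates (rf reduction when pruned):\n")
    for (i in seq_len(nrow(x$displaced))) {
      cat(sprintf("  %s: %d\n", x$displaced$taxon[i],
                  x$displaced$rf_reduction[i]))
    }
  } else cat("no displaced taxa\n")
  for (nm in names(x$monophyly_results)) {
    cat(sprintf("  monophyly[%s]: %s\n", nm, x$monophyly_results[[nm]]))
  }
  invisible(x)
}
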