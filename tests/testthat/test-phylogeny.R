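# Distances, Poisson correction, neighbor joining and the bootstrap.

test_that("p-distance counts mismatches over comparable columns", {
  expect_equal(p_distance("MKVL", "MKVL"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("A-CD", "ABCD"), 0)  # 3 comparable, 0 mismatches
  expect_true(is.na(p_distance("--", "AA")))
  expect_error(p_distance("AA", "AAA"), "equal length")
})

test_that("Poisson correction matches its closed form and flags p >= 1", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), log(2))
  expect_true(is.na(poisson_correct(1)))
  expect_error(poisson_correct(-0.1), "0, 1")
  # strictly increasing and >= identity on [0, 1)
  p <- seq(0, 0.99, 0.01)
  d <- poisson_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("complete deletion removes gapped columns matrix-wide", {
  rows <- c(a = "AKCDE", b = "A-CDE", c = "AKCDD")
  Dc <- distance_matrix(rows, deletion = "complete", model = "p")
  # column 2 is dropped for every pair, so a vs c compare on ACDE/ACDD
  expect_equal(Dc["a", "c"], 0.25)
  Dp <- distance_matrix(rows, deletion = "pairwise", model = "p")
  expect_equal(Dp["a", "c"], 0.2)  # all 5 columns comparable
  expect_equal(Dc, t(Dc), ignore_attr = TRUE)
  expect_equal(unname(diag(Dc)), rep(0, 3))
})

test_that("three taxa join with closed-form branch lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(ape::Ntip(tr), 3)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["a"]), (2 + 3 - 4) / 2)
  expect_equal(unname(len["b"]), (2 + 4 - 3) / 2)
  expect_equal(unname(len["c"]), (3 + 4 - 2) / 2)
})

test_that("a four-taxon additive matrix is recovered exactly", {
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  D <- ape::cophenetic.phylo(gen)[c("A", "B", "C", "D"),
                                  c("A", "B", "C", "D")]
  tr <- nj_tree(D)
  # oracle: least-squares fit of all 3 unrooted 4-leaf topologies
  topo_fit <- function(pair) {
    others <- setdiff(c("A", "B", "C", "D"), pair)
    X <- rbind(
      c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 1), c(1, 0, 0, 1, 1),
      c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 1), c(0, 0, 1, 1, 0))
    pairs <- rbind(c(pair[1], pair[2]), c(pair[1], others[1]),
                   c(pair[1], others[2]), c(pair[2], others[1]),
                   c(pair[2], others[2]), c(others[1], others[2]))
    y <- D[pairs]
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss <- vapply(list(c("A", "B"), c("A", "C"), c("A", "D")), topo_fit,
                numeric(1))
  expect_equal(which.min(rss), 1)  # AB|CD is the additive topology
  expect_lt(rss[1], 1e-20)
  expect_true(check_monophyly(tr, c("A", "B")))
  expect_equal(rf_oracle(tr, gen), 0)
  # exact branch lengths: path lengths reproduce the matrix
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D)
})

test_that("neighbor joining is consistent on random additive matrices", {
  withr::with_seed(40, {
    for (rep in 1:30) {
      ra <- random_additive(8)
      tr <- nj_tree(ra$D)
      expect_equal(rf_oracle(tr, ra$tree), 0)
      expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$D),
                                             colnames(ra$D)],
                   ra$D, tolerance = 1e-8)
    }
  })
})

test_that("invalid distance matrices are rejected", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_error(nj_tree(D), "at least 3")
  D3 <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3), "undefined")
  D4 <- matrix(c(0, 1, 2, 1, 0, 1, 2.5, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D4), "symmetric")
  # greedy pruning resolves undefined entries
  D5 <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D5) <- 0
  D5["a", "d"] <- D5["d", "a"] <- NA
  out <- resolve_undefined(D5, action = "drop")
  expect_false(anyNA(out))
  expect_equal(nrow(out), 3)
  expect_error(resolve_undefined(D5, action = "error"), "undefined")
})

test_that("bootstrap gives full support to a constant signal and is seeded", {
  # every column supports the same 4-taxon split
  rows <- c(a = strrep("AW", 20), b = strrep("AW", 20),
            c = strrep("AA", 20), d = strrep("AA", 20))
  sm <- structure(list(taxa = names(rows), rows = rows,
                       partitions = tibble::tibble(
                         family = "x", start = 0L, end = 40L)),
                  class = "plts_supermatrix")
  bs <- bootstrap_support(sm, n_reps = 100, seed = 3)
  sup <- attr(bs, "support")
  expect_equal(unname(sup[!is.na(sup)]), 1)
  expect_equal(attr(bs, "n_replicates"), 100L)
  expect_equal(attr(bs, "n_replicates_used"), 100L)
  # same seed -> identical supports; the full-data tree is unchanged
  ds <- small_dataset()
  sm5 <- fixture("small_supermatrix", function() {
    fams <- c("Sheath", "Gp25", "BaseplateJ", "LysM", "VgrG")
    concatenate_alignments(lapply(fams, function(f) {
      align_family(ds$family_seqs[[f]], family = f)
    }))
  })
  b1 <- bootstrap_support(sm5, n_reps = 60, seed = 9)
  b2 <- bootstrap_support(sm5, n_reps = 60, seed = 9)
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  expect_error(bootstrap_support(sm5, n_reps = 0), "at least 1")
})

test_that("fixed config and seed give byte-identical Newick output", {
  ds <- small_dataset()
  sm5 <- fixture("small_supermatrix", function() {
    fams <- c("Sheath", "Gp25", "BaseplateJ", "LysM", "VgrG")
    concatenate_alignments(lapply(fams, function(f) {
      align_family(ds$family_seqs[[f]], family = f)
    }))
  })
  p1 <- withr::local_tempfile(fileext = ".nwk")
  p2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bootstrap_support(sm5, n_reps = 40, seed = 4), p1)
  write_newick(bootstrap_support(sm5, n_reps = 40, seed = 4), p2)
  expect_identical(readLines(p1), readLines(p2))
})
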