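test_that("the move set matches a brute-force scan and is symmetric", {
  expect_equal(nrow(neighbors("AAAAA", ".....")), 0L)
  nb <- neighbors("GGGAAACCC", ".........")
  expect_setequal(nb$db, oracle_neighbors("GGGAAACCC", "........."))

  set.seed(2)
  for (sq in random_sequences(3, 12, seed = 14)) {
    land <- oracle_landscape(sq$seq)
    for (db in sample(land$db, min(8, nrow(land)))) {
      nb <- neighbors(sq, db)$db
      expect_setequal(nb, oracle_neighbors(sq$seq, db))
      # every removal is present; symmetry of the relation
      np <- nrow(oracle_pairs_from_db(db))
      expect_gte(length(nb), np)
      for (t in nb) expect_true(db %in% neighbors(sq, t)$db)
    }
  }
})

test_that("gradient walks agree with the brute-force steepest descent", {
  # a local minimum maps to itself
  expect_equal(gradient_walk("GGGAAACCC", "(((...)))")$db, "(((...)))")

  for (sq in random_sequences(3, 13, seed = 25)) {
    land <- oracle_landscape(sq$seq)
    walked <- rnascape:::gradient_walk_batch(sq, land$db)
    expected <- vapply(land$db, function(d) oracle_walk(sq$seq, d),
                       character(1), USE.NAMES = FALSE)
    expect_identical(walked, expected)
    # endpoints are fixed points; basins partition the whole space
    for (mn in unique(walked)) {
      expect_identical(gradient_walk(sq, mn)$db, mn)
    }
    expect_equal(length(walked), nrow(land))
  }
})

test_that("basin maps count attracted samples per minimum", {
  sq <- "GGGAAACCC"
  bm <- basin_map(sq, rep("(((...)))", 5))
  expect_equal(nrow(bm$minima), 1L)
  expect_equal(bm$minima$count, 5L)
  expect_equal(bm$n_samples, 5L)

  # exhaustive samples: basin sizes equal the oracle's
  land <- oracle_landscape(sq)
  bm <- basin_map(sq, land$db)
  oracle_sizes <- table(vapply(land$db, function(d) oracle_walk(sq, d),
                               character(1)))
  expect_equal(sum(bm$minima$count), nrow(land))
  expect_equal(stats::setNames(bm$minima$count, bm$minima$db),
               stats::setNames(as.integer(oracle_sizes),
                               names(oracle_sizes))[bm$minima$db])

  empty <- basin_map(sq, character(0))
  expect_equal(nrow(empty$minima), 0L)
  expect_equal(empty$n_samples, 0L)
})

test_that("flooding reproduces minimax saddle heights between all leaf pairs", {
  skip_if_not_installed("igraph")
  for (sq in random_sequences(2, 12, seed = 36)) {
    land <- enumerate_structures(sq)
    tree <- barrier_tree(land, sq, merge_threshold = 0)
    mm <- oracle_minimax(land, sq$seq)
    leaves <- tree$leaves$db
    if (nrow(tree$merges) == 0L) next
    # saddle height implied by the tree between any two leaves = the energy
    # of the highest merge on the path joining them; compare to the
    # bottleneck value on the full neighbour graph
    for (a in seq_along(leaves)) {
      for (b in seq_along(leaves)) {
        if (a >= b) next
        tree_saddle <- tree_saddle_between(tree, leaves[a], leaves[b])
        expect_equal(tree_saddle, mm$saddle(leaves[a], leaves[b]),
                     info = paste(sq$seq, leaves[a], leaves[b]))
      }
    }
  }
})

test_that("single-minimum landscapes give one leaf and no merges", {
  tree <- barrier_tree(enumerate_structures("AAAAA"), "AAAAA")
  expect_equal(nrow(tree$leaves), 1L)
  expect_equal(nrow(tree$merges), 0L)
})

test_that("merge threshold is monotone and Inf collapses to one basin", {
  sq <- bistable_sequence()
  e <- enumerate_structures(sq)
  prev <- Inf
  for (th in c(0, 1, 2, 3, 4, 6, Inf)) {
    tree <- barrier_tree(e, sq, merge_threshold = th)
    expect_lte(nrow(tree$leaves), prev)
    prev <- nrow(tree$leaves)
  }
  treeI <- barrier_tree(e, sq, merge_threshold = Inf)
  expect_equal(nrow(treeI$leaves), 1L)
  expect_equal(nrow(treeI$merges), 0L)
})

test_that("barrier_tree refuses non-exhaustive input and flags band edges", {
  e <- enumerate_structures("GGGAAACCC")
  broken <- e
  attr(broken, "complete") <- NULL
  expect_error(barrier_tree(broken, "GGGAAACCC"), "complete enumeration")
  banded <- enumerate_structures(bistable_sequence(), band = 4)
  expect_warning(barrier_tree(banded, bistable_sequence()), "band")
})

test_that("coverage fractions behave at the extremes", {
  sq <- bistable_sequence()
  e <- enumerate_structures(sq)
  tree <- barrier_tree(e, sq, merge_threshold = 0)
  all_leaves <- tree$leaves$db
  expect_equal(unname(barrier_coverage(tree, all_leaves)),
               c(1, 1))
  expect_equal(unname(barrier_coverage(tree, character(0))),
               c(0, 0))
  mfe_leaf <- tree$leaves$db[which.min(tree$leaves$energy)]
  bc <- barrier_coverage(tree, mfe_leaf)
  expect_equal(unname(bc["basin_fraction"]), 1 / nrow(tree$leaves))
  expect_equal(unname(bc["barrier_fraction"]), 0)
})
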