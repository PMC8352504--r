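test_that("mfe_fold attains the enumerated minimum", {
  f <- mfe_fold("AAAAAAAA")
  expect_equal(f$structure$db, "........")
  expect_equal(f$energy, 0)

  f <- mfe_fold("GGGAAACCC")
  expect_equal(f$structure$db, "(((...)))")
  expect_equal(f$energy, -11)

  for (sq in random_sequences(5, 14, seed = 33)) {
    land <- oracle_landscape(sq$seq)
    f <- mfe_fold(sq)
    expect_equal(f$energy, min(land$energy))
    expect_true(f$structure$db %in% land$db)
    # the returned structure is the lexicographically smallest co-optimal one
    opt <- land$db[land$energy == min(land$energy)]
    expect_identical(f$structure$db, sort(opt, method = "radix")[1L])
  }
})

test_that("constrained folding excludes forbidden pairs", {
  f1 <- mfe_fold("GGGAAACCC")
  f2 <- mfe_fold("GGGAAACCC", forbidden = f1$structure)
  shared <- intersect(paste(f1$structure$pairs[, 1], f1$structure$pairs[, 2]),
                      paste(f2$structure$pairs[, 1], f2$structure$pairs[, 2]))
  expect_length(shared, 0)
  # oracle: best structure over the restricted space
  land <- oracle_landscape("GGGAAACCC")
  keys1 <- paste(f1$structure$pairs[, 1], f1$structure$pairs[, 2])
  ok <- vapply(land$db, function(d) {
    p <- oracle_pairs_from_db(d)
    !any(paste(p[, 1], p[, 2]) %in% keys1)
  }, logical(1))
  expect_equal(f2$energy, min(land$energy[ok]))
})

test_that("partition function equals the brute-force Boltzmann sum", {
  m <- bpstack_model()
  for (sq in random_sequences(6, 16, seed = 44)) {
    land <- oracle_landscape(sq$seq)
    z_brute <- sum(exp(-m$beta * land$energy))
    pr <- partition_function(sq, m)
    expect_equal(pr$Z, z_brute, tolerance = 1e-9)
    expect_gte(pr$Z, 1)  # the open chain contributes exp(0)
  }
})

test_that("partition function handles guiding potentials (Boltzmann sum over E-hat)", {
  m <- bpstack_model()
  set.seed(9)
  for (sq in random_sequences(3, 14, seed = 55)) {
    pot <- pair_potential(sq$n)
    nz <- cbind(sample(sq$n %/% 2, 5), sq$n %/% 2 + sample(sq$n %/% 2, 5))
    pot$mat[nz] <- round(stats::rnorm(5, sd = 0.8), 3)
    land <- oracle_landscape(sq$seq, pot = pot$mat)
    pr <- partition_function(sq, m, pot)
    expect_equal(pr$Z, sum(exp(-m$beta * land$energy)), tolerance = 1e-9)
  }
})

test_that("partition function does not overflow at n = 300", {
  sq <- random_sequences(1, 300, seed = 66)[[1]]
  pr <- partition_function(sq)
  expect_true(is.finite(pr$logZ))
})

test_that("single-structure ensembles sample deterministically", {
  pr <- partition_function("AAAAAAAA")
  ss <- boltzmann_sample(pr, 50, seed = 1)
  expect_equal(ss$draws$db, "........")
  expect_equal(ss$draws$count, 50L)
})

test_that("identical seed reproduces the identical multiset", {
  pr <- partition_function("GGGAAACCCAAAGGGAAACCC")
  a <- boltzmann_sample(pr, 500, seed = 77)
  b <- boltzmann_sample(pr, 500, seed = 77)
  expect_identical(a$draws, b$draws)
  c <- boltzmann_sample(pr, 500, seed = 78)
  expect_false(identical(a$draws, c$draws))
})

test_that("sampled frequencies track the exact Boltzmann distribution", {
  m <- bpstack_model()
  sq <- "GCGCAAAAGCGCAAAGC"
  land <- oracle_landscape(sq)
  p <- oracle_probs(land, m$beta)
  pr <- partition_function(sq, m)
  ss <- boltzmann_sample(pr, 2e4, seed = 3)
  expect_true(all(ss$draws$db %in% land$db))
  expect_lt(tv_distance(empirical_freq(ss, land$db), p), 0.03)
})

test_that("enumeration is complete, duplicate-free and sorted", {
  e <- enumerate_structures("AAAAA")
  expect_equal(nrow(e), 1L)
  expect_equal(e$db, ".....")

  for (sq in random_sequences(4, 13, seed = 88)) {
    e <- enumerate_structures(sq)
    expect_equal(nrow(e), oracle_count(sq$seq))
    expect_false(any(duplicated(e$db)))
    expect_false(is.unsorted(e$energy))
    # band = 0 retains exactly the MFE-energy structures
    e0 <- enumerate_structures(sq, band = 0)
    expect_equal(e0$energy, rep(min(e$energy), nrow(e0)))
    expect_equal(nrow(e0), sum(e$energy == min(e$energy)))
  }
})

test_that("the enumeration ceiling raises an explicit error", {
  expect_error(enumerate_structures("GGGGGAAAACCCCC", ceiling = 10),
               "ceiling of 10")
})

test_that("uniform sampling is the beta = 0 limit", {
  sq <- "GGGAAACCC"
  land <- oracle_landscape(sq)
  K <- nrow(land)
  us <- uniform_sample(sq, 2e4, seed = 12)
  expect_equal(us$source, "uniform")
  f <- empirical_freq(us, land$db)
  expect_lt(tv_distance(f, stats::setNames(rep(1 / K, K), land$db)), 0.02)
  expect_equal(uniform_sample("AAAAA", 10, seed = 1)$draws$db, ".....")
})
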