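test_that("repellent penalty is linear in the shared-pair count", {
  ref <- "(((...)))...((....))"
  expect_equal(repellent_penalty(ref, ref, 0.7), 0.7)
  expect_equal(repellent_penalty(ref, paste(rep(".", 20), collapse = ""),
                                 0.7), 0)
  # |ref| = 5, two shared pairs
  s <- "(((...)))..........."
  expect_equal(repellent_penalty(ref, s, 0.5), 0.5 * 3 / 5)
  # |ref| = 4, overlap 2, alpha 0.6 -> 0.3
  ref4 <- "((((....))))"
  s2 <- "((..(....)))"  # shares (1,12), (2,11); adds (5,10)
  expect_equal(repellent_penalty(ref4, s2, 0.6), 0.3)
  expect_error(repellent_penalty("....." , ".....", 1), "no base pairs")
})

test_that("per-pair accumulation equals the sum of per-round penalties", {
  sq <- random_sequences(1, 16, seed = 61)[[1]]
  land <- oracle_landscape(sq$seq)
  withpairs <- land$db[land$db != strrep(".", sq$n)]
  set.seed(62)
  refs <- sample(withpairs, 25, replace = TRUE)
  alphas <- stats::runif(25, 0, 1.2)
  pot <- pair_potential(sq$n)
  for (k in 1:25) pot <- accumulate_potential(pot, refs[k], alphas[k])
  expect_length(pot$history, 25)
  for (db in sample(land$db, 50, replace = TRUE)) {
    direct <- sum(vapply(1:25, function(k)
      repellent_penalty(refs[k], db, alphas[k]), numeric(1)))
    expect_equal(guiding_term(pot, db), direct, tolerance = 1e-12)
  }
  # replaying the history from zero reproduces the entries exactly
  replay <- pair_potential(sq$n)
  for (h in pot$history) replay <- accumulate_potential(replay, h$db, h$alpha)
  expect_identical(replay$mat, pot$mat)
  # zero-alpha updates leave the entries unchanged
  pot0 <- accumulate_potential(pot, refs[1], 0)
  expect_identical(pot0$mat, pot$mat)
})

test_that("target selection takes the argmax with a lexicographic tie rule", {
  expect_equal(select_repellent_target(c(a = 3, b = 1)), "a")
  expect_equal(select_repellent_target(c(b = 2, a = 2)), "a")
  expect_equal(select_repellent_target(c(x = 1)), "x")
  expect_error(select_repellent_target(integer(0)), "empty")
})

test_that("saturation ratio handles every regime", {
  expect_equal(saturation_ratio(c(a = 3, b = 1, c = 1)), 2)
  expect_equal(saturation_ratio(c(a = 3, b = 2)), 0)
  expect_equal(saturation_ratio(c(a = 1, b = 1)), Inf)
  expect_equal(saturation_ratio(integer(0)), 0)
})

test_that("a single round applies no potential before sampling", {
  sq <- bistable_sequence()
  res <- explore_landscape(sq, N = 200, g = 200, seed = 5)
  expect_equal(nrow(res$per_round), 1L)
  # the draws came from the unmodified Boltzmann distribution
  pr <- partition_function(sq)
  plain <- boltzmann_sample(pr, 200, seed = rnascape:::round_seed(5, 1))
  expect_identical(res$samples$draws, plain$draws)
})

test_that("alpha = 0 reproduces the plain Boltzmann distribution", {
  m <- bpstack_model()
  sq <- "GCGCAAAAGCGCAAAGC"
  land <- oracle_landscape(sq)
  p <- oracle_probs(land, m$beta)
  res <- explore_landscape(sq, N = 2e4, g = 500, seed = 10, alpha = 0)
  expect_lt(tv_distance(empirical_freq(res$samples, land$db), p), 0.03)
  # no partition-function recomputation was ever needed after round 1
  expect_equal(sum(res$per_round$pf_recomputed), 1L)
})

test_that("a repellent update strictly decreases the target's probability", {
  m <- bpstack_model()
  sq <- bistable_sequence()
  land <- oracle_landscape(sq$seq)
  p0 <- oracle_probs(land, m$beta)
  pr <- partition_function(sq, m)
  bm <- basin_map(sq, boltzmann_sample(pr, 500, seed = 2), m)
  target <- select_repellent_target(bm)
  pot <- accumulate_potential(pair_potential(sq$n), target, m$kT)
  land1 <- oracle_landscape(sq$seq, pot = pot$mat)
  p1 <- oracle_probs(land1, m$beta)
  expect_lt(p1[[target]], p0[[target]])
})

test_that("sample frequencies match the exact distribution for the current potential", {
  m <- bpstack_model()
  sq <- "GCGCAAAAGCGCAAAGC"
  pot <- accumulate_potential(pair_potential(17), "((((....)))).....", m$kT)
  pot <- accumulate_potential(pot, "....((((....)))).", 0.4)
  land <- oracle_landscape(sq, pot = pot$mat)
  p <- oracle_probs(land, m$beta)
  pr <- partition_function(sq, m, pot)
  ss <- boltzmann_sample(pr, 2e4, seed = 8)
  expect_lt(tv_distance(empirical_freq(ss, land$db), p), 0.03)
})

test_that("runs are reproducible and caching does not change results", {
  sq <- bistable_sequence()
  a <- explore_landscape(sq, N = 600, g = 100, seed = 3)
  b <- explore_landscape(sq, N = 600, g = 100, seed = 3)
  expect_identical(a$samples$draws, b$samples$draws)
  expect_identical(a$per_round$target, b$per_round$target)
  d <- explore_landscape(sq, N = 600, g = 100, seed = 3, cache_pf = FALSE)
  expect_identical(a$samples$draws, d$samples$draws)
  expect_identical(a$potential$mat, d$potential$mat)
  expect_identical(a$basins$minima, d$basins$minima)
  # caching reused the partition function in some non-update rounds
  expect_lt(sum(a$per_round$pf_recomputed), nrow(a$per_round))
  expect_equal(sum(d$per_round$pf_recomputed), nrow(d$per_round))
})

test_that("guided sampling discovers both designed basins and dominates plain sampling", {
  sq <- bistable_sequence()
  m <- bpstack_model()
  refs <- reference_pair(sq, m)
  min1 <- gradient_walk(sq, refs$s1, m)$db
  min2 <- gradient_walk(sq, refs$s2, m)$db
  pr <- partition_function(sq, m)
  n_x <- n_b <- integer(6)
  both <- logical(6)
  for (s in 1:6) {
    res <- explore_landscape(sq, m, N = 1000, g = 100, seed = s)
    bm <- basin_map(sq, boltzmann_sample(pr, 1000, seed = s + 500), m)
    n_x[s] <- nrow(res$basins$minima)
    n_b[s] <- nrow(bm$minima)
    both[s] <- all(c(min1, min2) %in% res$basins$minima$db)
  }
  expect_gte(sum(both), 5)
  expect_gte(mean(n_x), mean(n_b))
})

test_that("negative alpha attracts sampling toward the reference", {
  m <- bpstack_model()
  sq <- bistable_sequence()
  refs <- reference_pair(sq, m)
  land <- oracle_landscape(sq$seq)
  p0 <- oracle_probs(land, m$beta)
  pot <- accumulate_potential(pair_potential(sq$n), refs$s2, -2 * m$kT)
  land1 <- oracle_landscape(sq$seq, pot = pot$mat)
  p1 <- oracle_probs(land1, m$beta)
  expect_gt(p1[[refs$s2$db]], p0[[refs$s2$db]])
})
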