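bp_distance_vec <- function(dbs, ref) {
  vapply(dbs, function(d) bp_distance(d, ref), numeric(1), USE.NAMES = FALSE)
}

test_that("reference pair is the MFE plus the best pair-disjoint structure", {
  sq <- bistable_sequence()
  refs <- reference_pair(sq)
  f1 <- mfe_fold(sq)
  expect_identical(refs$s1$db, f1$structure$db)
  expect_gt(nrow(refs$s1$pairs), 0)
  expect_gt(nrow(refs$s2$pairs), 0)
  k1 <- paste(refs$s1$pairs[, 1], refs$s1$pairs[, 2])
  k2 <- paste(refs$s2$pairs[, 1], refs$s2$pairs[, 2])
  expect_length(intersect(k1, k2), 0)
  # oracle: s2 is optimal among structures disjoint from s1
  land <- oracle_landscape(sq$seq)
  ok <- vapply(land$db, function(d) {
    p <- oracle_pairs_from_db(d)
    nrow(p) == 0L || !any(paste(p[, 1], p[, 2]) %in% k1)
  }, logical(1))
  expect_equal(refs$e2, min(land$energy[ok]))
  expect_error(reference_pair("AAAAAAAA"), "degenerate")
})

test_that("projection assigns every structure to exactly one class", {
  m <- bpstack_model()
  sq <- "GCGCAAAAGCGCAAAGC"
  refs <- reference_pair(sq)
  # a single input lands in cell (0, d(s1, s2)) at its own energy
  g1 <- project_classes(data.frame(db = refs$s1$db,
                                   energy = structure_energy(sq, refs$s1)),
                        refs$s1, refs$s2, m$beta)
  expect_equal(nrow(g1$cells), 1L)
  expect_equal(g1$cells$d1, 0L)
  expect_equal(g1$cells$d2, bp_distance(refs$s1, refs$s2))
  expect_equal(g1$cells$best_energy, structure_energy(sq, refs$s1))

  land <- oracle_landscape(sq)
  truth <- project_classes(land, refs$s1, refs$s2, m$beta,
                           source = "exhaustive")
  expect_equal(sum(truth$cells$count), nrow(land))
  # per-cell best energy equals the brute-force class minimum
  d1 <- vapply(land$db, function(d) bp_distance(d, refs$s1), numeric(1))
  d2 <- vapply(land$db, function(d) bp_distance(d, refs$s2), numeric(1))
  for (r in seq_len(nrow(truth$cells))) {
    inc <- d1 == truth$cells$d1[r] & d2 == truth$cells$d2[r]
    expect_equal(truth$cells$best_energy[r], min(land$energy[inc]))
    # triangle inequality between the two reference distances
    expect_lte(abs(truth$cells$d1[r] - truth$cells$d2[r]), truth$d12)
    expect_lte(truth$d12, truth$cells$d1[r] + truth$cells$d2[r])
    # the Boltzmann sum dominates the best single structure
    expect_gte(truth$cells$Zsum[r],
               exp(-m$beta * truth$cells$best_energy[r]) - 1e-12)
  }
  # the exhaustive cell at (0, d12) holds the MFE reference energy
  c0 <- truth$cells[truth$cells$d1 == 0 & truth$cells$d2 == truth$d12, ]
  expect_equal(c0$best_energy, structure_energy(sq, refs$s1))
})

test_that("duplicates double Zsum but leave the class optimum alone", {
  m <- bpstack_model()
  refs <- reference_pair("GGGAAACCC")
  one <- data.frame(db = "(((...)))", energy = -11)
  two <- rbind(one, one)
  gA <- project_classes(one, refs$s1, refs$s2, m$beta)
  gB <- project_classes(two, refs$s1, refs$s2, m$beta)
  expect_equal(gB$cells$Zsum, 2 * gA$cells$Zsum)
  expect_equal(gB$cells$best_energy, gA$cells$best_energy)
})

test_that("coverage is 1 for the truth itself, 0 for nothing, monotone otherwise", {
  m <- bpstack_model()
  sq <- bistable_sequence()
  refs <- reference_pair(sq)
  land <- enumerate_structures(sq)
  truth <- project_classes(land, refs$s1, refs$s2, m$beta,
                           source = "exhaustive")
  expect_equal(class_coverage(truth, truth, 0), 1)
  empty <- project_classes(data.frame(db = character(0), energy = numeric(0)),
                           refs$s1, refs$s2, m$beta)
  expect_equal(class_coverage(empty, truth, 0), 0)

  # dropping exactly one of K occupied truth cells at infinite margin
  K <- nrow(truth$cells)
  d1_all <- bp_distance_vec(land$db, refs$s1)
  d2_all <- bp_distance_vec(land$db, refs$s2)
  in_last <- d1_all == truth$cells$d1[K] & d2_all == truth$cells$d2[K]
  gK <- project_classes(land[!in_last, ], refs$s1, refs$s2, m$beta)
  expect_equal(class_coverage(gK, truth, Inf), (K - 1) / K)

  # monotone in theta and in sample size (same seed gives nested prefixes)
  pr <- partition_function(sq, m)
  cov_by_size <- numeric(0)
  for (nS in c(50, 200, 1000)) {
    ss <- boltzmann_sample(pr, nS, seed = 17)
    df <- ss$draws
    df$energy <- vapply(df$db, function(d) structure_energy(sq, d),
                        numeric(1))
    gs <- project_classes(df, refs$s1, refs$s2, m$beta)
    cov0 <- class_coverage(gs, truth, 0)
    cov_by_size <- c(cov_by_size, cov0)
    prev_th <- cov0
    for (th in c(1, 5, Inf)) {
      cth <- class_coverage(gs, truth, th)
      expect_gte(cth, prev_th)
      prev_th <- cth
    }
  }
  expect_false(is.unsorted(cov_by_size))
  # never below truth: every sampled cell optimum >= the exhaustive optimum
  ss <- boltzmann_sample(pr, 500, seed = 19)
  df <- ss$draws
  df$energy <- vapply(df$db, function(d) structure_energy(sq, d), numeric(1))
  gs <- project_classes(df, refs$s1, refs$s2, m$beta)
  keyt <- paste(truth$cells$d1, truth$cells$d2)
  keys <- paste(gs$cells$d1, gs$cells$d2)
  idx <- match(keys, keyt)
  expect_true(all(gs$cells$best_energy >= truth$cells$best_energy[idx] - 1e-9))
  # G-based coverage shares the contract
  expect_equal(class_coverage(truth, truth, 0, measure = "G"), 1)
  expect_gte(class_coverage(gs, truth, 5, measure = "G"),
             class_coverage(gs, truth, 0, measure = "G"))
})
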