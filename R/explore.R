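#' Repellent (or attractive) penalty of a structure relative to a reference
#'
#' The per-round guiding contribution `alpha * |s intersect ref| / |ref|`:
#' linear in the number of base pairs `s` shares with the reference,
#' reaching `alpha` at `s == ref` and 0 when they share no pair. Positive
#' `alpha` repels sampling from the reference, negative `alpha` attracts it.
#'
#' @param ref Reference structure with at least one pair.
#' @param s Structure to evaluate.
#' @param alpha Weight in kcal/mol.
#' @return Energy in kcal/mol.
#' @export
repellent_penalty <- function(ref, s, alpha) {
  rp <- db_parse(as_db(ref))$pairs
  if (nrow(rp) == 0L) {
    stop("reference structure has no base pairs; the penalty is undefined")
  }
  sp <- db_parse(as_db(s))$pairs
  shared <- sum(paste(rp[, 1L], rp[, 2L]) %in% paste(sp[, 1L], sp[, 2L]))
  alpha * shared / nrow(rp)
}

#' Accumulate a reference structure into a guiding potential
#'
#' Adds `alpha / |ref|` to the potential entry of every pair of `ref` and
#' appends `(ref, alpha)` to the history, so that for any structure the
#' increase of [guiding_term()] equals [repellent_penalty()] for this
#' update, and the entries remain the exact per-pair accumulation of the
#' whole history.
#'
#' @param potential A [pair_potential()].
#' @inheritParams repellent_penalty
#' @return The updated `pair_potential`.
#' @export
accumulate_potential <- function(potential, ref, alpha) {
  stopifnot(inherits(potential, "pair_potential"))
  db <- as_db(ref)
  rp <- db_parse(db)$pairs
  if (nrow(rp) == 0L) {
    stop("reference structure has no base pairs; the update is undefined")
  }
  potential$mat[rp] <- potential$mat[rp] + alpha / nrow(rp)
  potential$history[[length(potential$history) + 1L]] <-
    list(db = db, alpha = alpha)
  potential
}

#' Most over-represented local minimum of a sampling round
#'
#' The argmax of the basin counts; ties go to the lexicographically smallest
#' dot-bracket string so the choice is deterministic.
#'
#' @param counts Named integer/numeric vector (names are local-minimum
#'   dot-bracket strings) or a `basin_map`.
#' @return The selected minimum's dot-bracket string.
#' @export
select_repellent_target <- function(counts) {
  if (inherits(counts, "basin_map")) {
    counts <- stats::setNames(counts$minima$count, counts$minima$db)
  }
  if (length(counts) == 0L) stop("no basins observed: empty count map")
  top <- names(counts)[counts == max(counts)]
  sort(top, method = "radix")[1L]
}

#' Saturation ratio |M1| / |M>1|
#'
#' `M1` is the set of local minima observed exactly once over all completed
#' rounds, `M>1` those observed multiple times. The ratio is small when
#' collisions pervade, i.e. when sampling at the current potential is
#' saturated. Returns `Inf` when there are singletons but no multiply
#' observed minima, and 0 when there are no singletons (including the empty
#' map).
#'
#' @inheritParams select_repellent_target
#' @return A non-negative ratio, possibly `Inf`.
#' @export
saturation_ratio <- function(counts) {
  if (inherits(counts, "basin_map")) {
    counts <- stats::setNames(counts$minima$count, counts$minima$db)
  }
  m1 <- sum(counts == 1)
  mg <- sum(counts > 1)
  if (m1 == 0) return(0)
  if (mg == 0) return(Inf)
  m1 / mg
}

round_seed <- function(master, m) {
  as.integer((as.double(master) %% 2147483647 * 2971 + m * 7919) %% 2147483647)
}

#' Adaptive landscape exploration with repellent guiding potentials
#'
#' The core iterative sampler. Rounds `m = 1 .. ceiling(N / g)` each:
#' \enumerate{
#'   \item recompute the (soft-constrained) partition function if the
#'     potential changed since it was last computed, otherwise reuse it;
#'   \item draw `g` structures by stochastic backtracking from the current
#'     distorted Boltzmann distribution;
#'   \item gradient-walk every draw (on the unmodified energy landscape) to
#'     its local minimum and update the cumulative basin counts;
#'   \item pick this round's most over-represented minimum;
#'   \item if the cumulative saturation ratio `|M1|/|M>1|` does not exceed
#'     `mu`, add the repellent penalty for that minimum to the guiding
#'     potential (an update targeting the open chain is skipped).
#' }
#' The run is fully reproducible from `(seq, model, arguments, seed)`:
#' per-round RNG streams are derived deterministically from the master seed.
#'
#' @inheritParams mfe_fold
#' @param N Total number of samples; default 1e5.
#' @param g Granularity: samples per round; default 100.
#' @param alpha Repellent weight in kcal/mol; default `kT` of the model.
#'   `alpha = 0` reproduces plain Boltzmann sampling.
#' @param mu Saturation threshold; default 0.1.
#' @param seed Master RNG seed.
#' @param invert_gate Experimental: invert the saturation gate (update when
#'   the ratio exceeds `mu` instead). Default `FALSE`, the literal rule.
#' @param cache_pf Reuse the partition function across rounds in which the
#'   potential did not change (results are identical either way; this only
#'   saves time). Default `TRUE`.
#' @return An object of class `landscape_exploration`: `$samples`
#'   (cumulative `sample_set`), `$basins` (cumulative `basin_map`),
#'   `$potential` (final [pair_potential()] with full history) and
#'   `$per_round` (`data.frame`: round, target, saturation ratio before the
#'   gate, whether the potential was updated, whether the partition function
#'   was recomputed).
#' @examples
#' res <- explore_landscape("GCGGCAAAAGCCGCAAAGCG", N = 500, g = 50, seed = 1)
#' res$basins$minima
#' @export
explore_landscape <- function(seq, model = bpstack_model(), N = 1e5,
                              g = 100, alpha = model$kT, mu = 0.1,
                              seed = 1L, potential = NULL,
                              invert_gate = FALSE, cache_pf = TRUE) {
  seq <- as_rna(seq)
  stopifnot(N >= g, g >= 1, is.finite(alpha), mu >= 0)
  pot <- if (is.null(potential)) pair_potential(seq$n) else potential
  m_max <- ceiling(N / g)
  codes <- seq_codes(seq)
  pm <- model$pair_centi
  sc <- model$stack_centi

  pr <- NULL
  pot_dirty <- TRUE
  walk_cache <- new.env(hash = TRUE, parent = emptyenv())
  cum_counts <- new.env(hash = TRUE, parent = emptyenv())
  assignments <- new.env(hash = TRUE, parent = emptyenv())
  all_draw_db <- character(0)
  all_draw_n <- integer(0)
  per_round <- vector("list", m_max)
  drawn <- 0L

  for (m in seq_len(m_max)) {
    take <- as.integer(min(g, N - drawn))
    recomputed <- FALSE
    if (is.null(pr) || pot_dirty || !cache_pf) {
      pr <- partition_function(seq, model, pot)
      pot_dirty <- FALSE
      recomputed <- TRUE
    }
    draws <- boltzmann_sample(pr, take, seed = round_seed(seed, m))
    drawn <- drawn + take

    # gradient walks on the true landscape, cached across rounds
    uniq <- draws$draws
    need <- uniq$db[vapply(uniq$db, function(d)
      is.null(get0(d, envir = walk_cache, inherits = FALSE)), logical(1))]
    if (length(need) > 0L) {
      walked <- gradient_walk_many_cpp(codes, need, pm, sc,
                                       matrix(0, 0L, 0L))
      for (k in seq_along(need)) assign(need[k], walked[k],
                                        envir = walk_cache)
    }
    mins <- vapply(uniq$db, function(d) get(d, envir = walk_cache),
                   character(1), USE.NAMES = FALSE)
    round_counts <- tapply(uniq$count, mins, sum)
    for (k in seq_along(round_counts)) {
      nm <- names(round_counts)[k]
      assign(nm, (get0(nm, envir = cum_counts, ifnotfound = 0L) +
                    as.integer(round_counts[k])), envir = cum_counts)
    }
    for (k in seq_len(nrow(uniq))) assign(uniq$db[k], mins[k],
                                          envir = assignments)
    all_draw_db <- c(all_draw_db, uniq$db)
    all_draw_n <- c(all_draw_n, uniq$count)

    target <- select_repellent_target(round_counts)
    cc <- unlist(as.list(cum_counts, all.names = TRUE))
    ratio <- saturation_ratio(cc)
    gate <- if (invert_gate) ratio > mu else ratio <= mu
    updated <- FALSE
    if (gate) {
      if (grepl("(", target, fixed = TRUE)) {
        pot <- accumulate_potential(pot, target, alpha)
        updated <- TRUE
        if (alpha != 0) pot_dirty <- TRUE
      }
      # an open-chain target has no pairs; the update is skipped
    }
    per_round[[m]] <- data.frame(round = m, target = target,
                                 saturation = ratio, updated = updated,
                                 pf_recomputed = recomputed,
                                 stringsAsFactors = FALSE)
  }

  agg <- tapply(all_draw_n, all_draw_db, sum)
  draws_df <- data.frame(db = names(agg), count = as.integer(agg),
                         stringsAsFactors = FALSE)
  draws_df <- draws_df[order(draws_df$db, method = "radix"), , drop = FALSE]
  rownames(draws_df) <- NULL
  samples <- structure(list(draws = draws_df, n_total = sum(draws_df$count),
                            seq = seq, seed = as.integer(seed),
                            source = "xplorer"),
                       class = "sample_set")

  cc <- unlist(as.list(cum_counts, all.names = TRUE))
  minima <- data.frame(db = names(cc), count = as.integer(cc),
                       stringsAsFactors = FALSE)
  minima$energy <- vapply(minima$db, function(d)
    structure_energy(seq, d, model), numeric(1), USE.NAMES = FALSE)
  minima <- minima[order(minima$energy, minima$db, method = "radix"),
                   c("db", "energy", "count")]
  rownames(minima) <- NULL
  basins <- structure(list(assignments = unlist(as.list(assignments, all.names = TRUE)),
                           minima = minima, n_samples = samples$n_total),
                      class = "basin_map")

  structure(list(samples = samples, basins = basins, potential = pot,
                 per_round = do.call(rbind, per_round),
                 config = list(N = N, g = g, alpha = alpha, mu = mu,
                               seed = as.integer(seed),
                               invert_gate = invert_gate)),
            class = "landscape_exploration")
}

#' @export
print.landscape_exploration <- function(x, ...) {
  cat("guided landscape exploration:", x$samples$n_total, "samples in",
      nrow(x$per_round), "round(s);", nrow(x$basins$minima),
      "local minima;", sum(x$per_round$updated), "potential update(s)\n")
  invisible(x)
}
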