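#' Minimum free energy folding
#'
#' Dynamic-programming MFE folding under the pair+stack model, an optional
#' guiding potential (so the minimum is over `E + E_psi`), and optional hard
#' constraints forbidding individual base pairs. Among co-optimal structures
#' the lexicographically smallest dot-bracket string is returned
#' (`'(' < ')' < '.'`, plain byte order). The open chain is always feasible,
#' so the fold never fails: if no pair is allowed the result is the open
#' chain at energy 0.
#'
#' @param seq Sequence ([rna()] or string).
#' @param model Energy model, see [bpstack_model()].
#' @param potential Optional [pair_potential()].
#' @param forbidden Optional set of prohibited pairs: an `rna_structure`, a
#'   dot-bracket string, or a two-column matrix of 1-based pairs.
#' @return A list with components `structure` (an `rna_structure`) and
#'   `energy` (kcal/mol).
#' @examples
#' mfe_fold("GGGAAACCC")
#' @export
mfe_fold <- function(seq, model = bpstack_model(), potential = NULL,
                     forbidden = NULL) {
  seq <- as_rna(seq)
  fb <- matrix(FALSE, 0L, 0L)
  if (!is.null(forbidden)) {
    fp <- if (is.matrix(forbidden)) as_pair_matrix(forbidden)
          else db_parse(as_db(forbidden))$pairs
    fb <- matrix(FALSE, seq$n, seq$n)
    if (nrow(fp) > 0L) {
      if (any(fp > seq$n)) stop("forbidden pair out of range")
      fb[fp] <- TRUE
    }
  }
  res <- mfe_cpp(seq_codes(seq), model$pair_centi, model$stack_centi,
                 pot_matrix(potential), fb)
  list(structure = db_parse(res$db, seq), energy = res$energy)
}

#' Partition function under a model and optional guiding potential
#'
#' Computes `Z = sum over all valid structures of exp(-beta * E(s))`, with
#' `E` replaced by `E + E_psi` when a potential is supplied, by O(n^3)
#' dynamic programming. The DP tables are rescaled per nucleotide (anchored
#' at the MFE) to avoid overflow; the returned object retains the tables and
#' is the sampling source for [boltzmann_sample()].
#'
#' @inheritParams mfe_fold
#' @param beta Inverse temperature in mol/kcal; defaults to the model's.
#'   `beta = 0` yields the uniform ensemble (every structure weight 1).
#' @return An object of class `partition_result` with fields `logZ`, `Z`
#'   (may overflow to `Inf` for long sequences; `logZ` is always finite),
#'   `beta`, and the DP tables.
#' @examples
#' partition_function("GGGAAACCC")
#' @export
partition_function <- function(seq, model = bpstack_model(),
                               potential = NULL, beta = model$beta) {
  seq <- as_rna(seq)
  lnq <- 0
  if (beta > 0) {
    e_min <- mfe_fold(seq, model, potential)$energy
    lnq <- max(0, -beta * e_min) / seq$n
  }
  pf <- pf_cpp(seq_codes(seq), model$pair_centi, model$stack_centi,
               pot_matrix(potential), beta, lnq)
  structure(list(seq = seq, model = model, potential = potential,
                 beta = beta, lnq = lnq, logZ = pf$logZ,
                 Z = exp(pf$logZ),
                 tables = list(Z = pf$Z, Zp = pf$Zp, Znp = pf$Znp)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("partition function on", x$seq$n, "nt: log Z =", x$logZ,
      "(beta =", signif(x$beta, 5), "mol/kcal)\n")
  invisible(x)
}

new_sample_set <- function(draws, seq, seed, source) {
  tab <- table(draws)
  df <- data.frame(db = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(df$db, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(draws = df, n_total = length(draws), seq = seq,
                 seed = seed, source = source),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("sample set (", x$source, "): ", x$n_total, " draws, ",
      nrow(x$draws), " unique structures, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sample_set <- function(x, ...) x$draws

#' Boltzmann sampling by stochastic backtracking
#'
#' Draws structures i.i.d. from `p(s) = exp(-beta * E(s)) / Z` (with
#' `E + E_psi` and `Z-hat` under a guiding potential) by random backtracking
#' through the partition-function DP tables. Identical
#' `(partition_result, count, seed)` reproduce the identical multiset.
#'
#' @param pr A [partition_function()] result.
#' @param count Number of draws (>= 1).
#' @param seed RNG seed (integer).
#' @return A `sample_set`: the multiset of draws (`$draws` is a
#'   `data.frame` with columns `db`, `count`), plus seed and source labels.
#' @export
boltzmann_sample <- function(pr, count, seed) {
  stopifnot(inherits(pr, "partition_result"), count >= 1)
  set.seed(as.integer(seed))
  draws <- sample_cpp(seq_codes(pr$seq), pr$model$pair_centi,
                      pr$model$stack_centi, pot_matrix(pr$potential),
                      pr$beta, pr$lnq, pr$tables$Z, pr$tables$Zp,
                      pr$tables$Znp, as.integer(count))
  new_sample_set(draws, pr$seq, as.integer(seed), "boltzmann")
}

#' Uniform sampling over the conformation space
#'
#' The infinite-temperature (`beta -> 0`) limit of Boltzmann sampling:
#' every valid structure is drawn with probability `1 / |Omega|`.
#' Implemented as [boltzmann_sample()] at `beta = 0` exactly.
#'
#' @inheritParams mfe_fold
#' @inheritParams boltzmann_sample
#' @export
uniform_sample <- function(seq, count, seed, model = bpstack_model()) {
  pr <- partition_function(seq, model, beta = 0)
  out <- boltzmann_sample(pr, count, seed)
  out$source <- "uniform"
  out
}

#' Exhaustive enumeration of secondary structures
#'
#' Generates the complete, duplicate-free conformation space of a sequence,
#' optionally truncated to an energy band above the MFE, sorted by
#' `(energy, dot-bracket)` ascending (byte order). Intended for short
#' sequences; generation aborts with an error once `ceiling` structures have
#' been produced.
#'
#' @inheritParams mfe_fold
#' @param band Energy band in kcal/mol above the MFE to retain; `Inf` keeps
#'   all of the conformation space.
#' @param ceiling Hard limit on the number of structures generated.
#' @return A `data.frame` with columns `db` and `energy`, with attributes
#'   `band`, `complete` (`TRUE`: nothing inside the band is missing) and
#'   `mfe`.
#' @examples
#' enumerate_structures("GGGAAACCC")
#' @export
enumerate_structures <- function(seq, model = bpstack_model(),
                                 potential = NULL, band = Inf,
                                 ceiling = 5e6) {
  seq <- as_rna(seq)
  res <- enumerate_cpp(seq_codes(seq), model$pair_centi, model$stack_centi,
                       pot_matrix(potential), ceiling)
  df <- data.frame(db = res$db, energy = res$energy,
                   stringsAsFactors = FALSE)
  e_min <- min(df$energy)
  if (is.finite(band)) {
    df <- df[df$energy <= e_min + band + 1e-9, , drop = FALSE]
  }
  df <- df[order(df$energy, df$db, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "band") <- band
  attr(df, "complete") <- TRUE
  attr(df, "mfe") <- e_min
  attr(df, "seq") <- seq$seq
  df
}
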