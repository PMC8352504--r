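#' Density of states
#'
#' Counts unique structures per energy bin. Bins are half-open
#' `[lo, lo + w)` and anchored at the minimum energy of the input;
#' duplicate structures are removed before binning.
#'
#' @param items A `data.frame` with columns `db` and `energy`, or a
#'   `sample_set` plus `model`.
#' @param bin_width Bin width in kcal/mol; default 1.
#' @param model Used to compute energies when `items` is a `sample_set`.
#' @return A `data.frame` with columns `bin_lo`, `bin_hi`, `count`
#'   (only non-empty bins).
#' @export
density_of_states <- function(items, bin_width = 1.0,
                              model = bpstack_model()) {
  stopifnot(bin_width > 0)
  items <- items_as_df(items, model)
  if (nrow(items) == 0L) stop("empty input: no structures to bin")
  items <- items[!duplicated(items$db), , drop = FALSE]
  lo <- min(items$energy)
  bin <- floor((items$energy - lo) / bin_width + 1e-12)
  tab <- table(bin)
  b <- as.integer(names(tab))
  out <- data.frame(bin_lo = lo + b * bin_width,
                    bin_hi = lo + (b + 1) * bin_width,
                    count = as.integer(tab))
  rownames(out) <- NULL
  out
}

items_as_df <- function(items, model) {
  if (inherits(items, "sample_set")) {
    df <- items$draws
    df$energy <- vapply(df$db, function(d)
      structure_energy(items$seq, d, model), numeric(1), USE.NAMES = FALSE)
    return(df)
  }
  stopifnot(is.data.frame(items), all(c("db", "energy") %in% names(items)))
  items
}

#' Weighted mean base-pair distance of a structure ensemble
#'
#' The expected pairwise base-pair distance
#' `sum_s sum_t w(s) w(t) d(s, t)` with Boltzmann weights
#' `w(s) = exp(-beta E(s))` renormalised over the unique structures of the
#' input. Computed through the pair-frequency identity
#' `sum_(i,j) 2 q_ij (1 - q_ij)` with `q_ij` the weighted frequency of pair
#' `(i, j)`, which equals the double sum exactly.
#'
#' @inheritParams density_of_states
#' @param beta Inverse temperature in mol/kcal.
#' @return Expected distance in base pairs; 0 iff there is a single unique
#'   structure.
#' @export
weighted_mean_bp_distance <- function(items, beta = bpstack_model()$beta,
                                      model = bpstack_model()) {
  items <- items_as_df(items, model)
  stopifnot(nrow(items) >= 1L)
  items <- items[!duplicated(items$db), , drop = FALSE]
  w <- exp(-beta * (items$energy - min(items$energy)))
  w <- w / sum(w)
  q <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(nrow(items))) {
    p <- db_parse(items$db[k])$pairs
    if (nrow(p) == 0L) next
    for (r in seq_len(nrow(p))) {
      key <- paste(p[r, 1L], p[r, 2L])
      assign(key, get0(key, envir = q, ifnotfound = 0) + w[k], envir = q)
    }
  }
  qv <- unlist(as.list(q))
  if (length(qv) == 0L) return(0)
  sum(2 * qv * (1 - qv))
}

#' Diversity report for a sample set
#'
#' Bundles the general diversity measures: sample and unique-structure
#' counts, number of unique gradient-walk local minima, density of states,
#' and the weighted mean base-pair distance.
#'
#' @param samples A `sample_set`.
#' @param seq Sequence the samples live on (defaults to the sample set's).
#' @param model Energy model.
#' @param bin_width DOS bin width in kcal/mol.
#' @return An object of class `diversity_report`.
#' @export
diversity_report <- function(samples, seq = samples$seq,
                             model = bpstack_model(), bin_width = 1.0) {
  stopifnot(inherits(samples, "sample_set"))
  df <- items_as_df(samples, model)
  bm <- basin_map(seq, samples, model)
  structure(list(n_samples = samples$n_total,
                 n_unique_structures = nrow(df),
                 n_unique_minima = nrow(bm$minima),
                 dos = density_of_states(df, bin_width),
                 weighted_mean_bp_distance =
                   weighted_mean_bp_distance(df, model$beta)),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("diversity report:\n",
      " samples:            ", x$n_samples, "\n",
      " unique structures:  ", x$n_unique_structures, "\n",
      " unique local minima:", x$n_unique_minima, "\n",
      " weighted mean bp distance:",
      signif(x$weighted_mean_bp_distance, 4), "\n")
  invisible(x)
}
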