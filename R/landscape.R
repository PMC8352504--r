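#' Single base-pair move-set neighbourhood
#'
#' All valid structures obtained from `s` by removing one of its pairs or by
#' inserting one pair allowed by canonicity, the hairpin constraint, and
#' nesting (no crossing with existing pairs). The relation is symmetric:
#' `t` is a neighbour of `s` iff `s` is a neighbour of `t`.
#'
#' @inheritParams mfe_fold
#' @param s Structure (`rna_structure` or dot-bracket string), valid on `seq`.
#' @return A `data.frame` with columns `db` and `energy` (kcal/mol,
#'   including the guiding term when a potential is given).
#' @export
neighbors <- function(seq, s, model = bpstack_model(), potential = NULL) {
  seq <- as_rna(seq)
  res <- neighbors_cpp(seq_codes(seq), as_db(s), model$pair_centi,
                       model$stack_centi, pot_matrix(potential))
  data.frame(db = res$db, energy = res$energy, stringsAsFactors = FALSE)
}

#' Gradient walk to a local minimum
#'
#' Steepest descent under single base-pair moves: repeatedly move to the
#' strictly lowest-energy neighbour, breaking ties by the lexicographically
#' smallest dot-bracket string (`'(' < ')' < '.'`); stop when no neighbour is
#' strictly lower. The endpoint is the local minimum of the start
#' structure's gradient basin; local minima are fixed points.
#'
#' Energies are the unmodified model energies unless a `potential` is
#' passed explicitly; the adaptive sampler deliberately walks on the true
#' landscape (see [explore_landscape()]).
#'
#' @inheritParams neighbors
#' @return The local minimum as an `rna_structure`.
#' @export
gradient_walk <- function(seq, s, model = bpstack_model(), potential = NULL) {
  seq <- as_rna(seq)
  db <- gradient_walk_cpp(seq_codes(seq), as_db(s), model$pair_centi,
                          model$stack_centi, pot_matrix(potential))
  db_parse(db, seq)
}

# vectorised gradient walks with path memoisation (shared cache per call)
gradient_walk_batch <- function(seq, dbs, model = bpstack_model(),
                                potential = NULL) {
  seq <- as_rna(seq)
  gradient_walk_many_cpp(seq_codes(seq), dbs, model$pair_centi,
                         model$stack_centi, pot_matrix(potential))
}

#' Map samples to gradient basins
#'
#' Gradient-walks every sampled structure to its local minimum and counts,
#' per minimum, the number of attracted samples (respecting multiplicities).
#' The walks partition the observed structures uniquely.
#'
#' @inheritParams neighbors
#' @param samples A `sample_set` (see [boltzmann_sample()]), a character
#'   vector of dot-bracket draws, or a `data.frame` with columns `db` and
#'   `count`.
#' @return An object of class `basin_map`: `$assignments` (named character,
#'   observed structure -> its minimum), `$minima` (`data.frame` with `db`,
#'   `energy`, `count`), `$n_samples`.
#' @export
basin_map <- function(seq, samples, model = bpstack_model()) {
  seq <- as_rna(seq)
  df <- samples_as_df(samples)
  if (nrow(df) == 0L) {
    return(structure(list(assignments = stats::setNames(character(0),
                                                        character(0)),
                          minima = data.frame(db = character(0),
                                              energy = numeric(0),
                                              count = integer(0),
                                              stringsAsFactors = FALSE),
                          n_samples = 0L),
                     class = "basin_map"))
  }
  mins <- gradient_walk_batch(seq, df$db, model)
  counts <- tapply(df$count, mins, sum)
  minima <- data.frame(db = names(counts), count = as.integer(counts),
                       stringsAsFactors = FALSE)
  minima$energy <- vapply(minima$db, function(d)
    structure_energy(seq, d, model), numeric(1), USE.NAMES = FALSE)
  minima <- minima[order(minima$energy, minima$db, method = "radix"),
                   c("db", "energy", "count")]
  rownames(minima) <- NULL
  structure(list(assignments = stats::setNames(mins, df$db),
                 minima = minima, n_samples = sum(df$count)),
            class = "basin_map")
}

samples_as_df <- function(samples) {
  if (inherits(samples, "sample_set")) return(samples$draws)
  if (is.character(samples)) {
    tab <- table(samples)
    return(data.frame(db = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(samples)) {
    stopifnot("db" %in% names(samples))
    if (!"count" %in% names(samples)) samples$count <- 1L
    return(samples[, c("db", "count")])
  }
  stop("samples must be a sample_set, a character vector, or a data.frame")
}

#' @export
print.basin_map <- function(x, ...) {
  cat("basin map:", x$n_samples, "samples in", nrow(x$minima),
      "gradient basin(s)\n")
  invisible(x)
}

#' Barrier tree by exhaustive flooding
#'
#' Processes a complete enumeration in increasing `(energy, dot-bracket)`
#' order. A structure with no previously assigned neighbour opens a new
#' basin (it is a local minimum); with one adjacent basin it joins it; with
#' several it is a saddle that merges them at its energy. After flooding,
#' any minimum whose barrier (saddle energy minus its own energy) is below
#' `merge_threshold` is absorbed into the deeper neighbouring basin, in
#' ascending saddle order (the standard coarse graining).
#'
#' @inheritParams mfe_fold
#' @param enumeration Output of [enumerate_structures()]; must be complete
#'   within its band (the constructor refuses anything else). With a finite
#'   band, basins whose members touch the band boundary (have neighbours
#'   outside the enumeration) are flagged and a warning is issued.
#' @param merge_threshold Minimal barrier in kcal/mol for a minimum to
#'   remain its own leaf; default 3.
#' @return An object of class `barrier_tree`: `$leaves` (`db`, `energy`,
#'   `boundary`), `$merges` (`saddle_db`, `saddle_energy`, `left_db`,
#'   `right_db` -- the deepest minima of the two merged sides -- ordered by
#'   saddle energy), and `$mapping` (named integer: local minimum ->
#'   leaf index).
#' @export
barrier_tree <- function(enumeration, seq, model = bpstack_model(),
                         merge_threshold = 3.0) {
  if (!isTRUE(attr(enumeration, "complete"))) {
    stop("barrier_tree requires a complete enumeration ",
         "(from enumerate_structures)")
  }
  seq <- as_rna(seq)
  band <- attr(enumeration, "band")
  db <- enumeration$db
  en <- enumeration$energy
  o <- order(en, db, method = "radix")
  db <- db[o]; en <- en[o]
  nS <- length(db)
  codes <- seq_codes(seq)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(nS)) assign(db[k], k, envir = idx)

  parent <- integer(0)          # union-find over basins
  basin_min <- character(0)     # deepest minimum (db) per root
  basin_min_e <- numeric(0)
  basin_of <- integer(nS)       # basin id per structure
  boundary <- logical(0)        # basin touches band edge
  merges <- list()
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }

  for (k in seq_len(nS)) {
    nb <- neighbors_cpp(codes, db[k], model$pair_centi,
                        model$stack_centi, matrix(0, 0L, 0L))$db
    roots <- integer(0)
    out_of_set <- FALSE
    for (d in nb) {
      pos <- get0(d, envir = idx, inherits = FALSE)
      if (is.null(pos)) { out_of_set <- TRUE; next }
      if (pos < k) roots <- c(roots, find(basin_of[pos]))
    }
    roots <- unique(roots)
    if (length(roots) == 0L) {
      parent <- c(parent, length(parent) + 1L)
      basin_min <- c(basin_min, db[k])
      basin_min_e <- c(basin_min_e, en[k])
      boundary <- c(boundary, out_of_set)
      basin_of[k] <- length(parent)
    } else {
      if (length(roots) > 1L) {
        # saddle: merge deeper-first for deterministic left/right labels
        ord <- order(basin_min_e[roots], basin_min[roots], method = "radix")
        roots <- roots[ord]
        target <- roots[1L]
        for (r in roots[-1L]) {
          merges[[length(merges) + 1L]] <-
            list(saddle_db = db[k], saddle_energy = en[k],
                 left_db = basin_min[target], right_db = basin_min[r])
          parent[r] <- target
          boundary[target] <- boundary[target] || boundary[r]
        }
        roots <- target
      }
      basin_of[k] <- roots[1L]
      if (out_of_set) boundary[roots[1L]] <- TRUE
    }
  }

  leaves <- data.frame(db = basin_min, energy = basin_min_e,
                       boundary = boundary, stringsAsFactors = FALSE)
  merges_df <- if (length(merges) == 0L) {
    data.frame(saddle_db = character(0), saddle_energy = numeric(0),
               left_db = character(0), right_db = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(merges, as.data.frame, stringsAsFactors = FALSE))
  }

  res <- coarse_grain_tree(leaves, merges_df, merge_threshold)
  if (is.finite(band) && any(res$leaves$boundary)) {
    warning("enumeration band is finite: ", sum(res$leaves$boundary),
            " basin(s) touch the band boundary and may be artifacts")
  }
  mapping <- stats::setNames(seq_len(nrow(res$leaves)), res$leaves$db)
  structure(list(leaves = res$leaves, merges = res$merges,
                 mapping = mapping, merge_threshold = merge_threshold,
                 band = band),
            class = "barrier_tree")
}

# absorb shallow minima (barrier < threshold) into the deeper side,
# processing saddles in ascending (energy, lexicographic) order
coarse_grain_tree <- function(leaves, merges, threshold) {
  nL <- nrow(leaves)
  if (nL == 0L) return(list(leaves = leaves, merges = merges))
  id_of <- stats::setNames(seq_len(nL), leaves$db)
  parent <- seq_len(nL)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  rep_db <- leaves$db
  rep_e <- leaves$energy
  absorbed <- logical(nL)
  kept <- list()
  if (nrow(merges) > 0L) {
    o <- order(merges$saddle_energy, merges$saddle_db, method = "radix")
    merges <- merges[o, , drop = FALSE]
    for (r in seq_len(nrow(merges))) {
      a <- find(id_of[[merges$left_db[r]]])
      b <- find(id_of[[merges$right_db[r]]])
      if (a == b) next
      # deeper side keeps the representative; lexicographic tie-break
      if (rep_e[a] > rep_e[b] ||
          (rep_e[a] == rep_e[b] && rep_db[a] > rep_db[b])) {
        tmp <- a; a <- b; b <- tmp
      }
      barrier_shallow <- merges$saddle_energy[r] - rep_e[b]
      if (barrier_shallow < threshold) {
        absorbed[b] <- TRUE
        parent[b] <- a
      } else {
        kept[[length(kept) + 1L]] <-
          data.frame(saddle_db = merges$saddle_db[r],
                     saddle_energy = merges$saddle_energy[r],
                     left_db = rep_db[a], right_db = rep_db[b],
                     stringsAsFactors = FALSE)
        parent[b] <- a
      }
    }
  }
  keep <- !absorbed
  leaves_out <- leaves[keep, , drop = FALSE]
  leaves_out <- leaves_out[order(leaves_out$energy, leaves_out$db,
                                 method = "radix"), , drop = FALSE]
  rownames(leaves_out) <- NULL
  merges_out <- if (length(kept) == 0L) {
    data.frame(saddle_db = character(0), saddle_energy = numeric(0),
               left_db = character(0), right_db = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, kept)
  }
  rownames(merges_out) <- NULL
  list(leaves = leaves_out, merges = merges_out)
}

#' @export
print.barrier_tree <- function(x, ...) {
  cat("barrier tree:", nrow(x$leaves), "leaf/leaves,", nrow(x$merges),
      "merge(s), coarse-grained at", x$merge_threshold, "kcal/mol\n")
  invisible(x)
}

#' Barrier and basin coverage of a barrier tree
#'
#' Ranks the tree's merges by saddle energy, descending. A merge counts as
#' covered when the deepest minimum on each of its two sides is among the
#' minima found by a sampling run; `barrier_fraction` is the covered share
#' of the `top_k` highest saddles (or of all merges when fewer exist).
#' `basin_fraction` is the share of tree leaves among the found minima.
#' Found minima that are not leaves of the tree never cover anything.
#'
#' @param tree A [barrier_tree()].
#' @param basins_found Character vector of local-minimum dot-bracket
#'   strings (or a `basin_map`).
#' @param top_k Number of highest saddles to score; default 100.
#' @return Named numeric vector `c(barrier_fraction, basin_fraction)`.
#' @export
barrier_coverage <- function(tree, basins_found, top_k = 100L) {
  stopifnot(inherits(tree, "barrier_tree"))
  if (inherits(basins_found, "basin_map")) {
    basins_found <- basins_found$minima$db
  }
  basin_fraction <- if (nrow(tree$leaves) == 0L) 0 else
    mean(tree$leaves$db %in% basins_found)
  m <- tree$merges
  if (nrow(m) == 0L) {
    barrier_fraction <- 0
  } else {
    o <- order(-m$saddle_energy, m$saddle_db, method = "radix")
    m <- m[utils::head(o, top_k), , drop = FALSE]
    barrier_fraction <- mean(m$left_db %in% basins_found &
                             m$right_db %in% basins_found)
  }
  c(barrier_fraction = barrier_fraction, basin_fraction = basin_fraction)
}
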