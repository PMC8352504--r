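#' Reference structures for the 2D distance-class projection
#'
#' Returns (i) the MFE structure and (ii) the most stable structure that
#' shares no base pair with it, obtained from a constrained fold in which
#' all MFE pairs are prohibited. The two references are disjoint by
#' construction. If the MFE structure is the open chain the references are
#' degenerate and an error is raised.
#'
#' @inheritParams mfe_fold
#' @return A list with `s1`, `s2` (`rna_structure`) and their energies
#'   `e1`, `e2`.
#' @export
reference_pair <- function(seq, model = bpstack_model()) {
  seq <- as_rna(seq)
  f1 <- mfe_fold(seq, model)
  if (nrow(f1$structure$pairs) == 0L) {
    stop("degenerate references: the MFE structure is the open chain")
  }
  f2 <- mfe_fold(seq, model, forbidden = f1$structure)
  list(s1 = f1$structure, s2 = f2$structure, e1 = f1$energy, e2 = f2$energy)
}

#' Project structures onto 2D base-pair distance classes
#'
#' Assigns each input structure to the class `C(d1, d2)` with
#' `d1 = d_BP(s, s1)` and `d2 = d_BP(s, s2)` and summarises every occupied
#' class by its best (lowest) energy, the structure attaining it, the
#' Boltzmann sum `Zsum = sum of count * exp(-beta * E)`, and the class
#' ensemble free energy `G = -(1/beta) * log(Zsum)`.
#'
#' @param structures A `data.frame` with columns `db`, `energy` and
#'   optionally `count` (multiplicities; default 1), e.g. from
#'   [enumerate_structures()] or a `sample_set`'s draws joined with
#'   energies; or a `sample_set` (energies computed with `model`).
#' @param s1,s2 The two reference structures.
#' @param beta Inverse temperature in mol/kcal.
#' @param model Used only to compute energies when `structures` is a
#'   `sample_set`.
#' @param source Label: `"exhaustive"` grids are ground truth for
#'   [class_coverage()]; anything else is a sampled grid.
#' @return An object of class `distance_class_grid` with `$cells`
#'   (`d1, d2, best_energy, best_db, Zsum, G, count`), the references and
#'   `beta`.
#' @export
project_classes <- function(structures, s1, s2, beta = bpstack_model()$beta,
                            model = bpstack_model(), source = "sampled") {
  if (inherits(structures, "sample_set")) {
    df <- structures$draws
    df$energy <- vapply(df$db, function(d)
      structure_energy(structures$seq, d, model), numeric(1),
      USE.NAMES = FALSE)
    structures <- df
  }
  stopifnot(is.data.frame(structures),
            all(c("db", "energy") %in% names(structures)))
  if (!"count" %in% names(structures)) {
    structures$count <- rep(1L, nrow(structures))
  }
  db1 <- as_db(s1)
  db2 <- as_db(s2)
  if (nrow(structures) == 0L) {
    cells <- data.frame(d1 = integer(0), d2 = integer(0),
                        best_energy = numeric(0), best_db = character(0),
                        Zsum = numeric(0), G = numeric(0),
                        count = integer(0), stringsAsFactors = FALSE)
  } else {
    d1 <- bp_distance_batch_cpp(structures$db, db1)
    d2 <- bp_distance_batch_cpp(structures$db, db2)
    key <- paste(d1, d2, sep = ",")
    o <- order(structures$energy, structures$db, method = "radix")
    first <- !duplicated(key[o])
    best <- data.frame(key = key[o][first],
                       best_energy = structures$energy[o][first],
                       best_db = structures$db[o][first],
                       stringsAsFactors = FALSE)
    zs <- tapply(structures$count * exp(-beta * structures$energy), key, sum)
    cnt <- tapply(structures$count, key, sum)
    d1u <- as.integer(sub(",.*", "", best$key))
    d2u <- as.integer(sub(".*,", "", best$key))
    cells <- data.frame(d1 = d1u, d2 = d2u,
                        best_energy = best$best_energy,
                        best_db = best$best_db,
                        Zsum = as.numeric(zs[best$key]),
                        count = as.integer(cnt[best$key]),
                        stringsAsFactors = FALSE)
    cells$G <- if (beta > 0) -log(cells$Zsum) / beta else NA_real_
    cells <- cells[order(cells$d1, cells$d2),
                   c("d1", "d2", "best_energy", "best_db", "Zsum", "G",
                     "count")]
    rownames(cells) <- NULL
  }
  structure(list(cells = cells, s1_db = db1, s2_db = db2,
                 d12 = bp_distance_cpp(db1, db2), beta = beta,
                 source = source),
            class = "distance_class_grid")
}

#' @export
print.distance_class_grid <- function(x, ...) {
  cat("distance-class grid (", x$source, "): ", nrow(x$cells),
      " occupied class(es), d(s1, s2) = ", x$d12, "\n", sep = "")
  invisible(x)
}

#' Distance-class coverage of a sample relative to the exhaustive truth
#'
#' The fraction of occupied ground-truth classes `C(d1, d2)` in which the
#' sample reaches within an energy margin `theta` of the class optimum:
#' covered iff the class is occupied in `sampled` and
#' `min E(sampled in class) - MFE(class) <= theta` (measure `"mfe"`), or the
#' analogous condition on the class ensemble free energies `G`
#' (measure `"G"`). The denominator counts the occupied truth classes.
#' Reporting defaults elsewhere in the package are `theta = 0` and
#' `theta = 5` kcal/mol.
#'
#' @param sampled,truth [project_classes()] grids over the same references;
#'   `truth` must come from an exhaustive enumeration.
#' @param theta Energy margin in kcal/mol.
#' @param measure `"mfe"` (class minimum energy) or `"G"` (class ensemble
#'   free energy).
#' @return A fraction in `[0, 1]`.
#' @export
class_coverage <- function(sampled, truth, theta = 0, measure = c("mfe", "G")) {
  measure <- match.arg(measure)
  stopifnot(inherits(sampled, "distance_class_grid"),
            inherits(truth, "distance_class_grid"))
  if (!identical(truth$source, "exhaustive")) {
    stop("truth grid must be exhaustive (source = \"exhaustive\")")
  }
  if (sampled$s1_db != truth$s1_db || sampled$s2_db != truth$s2_db) {
    stop("reference mismatch between sampled and truth grids")
  }
  tc <- truth$cells
  if (nrow(tc) == 0L) return(0)
  key_t <- paste(tc$d1, tc$d2, sep = ",")
  sc <- sampled$cells
  key_s <- paste(sc$d1, sc$d2, sep = ",")
  idx <- match(key_t, key_s)
  v_t <- if (measure == "mfe") tc$best_energy else tc$G
  v_s <- if (measure == "mfe") sc$best_energy else sc$G
  covered <- !is.na(idx) & (v_s[idx] - v_t <= theta + 1e-9)
  mean(covered)
}

#' Write a distance-class grid as sparse TSV
#'
#' Only occupied cells are emitted, columns
#' `d1, d2, best_energy, G, count, best_structure`.
#'
#' @param grid A [project_classes()] grid.
#' @param path Output file.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "distance_class_grid"))
  cells <- grid$cells
  out <- data.frame(d1 = cells$d1, d2 = cells$d2,
                    best_energy = round(cells$best_energy, 2),
                    G = round(cells$G, 4), count = cells$count,
                    best_structure = cells$best_db,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# references: ", grid$s1_db, " ", grid$s2_db),
               paste0("# source: ", grid$source)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
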