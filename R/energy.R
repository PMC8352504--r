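# gas constant in kcal/(mol K)
R_GAS <- 1.98717e-3

E_DISALLOWED <- 1000000L

# round half away from zero, in units of 10^-2 kcal/mol
round_centi <- function(x) as.integer(sign(x) * floor(abs(x) * 100 + 0.5))

#' Built-in pair-plus-stack energy model
#'
#' A deliberately simple, fully specified nearest-neighbour-style model:
#' every canonical pair contributes a pair energy (GC/CG, AU/UA, GU/UG) and
#' every stacked adjacency -- pairs `(i, j)` and `(i+1, j-1)` both present --
#' contributes a stacking bonus. The open chain has energy exactly 0.
#' Energies are held internally as integers in units of 0.01 kcal/mol so
#' that energy comparisons (and gradient-walk tie-breaking) are exact and
#' platform independent.
#'
#' The model houses the thermodynamic constants: `kT = R * T` in kcal/mol
#' and `beta = 1 / kT`. At the default 37 C (310.15 K), `kT` is about
#' 0.6163 kcal/mol.
#'
#' Any alternative backend must expose the same fields: a 4x4 table of
#' per-pair energies (centi-kcal, `1000000` marking a disallowed pair), a
#' stacking bonus, and a temperature; the dynamic programming in this
#' package consumes exactly those loop-decomposable terms.
#'
#' @param gc,au,gu Pair energies in kcal/mol for GC/CG, AU/UA and GU/UG.
#' @param stack Bonus in kcal/mol per stacked adjacency.
#' @param temperature Temperature in Kelvin; default 310.15 (37 C).
#' @return An object of class `energy_model`.
#' @examples
#' m <- bpstack_model()
#' m$kT
#' @export
bpstack_model <- function(gc = -3.0, au = -2.0, gu = -1.0, stack = -1.0,
                          temperature = 310.15) {
  pe <- matrix(E_DISALLOWED, 4L, 4L, dimnames = list(BASES, BASES))
  pe["G", "C"] <- pe["C", "G"] <- round_centi(gc)
  pe["A", "U"] <- pe["U", "A"] <- round_centi(au)
  pe["G", "U"] <- pe["U", "G"] <- round_centi(gu)
  kT <- R_GAS * temperature
  structure(list(name = "bpstack", pair_centi = pe,
                 stack_centi = round_centi(stack),
                 temperature = temperature, kT = kT, beta = 1 / kT),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("energy model '", x$name, "' (T = ", x$temperature, " K, kT = ",
      signif(x$kT, 5), " kcal/mol)\n", sep = "")
  invisible(x)
}

#' Per-base-pair pseudo-energy (guiding potential)
#'
#' A sparse-by-construction matrix of pseudo-energies `E_ij` in kcal/mol,
#' one entry per base pair, together with the ordered history of
#' `(reference structure, alpha)` repel/attract updates applied so far. The
#' zero potential has every entry 0 and an empty history; entries are always
#' exactly the per-pair accumulation `sum_l alpha_l * [ (i,j) in s'_l ] / |s'_l|`
#' of the history.
#'
#' @param n Sequence length.
#' @return An object of class `pair_potential`.
#' @seealso [accumulate_potential()], [guiding_term()]
#' @export
pair_potential <- function(n) {
  stopifnot(n >= 1L)
  structure(list(n = as.integer(n), mat = matrix(0, n, n), history = list()),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  nz <- which(x$mat != 0, arr.ind = TRUE)
  cat("pair potential on", x$n, "nt:", nrow(nz), "non-zero entries,",
      length(x$history), "accumulated update(s)\n")
  invisible(x)
}

# zero-row matrix stands for "no potential" at the C++ interface
pot_matrix <- function(potential) {
  if (is.null(potential)) return(matrix(0, 0L, 0L))
  stopifnot(inherits(potential, "pair_potential"))
  potential$mat
}

#' Guiding-potential term of a structure
#'
#' The pair-additive pseudo-energy of `s`: the sum of potential entries over
#' the pairs present in `s`. Zero for the zero potential.
#'
#' @param potential A [pair_potential()].
#' @param s Structure (`rna_structure` or dot-bracket string).
#' @return Energy in kcal/mol.
#' @export
guiding_term <- function(potential, s) {
  stopifnot(inherits(potential, "pair_potential"))
  p <- if (inherits(s, "rna_structure")) s$pairs else db_parse(as_db(s))$pairs
  if (nrow(p) == 0L) return(0)
  sum(potential$mat[p])
}

#' Structure energy under a model and optional guiding potential
#'
#' Returns `E(s) + E_psi(s)`: the base-model energy plus, when a potential
#' is supplied, the pair-additive guiding term. With the zero potential (or
#' `potential = NULL`) this is the plain model energy.
#'
#' @param seq Sequence ([rna()] or string).
#' @param s Structure (`rna_structure` or dot-bracket string); must be valid
#'   on `seq`.
#' @param model An [bpstack_model()] energy model.
#' @param potential Optional [pair_potential()].
#' @return Energy in kcal/mol.
#' @examples
#' structure_energy("GGGAAACCC", "(((...)))")
#' @export
structure_energy <- function(seq, s, model = bpstack_model(),
                             potential = NULL) {
  seq <- as_rna(seq)
  db <- as_db(s)
  if (nchar(db) != seq$n) stop("structure/sequence length mismatch")
  validate_pairs(db_parse(db)$pairs, seq$n, seq)
  energy_cpp(seq_codes(seq), db, model$pair_centi, model$stack_centi,
             pot_matrix(potential))
}

#' Read / write pseudo-energy tables
#'
#' Tab-separated tables with columns `i`, `j`, `E_ij` (kcal/mol), 1-based,
#' `i < j`. On reading, energies are rounded half-away-from-zero to
#' 0.01 kcal/mol, the package's internal energy resolution for file inputs.
#'
#' @param path File path.
#' @param n Sequence length for the resulting potential.
#' @return `read_potential` returns a [pair_potential()];
#'   `write_potential` returns `path` invisibly.
#' @export
read_potential <- function(path, n) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  stopifnot(all(c("i", "j", "E_ij") %in% names(tab)))
  pot <- pair_potential(n)
  if (nrow(tab) > 0L) {
    i <- pmin(tab$i, tab$j)
    j <- pmax(tab$i, tab$j)
    if (any(i < 1L) || any(j > n)) stop("potential entry out of range 1..", n)
    pot$mat[cbind(i, j)] <- round_centi(tab$E_ij) / 100
  }
  pot
}

#' @rdname read_potential
#' @param potential A [pair_potential()] to write.
#' @export
write_potential <- function(potential, path) {
  stopifnot(inherits(potential, "pair_potential"))
  nz <- which(potential$mat != 0, arr.ind = TRUE)
  nz <- nz[nz[, 1L] < nz[, 2L], , drop = FALSE]
  tab <- data.frame(i = nz[, 1L], j = nz[, 2L],
                    E_ij = potential$mat[nz])
  tab <- tab[order(tab$i, tab$j), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
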