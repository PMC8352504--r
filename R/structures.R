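BASES <- c("A", "C", "G", "U")

#' RNA sequence object
#'
#' Creates an immutable RNA sequence. Input is uppercased and DNA-style `T`
#' is normalised to `U`; any other character is an error.
#'
#' @param x A single string over the alphabet `ACGU` (or `acgt`/`T` input).
#' @param id Optional label.
#' @return An object of class `rna` with fields `id`, `seq` (string) and
#'   `n` (length in nucleotides).
#' @examples
#' rna("GGGAAACCC", id = "toy")
#' @export
rna <- function(x, id = NULL) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  s <- chartr("tT", "uU", x)
  s <- toupper(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (length(chars) < 1L) stop("sequence must have length >= 1")
  bad <- setdiff(unique(chars), BASES)
  if (length(bad) > 0L) {
    stop("invalid residue(s): ", paste(bad, collapse = ", "),
         "; alphabet is A, C, G, U")
  }
  structure(list(id = if (is.null(id)) NA_character_ else as.character(id),
                 seq = s, n = length(chars)),
            class = "rna")
}

as_rna <- function(x, id = NULL) {
  if (inherits(x, "rna")) return(x)
  rna(x, id = id)
}

#' @export
print.rna <- function(x, ...) {
  cat("RNA sequence", if (!is.na(x$id)) paste0("'", x$id, "'") else "",
      "(", x$n, "nt )\n")
  cat(" ", x$seq, "\n")
  invisible(x)
}

#' @export
as.character.rna <- function(x, ...) x$seq

# integer base codes A=0, C=1, G=2, U=3 for the C++ layer
seq_codes <- function(x) {
  x <- as_rna(x)
  match(strsplit(x$seq, "", fixed = TRUE)[[1L]], BASES) - 1L
}

#' Parse a dot-bracket string into a secondary structure
#'
#' Positions are 1-based and pairs are stored with `i < j`. The structure
#' must be pseudoknot free (guaranteed by the bracket grammar), every hairpin
#' must enclose at least three unpaired bases (`j - i >= 4`), and, when a
#' sequence is supplied, every pair must be canonical
#' (`AU, UA, GC, CG, GU, UG`).
#'
#' @param text Dot-bracket string using only `(`, `)` and `.`.
#' @param seq Optional [rna()] sequence (or string) the structure must be
#'   valid on; lengths must match.
#' @return An object of class `rna_structure` with fields `pairs`
#'   (two-column integer matrix, one row per pair, ordered by `i`), `n` and
#'   `db` (the canonical dot-bracket serialisation).
#' @examples
#' db_parse("((...))", "GGAAACC")
#' @export
db_parse <- function(text, seq = NULL) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0L) {
    stop("dot-bracket strings may only contain '(', ')' and '.'; found: ",
         paste(bad, collapse = ", "))
  }
  n <- length(chars)
  open <- integer(0)
  np <- 0L
  ii <- integer(n); jj <- integer(n)
  for (k in seq_len(n)) {
    if (chars[k] == "(") {
      open <- c(open, k)
    } else if (chars[k] == ")") {
      if (length(open) == 0L) stop("unbalanced brackets: unmatched ')'")
      i <- open[length(open)]
      open <- open[-length(open)]
      np <- np + 1L
      ii[np] <- i; jj[np] <- k
    }
  }
  if (length(open) > 0L) stop("unbalanced brackets: unmatched '('")
  pairs <- cbind(i = ii[seq_len(np)], j = jj[seq_len(np)])
  if (np > 0L) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  validate_pairs(pairs, n, seq)
  structure(list(pairs = pairs, n = n, db = text), class = "rna_structure")
}

validate_pairs <- function(pairs, n, seq = NULL) {
  if (nrow(pairs) > 0L) {
    if (any(pairs[, 2L] - pairs[, 1L] < 4L)) {
      stop("hairpin constraint violated: every pair needs at least three ",
           "unpaired bases between its ends (j - i >= 4)")
    }
  }
  if (!is.null(seq)) {
    seq <- as_rna(seq)
    if (seq$n != n) {
      stop("length mismatch: structure has ", n, " positions, sequence has ",
           seq$n)
    }
    if (nrow(pairs) > 0L) {
      chars <- strsplit(seq$seq, "", fixed = TRUE)[[1L]]
      pr <- paste0(chars[pairs[, 1L]], chars[pairs[, 2L]])
      ok <- pr %in% c("AU", "UA", "GC", "CG", "GU", "UG")
      if (!all(ok)) {
        stop("non-canonical pair(s) for this sequence: ",
             paste(unique(pr[!ok]), collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

#' Serialise a set of base pairs to dot-bracket notation
#'
#' Round-trip identity with [db_parse()] holds for every valid structure.
#'
#' @param s An `rna_structure`, or a two-column matrix of 1-based pairs.
#' @param n Structure length; defaults to the structure's own length.
#' @return A dot-bracket string.
#' @examples
#' db_format(cbind(c(1, 2), c(7, 6)), n = 7)
#' @export
db_format <- function(s, n = NULL) {
  if (inherits(s, "rna_structure")) {
    pairs <- s$pairs
    if (is.null(n)) n <- s$n
  } else {
    pairs <- as_pair_matrix(s)
    if (is.null(n)) stop("n is required when pairs are given as a matrix")
  }
  if (nrow(pairs) > 0L && (any(pairs > n) || any(pairs < 1L))) {
    stop("pair position out of range 1..", n)
  }
  chars <- rep(".", n)
  chars[pairs[, 1L]] <- "("
  chars[pairs[, 2L]] <- ")"
  paste(chars, collapse = "")
}

as_pair_matrix <- function(x) {
  if (inherits(x, "rna_structure")) return(x$pairs)
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("pairs must be a two-column matrix")
  storage.mode(x) <- "integer"
  x <- cbind(i = pmin(x[, 1L], x[, 2L]), j = pmax(x[, 1L], x[, 2L]))
  if (nrow(x) > 0L) x[order(x[, 1L]), , drop = FALSE] else x
}

# accept either an rna_structure or a plain dot-bracket string
as_db <- function(x) {
  if (inherits(x, "rna_structure")) return(x$db)
  if (is.character(x) && length(x) == 1L) return(x)
  stop("expected an rna_structure or a dot-bracket string")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure (", x$n, "nt,", nrow(x$pairs), "pairs )\n")
  cat(" ", x$db, "\n")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) x$db

#' Base-pair distance between two structures
#'
#' The number of base pairs to remove and insert to turn one structure into
#' the other: `|s1| + |s2| - 2 |s1 intersect s2|`. Symmetric, zero iff the
#' structures are equal, and a metric on structures of equal length.
#'
#' @param s1,s2 Structures on the same sequence length (`rna_structure` or
#'   dot-bracket strings).
#' @return A non-negative integer.
#' @examples
#' bp_distance("((...))", ".(...).")
#' @export
bp_distance <- function(s1, s2) {
  bp_distance_cpp(as_db(s1), as_db(s2))
}
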