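#' Random RNA sequences
#'
#' I.i.d. uniform draws over `{A, C, G, U}`, seeded and reproducible.
#'
#' @param count Number of sequences.
#' @param length Length of each sequence in nucleotides.
#' @param seed RNG seed.
#' @return A list of [rna()] objects (`random_1`, `random_2`, ...).
#' @export
random_sequences <- function(count, length, seed = 1L) {
  stopifnot(count >= 1L, length >= 1L)
  set.seed(as.integer(seed))
  lapply(seq_len(count), function(k)
    rna(paste(sample(BASES, length, replace = TRUE), collapse = ""),
        id = paste0("random_", k)))
}

#' Designed bistable test sequence
#'
#' A deterministic toy sequence admitting two mutually exclusive helices: a
#' strong 5' helix (the MFE arrangement) and a weaker 3' helix that pairs
#' part of the same tract elsewhere, giving a metastable basin of low
#' Boltzmann mass. The 5' tract uses an aperiodic G/C pattern so that
#' shifted pairing registers break complementarity. [reference_pair()] on
#' the fixture yields two non-trivial, pair-disjoint structures, and the
#' exhaustively enumerated landscape has at least two gradient basins.
#'
#' @param helix_len Length of the strong helix (>= 4).
#' @param linker Length of the unpaired linker between the two strands of
#'   the strong helix (>= 3).
#' @return An [rna()] sequence.
#' @examples
#' bistable_sequence()
#' @export
bistable_sequence <- function(helix_len = 5L, linker = 4L) {
  stopifnot(helix_len >= 4L, linker >= 3L)
  pattern <- c("G", "C", "G", "G", "C")  # low autocorrelation under shifts
  tract1 <- pattern[((seq_len(helix_len) - 1L) %% 5L) + 1L]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  tract2 <- rev(unname(comp[tract1]))
  t <- max(3L, helix_len - 2L)
  tract3 <- rev(unname(comp[tract2[(helix_len - t + 1L):helix_len]]))
  rna(paste(c(tract1, rep("A", linker), tract2, rep("A", 3L), tract3),
            collapse = ""),
      id = sprintf("bistable_h%d_l%d", helix_len, linker))
}
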