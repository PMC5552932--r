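# Substitution matrices and alphabet handling for the alignment engine.

.matrix_cache <- new.env(parent = emptyenv())

#' BLOSUM62 with impassable stop codons
#'
#' The standard BLOSUM62 matrix (as shipped with Biostrings) modified so that
#' any column pairing a stop (`*`) with anything, including another stop,
#' scores strongly negative. Translated-search alignments therefore never
#' cross a stop codon: a local alignment ends rather than pay the penalty.
#'
#' @return Integer matrix with dimnames over the BLOSUM62 alphabet.
#' @export
blosum62_stopless <- function() {
  if (!is.null(.matrix_cache$b62)) return(.matrix_cache$b62)
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()), envir = environment())
  b62 <- b62[rownames(b62) != "", colnames(b62) != "", drop = FALSE]
  stop_i <- which(rownames(b62) == "*")
  b62[stop_i, ] <- -1000L
  b62[, stop_i] <- -1000L
  storage.mode(b62) <- "integer"
  .matrix_cache$b62 <- b62
  b62
}

#' Simple match/mismatch nucleotide scoring matrix
#'
#' @param match score for identical bases (positive).
#' @param mismatch penalty for differing bases (positive; applied as
#'   `-mismatch`). `N` against anything scores as a mismatch.
#' @return 5x5 integer matrix over `A,C,G,T,N`.
#' @export
nucleotide_matrix <- function(match = 1, mismatch = 2) {
  alph <- c("A", "C", "G", "T", "N")
  m <- matrix(-as.integer(mismatch), 5, 5, dimnames = list(alph, alph))
  diag(m) <- as.integer(match)
  m["N", "N"] <- -as.integer(mismatch)
  m
}

# index used for residues outside the matrix alphabet
.fallback_index <- function(alphabet) {
  i <- match("X", alphabet)
  if (is.na(i)) i <- match("N", alphabet)
  if (is.na(i)) stop("substitution matrix alphabet has neither X nor N")
  i
}
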