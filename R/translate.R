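# Six-frame translation of nucleotide reads for the translated search.

#' Reverse complement of nucleotide strings
#' @param seq character vector over A,C,G,T,N (case-insensitive).
#' @return character vector of reverse complements (uppercase).
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# translate one reading-frame offset (1..3) for a whole read set
.translate_frame <- function(dna, offset, code) {
  w <- Biostrings::width(dna)
  len <- pmax(0L, 3L * ((w - offset + 1L) %/% 3L))
  start <- ifelse(len > 0, offset, 1L)
  sub <- Biostrings::subseq(dna, start = start, width = len)
  as.character(Biostrings::translate(sub, genetic.code = code,
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Translate reads in all six reading frames
#'
#' Frames +1..+3 read the sequence as given, frames -1..-3 read its reverse
#' complement. Trailing partial codons are dropped; any codon containing an
#' ambiguity (N) translates to `X`; stop codons appear as `*`.
#'
#' @param seq character vector of nucleotide sequences.
#' @param genetic_code NCBI genetic code id (default `"11"`,
#'   bacterial/archaeal).
#' @return for a single sequence, a named character vector of six peptides
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`); for several sequences, a 6-column
#'   character matrix with those column names.
#' @export
six_frame_translate <- function(seq, genetic_code = "11") {
  code <- Biostrings::getGeneticCode(genetic_code)
  dna <- Biostrings::DNAStringSet(toupper(seq))
  rc <- Biostrings::reverseComplement(dna)
  out <- cbind(`+1` = .translate_frame(dna, 1L, code),
               `+2` = .translate_frame(dna, 2L, code),
               `+3` = .translate_frame(dna, 3L, code),
               `-1` = .translate_frame(rc, 1L, code),
               `-2` = .translate_frame(rc, 2L, code),
               `-3` = .translate_frame(rc, 3L, code))
  if (length(seq) == 1) out[1, ] else out
}

FRAME_LEVELS <- c(1L, 2L, 3L, -1L, -2L, -3L)

# map a peptide-coordinate span in frame `frame` back to 1-based nucleotide
# coordinates on the forward read (qstart > qend on the minus strand)
frame_to_read_coords <- function(frame, aa_start, aa_end, read_len) {
  k <- abs(frame)
  nt_start <- k + 3L * (aa_start - 1L)
  nt_end <- k + 3L * aa_end - 1L
  if (frame > 0) c(nt_start, nt_end)
  else c(read_len - nt_start + 1L, read_len - nt_end + 1L)
}
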