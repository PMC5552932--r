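# Translated search: Smith-Waterman over six reading frames with
# Karlin-Altschul statistics -- the blastx-equivalent stage of the pipeline.

#' Local protein alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment under BLOSUM62 (stops impassable, see
#' [blosum62_stopless()]) with affine gap costs `gap_open + L * gap_extend`.
#' Traceback is deterministic: at equal score, diagonal beats a gap in the
#' subject, which beats a gap in the query; the reported alignment ends at
#' the maximal cell with the smallest query, then subject, coordinate.
#' Residues outside the matrix alphabet score as `X`.
#'
#' @param peptide,protein non-empty residue strings.
#' @param scoring a [scoring_scheme()].
#' @return list with `score` (raw), `identity` (matches / aligned columns),
#'   `q_start`, `q_end`, `s_start`, `s_end` (1-based inclusive),
#'   `aligned_cols`, `matches`, `mismatches`, `gap_opens`, `gap_cols`, and
#'   the aligned strings `q_aln`, `s_aln`.
#' @export
smith_waterman <- function(peptide, protein, scoring = scoring_scheme()) {
  if (!nzchar(peptide) || !nzchar(protein))
    stop("both sequences must be non-empty")
  mat <- blosum62_stopless()
  alph <- rownames(mat)
  r <- sw_traceback_cpp(toupper(peptide), toupper(protein), mat, alph,
                        .fallback_index(alph),
                        scoring$gap_open, scoring$gap_extend,
                        scoring$gap_open, scoring$gap_extend)
  r$identity <- if (r$aligned_cols > 0) r$matches / r$aligned_cols else NA_real_
  r
}

#' Karlin-Altschul bit score and E-value
#'
#' Converts a raw local-alignment score into a bit score,
#' `S' = (lambda * S - ln K) / ln 2`, and the expected number of chance hits
#' in a search space of `m * n`, `E = m * n * 2^(-S')`.
#'
#' @param raw_score non-negative raw score (vectorized).
#' @param scoring a [scoring_scheme()] or [nucleotide_scoring()] providing
#'   `lambda` and `K`.
#' @param m query length (residues or bases).
#' @param n total database length.
#' @return list with numeric vectors `bit_score` and `evalue`.
#' @export
karlin_altschul <- function(raw_score, scoring, m, n) {
  stopifnot(all(raw_score >= 0), all(m >= 1), all(n >= 1))
  bit <- (scoring$lambda * raw_score - log(scoring$K)) / log(2)
  list(bit_score = bit, evalue = m * n * 2^(-bit))
}

# minimal raw score that can reach E <= cutoff for query length m
.min_raw_score <- function(scoring, m, n, cutoff) {
  bits_min <- log2(m * n / cutoff)
  (bits_min * log(2) + log(scoring$K)) / scoring$lambda
}

#' Six-frame translated search of reads against a protein database
#'
#' Every read is translated in all six frames and each frame is aligned
#' against every database protein by full Smith-Waterman (no seeding
#' heuristic). Hits with E-value at most `evalue_cutoff` are returned,
#' sorted per read by descending bit score with ties broken by subject id.
#' The search space for a hit is `m * n` with `m` the translated frame
#' length and `n` the total residue count of the database.
#'
#' @param reads read tibble (`read_id`, `seq`).
#' @param protein_db reference tibble with `ref_id`, `seq` and optionally
#'   `gene_family` (copied onto hits when present).
#' @param scoring a [scoring_scheme()].
#' @param evalue_cutoff maximum E-value for a reported hit.
#' @param genetic_code NCBI genetic code id for translation.
#' @return hit tibble: `read_id`, `ref_id`, `gene_family` (if available),
#'   `frame`, `raw_score`, `bit_score`, `evalue`, `identity`,
#'   `aligned_cols`, `mismatches`, `gap_opens`, `q_start`, `q_end` (1-based
#'   nucleotide coordinates on the read; start > end on the minus strand),
#'   `s_start`, `s_end` (residue coordinates on the subject).
#' @export
search_reads <- function(reads, protein_db, scoring = scoring_scheme(),
                         evalue_cutoff = 1e-6, genetic_code = "11") {
  if (nrow(protein_db) == 0) stop("empty protein database")
  empty <- tibble(read_id = character(), ref_id = character(),
                  gene_family = character(), frame = integer(),
                  raw_score = integer(), bit_score = numeric(),
                  evalue = numeric(), identity = numeric(),
                  aligned_cols = integer(), mismatches = integer(),
                  gap_opens = integer(), q_start = integer(),
                  q_end = integer(), s_start = integer(), s_end = integer())
  if (nrow(reads) == 0) return(empty)

  mat <- blosum62_stopless()
  alph <- rownames(mat)
  fb <- .fallback_index(alph)
  n_db <- sum(nchar(protein_db$seq))

  pep <- six_frame_translate(reads$seq, genetic_code)
  if (is.null(dim(pep))) pep <- matrix(pep, nrow = 1,
                                       dimnames = list(NULL, names(pep)))
  # one row per (read, frame)
  qframe <- rep(FRAME_LEVELS, each = nrow(reads))
  qread <- rep(seq_len(nrow(reads)), times = 6)
  qpep <- as.vector(pep)
  keep <- nchar(qpep) > 0
  qframe <- qframe[keep]; qread <- qread[keep]; qpep <- qpep[keep]
  if (length(qpep) == 0) return(empty)

  scores <- sw_scores_cpp(qpep, protein_db$seq, mat, alph, fb,
                          scoring$gap_open, scoring$gap_extend,
                          scoring$gap_open, scoring$gap_extend)
  m_len <- nchar(qpep)
  smin <- .min_raw_score(scoring, m_len, n_db, evalue_cutoff)
  pass <- which(scores >= (smin - 1e-9), arr.ind = TRUE)
  if (nrow(pass) == 0) return(empty)

  rows <- vector("list", nrow(pass))
  for (k in seq_len(nrow(pass))) {
    qi <- pass[k, 1]; sj <- pass[k, 2]
    ka <- karlin_altschul(scores[qi, sj], scoring, m_len[qi], n_db)
    if (ka$evalue > evalue_cutoff) next
    tb <- sw_traceback_cpp(qpep[qi], protein_db$seq[sj], mat, alph, fb,
                           scoring$gap_open, scoring$gap_extend,
                           scoring$gap_open, scoring$gap_extend)
    ri <- qread[qi]
    qc <- frame_to_read_coords(qframe[qi], tb$q_start, tb$q_end,
                               nchar(reads$seq[ri]))
    rows[[k]] <- tibble(
      read_id = reads$read_id[ri], ref_id = protein_db$ref_id[sj],
      gene_family = if ("gene_family" %in% names(protein_db))
        protein_db$gene_family[sj] else NA_character_,
      frame = qframe[qi], raw_score = tb$score,
      bit_score = ka$bit_score, evalue = ka$evalue,
      identity = tb$matches / tb$aligned_cols,
      aligned_cols = tb$aligned_cols, mismatches = tb$mismatches,
      gap_opens = tb$gap_opens, q_start = qc[1], q_end = qc[2],
      s_start = tb$s_start, s_end = tb$s_end)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  order_hits(bind_rows(rows))
}
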