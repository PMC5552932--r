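# Length-based read QC: the trimming stage of the pipeline keeps only reads
# strictly longer than a threshold (default 100 nt).

#' Filter reads by length
#'
#' Keeps reads whose sequence is strictly longer than
#' `min_len_exclusive` nucleotides; input order is preserved and the filter
#' is idempotent.
#'
#' @param reads read tibble (`read_id`, `seq`, optionally `qual`).
#' @param min_len_exclusive reads must exceed this length to be kept.
#' @return the kept subset of `reads`.
#' @export
filter_by_length <- function(reads, min_len_exclusive = 100) {
  reads[nchar(reads$seq) > min_len_exclusive, , drop = FALSE]
}

#' Per-sample read statistics
#'
#' @param reads read tibble.
#' @param sample_id sample label.
#' @return one-row tibble with `sample_id`, `n_reads` and `mean_len`
#'   (arithmetic mean length, rounded half-even to 2 decimals; `NA` for an
#'   empty set).
#' @export
summarize_reads <- function(reads, sample_id = "sample") {
  n <- nrow(reads)
  tibble(sample_id = sample_id, n_reads = n,
         mean_len = if (n == 0) NA_real_ else round(mean(nchar(reads$seq)), 2))
}

#' QC a sample: length filter plus raw/kept statistics
#'
#' @inheritParams filter_by_length
#' @param sample_id sample label.
#' @return list with `reads` (kept reads) and `stats`, a one-row tibble
#'   (`sample_id`, `n_reads_raw`, `n_reads_kept`, `mean_len_kept`).
#' @export
qc_reads <- function(reads, sample_id = "sample", min_len_exclusive = 100) {
  kept <- filter_by_length(reads, min_len_exclusive)
  s <- summarize_reads(kept, sample_id)
  list(reads = kept,
       stats = tibble(sample_id = sample_id, n_reads_raw = nrow(reads),
                      n_reads_kept = nrow(kept),
                      mean_len_kept = s$mean_len))
}
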