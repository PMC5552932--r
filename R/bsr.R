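# Two-database bit-score-ratio curation: for every read with a hit in the
# curated functional-gene database, the ratio of its best curated bit score
# to its best comprehensive-database ("background") bit score separates
# true family members (ratio near 1, the background best hit is the family
# protein itself) from false positives whose closest relative lies outside
# the family (ratio well below 1).

#' Compute per-read bit-score ratios
#'
#' One record per read with at least one curated hit. Bit scores are the
#' per-database maxima; the gene family is taken from the top curated hit
#' (descending bit score, ties by subject id). Reads without any background
#' hit keep ratio 1 and are flagged, since the absence of a better
#' generalist hit is no evidence of a false positive. Reads with only a
#' background hit are excluded; their count is `attr(, "n_background_only")`.
#'
#' @param curated_hits hit tibble from [search_reads()] against the curated
#'   database (must carry `gene_family`).
#' @param background_hits hit tibble against the background database.
#' @return tibble `read_id`, `gene_family`, `bit_curated`,
#'   `bit_background`, `ratio`, `no_background_hit`.
#' @export
compute_bsr <- function(curated_hits, background_hits) {
  empty <- tibble(read_id = character(), gene_family = character(),
                  bit_curated = numeric(), bit_background = numeric(),
                  ratio = numeric(), no_background_hit = logical())
  n_bg_only <- length(setdiff(background_hits$read_id,
                              curated_hits$read_id))
  if (nrow(curated_hits) == 0) {
    attr(empty, "n_background_only") <- n_bg_only
    return(empty)
  }
  top_cur <- order_hits(curated_hits)
  top_cur <- top_cur[!duplicated(top_cur$read_id), , drop = FALSE]
  bg_best <- if (nrow(background_hits) > 0) {
    b <- order_hits(background_hits)
    b[!duplicated(b$read_id), c("read_id", "bit_score"), drop = FALSE]
  } else tibble(read_id = character(), bit_score = numeric())
  names(bg_best)[2] <- "bit_background"
  rec <- left_join(
    tibble(read_id = top_cur$read_id, gene_family = top_cur$gene_family,
           bit_curated = top_cur$bit_score),
    bg_best, by = "read_id")
  rec$no_background_hit <- is.na(rec$bit_background)
  rec$ratio <- ifelse(rec$no_background_hit, 1,
                      rec$bit_curated / rec$bit_background)
  rec <- rec[, c("read_id", "gene_family", "bit_curated", "bit_background",
                 "ratio", "no_background_hit")]
  attr(rec, "n_background_only") <- n_bg_only
  rec
}

#' Apply per-gene bit-score-ratio cutoffs
#'
#' A record is kept when its ratio reaches the cutoff of its gene family
#' (families absent from the configuration use the default cutoff). The
#' partition is exhaustive: every input record is either kept or rejected.
#'
#' @param records tibble from [compute_bsr()].
#' @param cfg a [curation_config()].
#' @return list with `kept`, `rejected` (sub-tibbles of `records` with an
#'   added `cutoff` column) and `summary` (per-gene kept/rejected counts).
#' @export
apply_cutoffs <- function(records, cfg = curation_config()) {
  cutoff <- unname(cfg$cutoffs[records$gene_family])
  cutoff[is.na(cutoff)] <- cfg$default_cutoff
  records$cutoff <- cutoff
  kept <- records[records$ratio >= cutoff, , drop = FALSE]
  rejected <- records[records$ratio < cutoff, , drop = FALSE]
  summary <- records %>%
    group_by(gene_family) %>%
    summarise(n_kept = sum(ratio >= cutoff),
              n_rejected = sum(ratio < cutoff), .groups = "drop") %>%
    arrange(gene_family)
  list(kept = kept, rejected = rejected, summary = summary)
}

#' Export bit-score-ratio plot data
#'
#' Writes the per-read scatter behind the curation decision: background bit
#' score against curated bit score, the ratio, the applicable cutoff and
#' the kept flag. True positives lie on the diagonal (ratio 1); false
#' positives fall below the cutoff line.
#'
#' @param records tibble from [compute_bsr()].
#' @param path output TSV path.
#' @param cfg a [curation_config()] supplying the cutoff column.
#' @return the plot-data tibble, invisibly.
#' @export
export_ratio_plot_data <- function(records, path,
                                   cfg = curation_config()) {
  cut <- apply_cutoffs(records, cfg)
  d <- bind_rows(mutate(cut$kept, kept = TRUE),
                 mutate(cut$rejected, kept = FALSE))
  d <- d[order(d$read_id),
         c("read_id", "gene_family", "bit_background", "bit_curated",
           "ratio", "cutoff", "kept")]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
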