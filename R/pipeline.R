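# End-to-end orchestration of one sample: QC, SSU profiling, translated
# search against the curated and background databases, bit-score-ratio
# curation, LCA classification and quantification.

#' Run the full marker-gene profiling pipeline on one sample
#'
#' Stages, in order:
#' \enumerate{
#'   \item length QC (strictly greater than
#'     `cfg$min_read_len_exclusive` nt);
#'   \item SSU recruitment: mapping under `cfg$mapping`, confirmation by
#'     nucleotide search at `cfg$evalue_cutoff`, lineage assignment;
#'   \item six-frame translated search of all QC-passed reads against the
#'     curated protein database (`cfg$scoring`, `cfg$evalue_cutoff`); reads
#'     with a hit form the extracted set;
#'   \item translated search of the extracted reads against the background
#'     database;
#'   \item bit-score-ratio curation under `cfg$curation`;
#'   \item LCA classification of curation-passed reads from their
#'     background hits under `cfg$lca`;
#'   \item per-gene nrc profiles (including the confirmed SSU fraction) and
#'     genus-level identity breakdowns.
#' }
#'
#' @param reads raw read tibble.
#' @param refs a `ncyc_refs` object, or any list with reference tibbles
#'   `curated`, `background`, `ssu`.
#' @param sample_id sample label.
#' @param cfg a [run_config()].
#' @return list with `stats`, `ssu_assignments`, `curated_hits`,
#'   `background_hits`, `bsr`, `kept`, `rejected`, `curation_summary`,
#'   `assignments`, `profiles`, `identity_breakdown`.
#' @export
run_pipeline <- function(reads, refs, sample_id = "sample",
                         cfg = run_config()) {
  qc <- qc_reads(reads, sample_id, cfg$min_read_len_exclusive)

  mapped <- map_reads(qc$reads, refs$ssu, cfg$mapping)
  ssu_assign <- confirm_by_search(qc$reads, mapped, refs$ssu,
                                  cfg$evalue_cutoff, cfg$ssu_scoring)

  curated_hits <- search_reads(qc$reads, refs$curated, cfg$scoring,
                               cfg$evalue_cutoff)
  extracted <- qc$reads[qc$reads$read_id %in% unique(curated_hits$read_id),
                        , drop = FALSE]
  background_hits <- search_reads(extracted, refs$background, cfg$scoring,
                                  cfg$evalue_cutoff)

  bsr <- compute_bsr(curated_hits, background_hits)
  cur <- apply_cutoffs(bsr, cfg$curation)

  bg_lin <- setNames(refs$background$lineage, refs$background$ref_id)
  kept_bg_hits <- background_hits[background_hits$read_id %in%
                                    cur$kept$read_id, , drop = FALSE]
  assignments <- classify_reads(kept_bg_hits, bg_lin, cfg$lca)

  kept <- mutate(cur$kept, sample_id = sample_id)
  ssu_counts <- if (nrow(ssu_assign) > 0) {
    tibble(sample_id = sample_id, read_count = nrow(ssu_assign),
           avg_len_nt = mean(refs$ssu$length_nt))
  } else NULL
  profiles <- profile_table(kept, qc$stats, refs$curated, ssu_counts)

  top_kept <- order_hits(curated_hits)
  top_kept <- top_kept[!duplicated(top_kept$read_id) &
                         top_kept$read_id %in% cur$kept$read_id, ,
                       drop = FALSE]
  breakdown <- identity_breakdown(top_kept, refs$curated)

  list(stats = qc$stats, ssu_assignments = ssu_assign,
       curated_hits = curated_hits, background_hits = background_hits,
       bsr = bsr, kept = kept, rejected = cur$rejected,
       curation_summary = cur$summary, assignments = assignments,
       profiles = profiles, identity_breakdown = breakdown)
}
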