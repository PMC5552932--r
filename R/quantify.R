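# Per-gene, per-sample quantification: normalized read counts (nrc),
# proportional gene distributions, marker-gene-to-16S ratios and per-taxon
# identity breakdowns.

#' Normalized read count (nrc)
#'
#' The cross-sample abundance unit:
#' `nrc = read_count * 1e9 / (total_reads * avg_gene_length_nt)`,
#' i.e. an RPKM-like quantity using the average nucleotide length of the
#' gene family's curated references. Linear in `read_count` and invariant
#' to scaling reads and library size together.
#'
#' @param read_count curated, post-curation read count (vectorized).
#' @param total_reads post-QC metagenome read count.
#' @param avg_gene_length_nt average gene length in nucleotides.
#' @return numeric nrc value(s).
#' @export
nrc <- function(read_count, total_reads, avg_gene_length_nt) {
  if (any(total_reads < 1) || any(avg_gene_length_nt <= 0))
    stop("total_reads must be >= 1 and avg_gene_length_nt > 0")
  if (any(read_count < 0)) stop("read_count must be non-negative")
  read_count * 1e9 / (total_reads * avg_gene_length_nt)
}

#' Average nucleotide gene length per curated family
#'
#' @param curated_db curated reference tibble.
#' @return named numeric vector of mean `length_nt` per gene family.
#' @export
family_lengths_nt <- function(curated_db) {
  x <- tapply(curated_db$length_nt, curated_db$gene_family, mean)
  setNames(as.numeric(x), names(x))
}

#' Per-sample, per-gene profile table with nrc and proportions
#'
#' One row per (sample, gene family) for every family present in the
#' curated database, plus an `SSU_rRNA` row per sample when SSU counts are
#' supplied. The proportional column divides each row's nrc by the sample's
#' total displayed nrc (all analyzed genes plus 16S), the layout of a
#' proportional gene-distribution panel.
#'
#' @param kept curated, curation-passed records (tibble with `sample_id`,
#'   `read_id`, `gene_family`).
#' @param sample_stats tibble with `sample_id` and `n_reads_kept` (post-QC
#'   library sizes; see [qc_reads()]).
#' @param curated_db curated reference tibble (gene lengths).
#' @param ssu_counts optional tibble with `sample_id`, `read_count` and
#'   `avg_len_nt` for the confirmed SSU fraction.
#' @return tibble `sample_id`, `gene_family`, `read_count`,
#'   `avg_gene_length_nt`, `total_reads`, `nrc`, `proportion`, ordered by
#'   sample then canonical family order.
#' @export
profile_table <- function(kept, sample_stats, curated_db,
                          ssu_counts = NULL) {
  fams <- intersect(GENE_FAMILY_LEVELS, unique(curated_db$gene_family))
  if (length(fams) == 0) stop("curated database has no gene families")
  flen <- family_lengths_nt(curated_db)
  rows <- list()
  for (s in sample_stats$sample_id) {
    total <- sample_stats$n_reads_kept[sample_stats$sample_id == s]
    ks <- kept[kept$sample_id == s, , drop = FALSE]
    unknown <- setdiff(unique(ks$gene_family), fams)
    if (length(unknown) > 0)
      stop("gene families without curated references: ",
           paste(unknown, collapse = ", "))
    counts <- table(factor(ks$gene_family, levels = fams))
    d <- tibble(sample_id = s, gene_family = fams,
                read_count = as.integer(counts),
                avg_gene_length_nt = unname(flen[fams]),
                total_reads = total)
    if (!is.null(ssu_counts)) {
      sc <- ssu_counts[ssu_counts$sample_id == s, , drop = FALSE]
      if (nrow(sc) == 1) {
        d <- bind_rows(d, tibble(sample_id = s, gene_family = "SSU_rRNA",
                                 read_count = as.integer(sc$read_count),
                                 avg_gene_length_nt = sc$avg_len_nt,
                                 total_reads = total))
      }
    }
    d$nrc <- nrc(d$read_count, d$total_reads, d$avg_gene_length_nt)
    tot_nrc <- sum(d$nrc)
    d$proportion <- if (tot_nrc > 0) d$nrc / tot_nrc else 0
    rows[[s]] <- d
  }
  bind_rows(rows)
}

#' nrc of the (optionally taxon-restricted) SSU fraction
#'
#' @param assignments confirmed SSU assignments ([confirm_by_search()]).
#' @param ssu_db SSU reference tibble.
#' @param total_reads post-QC library size.
#' @param taxon optional taxon name; only assignments whose lineage
#'   contains it are counted, and the average length is computed over the
#'   matching references.
#' @return list with `nrc`, `read_count` and `avg_len_nt`.
#' @export
ssu_nrc <- function(assignments, ssu_db, total_reads, taxon = NULL) {
  sel <- rep(TRUE, nrow(assignments))
  refs_sel <- rep(TRUE, nrow(ssu_db))
  if (!is.null(taxon)) {
    sel <- vapply(lineage_split(assignments$lineage),
                  function(p) taxon %in% p, logical(1))
    refs_sel <- vapply(lineage_split(ssu_db$lineage),
                       function(p) taxon %in% p, logical(1))
    if (!any(refs_sel)) stop("no SSU references for taxon ", taxon)
  }
  count <- sum(sel)
  avg_len <- mean(ssu_db$length_nt[refs_sel])
  list(nrc = nrc(count, total_reads, avg_len), read_count = count,
       avg_len_nt = avg_len)
}

#' Marker-gene to 16S nrc ratio
#'
#' Approximates per-genome gene dosage when both nrc values come from the
#' same sample and the 16S denominator is restricted to the gene's host
#' group (e.g. amoA against Marine-Group-I 16S).
#'
#' @param nrc_gene marker-gene nrc.
#' @param nrc_16s taxon-restricted 16S nrc.
#' @return the ratio, or `NA` (flagged missing) when the denominator is 0.
#' @export
marker_ratio <- function(nrc_gene, nrc_16s) {
  ifelse(nrc_16s > 0, nrc_gene / nrc_16s, NA_real_)
}

#' Per-taxon identity breakdown of a gene family's reads
#'
#' Groups curation-passed reads by the taxon of their top curated hit at
#' the requested rank and reports integer percentage shares (largest
#' remainder, summing to 100 per family) with the min/max percent identity
#' per group.
#'
#' @param kept_hits top curated hits of curation-passed reads (tibble with
#'   `gene_family`, `ref_id`, `identity`).
#' @param curated_db curated reference tibble (lineages).
#' @param rank taxonomic rank for grouping (default `"genus"`).
#' @return tibble `gene_family`, `taxon`, `n_reads`, `share_pct`,
#'   `id_min_pct`, `id_max_pct`.
#' @export
identity_breakdown <- function(kept_hits, curated_db, rank = "genus") {
  if (!rank %in% RANK_NAMES) stop("unknown rank: ", rank)
  empty <- tibble(gene_family = character(), taxon = character(),
                  n_reads = integer(), share_pct = integer(),
                  id_min_pct = integer(), id_max_pct = integer())
  if (nrow(kept_hits) == 0) return(empty)
  level <- match(rank, RANK_NAMES)
  lin <- setNames(curated_db$lineage, curated_db$ref_id)
  taxon <- vapply(lineage_split(unname(lin[kept_hits$ref_id])),
                  function(p) if (length(p) >= level) p[level]
                  else "unclassified", character(1))
  d <- tibble(gene_family = kept_hits$gene_family, taxon = taxon,
              identity = kept_hits$identity)
  out <- list()
  for (fam in unique(d$gene_family)) {
    di <- d[d$gene_family == fam, , drop = FALSE]
    g <- di %>%
      group_by(taxon) %>%
      summarise(n_reads = n(), id_min_pct = as.integer(round(100 *
                  min(identity))),
                id_max_pct = as.integer(round(100 * max(identity))),
                .groups = "drop") %>%
      arrange(desc(n_reads), taxon)
    g$share_pct <- largest_remainder(g$n_reads, 100L)
    g$gene_family <- fam
    out[[fam]] <- g[, c("gene_family", "taxon", "n_reads", "share_pct",
                        "id_min_pct", "id_max_pct")]
  }
  bind_rows(out)
}
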