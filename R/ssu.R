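# SSU rRNA fragment recruitment: map reads to the SSU reference set with
# per-operation costs and acceptance fractions, confirm mappings with a
# nucleotide similarity search under Karlin-Altschul statistics, assign
# lineages from the confirmed best hit, and summarize community
# composition.

RANK_NAMES <- c("domain", "phylum", "class", "order", "genus")

# reads sharing no exact k-mer with any reference (either strand) cannot be
# recruited at 80% identity over half the read; skip their DP
.kmer_prescreen <- function(seqs, ref_seqs, k) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }
  ref_k <- unique(unlist(lapply(c(ref_seqs, reverse_complement(ref_seqs)),
                                kmers_of)))
  read_k <- lapply(seqs, kmers_of)
  hit <- unlist(read_k) %in% ref_k
  idx <- rep(seq_along(seqs), lengths(read_k))
  out <- logical(length(seqs))
  out[unique(idx[hit])] <- TRUE
  out
}

#' Map reads to the SSU reference set
#'
#' Local alignment of each read (both strands) against every reference,
#' scored match +1, mismatch `-mismatch_cost`, each read base inserted
#' relative to the reference `-insertion_cost`, each deleted base
#' `-deletion_cost` (linear, per-base gap costs). A candidate is accepted
#' only if the aligned read fraction reaches `length_fraction` and the
#' identity over aligned columns reaches `similarity_fraction`; the
#' best-scoring acceptable reference wins, ties broken by reference id.
#' An exact k-mer prescreen (`prescreen_k`, 0 disables) skips reads that
#' share no word with the reference set and cannot pass the acceptance
#' fractions.
#'
#' @param reads read tibble.
#' @param ssu_db SSU reference tibble.
#' @param cfg a [mapping_config()].
#' @param prescreen_k word length of the exact-match prescreen.
#' @return tibble of accepted mappings: `read_id`, `ref_id`, `strand`,
#'   `raw_score`, `identity`, `read_fraction`, `aligned_cols`, `q_start`,
#'   `q_end`, `s_start`, `s_end`.
#' @export
map_reads <- function(reads, ssu_db, cfg = mapping_config(),
                      prescreen_k = 16) {
  if (nrow(ssu_db) == 0) stop("empty SSU database")
  empty <- tibble(read_id = character(), ref_id = character(),
                  strand = character(), raw_score = integer(),
                  identity = numeric(), read_fraction = numeric(),
                  aligned_cols = integer(), q_start = integer(),
                  q_end = integer(), s_start = integer(), s_end = integer())
  if (nrow(reads) == 0) return(empty)
  mat <- nucleotide_matrix(1, cfg$mismatch_cost)
  alph <- rownames(mat)
  fb <- .fallback_index(alph)

  cand <- if (prescreen_k > 0) {
    which(.kmer_prescreen(reads$seq, ssu_db$seq, prescreen_k))
  } else seq_len(nrow(reads))
  if (length(cand) == 0) return(empty)

  fwd <- reads$seq[cand]
  rev <- reverse_complement(fwd)
  # linear gap costs: open 0, per-base extension cost
  sc_f <- sw_scores_cpp(fwd, ssu_db$seq, mat, alph, fb,
                        0L, cfg$insertion_cost, 0L, cfg$deletion_cost)
  sc_r <- sw_scores_cpp(rev, ssu_db$seq, mat, alph, fb,
                        0L, cfg$insertion_cost, 0L, cfg$deletion_cost)

  out <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    ri <- cand[i]
    rlen <- nchar(reads$seq[ri])
    cand_tab <- tibble(ref = rep(seq_len(nrow(ssu_db)), 2),
                       strand = rep(c("+", "-"), each = nrow(ssu_db)),
                       score = c(sc_f[i, ], sc_r[i, ]))
    # lower bound on the optimal score of any acceptable alignment: at least
    # len_frac*rlen columns, of which >= sim are +1 matches and the rest
    # cost at most the largest per-column penalty
    maxcost <- max(cfg$mismatch_cost, cfg$insertion_cost, cfg$deletion_cost)
    floor_score <- cfg$length_fraction * rlen *
      (cfg$similarity_fraction - maxcost * (1 - cfg$similarity_fraction))
    cand_tab <- cand_tab[cand_tab$score >= max(1, floor_score), , drop = FALSE]
    cand_tab <- cand_tab[order(-cand_tab$score, ssu_db$ref_id[cand_tab$ref],
                               cand_tab$strand), , drop = FALSE]
    for (j in seq_len(nrow(cand_tab))) {
      qseq <- if (cand_tab$strand[j] == "+") fwd[i] else rev[i]
      tb <- sw_traceback_cpp(qseq, ssu_db$seq[cand_tab$ref[j]], mat, alph,
                             fb, 0L, cfg$insertion_cost, 0L,
                             cfg$deletion_cost)
      if (tb$aligned_cols == 0) next
      read_frac <- (tb$q_end - tb$q_start + 1) / rlen
      ident <- tb$matches / tb$aligned_cols
      if (read_frac >= cfg$length_fraction &&
          ident >= cfg$similarity_fraction) {
        out[[i]] <- tibble(read_id = reads$read_id[ri],
                           ref_id = ssu_db$ref_id[cand_tab$ref[j]],
                           strand = cand_tab$strand[j],
                           raw_score = tb$score, identity = ident,
                           read_fraction = read_frac,
                           aligned_cols = tb$aligned_cols,
                           q_start = tb$q_start, q_end = tb$q_end,
                           s_start = tb$s_start, s_end = tb$s_end)
        break
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' @rdname map_reads
#' @param read a one-row read tibble (or list with `read_id` and `seq`).
#' @return `map_read` returns a one-row tibble or `NULL` when the read does
#'   not map.
#' @export
map_read <- function(read, ssu_db, cfg = mapping_config(),
                     prescreen_k = 0) {
  r <- map_reads(tibble(read_id = read$read_id, seq = read$seq), ssu_db,
                 cfg, prescreen_k)
  if (nrow(r) == 0) NULL else r
}

#' Confirm mapped SSU reads by nucleotide similarity search
#'
#' Re-searches previously mapped reads against the SSU reference set with a
#' scored nucleotide local alignment ([nucleotide_scoring()] defaults:
#' match +2, mismatch -3, gap open 5, gap extend 2) and Karlin-Altschul
#' statistics (search space: read length times total database length). The
#' best hit per read with E-value at most `evalue_cutoff` is retained and
#' its lineage assigned; the confirmed hit takes precedence over the
#' mapping hit. Reads failing the cutoff are dropped; their count is
#' available as `attr(, "n_dropped")`.
#'
#' @param reads read tibble (provides sequences).
#' @param mapped mapping tibble from [map_reads()].
#' @param ssu_db SSU reference tibble (with `lineage`).
#' @param evalue_cutoff maximum E-value.
#' @param scoring a [nucleotide_scoring()].
#' @return tibble of SSU assignments: `read_id`, `ref_id`, `lineage`,
#'   `strand`, `raw_score`, `bit_score`, `evalue`, `identity`,
#'   `aligned_cols`, `mismatches`, `gap_opens`, `q_start`, `q_end`,
#'   `s_start`, `s_end`.
#' @export
confirm_by_search <- function(reads, mapped, ssu_db, evalue_cutoff = 1e-6,
                              scoring = nucleotide_scoring()) {
  empty <- tibble(read_id = character(), ref_id = character(),
                  lineage = character(), strand = character(),
                  raw_score = integer(), bit_score = numeric(),
                  evalue = numeric(), identity = numeric(),
                  aligned_cols = integer(), mismatches = integer(),
                  gap_opens = integer(), q_start = integer(),
                  q_end = integer(), s_start = integer(), s_end = integer())
  if (nrow(mapped) == 0) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  idx <- match(unique(mapped$read_id), reads$read_id)
  if (anyNA(idx)) stop("mapped read ids missing from read set")
  mat <- nucleotide_matrix(scoring$match, scoring$mismatch)
  alph <- rownames(mat)
  fb <- .fallback_index(alph)
  n_db <- sum(nchar(ssu_db$seq))
  fwd <- reads$seq[idx]
  rev <- reverse_complement(fwd)
  sc_f <- sw_scores_cpp(fwd, ssu_db$seq, mat, alph, fb,
                        scoring$gap_open, scoring$gap_extend,
                        scoring$gap_open, scoring$gap_extend)
  sc_r <- sw_scores_cpp(rev, ssu_db$seq, mat, alph, fb,
                        scoring$gap_open, scoring$gap_extend,
                        scoring$gap_open, scoring$gap_extend)
  out <- vector("list", length(idx))
  n_dropped <- 0L
  for (i in seq_along(idx)) {
    scores <- c(sc_f[i, ], sc_r[i, ])
    strands <- rep(c("+", "-"), each = nrow(ssu_db))
    refs_i <- rep(seq_len(nrow(ssu_db)), 2)
    ord <- order(-scores, ssu_db$ref_id[refs_i], strands)
    bi <- ord[1]
    m <- nchar(fwd[i])
    ka <- karlin_altschul(scores[bi], scoring, m, n_db)
    if (ka$evalue > evalue_cutoff) {
      n_dropped <- n_dropped + 1L
      next
    }
    qseq <- if (strands[bi] == "+") fwd[i] else rev[i]
    tb <- sw_traceback_cpp(qseq, ssu_db$seq[refs_i[bi]], mat, alph, fb,
                           scoring$gap_open, scoring$gap_extend,
                           scoring$gap_open, scoring$gap_extend)
    out[[i]] <- tibble(read_id = reads$read_id[idx[i]],
                       ref_id = ssu_db$ref_id[refs_i[bi]],
                       lineage = ssu_db$lineage[refs_i[bi]],
                       strand = strands[bi], raw_score = tb$score,
                       bit_score = ka$bit_score, evalue = ka$evalue,
                       identity = tb$matches / max(1, tb$aligned_cols),
                       aligned_cols = tb$aligned_cols,
                       mismatches = tb$mismatches,
                       gap_opens = tb$gap_opens, q_start = tb$q_start,
                       q_end = tb$q_end, s_start = tb$s_start,
                       s_end = tb$s_end)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out) == 0) empty else bind_rows(out)
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Summarize community composition at a taxonomic rank
#'
#' Proportions of assigned reads per taxon at the requested rank,
#' optionally restricted to (and renormalized within) a scope taxon.
#' Groups below `reporting_floor` are folded into `"other"`. Within the
#' chosen scope, proportions sum to 1.
#'
#' @param assignments tibble with a `lineage` column (semicolon paths), one
#'   row per read.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"genus"`.
#' @param reporting_floor minimum proportion reported as its own group.
#' @param scope optional taxon name; only reads whose lineage contains it
#'   are counted and proportions are normalized within that subset.
#' @return tibble `taxon`, `n_reads`, `proportion`, ordered by decreasing
#'   proportion with `"other"` last.
#' @export
summarize_composition <- function(assignments, rank = "domain",
                                  reporting_floor = 0, scope = NULL) {
  if (!rank %in% RANK_NAMES)
    stop("unknown rank: ", rank, " (use ",
         paste(RANK_NAMES, collapse = ", "), ")")
  if (nrow(assignments) == 0) stop("no assignments to summarize")
  paths <- lineage_split(assignments$lineage)
  if (!is.null(scope)) {
    keep <- vapply(paths, function(p) scope %in% p, logical(1))
    paths <- paths[keep]
    if (length(paths) == 0) stop("no assignments within scope ", scope)
  }
  level <- match(rank, RANK_NAMES)
  taxon <- vapply(paths, function(p)
    if (length(p) >= level) p[level] else "unclassified", character(1))
  counts <- sort(table(taxon), decreasing = TRUE)
  prop <- as.numeric(counts) / sum(counts)
  low <- prop < reporting_floor
  res <- tibble(taxon = names(counts)[!low],
                n_reads = as.integer(counts[!low]),
                proportion = prop[!low])
  if (any(low)) {
    res <- bind_rows(res, tibble(taxon = "other",
                                 n_reads = sum(as.integer(counts[low])),
                                 proportion = sum(prop[low])))
  }
  res
}
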