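# Run configuration: typed constructors with validation plus a flat
# key=value serialization so that a whole run is reproducible from one file.

#' Alignment scoring scheme for translated protein searches
#'
#' Holds the substitution matrix name, affine gap penalties (a gap of length
#' L costs `gap_open + L * gap_extend`) and the Karlin-Altschul parameters
#' lambda and K used to convert raw Smith-Waterman scores into bit scores
#' and E-values. Defaults are the standard gapped BLOSUM62 constants.
#'
#' @param matrix substitution matrix name (only `"BLOSUM62"` is shipped).
#' @param gap_open,gap_extend positive integer gap penalties.
#' @param lambda,K Karlin-Altschul statistical parameters.
#' @return a `ncyc_scoring` list.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0, gap_open > 0, gap_extend > 0)
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "ncyc_scoring")
}

#' Nucleotide scoring scheme for the SSU confirmation search
#'
#' Megablast-style rewards/penalties with their ungapped Karlin-Altschul
#' constants.
#'
#' @param match,mismatch positive match reward and mismatch penalty.
#' @param gap_open,gap_extend affine gap penalties.
#' @param lambda,K Karlin-Altschul parameters for this reward scheme.
#' @return a `ncyc_scoring_nuc` list.
#' @export
nucleotide_scoring <- function(match = 2, mismatch = 3, gap_open = 5,
                               gap_extend = 2, lambda = 0.625, K = 0.41) {
  stopifnot(match > 0, mismatch > 0, lambda > 0, K > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "ncyc_scoring_nuc")
}

#' SSU read-mapping parameters
#'
#' Per-operation costs and acceptance fractions of the fragment-recruitment
#' stage: match +1, mismatch `-mismatch_cost`, each inserted read base
#' `-insertion_cost`, each deleted read base `-deletion_cost` (linear gap
#' costs). A mapping is accepted only if at least `length_fraction` of the
#' read is aligned and at least `similarity_fraction` of aligned columns are
#' identities.
#'
#' @param mismatch_cost,insertion_cost,deletion_cost positive integer costs.
#' @param length_fraction,similarity_fraction acceptance fractions in (0,1].
#' @return a `ncyc_mapping` list.
#' @export
mapping_config <- function(mismatch_cost = 2, insertion_cost = 3,
                           deletion_cost = 3, length_fraction = 0.5,
                           similarity_fraction = 0.8) {
  stopifnot(mismatch_cost > 0, insertion_cost > 0, deletion_cost > 0,
            length_fraction > 0, length_fraction <= 1,
            similarity_fraction > 0, similarity_fraction <= 1)
  structure(list(mismatch_cost = as.integer(mismatch_cost),
                 insertion_cost = as.integer(insertion_cost),
                 deletion_cost = as.integer(deletion_cost),
                 length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction),
            class = "ncyc_mapping")
}

#' LCA classifier parameters
#'
#' The MEGAN-style filter and binning parameters: hits below `min_score`
#' bits or above `max_expected` are discarded; of the rest, only hits within
#' `top_percent` percent of the best bit score per read are used; the read
#' is assigned to the deepest taxonomy node covering at least `lca_percent`
#' percent of the used hits. `min_support` moves reads on weakly supported
#' taxa to the parent; `max_support_percent = 0` and `min_complexity = 0`
#' disable the respective filters.
#'
#' @param min_score minimum hit bit score.
#' @param max_expected maximum hit E-value.
#' @param top_percent retain hits within this percent of the best bit score.
#' @param max_support_percent disabled at 0.
#' @param min_support minimum reads per reported taxon.
#' @param lca_percent coverage percentage defining the assignment node.
#' @param min_complexity accepted for completeness; non-zero values warn and
#'   are ignored.
#' @return a `ncyc_lca` list.
#' @export
lca_config <- function(min_score = 50, max_expected = 0.01, top_percent = 1,
                       max_support_percent = 0, min_support = 1,
                       lca_percent = 50, min_complexity = 0) {
  stopifnot(top_percent >= 0, top_percent <= 100,
            lca_percent > 0, lca_percent <= 100, min_support >= 1)
  if (min_complexity != 0)
    warning("min_complexity is accepted but not implemented; ignoring")
  structure(list(min_score = min_score, max_expected = max_expected,
                 top_percent = top_percent,
                 max_support_percent = max_support_percent,
                 min_support = as.integer(min_support),
                 lca_percent = lca_percent, min_complexity = min_complexity),
            class = "ncyc_lca")
}

#' Bit-score-ratio curation parameters
#'
#' @param cutoffs named numeric vector of per-gene-family ratio cutoffs in
#'   (0, 1].
#' @param default_cutoff cutoff used for families absent from `cutoffs`.
#' @return a `ncyc_curation` list.
#' @export
curation_config <- function(cutoffs = numeric(0), default_cutoff = 0.8) {
  stopifnot(all(cutoffs > 0), all(cutoffs <= 1),
            default_cutoff > 0, default_cutoff <= 1)
  structure(list(cutoffs = cutoffs, default_cutoff = default_cutoff),
            class = "ncyc_curation")
}

#' Full pipeline configuration
#'
#' @param min_read_len_exclusive reads must be strictly longer than this to
#'   pass QC (default 100 nt).
#' @param evalue_cutoff E-value cutoff for both the translated and the SSU
#'   confirmation searches.
#' @param mapping [mapping_config()].
#' @param lca [lca_config()].
#' @param curation [curation_config()].
#' @param scoring [scoring_scheme()].
#' @param ssu_scoring [nucleotide_scoring()].
#' @param seed integer seed for any stochastic step.
#' @return a `ncyc_config` list.
#' @export
run_config <- function(min_read_len_exclusive = 100, evalue_cutoff = 1e-6,
                       mapping = mapping_config(), lca = lca_config(),
                       curation = curation_config(),
                       scoring = scoring_scheme(),
                       ssu_scoring = nucleotide_scoring(), seed = 1L) {
  stopifnot(min_read_len_exclusive >= 0, evalue_cutoff > 0,
            is.finite(evalue_cutoff))
  structure(list(min_read_len_exclusive = as.integer(min_read_len_exclusive),
                 evalue_cutoff = evalue_cutoff, mapping = mapping,
                 lca = lca, curation = curation, scoring = scoring,
                 ssu_scoring = ssu_scoring, seed = as.integer(seed)),
            class = "ncyc_config")
}

# flatten a config into key=value lines (dotted keys for nested sections)
.flatten_cfg <- function(x, prefix = "") {
  out <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v)) {
      out <- c(out, .flatten_cfg(v, key))
    } else if (length(v) > 1 || !is.null(names(v))) {
      if (length(v) == 0) next
      out <- c(out, paste0(key, ".", names(v), "=",
                           vapply(v, format, character(1), digits = 17)))
    } else {
      out <- c(out, paste0(key, "=", format(v, digits = 17)))
    }
  }
  out
}

#' Write / read a run configuration as a flat key=value file
#'
#' The serialization is lossless: `read_config(write_config(cfg, p))`
#' reproduces `cfg`.
#'
#' @param cfg a `ncyc_config` object.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  writeLines(.flatten_cfg(unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  get_num <- function(key, default) {
    i <- match(key, keys)
    if (is.na(i)) default else as.numeric(vals[i])
  }
  cut_keys <- grep("^curation\\.cutoffs\\.", keys, value = TRUE)
  cutoffs <- setNames(as.numeric(vals[match(cut_keys, keys)]),
                      sub("^curation\\.cutoffs\\.", "", cut_keys))
  mat_i <- match("scoring.matrix", keys)
  run_config(
    min_read_len_exclusive = get_num("min_read_len_exclusive", 100),
    evalue_cutoff = get_num("evalue_cutoff", 1e-6),
    mapping = mapping_config(
      mismatch_cost = get_num("mapping.mismatch_cost", 2),
      insertion_cost = get_num("mapping.insertion_cost", 3),
      deletion_cost = get_num("mapping.deletion_cost", 3),
      length_fraction = get_num("mapping.length_fraction", 0.5),
      similarity_fraction = get_num("mapping.similarity_fraction", 0.8)),
    lca = lca_config(
      min_score = get_num("lca.min_score", 50),
      max_expected = get_num("lca.max_expected", 0.01),
      top_percent = get_num("lca.top_percent", 1),
      max_support_percent = get_num("lca.max_support_percent", 0),
      min_support = get_num("lca.min_support", 1),
      lca_percent = get_num("lca.lca_percent", 50),
      min_complexity = get_num("lca.min_complexity", 0)),
    curation = curation_config(
      cutoffs = cutoffs,
      default_cutoff = get_num("curation.default_cutoff", 0.8)),
    scoring = scoring_scheme(
      matrix = if (is.na(mat_i)) "BLOSUM62" else vals[mat_i],
      gap_open = get_num("scoring.gap_open", 11),
      gap_extend = get_num("scoring.gap_extend", 1),
      lambda = get_num("scoring.lambda", 0.267),
      K = get_num("scoring.K", 0.041)),
    ssu_scoring = nucleotide_scoring(
      match = get_num("ssu_scoring.match", 2),
      mismatch = get_num("ssu_scoring.mismatch", 3),
      gap_open = get_num("ssu_scoring.gap_open", 5),
      gap_extend = get_num("ssu_scoring.gap_extend", 2),
      lambda = get_num("ssu_scoring.lambda", 0.625),
      K = get_num("ssu_scoring.K", 0.41)),
    seed = get_num("seed", 1))
}
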