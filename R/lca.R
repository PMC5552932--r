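# MEGAN-style taxonomic assignment: per-read hit filtering (min score, max
# expected, top percent) followed by a weighted-coverage lowest-common-
# ancestor over the retained hits' lineages, and a min-support pass.

#' Filter hits per read before LCA assignment
#'
#' Drops hits below `min_score` bits or above `max_expected` E-value, then
#' keeps, per read, only hits whose bit score is at least
#' `(1 - top_percent/100)` of that read's best remaining bit score.
#' `min_complexity = 0` disables the complexity filter (a no-op here).
#'
#' @param hits hit tibble with `read_id`, `bit_score`, `evalue`.
#' @param cfg a [lca_config()].
#' @return the retained subset of `hits`.
#' @export
filter_hits <- function(hits, cfg = lca_config()) {
  h <- hits[hits$bit_score >= cfg$min_score &
              hits$evalue <= cfg$max_expected, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  h %>%
    group_by(read_id) %>%
    filter(bit_score >= (1 - cfg$top_percent / 100) * max(bit_score)) %>%
    ungroup()
}

#' Weighted-coverage lowest common ancestor of a set of lineages
#'
#' Starting at the root, descends while exactly one child's subtree covers
#' at least `lca_percent` percent of the hits (each hit weighted equally).
#' With `lca_percent = 100` this is the strict path-intersection LCA. When
#' several children qualify (possible for thresholds of 50 or below) the
#' descent stops: the shallower node wins.
#'
#' @param lineages character vector of semicolon-joined lineages, one per
#'   retained hit.
#' @param lca_percent coverage threshold in (0, 100].
#' @return list with `lineage` (semicolon-joined path of the assigned node;
#'   `""` for the root), `taxon` (its last name or `"root"`) and `depth`.
#' @export
assign_lca <- function(lineages, lca_percent = 50) {
  stopifnot(length(lineages) > 0, lca_percent > 0, lca_percent <= 100)
  paths <- lineage_split(lineages)
  n <- length(paths)
  need <- lca_percent / 100 * n
  prefix <- character(0)
  depth <- 0L
  active <- rep(TRUE, n)
  repeat {
    nxt <- vapply(paths, function(p)
      if (length(p) > depth) p[depth + 1L] else NA_character_, character(1))
    nxt[!active] <- NA_character_
    tab <- table(nxt, useNA = "no")
    qual <- names(tab)[as.numeric(tab) >= need - 1e-9]
    if (length(qual) != 1) break
    prefix <- c(prefix, qual)
    depth <- depth + 1L
    active <- active & !is.na(nxt) & nxt == qual
  }
  list(lineage = paste(prefix, collapse = ";"),
       taxon = if (depth == 0) "root" else prefix[depth],
       depth = depth)
}

#' Classify reads by filtered hits and weighted LCA
#'
#' Applies [filter_hits()] and [assign_lca()] per read over the lineages of
#' the retained hits (taken from `lineages` keyed by subject id), then the
#' min-support pass of [apply_support()].
#'
#' @param hits background-database hit tibble for the reads to classify.
#' @param lineages named character vector mapping subject `ref_id` to a
#'   semicolon-joined lineage (e.g. [read_lineage_table()] output, or built
#'   from a reference tibble).
#' @param cfg a [lca_config()].
#' @return tibble `read_id`, `lineage`, `taxon`, `depth`, `n_hits_used`;
#'   reads whose hits are all filtered out are absent.
#' @export
classify_reads <- function(hits, lineages, cfg = lca_config()) {
  empty <- tibble(read_id = character(), lineage = character(),
                  taxon = character(), depth = integer(),
                  n_hits_used = integer())
  if (nrow(hits) == 0) return(empty)
  missing <- setdiff(unique(hits$ref_id), names(lineages))
  if (length(missing) > 0)
    stop("no lineage for subject(s): ", paste(missing, collapse = ", "))
  kept <- filter_hits(hits, cfg)
  if (nrow(kept) == 0) return(empty)
  res <- kept %>%
    group_by(read_id) %>%
    summarise(n_hits_used = n(),
              assignment = list(assign_lca(unname(lineages[ref_id]),
                                           cfg$lca_percent)),
              .groups = "drop")
  out <- tibble(read_id = res$read_id,
                lineage = vapply(res$assignment, `[[`, character(1),
                                 "lineage"),
                taxon = vapply(res$assignment, `[[`, character(1), "taxon"),
                depth = vapply(res$assignment, `[[`, integer(1), "depth"),
                n_hits_used = res$n_hits_used)
  apply_support(out, cfg)
}

#' Apply the minimum-support pass to per-read assignments
#'
#' Taxa supported by fewer than `min_support` reads have their reads moved
#' to the parent node, repeatedly, deepest node first; reads reaching the
#' root without support become unassigned (`NA` lineage). With
#' `min_support = 1` (and `max_support_percent = 0`, which disables the
#' percentage variant) this is a no-op.
#'
#' @param assignments tibble from [classify_reads()] (columns `read_id`,
#'   `lineage`, `taxon`, `depth`).
#' @param cfg a [lca_config()].
#' @return `assignments` with reads re-parented as needed.
#' @export
apply_support <- function(assignments, cfg = lca_config()) {
  min_support <- cfg$min_support
  if (cfg$max_support_percent > 0)
    min_support <- max(min_support,
                       ceiling(cfg$max_support_percent / 100 *
                                 nrow(assignments)))
  if (min_support <= 1 || nrow(assignments) == 0) return(assignments)
  a <- assignments
  repeat {
    counts <- table(a$lineage[!is.na(a$lineage)])
    weak <- names(counts)[as.numeric(counts) < min_support]
    if (length(weak) == 0) break
    # deepest offending node first
    weak <- weak[order(-vapply(lineage_split(weak), length, integer(1)))]
    w <- weak[1]
    at <- !is.na(a$lineage) & a$lineage == w
    if (w == "") {
      # the root has no parent: unsupported root reads become unassigned
      a$lineage[at] <- NA_character_
      a$taxon[at] <- NA_character_
      a$depth[at] <- NA_integer_
    } else {
      parent <- lineage_split(w)[[1]]
      newp <- paste(parent[-length(parent)], collapse = ";")
      a$lineage[at] <- newp
      a$taxon[at] <- if (nzchar(newp)) parent[length(parent) - 1] else "root"
      a$depth[at] <- length(parent) - 1L
    }
  }
  a
}
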