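# Readers and writers for the pipeline's on-disk artifacts: FASTA/FASTQ,
# lineage tables, 12-column tabular hit files, and curation tables.
#
# Reads are tibbles with columns read_id, seq, qual (list column of integer
# Phred scores, NULL where absent). Reference sets are tibbles with columns
# ref_id, seq, gene_family, lineage (semicolon-joined path) and length_nt.

#' Read a FASTA file
#'
#' Parses FASTA into a tibble of records. Sequences are uppercased and may be
#' wrapped over multiple lines; record order is preserved. Malformed input
#' (sequence data before the first header, an empty header, an empty
#' sequence, a duplicated identifier) is a parse error naming the offending
#' line.
#'
#' @param path file path.
#' @param id_column name of the identifier column in the result
#'   (`"read_id"` for read sets, `"ref_id"` for reference sets).
#' @return tibble with the identifier column, `desc` (header text after the
#'   first whitespace) and `seq`.
#' @export
read_fasta <- function(path, id_column = "read_id") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0) {
    out <- tibble(id = character(), desc = character(), seq = character())
    names(out)[1] <- id_column
    return(out)
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA parse error at line 1: expected '>' header")
  hdr_at <- which(is_hdr)
  hdr_txt <- sub("^>", "", lines[hdr_at])
  bad <- hdr_at[!nzchar(trimws(hdr_txt))]
  if (length(bad) > 0)
    stop("FASTA parse error at line ", bad[1], ": empty header")
  ids <- sub("\\s.*$", "", trimws(hdr_txt))
  desc <- sub("^\\S+\\s*", "", trimws(hdr_txt))
  grp <- cumsum(is_hdr)
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  seqs <- unname(seqs[as.character(seq_along(hdr_at))])
  seqs[is.na(seqs)] <- ""
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0)
    stop("FASTA parse error at line ", hdr_at[empty[1]],
         ": record '", ids[empty[1]], "' has an empty sequence")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate FASTA identifiers: ", paste(unique(dup), collapse = ", "))
  out <- tibble(id = ids, desc = desc, seq = seqs)
  names(out)[1] <- id_column
  out
}

#' Read a 4-line FASTQ file (Phred+33)
#'
#' @param path file path.
#' @return tibble with `read_id`, `seq`, and `qual` (list column of integer
#'   Phred scores).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0)
    return(tibble(read_id = character(), seq = character(), qual = list()))
  if (length(lines) %% 4 != 0)
    stop("FASTQ parse error: truncated record near line ",
         4 * (length(lines) %/% 4) + 1)
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- toupper(lines[seq(2, length(lines), 4)])
  plus <- lines[seq(3, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0)
    stop("FASTQ parse error at line ", (bad_hdr[1] - 1) * 4 + 1,
         ": expected '@' header")
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0)
    stop("FASTQ parse error at line ", (bad_plus[1] - 1) * 4 + 3,
         ": expected '+' separator")
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism) > 0)
    stop("FASTQ parse error at line ", (mism[1] - 1) * 4 + 2,
         ": sequence and quality lengths differ")
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate FASTQ identifiers: ", paste(unique(dup), collapse = ", "))
  tibble(read_id = ids, seq = seqs, qual = lapply(quals, phred_decode))
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual quality string.
#' @return integer vector of Phred scores.
#' @export
phred_decode <- function(qual) {
  if (is.na(qual) || !nzchar(qual)) return(integer(0))
  as.integer(utf8ToInt(qual)) - 33L
}

#' @rdname phred_decode
#' @param q integer vector of Phred scores.
#' @export
phred_encode <- function(q) {
  if (length(q) == 0) return("")
  intToUtf8(as.integer(q) + 33L)
}

#' Write reads to FASTA or FASTQ
#'
#' @param reads tibble with `read_id`, `seq` and (for FASTQ) `qual`.
#' @param path output path.
#' @export
write_fasta <- function(reads, path) {
  id_col <- intersect(c("read_id", "ref_id"), names(reads))[1]
  desc <- if ("desc" %in% names(reads)) {
    ifelse(nzchar(reads$desc), paste0(" ", reads$desc), "")
  } else ""
  writeLines(paste0(">", reads[[id_col]], desc, "\n", reads$seq), path,
             sep = "\n")
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) {
    vapply(seq_len(nrow(reads)), function(i) {
      q <- reads$qual[[i]]
      if (is.null(q) || length(q) == 0) {
        strrep("I", nchar(reads$seq[i]))   # default Q40
      } else phred_encode(q)
    }, character(1))
  } else strrep("I", nchar(reads$seq))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual),
             path, sep = "\n")
  invisible(path)
}

#' Read a two-column lineage table
#'
#' Tab-separated `ref_id` / semicolon-joined lineage pairs. Whitespace around
#' taxon names is stripped. Duplicate rows with identical lineages are
#' deduplicated; conflicting duplicates are an error. When `expected_ids` is
#' given, every id must be present.
#'
#' @param path file path.
#' @param expected_ids optional character vector of ids that must be covered.
#' @return named character vector mapping ref_id to a canonical
#'   semicolon-joined lineage.
#' @export
read_lineage_table <- function(path, expected_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- character(0)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 2))
      stop("lineage table parse error at line ", which(nf != 2)[1],
           ": expected 2 tab-separated columns")
    ids <- trimws(vapply(parts, `[`, character(1), 1))
    paths <- vapply(parts, `[`, character(1), 2)
    canon <- vapply(strsplit(paths, ";", fixed = TRUE),
                    function(x) paste(trimws(x), collapse = ";"), character(1))
    tab <- unique(data.frame(id = ids, lineage = canon,
                             stringsAsFactors = FALSE))
    dup <- unique(tab$id[duplicated(tab$id)])
    if (length(dup) > 0)
      stop("conflicting lineages for: ", paste(dup, collapse = ", "))
    out <- setNames(tab$lineage, tab$id)
  }
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, names(out))
    if (length(missing) > 0)
      stop("ids missing from lineage table: ",
           paste(missing, collapse = ", "))
  }
  out
}

#' @rdname read_lineage_table
#' @param lineages named character vector as returned by
#'   [read_lineage_table()].
#' @export
write_lineage_table <- function(lineages, path) {
  writeLines(paste0(names(lineages), "\t", unname(lineages)), path)
  invisible(path)
}

#' Split a semicolon-joined lineage into a taxon path
#' @param lineage character vector of semicolon-joined lineages.
#' @return list of character vectors, root first.
#' @export
lineage_split <- function(lineage) {
  lapply(strsplit(lineage, ";", fixed = TRUE), trimws)
}

#' Read a reference database (FASTA plus lineage table)
#'
#' FASTA descriptions may carry a `gene=<family>` tag; records without one
#' are labeled `background`. `length_nt` is taken from a `len_nt=` tag when
#' present, otherwise 3x the residue length for protein records or the
#' sequence length for nucleotide records.
#'
#' @param fasta_path reference FASTA.
#' @param lineage_path two-column lineage TSV covering every ref_id.
#' @param type `"protein"` or `"nucleotide"`.
#' @return reference tibble (`ref_id`, `seq`, `gene_family`, `lineage`,
#'   `length_nt`).
#' @export
read_reference_db <- function(fasta_path, lineage_path,
                              type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  fa <- read_fasta(fasta_path, id_column = "ref_id")
  lin <- read_lineage_table(lineage_path, expected_ids = fa$ref_id)
  gene <- sub("^.*gene=(\\S+).*$", "\\1", fa$desc)
  gene[!grepl("gene=", fa$desc)] <- "background"
  len <- suppressWarnings(as.numeric(sub("^.*len_nt=(\\d+).*$", "\\1",
                                         fa$desc)))
  len[!grepl("len_nt=", fa$desc)] <- NA
  fallback <- if (type == "protein") 3 * nchar(fa$seq) else nchar(fa$seq)
  tibble(ref_id = fa$ref_id, seq = fa$seq, gene_family = gene,
         lineage = unname(lin[fa$ref_id]),
         length_nt = ifelse(is.na(len), fallback, len))
}

#' @rdname read_reference_db
#' @param refs reference tibble.
#' @param fasta_path,lineage_path output paths.
#' @export
write_reference_db <- function(refs, fasta_path, lineage_path) {
  desc <- paste0("gene=", refs$gene_family, " len_nt=", refs$length_nt)
  writeLines(paste0(">", refs$ref_id, " ", desc, "\n", refs$seq), fasta_path)
  write_lineage_table(setNames(refs$lineage, refs$ref_id), lineage_path)
  invisible(fasta_path)
}

# deterministic hit ordering shared by the writer and the search functions
order_hits <- function(hits) {
  hits[order(hits$read_id, -hits$bit_score, hits$ref_id), , drop = FALSE]
}

#' Write alignment hits as a 12-column tabular file
#'
#' Standard tabular hit layout: query id, subject id, percent identity (two
#' decimals), alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, E-value, bit score. Coordinates are 1-based inclusive. Rows are
#' ordered by query id, then descending bit score, then subject id, so runs
#' are diffable.
#'
#' @param hits hit tibble as produced by [search_reads()] or
#'   [confirm_by_search()].
#' @param path output path.
#' @export
write_hits_table <- function(hits, path) {
  if (nrow(hits) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  h <- order_hits(hits)
  lines <- paste(h$read_id, h$ref_id, sprintf("%.2f", 100 * h$identity),
                 h$aligned_cols, h$mismatches, h$gap_opens,
                 h$q_start, h$q_end, h$s_start, h$s_end,
                 sprintf("%.3g", h$evalue), sprintf("%.4g", h$bit_score),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hits_table
#' @return `read_hits_table` returns a tibble with the 12 standard columns.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- tibble(read_id = character(), ref_id = character(),
                  identity = numeric(), aligned_cols = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = numeric(), bit_score = numeric())
  if (file.size(path) == 0) return(empty)
  d <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                  col.names = names(empty))
  d$identity <- d$identity / 100
  as_tibble(d)
}
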