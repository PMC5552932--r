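# Synthetic sediment-community generator: curated / background / SSU
# reference sets with known taxonomy, plus an Ion-Torrent-like read
# simulator that plants marker-gene fragments, decoy homologs, SSU rRNA
# fragments and background reads at configured proportions, with a
# per-read ground-truth table.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
NT4 <- c("A", "C", "G", "T")

# genus -> full five-rank lineage (Domain;Phylum;Class;Order;Genus)
LINEAGE_POOL <- c(
  Methylobacter    = "Bacteria;Proteobacteria;Gammaproteobacteria;Methylococcales;Methylobacter",
  Thioalkalivibrio = "Bacteria;Proteobacteria;Gammaproteobacteria;Chromatiales;Thioalkalivibrio",
  Geobacter        = "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Geobacter",
  Thauera          = "Bacteria;Proteobacteria;Betaproteobacteria;Rhodocyclales;Thauera",
  Nitrosomonas     = "Bacteria;Proteobacteria;Betaproteobacteria;Nitrosomonadales;Nitrosomonas",
  Bradyrhizobium   = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Bradyrhizobium",
  Kuenenia         = "Bacteria;Planctomycetes;Brocadiae;Brocadiales;Kuenenia",
  Scalindua        = "Bacteria;Planctomycetes;Brocadiae;Brocadiales;Scalindua",
  Brocadia         = "Bacteria;Planctomycetes;Brocadiae;Brocadiales;Brocadia",
  Jettenia         = "Bacteria;Planctomycetes;Brocadiae;Brocadiales;Jettenia",
  Nitrospira       = "Bacteria;Nitrospirae;Nitrospira;Nitrospirales;Nitrospira",
  Nitrospina       = "Bacteria;Nitrospinae;Nitrospinia;Nitrospinales;Nitrospina",
  Anaerolinea      = "Bacteria;Chloroflexi;Anaerolineae;Anaerolineales;Anaerolinea",
  Muricauda        = "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Muricauda",
  Desulfotomaculum = "Bacteria;Firmicutes;Clostridia;Clostridiales;Desulfotomaculum",
  Nitrosopumilus   = "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosopumilales;Nitrosopumilus",
  Nitrososphaera   = "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrososphaerales;Nitrososphaera",
  Methanosarcina   = "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosarcina",
  Thermoplasma     = "Archaea;Euryarchaeota;Thermoplasmata;Thermoplasmatales;Thermoplasma",
  Woesearchaeum    = "Archaea;Woesearchaeota;Woesearchaeia;Woesearchaeales;Woesearchaeum",
  Saccharomyces    = "Eukaryota;Opisthokonta;Fungi;Saccharomycetales;Saccharomyces",
  Thalassiosira    = "Eukaryota;Stramenopiles;Bacillariophyta;Thalassiosirales;Thalassiosira")

# plausible host genera per marker family; members are drawn in this order
FAMILY_TAXA <- list(
  narG = c("Thauera", "Geobacter", "Bradyrhizobium", "Anaerolinea"),
  napA = c("Thioalkalivibrio", "Bradyrhizobium", "Geobacter", "Muricauda"),
  nxrA = c("Nitrospira", "Nitrospina", "Kuenenia", "Scalindua"),
  nirK = c("Nitrosopumilus", "Bradyrhizobium", "Nitrosomonas", "Muricauda"),
  nirS = c("Thauera", "Methylobacter", "Thioalkalivibrio", "Geobacter"),
  nor  = c("Methylobacter", "Thauera", "Muricauda", "Geobacter"),
  nod  = c("Muricauda", "Methylobacter", "Thauera", "Anaerolinea"),
  nosZ = c("Bradyrhizobium", "Thauera", "Geobacter", "Desulfotomaculum"),
  nrfA = c("Geobacter", "Muricauda", "Desulfotomaculum", "Anaerolinea"),
  hao  = c("Kuenenia", "Scalindua", "Brocadia", "Jettenia"),
  hzsA = c("Kuenenia", "Scalindua", "Brocadia", "Jettenia"),
  amoA = c("Nitrosopumilus", "Nitrososphaera", "Nitrosomonas", "Methylobacter"),
  nifH = c("Methylobacter", "Methanosarcina", "Desulfotomaculum", "Geobacter"))

SSU_GENERA <- c("Nitrosopumilus", "Methanosarcina", "Thermoplasma",
                "Woesearchaeum", "Methylobacter", "Thauera", "Kuenenia",
                "Nitrospira", "Muricauda", "Geobacter", "Saccharomyces",
                "Thalassiosira")

.random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

.random_nt <- function(len) paste(sample(NT4, len, TRUE), collapse = "")

.mutate_seq <- function(seq, rate, alphabet) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(alphabet, x[i]), 1)
  paste(x, collapse = "")
}

# inverted genetic code: amino acid -> codons
.codon_table <- function(genetic_code = "11") {
  code <- Biostrings::getGeneticCode(genetic_code)
  split(names(code), unname(code))
}

.reverse_translate <- function(protein, codons) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(a) sample(codons[[a]], 1), character(1)),
        collapse = "")
}

#' Ion-Torrent-like sequencing error model
#'
#' Substitution and indel rates per base; indel probability is multiplied by
#' `homopolymer_multiplier` for bases that extend a homopolymer run, the
#' dominant error mode of the emulated platform. Insertions duplicate the
#' local base (homopolymer over-call); deletions drop it (under-call).
#'
#' @param substitution_rate,indel_rate per-base rates in \[0, 0.2\].
#' @param homopolymer_multiplier indel-rate multiplier (>= 1) inside
#'   homopolymer runs.
#' @return a `ncyc_error_model` list.
#' @export
error_model <- function(substitution_rate = 0.004, indel_rate = 0.004,
                        homopolymer_multiplier = 3) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.2,
            indel_rate >= 0, indel_rate <= 0.2, homopolymer_multiplier >= 1)
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 homopolymer_multiplier = homopolymer_multiplier),
            class = "ncyc_error_model")
}

.apply_errors <- function(seq, em) {
  if (em$substitution_rate <= 0 && em$indel_rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  sub_at <- which(runif(n) < em$substitution_rate)
  for (i in sub_at) x[i] <- sample(setdiff(NT4, x[i]), 1)
  if (em$indel_rate > 0) {
    in_run <- c(FALSE, x[-1] == x[-n])
    p <- pmin(0.5, em$indel_rate *
                ifelse(in_run, em$homopolymer_multiplier, 1))
    ind_at <- runif(n) < p
    is_ins <- runif(n) < 0.5
    counts <- rep(1L, n)
    counts[ind_at & is_ins] <- 2L    # duplicate the base
    counts[ind_at & !is_ins] <- 0L   # drop the base
    x <- rep(x, counts)
  }
  if (length(x) == 0) x <- sample(NT4, 1)
  paste(x, collapse = "")
}

#' Generate curated, background and SSU reference sets with taxonomy
#'
#' Builds the three reference databases the pipeline searches against:
#' \describe{
#'   \item{curated}{protein members of up to 13 nitrogen-cycle marker
#'     families (narG, napA, nxrA, nirK, nirS, nor, nod, nosZ, nrfA, hao,
#'     hzsA, amoA, nifH), each family descending from a random ancestor with
#'     `within_divergence` substitutions per member, hosted by plausible
#'     genera.}
#'   \item{background}{a strict superset of the curated proteins plus one
#'     decoy homolog per curated member, mutated to `divergence` amino-acid
#'     substitution rate and labeled `background`, plus unrelated random
#'     proteins. Stands in for a comprehensive protein database so the
#'     bit-score ratio of a true family read is 1 by construction.}
#'   \item{ssu}{nucleotide SSU rRNA references spanning three domains,
#'     generated hierarchically so within-domain references are more similar
#'     than cross-domain ones.}
#' }
#' Coding sequences (random synonymous codons, genetic code 11) are attached
#' for every protein so reads can be simulated from nucleotide space.
#'
#' @param seed integer seed; identical seeds give identical outputs.
#' @param n_families number of marker families (at most 13).
#' @param n_taxa_per_family members per family (at most 4).
#' @param divergence decoy amino-acid divergence in \[0, 0.9).
#' @param within_divergence within-family member divergence.
#' @param protein_len_range residue-length range for family ancestors.
#' @param family_lengths optional named vector fixing specific families'
#'   protein lengths (residues).
#' @param ssu_len SSU reference length (nt).
#' @param n_background_extra unrelated random proteins added to the
#'   background set.
#' @return a `ncyc_refs` list with reference tibbles `curated`,
#'   `background`, `ssu`, the coding sequences `cds` (`ref_id`, `seq`,
#'   `category`), and background read source scaffolds `scaffolds`.
#' @export
make_reference_sets <- function(seed, n_families = 13, n_taxa_per_family = 3,
                                divergence = 0.7, within_divergence = 0.15,
                                protein_len_range = c(120, 260),
                                family_lengths = NULL, ssu_len = 1404,
                                n_background_extra = 10) {
  if (divergence < 0 || divergence >= 0.9)
    stop("divergence must be in [0, 0.9)")
  if (n_families < 1 || n_families > length(MARKER_FAMILIES))
    stop("n_families must be between 1 and ", length(MARKER_FAMILIES))
  if (n_taxa_per_family < 1 || n_taxa_per_family > 4)
    stop("n_taxa_per_family must be between 1 and 4")
  families <- MARKER_FAMILIES[seq_len(n_families)]

  withr::with_seed(as.integer(seed), {
    codons <- .codon_table("11")
    cur <- list(); cds <- list(); dec <- list()
    for (fam in families) {
      len <- if (!is.null(family_lengths) && fam %in% names(family_lengths)) {
        as.integer(family_lengths[[fam]])
      } else sample(protein_len_range[1]:protein_len_range[2], 1)
      anc <- .random_protein(len)
      taxa <- FAMILY_TAXA[[fam]][seq_len(n_taxa_per_family)]
      for (tx in taxa) {
        rid <- paste0(fam, "_", tx)
        prot <- .mutate_seq(anc, within_divergence, AA20)
        cur[[rid]] <- tibble(ref_id = rid, seq = prot, gene_family = fam,
                             lineage = unname(LINEAGE_POOL[tx]),
                             length_nt = 3 * nchar(prot))
        cds[[rid]] <- tibble(ref_id = rid,
                             seq = paste0(.reverse_translate(prot, codons),
                                          "TAA"),
                             category = "gene")
        drid <- paste0("dcy_", rid)
        dprot <- .mutate_seq(prot, divergence, AA20)
        dec[[drid]] <- tibble(ref_id = drid, seq = dprot,
                              gene_family = "background",
                              lineage = unname(sample(LINEAGE_POOL, 1)),
                              length_nt = 3 * nchar(dprot))
        cds[[drid]] <- tibble(ref_id = drid,
                              seq = paste0(.reverse_translate(dprot, codons),
                                           "TAA"),
                              category = "decoy")
      }
    }
    curated <- bind_rows(cur)
    decoys <- bind_rows(dec)
    extra <- if (n_background_extra > 0) {
      tibble(ref_id = sprintf("bg_rnd_%02d", seq_len(n_background_extra)),
             seq = vapply(sample(protein_len_range[1]:protein_len_range[2],
                                 n_background_extra, TRUE),
                          .random_protein, character(1)),
             gene_family = "background",
             lineage = unname(sample(LINEAGE_POOL, n_background_extra,
                                     TRUE)))
    } else NULL
    if (!is.null(extra)) extra$length_nt <- 3 * nchar(extra$seq)
    background <- bind_rows(
      mutate(curated, gene_family = "background"), decoys, extra)

    ssu_root <- .random_nt(ssu_len)
    domains <- vapply(LINEAGE_POOL[SSU_GENERA], function(l)
      strsplit(l, ";", fixed = TRUE)[[1]][1], character(1))
    dom_seq <- lapply(unique(domains), function(d)
      .mutate_seq(ssu_root, 0.20, NT4))
    names(dom_seq) <- unique(domains)
    ssu <- bind_rows(lapply(SSU_GENERA, function(g) {
      tibble(ref_id = paste0("ssu_", g),
             seq = .mutate_seq(dom_seq[[domains[[g]]]], 0.10, NT4),
             gene_family = "SSU", lineage = unname(LINEAGE_POOL[g]),
             length_nt = ssu_len)
    }))

    scaffolds <- tibble(
      ref_id = sprintf("bg_scaffold_%02d", 1:8),
      seq = vapply(rep(3000, 8), .random_nt, character(1)),
      lineage = unname(sample(LINEAGE_POOL, 8, TRUE)))

    structure(list(curated = curated, background = background, ssu = ssu,
                   cds = bind_rows(cds), scaffolds = scaffolds,
                   seed = as.integer(seed)),
              class = "ncyc_refs")
  })
}

#' Largest-remainder integer apportionment
#'
#' Deterministically rounds `total * weights / sum(weights)` to integers
#' summing to `total`: floor quotas first, remaining units to the largest
#' fractional parts (ties by position).
#'
#' @param weights non-negative numeric weights.
#' @param total integer total to apportion.
#' @return integer vector of the same length as `weights`.
#' @export
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  if (sum(weights) == 0) return(rep(0L, length(weights)))
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Specification of one synthetic depth-zone sample
#'
#' Fractions are interpreted as expected read proportions; with the default
#' deterministic quota rounding (largest remainder) the realized counts are
#' exact, with `multinomial = TRUE` they are sampled.
#'
#' @param sample_id sample label (e.g. `"OAZ"`).
#' @param n_reads total reads to emit.
#' @param read_len_mean,read_len_sd truncated-normal read length (nt,
#'   minimum 30).
#' @param family_fractions named numeric vector of per-marker-family read
#'   fractions.
#' @param ssu_fraction fraction of SSU rRNA fragment reads.
#' @param ssu_taxon_weights named weights over SSU reference genera
#'   (default: uniform over the SSU set).
#' @param decoy_fraction fraction of reads from decoy homolog coding
#'   sequences.
#' @param background_fraction fraction of non-target background reads;
#'   `NULL` fills the remainder to 1.
#' @param error_model an [error_model()].
#' @param multinomial sample category counts instead of quota rounding.
#' @return a `ncyc_spec` list.
#' @export
community_spec <- function(sample_id, n_reads, read_len_mean = 290,
                           read_len_sd = 60, family_fractions = numeric(0),
                           ssu_fraction = 0, ssu_taxon_weights = NULL,
                           decoy_fraction = 0, background_fraction = NULL,
                           error_model = ncyc::error_model(),
                           multinomial = FALSE) {
  stopifnot(n_reads >= 1, read_len_mean > 30, read_len_sd >= 0)
  fr <- c(family_fractions, ssu = ssu_fraction, decoy = decoy_fraction)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must be in [0, 1]")
  partial <- sum(fr)
  if (is.null(background_fraction)) {
    if (partial > 1 + 1e-9) stop("fractions exceed 1")
    background_fraction <- 1 - partial
  }
  if (abs(partial + background_fraction - 1) > 1e-9)
    stop("fractions must sum to 1 with background")
  structure(list(sample_id = sample_id, n_reads = as.integer(n_reads),
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 family_fractions = family_fractions,
                 ssu_fraction = ssu_fraction,
                 ssu_taxon_weights = ssu_taxon_weights,
                 decoy_fraction = decoy_fraction,
                 background_fraction = background_fraction,
                 error_model = error_model, multinomial = multinomial),
            class = "ncyc_spec")
}

#' Simulate a metagenomic sample with ground truth
#'
#' Emits exactly `spec$n_reads` reads. Fragment start positions are uniform
#' over the source sequence, lengths are truncated-normal (minimum 30 nt,
#' capped at the source length), strands are random, and errors follow the
#' spec's [error_model()]. Qualities are a constant Q30 profile. The
#' category layout is deterministic given the seed.
#'
#' @param spec a [community_spec()].
#' @param refs a `ncyc_refs` object from [make_reference_sets()].
#' @param seed integer seed.
#' @return list with `reads` (tibble `read_id`, `seq`, `qual`) and `truth`
#'   (tibble `read_id`, `category` in gene family / SSU / decoy /
#'   background, `source_ref`, `source_lineage`, `gene_family`).
#' @export
simulate_reads <- function(spec, refs, seed) {
  stopifnot(inherits(spec, "ncyc_spec"), inherits(refs, "ncyc_refs"))
  fams <- names(spec$family_fractions)
  missing <- setdiff(fams[spec$family_fractions > 0],
                     unique(refs$curated$gene_family))
  if (length(missing) > 0)
    stop("families requested but absent from references: ",
         paste(missing, collapse = ", "))

  withr::with_seed(as.integer(seed), {
    w <- c(spec$family_fractions, SSU = spec$ssu_fraction,
           decoy = spec$decoy_fraction,
           background = spec$background_fraction)
    counts <- if (spec$multinomial) {
      as.integer(stats::rmultinom(1, spec$n_reads, w))
    } else largest_remainder(w, spec$n_reads)
    names(counts) <- names(w)

    # per-read source selection
    src_ref <- character(0); src_cat <- character(0); src_fam <- character(0)
    for (fam in fams) {
      nf <- counts[[fam]]
      if (nf == 0) next
      members <- refs$curated$ref_id[refs$curated$gene_family == fam]
      src_ref <- c(src_ref, sample(members, nf, TRUE))
      src_cat <- c(src_cat, rep(fam, nf))
      src_fam <- c(src_fam, rep(fam, nf))
    }
    if (counts[["SSU"]] > 0) {
      wts <- spec$ssu_taxon_weights
      if (is.null(wts))
        wts <- setNames(rep(1, nrow(refs$ssu)),
                        sub("^ssu_", "", refs$ssu$ref_id))
      ids <- paste0("ssu_", names(wts))
      unknown <- setdiff(ids, refs$ssu$ref_id)
      if (length(unknown) > 0)
        stop("SSU taxa absent from references: ",
             paste(unknown, collapse = ", "))
      ssu_counts <- if (spec$multinomial) {
        as.integer(stats::rmultinom(1, counts[["SSU"]], wts))
      } else largest_remainder(wts, counts[["SSU"]])
      src_ref <- c(src_ref, rep(ids, ssu_counts))
      src_cat <- c(src_cat, rep("SSU", counts[["SSU"]]))
      src_fam <- c(src_fam, rep(NA_character_, counts[["SSU"]]))
    }
    if (counts[["decoy"]] > 0) {
      dids <- refs$cds$ref_id[refs$cds$category == "decoy"]
      if (length(dids) == 0) stop("no decoy sequences in references")
      src_ref <- c(src_ref, sample(dids, counts[["decoy"]], TRUE))
      src_cat <- c(src_cat, rep("decoy", counts[["decoy"]]))
      src_fam <- c(src_fam, rep(NA_character_, counts[["decoy"]]))
    }
    if (counts[["background"]] > 0) {
      src_ref <- c(src_ref, sample(refs$scaffolds$ref_id,
                                   counts[["background"]], TRUE))
      src_cat <- c(src_cat, rep("background", counts[["background"]]))
      src_fam <- c(src_fam, rep(NA_character_, counts[["background"]]))
    }

    seq_by_id <- c(setNames(refs$cds$seq, refs$cds$ref_id),
                   setNames(refs$ssu$seq, refs$ssu$ref_id),
                   setNames(refs$scaffolds$seq, refs$scaffolds$ref_id))
    lin_by_id <- c(setNames(refs$curated$lineage, refs$curated$ref_id),
                   setNames(refs$background$lineage, refs$background$ref_id),
                   setNames(refs$ssu$lineage, refs$ssu$ref_id),
                   setNames(refs$scaffolds$lineage, refs$scaffolds$ref_id))

    n <- spec$n_reads
    lens <- pmax(30L, as.integer(round(rnorm(n, spec$read_len_mean,
                                             spec$read_len_sd))))
    src_seq <- unname(seq_by_id[src_ref])
    src_len <- nchar(src_seq)
    li <- pmin(lens, src_len)
    start <- vapply(src_len - li, function(r)
      if (r > 0) sample.int(r + 1L, 1) else 1L, integer(1))
    frags <- substr(src_seq, start, start + li - 1L)
    minus <- runif(n) < 0.5
    if (any(minus)) frags[minus] <- reverse_complement(frags[minus])
    seqs <- vapply(frags, .apply_errors, character(1),
                   em = spec$error_model, USE.NAMES = FALSE)

    perm <- sample.int(n)
    ids <- sprintf("%s_r%06d", spec$sample_id, seq_len(n))
    reads <- tibble(read_id = ids, seq = seqs[perm],
                    qual = lapply(nchar(seqs[perm]), function(k)
                      rep(30L, k)))
    truth <- tibble(read_id = ids, category = src_cat[perm],
                    source_ref = src_ref[perm],
                    source_lineage = unname(lin_by_id[src_ref[perm]]),
                    gene_family = src_fam[perm])
    list(reads = reads, truth = truth)
  })
}

#' Default three-zone study specifications
#'
#' Three depth-zone samples emulating an oxic-anoxic interface zone (OAZ), a
#' sulfate-methane transition zone (SMTZ) and a methanic zone (MZ): marker
#' and SSU abundances decline with depth, ammonia-oxidizer signal
#' (amoA, Marine-Group-I-like SSU) is concentrated in the surface zone, and
#' anammox signal (hao, hzsA, Brocadiales SSU) peaks in the middle zone.
#' Mean read lengths are 289/296/291 nt per zone.
#'
#' @param n_reads reads per sample.
#' @param error_model shared [error_model()].
#' @return named list of three [community_spec()] objects.
#' @export
default_zone_specs <- function(n_reads = 10000,
                               error_model = ncyc::error_model()) {
  fam <- function(...) c(...)
  list(
    OAZ = community_spec(
      "OAZ", n_reads, read_len_mean = 289,
      family_fractions = fam(narG = 0.016, napA = 0.012, nxrA = 0.010,
                             nirK = 0.012, nirS = 0.008, nor = 0.010,
                             nod = 0.004, nosZ = 0.010, nrfA = 0.004,
                             hao = 0.004, hzsA = 0.001, amoA = 0.012,
                             nifH = 0.002),
      ssu_fraction = 0.06,
      ssu_taxon_weights = c(Nitrosopumilus = 0.25, Methylobacter = 0.12,
                            Thauera = 0.10, Nitrospira = 0.08,
                            Kuenenia = 0.03, Muricauda = 0.10,
                            Geobacter = 0.10, Methanosarcina = 0.05,
                            Thermoplasma = 0.05, Woesearchaeum = 0.06,
                            Saccharomyces = 0.03, Thalassiosira = 0.03),
      decoy_fraction = 0.05, error_model = error_model),
    SMTZ = community_spec(
      "SMTZ", n_reads, read_len_mean = 296,
      family_fractions = fam(narG = 0.010, napA = 0.008, nxrA = 0.010,
                             nirK = 0.008, nirS = 0.005, nor = 0.007,
                             nod = 0.003, nosZ = 0.006, nrfA = 0.006,
                             hao = 0.008, hzsA = 0.003, amoA = 0.008,
                             nifH = 0.002),
      ssu_fraction = 0.06,
      ssu_taxon_weights = c(Nitrosopumilus = 0.10, Methylobacter = 0.06,
                            Thauera = 0.08, Nitrospira = 0.08,
                            Kuenenia = 0.08, Muricauda = 0.10,
                            Geobacter = 0.15, Methanosarcina = 0.10,
                            Thermoplasma = 0.08, Woesearchaeum = 0.10,
                            Saccharomyces = 0.03, Thalassiosira = 0.04),
      decoy_fraction = 0.05, error_model = error_model),
    MZ = community_spec(
      "MZ", n_reads, read_len_mean = 291,
      family_fractions = fam(narG = 0.004, napA = 0.003, nxrA = 0.002,
                             nirK = 0.004, nirS = 0.002, nor = 0.002,
                             nod = 0.001, nosZ = 0.002, nrfA = 0.003,
                             hao = 0.001, hzsA = 0.000, amoA = 0.002,
                             nifH = 0.001),
      ssu_fraction = 0.05,
      ssu_taxon_weights = c(Nitrosopumilus = 0.08, Methylobacter = 0.04,
                            Thauera = 0.06, Nitrospira = 0.06,
                            Kuenenia = 0.03, Muricauda = 0.08,
                            Geobacter = 0.12, Methanosarcina = 0.15,
                            Thermoplasma = 0.10, Woesearchaeum = 0.20,
                            Saccharomyces = 0.04, Thalassiosira = 0.04),
      decoy_fraction = 0.05, error_model = error_model))
}

#' Write a simulated sample and its references to a directory
#'
#' Writes `reads.fastq`, `truth.tsv`, the three reference FASTAs and their
#' lineage TSVs. Outputs are byte-deterministic given (spec, seed).
#'
#' @param sim result of [simulate_reads()].
#' @param refs a `ncyc_refs` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sim, refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads, file.path(dir, "reads.fastq"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_reference_db(refs$curated, file.path(dir, "curated.fasta"),
                     file.path(dir, "curated_lineages.tsv"))
  write_reference_db(refs$background, file.path(dir, "background.fasta"),
                     file.path(dir, "background_lineages.tsv"))
  write_reference_db(refs$ssu, file.path(dir, "ssu.fasta"),
                     file.path(dir, "ssu_lineages.tsv"))
  invisible(dir)
}
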