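make_ssu_db <- function(seqs, genera) {
  lineages <- c(
    Nitrosopumilus = "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosopumilales;Nitrosopumilus",
    Methylobacter = "Bacteria;Proteobacteria;Gammaproteobacteria;Methylococcales;Methylobacter",
    Kuenenia = "Bacteria;Planctomycetes;Brocadiae;Brocadiales;Kuenenia")
  tibble::tibble(ref_id = paste0("ssu_", genera), seq = seqs,
                 gene_family = "SSU", lineage = unname(lineages[genera]),
                 length_nt = nchar(seqs))
}

test_that("exact substring reads map with identity and fraction 1", {
  withr::with_seed(51, {
    ref <- random_dna(1000)
    db <- make_ssu_db(ref, "Nitrosopumilus")
    read <- tibble::tibble(read_id = "r1", seq = substr(ref, 101, 250))
    m <- map_reads(read, db, prescreen_k = 0)
    expect_equal(nrow(m), 1)
    expect_equal(m$identity, 1)
    expect_equal(m$read_fraction, 1)
    expect_equal(m$raw_score, 150)
    # and on the reverse strand
    mrc <- map_reads(tibble::tibble(read_id = "r1rc",
                                    seq = reverse_complement(read$seq)),
                     db, prescreen_k = 0)
    expect_equal(mrc$strand, "-")
    expect_equal(mrc$identity, 1)
  })
})

test_that("mapping rejects reads failing the aligned-length fraction", {
  withr::with_seed(52, {
    ref <- random_dna(1000)
    db <- make_ssu_db(ref, "Nitrosopumilus")
    # 200-nt read of which only 90 nt match the reference: 0.45 < 0.5
    read <- tibble::tibble(read_id = "short",
                           seq = paste0(substr(ref, 1, 90), random_dna(110)))
    expect_equal(nrow(map_reads(read, db, prescreen_k = 0)), 0)
    # 120 matching nt out of 200 passes 0.5 but tests similarity instead
  })
})

test_that("mapping rejects reads failing the similarity fraction", {
  withr::with_seed(53, {
    ref <- random_dna(1000)
    db <- make_ssu_db(ref, "Nitrosopumilus")
    frag <- strsplit(substr(ref, 201, 400), "")[[1]]
    # mutate every 4th base: identity ~0.75 < 0.8
    at <- seq(1, 200, by = 4)
    for (i in at) frag[i] <- setdiff(c("A", "C", "G", "T"), frag[i])[1]
    read <- tibble::tibble(read_id = "div", seq = paste(frag, collapse = ""))
    expect_equal(nrow(map_reads(read, db, prescreen_k = 0)), 0)

    # mutate every 20th base: identity ~0.95, accepted
    frag2 <- strsplit(substr(ref, 201, 400), "")[[1]]
    for (i in seq(1, 200, by = 20))
      frag2[i] <- setdiff(c("A", "C", "G", "T"), frag2[i])[1]
    read2 <- tibble::tibble(read_id = "ok", seq = paste(frag2, collapse = ""))
    m <- map_reads(read2, db, prescreen_k = 0)
    expect_equal(nrow(m), 1)
    expect_gte(m$identity, 0.8)
  })
})

test_that("relaxing acceptance fractions never loses mapped reads", {
  refs <- small_refs()
  sim <- small_noiseless_sim()
  ssu_reads <- sim$reads[sim$reads$read_id %in%
                           sim$truth$read_id[sim$truth$category == "SSU"], ]
  strict <- map_reads(ssu_reads, refs$ssu, mapping_config(), 0)
  relaxed <- map_reads(ssu_reads, refs$ssu,
                       mapping_config(length_fraction = 0.4,
                                      similarity_fraction = 0.7), 0)
  expect_true(all(strict$read_id %in% relaxed$read_id))
})

test_that("confirmation E-values follow the nucleotide Karlin-Altschul form", {
  withr::with_seed(54, {
    ref <- random_dna(1404)
    db <- make_ssu_db(ref, "Nitrosopumilus")
    reads <- tibble::tibble(read_id = "e1", seq = substr(ref, 301, 450))
    mapped <- map_reads(reads, db, prescreen_k = 0)
    conf <- confirm_by_search(reads, mapped, db)
    expect_equal(nrow(conf), 1)
    # exact 150-nt match: raw = 150 * 2; oracle E from the closed form
    sc <- nucleotide_scoring()
    bit <- (sc$lambda * 300 - log(sc$K)) / log(2)
    expect_equal(conf$raw_score, 300)
    expect_equal(conf$bit_score, bit, tolerance = 1e-9)
    expect_equal(conf$evalue, 150 * 1404 * 2^(-bit), tolerance = 1e-9)
    expect_lt(conf$evalue, 1e-6)

    # a random read with no significant hit is dropped and counted
    junk <- tibble::tibble(read_id = "junk", seq = random_dna(150))
    fake_map <- tibble::tibble(read_id = "junk")
    conf2 <- confirm_by_search(junk, fake_map, db)
    expect_equal(nrow(conf2), 0)
    expect_equal(attr(conf2, "n_dropped"), 1L)
  })
})

test_that("the confirmed best hit takes precedence over the mapping hit", {
  withr::with_seed(55, {
    refA <- random_dna(800)
    refB <- random_dna(800)
    db <- make_ssu_db(c(refA, refB), c("Methylobacter", "Kuenenia"))
    read <- tibble::tibble(read_id = "r", seq = substr(refB, 101, 300))
    # mapping stage (wrongly) recruited the read to refA
    stale <- tibble::tibble(read_id = "r", ref_id = "ssu_Methylobacter")
    conf <- confirm_by_search(read, stale, db)
    expect_equal(conf$ref_id, "ssu_Kuenenia")
    expect_match(conf$lineage, "Kuenenia")
  })
})

test_that("noiseless SSU reads recover their source lineage exactly", {
  refs <- small_refs()
  sim <- small_noiseless_sim()
  truth <- sim$truth[sim$truth$category == "SSU", ]
  reads <- sim$reads[sim$reads$read_id %in% truth$read_id, ]
  mapped <- map_reads(reads, refs$ssu)
  conf <- confirm_by_search(reads, mapped, refs$ssu)
  expect_equal(nrow(conf), nrow(truth))
  got <- conf$lineage[match(truth$read_id, conf$read_id)]
  expect_equal(got, truth$source_lineage)
})

test_that("composition summaries normalize, fold and scale correctly", {
  lin <- c(rep("Bacteria;Proteobacteria;Gammaproteobacteria", 50),
           rep("Bacteria;Proteobacteria;Deltaproteobacteria", 30),
           rep("Bacteria;Firmicutes;Clostridia", 19),
           rep("Archaea;Thaumarchaeota;Nitrososphaeria", 1))
  a <- tibble::tibble(lineage = lin)
  dom <- summarize_composition(a, "domain")
  expect_equal(dom$proportion[dom$taxon == "Bacteria"], 0.99)
  expect_equal(sum(dom$proportion), 1)

  # a 1% group folds under a 2% floor
  flo <- summarize_composition(a, "domain", reporting_floor = 0.02)
  expect_true("other" %in% flo$taxon)
  expect_equal(flo$proportion[flo$taxon == "other"], 0.01)

  # scope normalizes within Proteobacteria
  cls <- summarize_composition(a, "class", scope = "Proteobacteria")
  expect_equal(sort(cls$proportion, decreasing = TRUE), c(0.625, 0.375))
  expect_equal(sum(cls$proportion), 1)

  # duplicating every read leaves proportions unchanged
  dbl <- summarize_composition(a[rep(1:100, 2), ], "domain")
  expect_equal(dbl$proportion, dom$proportion)

  expect_error(summarize_composition(a, "species"), "unknown rank")
})
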