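b62 <- blosum62_stopless()

test_that("the pure-R reference DP agrees with true exhaustive enumeration", {
  withr::with_seed(41, {
    for (i in 1:12) {
      q <- random_peptide(sample(2:4, 1))
      s <- random_peptide(sample(2:4, 1))
      expect_equal(sw_score_ref(q, s, b62, 11, 1),
                   sw_score_enum(q, s, b62, 11, 1),
                   label = paste(q, s))
    }
  })
})

test_that("Smith-Waterman scores match the independent reference DP", {
  withr::with_seed(42, {
    for (i in 1:200) {
      q <- random_peptide(sample(2:8, 1))
      s <- random_peptide(sample(2:8, 1))
      got <- smith_waterman(q, s)$score
      expect_equal(got, sw_score_ref(q, s, b62, 11, 1),
                   label = paste(q, s))
    }
  })
})

test_that("self-alignment score is the BLOSUM62 diagonal sum", {
  pep <- "HEAGAWGHEE"
  expected <- sum(diag(b62)[match(strsplit(pep, "")[[1]], rownames(b62))])
  r <- smith_waterman(pep, pep)
  expect_equal(r$score, expected)
  expect_equal(r$identity, 1)
  expect_equal(r$aligned_cols, nchar(pep))
})

test_that("alignments with no positive-scoring pair report score 0", {
  # G vs W scores -2 under BLOSUM62
  r <- smith_waterman("GGGG", "WWWW")
  expect_equal(r$score, 0)
  expect_equal(r$aligned_cols, 0)
  expect_equal(r$q_aln, "")
})

test_that("Smith-Waterman agrees with Biostrings on longer pairs", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  withr::with_seed(43, {
    for (i in 1:20) {
      q <- random_peptide(60)
      s <- random_peptide(150)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
        substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
      expect_equal(smith_waterman(q, s)$score, Biostrings::score(pa))
    }
  })
})

test_that("Karlin-Altschul statistics match the closed form", {
  sc <- scoring_scheme()
  ka <- karlin_altschul(100, sc, 100, 1e6)
  expect_equal(ka$bit_score, (26.7 - log(0.041)) / log(2), tolerance = 1e-12)
  expect_equal(ka$evalue, 100 * 1e6 * 2^(-ka$bit_score), tolerance = 1e-12)

  # one extra bit halves E at fixed m, n
  s1 <- karlin_altschul(10, sc, 50, 1e4)
  raw_for_one_bit <- log(2) / sc$lambda
  s2 <- karlin_altschul(10 + raw_for_one_bit, sc, 50, 1e4)
  expect_equal(s2$evalue, s1$evalue / 2, tolerance = 1e-9)

  # S = 0 limit: E = m * n * K
  s0 <- karlin_altschul(0, sc, 30, 1e3)
  expect_equal(s0$bit_score, -log(0.041) / log(2), tolerance = 1e-12)
  expect_equal(s0$evalue, 30 * 1e3 * 0.041, tolerance = 1e-9)
})

test_that("translated search finds planted reads with correct coordinates", {
  refs <- small_refs()
  cds <- refs$cds$seq[refs$cds$category == "gene"][1]
  src <- refs$cds$ref_id[refs$cds$category == "gene"][1]
  # in-frame +2 fragment: prepend one base to a codon-aligned substring
  frag <- paste0("G", substr(cds, 31, 210))
  reads <- tibble::tibble(read_id = "p1", seq = frag)
  hits <- search_reads(reads, refs$curated)
  expect_gt(nrow(hits), 0)
  best <- hits[1, ]
  expect_equal(best$ref_id, src)
  expect_equal(best$identity, 1)
  expect_equal(best$frame, 2L)
  expect_true(best$q_start >= 1 && best$q_end <= nchar(frag))
  expect_true(best$q_start < best$q_end)

  # minus-strand read: frame negated, coordinates reversed
  hits_rc <- search_reads(tibble::tibble(read_id = "p1rc",
                                         seq = reverse_complement(frag)),
                          refs$curated)
  best_rc <- hits_rc[1, ]
  expect_equal(best_rc$ref_id, src)
  expect_equal(best_rc$frame, -2L)
  expect_true(best_rc$q_start > best_rc$q_end)
  expect_equal(best_rc$raw_score, best$raw_score)
})

test_that("hit bit scores and E-values satisfy their defining identities", {
  run <- standard_run()
  h <- run$curated_hits
  sc <- scoring_scheme()
  n_db <- sum(nchar(standard_refs()$curated$seq))
  expect_equal(h$bit_score, (sc$lambda * h$raw_score - log(sc$K)) / log(2),
               tolerance = 1e-9)
  m <- vapply(seq_len(nrow(h)), function(i) {
    read <- standard_sim()$reads$seq[
      match(h$read_id[i], standard_sim()$reads$read_id)]
    k <- abs(h$frame[i])
    (nchar(read) - k + 1) %/% 3
  }, numeric(1))
  expect_equal(h$evalue, m * n_db * 2^(-h$bit_score), tolerance = 1e-9)
  expect_true(all(h$identity >= 0 & h$identity <= 1))
  expect_true(all(h$evalue <= 1e-6))
})

test_that("shuffled reads yield E-values consistent with the null model", {
  refs <- small_refs()
  e0 <- 0.01
  withr::with_seed(44, {
    shuffled <- vapply(1:200, function(i) {
      paste(sample(strsplit(random_dna(290), "")[[1]]), collapse = "")
    }, character(1))
    reads <- tibble::tibble(read_id = paste0("n", 1:200), seq = shuffled)
    hits <- search_reads(reads, refs$curated, evalue_cutoff = e0)
    expect_lte(nrow(hits), 10 * e0 * 200)
  })
})

test_that("searching an empty database or empty peptide errors cleanly", {
  refs <- small_refs()
  expect_error(search_reads(tibble::tibble(read_id = "r", seq = "ACGT"),
                            refs$curated[0, ]), "empty")
  expect_error(smith_waterman("", "MA"), "non-empty")
})
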