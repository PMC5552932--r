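test_that("reference generation is deterministic and honors parameters", {
  a <- make_reference_sets(seed = 5, n_families = 3, n_taxa_per_family = 2)
  b <- make_reference_sets(seed = 5, n_families = 3, n_taxa_per_family = 2)
  expect_identical(a, b)

  expect_setequal(unique(a$curated$gene_family), c("narG", "napA", "nxrA"))
  # background is a strict superset of the curated proteins
  expect_true(all(a$curated$seq %in% a$background$seq))
  expect_gt(nrow(a$background), nrow(a$curated))
  # SSU set spans three domains
  doms <- vapply(lineage_split(a$ssu$lineage), `[`, character(1), 1)
  expect_setequal(unique(doms), c("Bacteria", "Archaea", "Eukaryota"))

  full <- make_reference_sets(seed = 5)
  expect_setequal(unique(full$curated$gene_family),
                  c("narG", "napA", "nxrA", "nirK", "nirS", "nor", "nod",
                    "nosZ", "nrfA", "hao", "hzsA", "amoA", "nifH"))
})

test_that("divergence-0 decoys are identical to their sources", {
  r <- make_reference_sets(seed = 9, n_families = 2, n_taxa_per_family = 1,
                           divergence = 0)
  dec <- r$background[startsWith(r$background$ref_id, "dcy_"), ]
  src <- sub("^dcy_", "", dec$ref_id)
  expect_equal(dec$seq, r$curated$seq[match(src, r$curated$ref_id)])
  expect_error(make_reference_sets(seed = 1, divergence = 0.95),
               "divergence")
})

test_that("simulation is deterministic and writes byte-identical samples", {
  refs <- small_refs()
  spec <- community_spec("det", 150,
                         family_fractions = c(narG = 0.1),
                         ssu_fraction = 0.1, decoy_fraction = 0.05)
  a <- simulate_reads(spec, refs, seed = 33)
  b <- simulate_reads(spec, refs, seed = 33)
  expect_identical(a, b)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sample(a, refs, d1)
  write_sample(b, refs, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  c <- simulate_reads(spec, refs, seed = 34)
  expect_false(identical(a$reads$seq, c$reads$seq))
})

test_that("quota rounding realizes planted fractions exactly", {
  truth <- standard_sim()$truth
  spec <- default_zone_specs(n_reads = 10000)$OAZ
  expect_equal(nrow(truth), 10000)
  counts <- table(truth$category)
  for (fam in names(spec$family_fractions)) {
    expect_equal(unname(counts[fam]),
                 round(spec$family_fractions[[fam]] * 10000),
                 label = fam)
  }
  expect_equal(unname(counts["SSU"]), spec$ssu_fraction * 10000)
  expect_equal(unname(counts["decoy"]), spec$decoy_fraction * 10000)
  # categories partition the read set
  expect_equal(sum(counts), 10000)
  expect_setequal(truth$read_id, standard_sim()$reads$read_id)
})

test_that("noiseless reads are exact substrings of their sources", {
  refs <- small_refs()
  sim <- small_noiseless_sim()
  src_seq <- c(setNames(refs$cds$seq, refs$cds$ref_id),
               setNames(refs$ssu$seq, refs$ssu$ref_id),
               setNames(refs$scaffolds$seq, refs$scaffolds$ref_id))
  ok <- vapply(seq_len(nrow(sim$reads)), function(i) {
    src <- src_seq[[sim$truth$source_ref[i]]]
    s <- sim$reads$seq[i]
    grepl(s, src, fixed = TRUE) ||
      grepl(reverse_complement(s), src, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("invalid community specs are rejected", {
  expect_error(community_spec("x", 100, family_fractions = c(narG = 0.9),
                              ssu_fraction = 0.2), "exceed")
  expect_error(community_spec("x", 100, family_fractions = c(narG = -0.1)),
               "fractions")
  expect_error(community_spec("x", 100, family_fractions = c(narG = 0.5),
                              background_fraction = 0.2), "sum to 1")
  refs <- small_refs()  # only 4 families
  spec <- community_spec("x", 50, family_fractions = c(amoA = 0.1))
  expect_error(simulate_reads(spec, refs, seed = 1), "absent")
})

test_that("largest-remainder apportionment is exact and deterministic", {
  expect_equal(largest_remainder(c(1, 1, 1), 10), c(4L, 3L, 3L))
  expect_equal(sum(largest_remainder(runif(7), 123)), 123)
  expect_equal(largest_remainder(c(0.02, 0.98), 10000), c(200L, 9800L))
  expect_equal(largest_remainder(c(0, 5), 7), c(0L, 7L))
})
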