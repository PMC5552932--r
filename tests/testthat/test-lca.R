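test_that("hit filtering applies min score, max expected and top percent", {
  hits <- tibble::tibble(read_id = "r1", ref_id = paste0("s", 1:3),
                         bit_score = c(200, 199, 197),
                         evalue = c(1e-30, 1e-29, 1e-28))
  kept <- filter_hits(hits, lca_config(top_percent = 1))
  expect_setequal(kept$bit_score, c(200, 199))

  low <- tibble::tibble(read_id = "r2", ref_id = "s9", bit_score = 49,
                        evalue = 1e-20)
  expect_equal(nrow(filter_hits(low, lca_config())), 0)

  weak_e <- tibble::tibble(read_id = "r3", ref_id = "s8", bit_score = 80,
                           evalue = 0.02)
  expect_equal(nrow(filter_hits(weak_e, lca_config())), 0)
})

test_that("strict LCA and weighted coverage behave as specified", {
  two <- c("Bacteria;Proteobacteria;Gammaproteobacteria",
           "Bacteria;Proteobacteria;Deltaproteobacteria")
  strict <- assign_lca(two, lca_percent = 100)
  expect_equal(strict$lineage, "Bacteria;Proteobacteria")

  # 3 Gamma vs 1 Delta at 50%: Gamma covers 75%
  four <- c(rep("Bacteria;Proteobacteria;Gammaproteobacteria", 3),
            "Bacteria;Proteobacteria;Deltaproteobacteria")
  w <- assign_lca(four, lca_percent = 50)
  expect_equal(w$taxon, "Gammaproteobacteria")

  # a single hit is assigned to its leaf
  one <- assign_lca("Archaea;Thaumarchaeota;Nitrososphaeria", 50)
  expect_equal(one$lineage, "Archaea;Thaumarchaeota;Nitrososphaeria")
  expect_equal(one$depth, 3)

  # an exact 50/50 split at threshold 50 stops at the branch point
  even <- assign_lca(rep(two, 2), lca_percent = 50)
  expect_equal(even$lineage, "Bacteria;Proteobacteria")
})

test_that("weighted LCA at 100% equals path-intersection on random sets", {
  pool <- ncyc:::LINEAGE_POOL
  withr::with_seed(71, {
    for (i in 1:300) {
      lin <- sample(pool, sample(1:20, 1), replace = TRUE)
      got <- assign_lca(unname(lin), lca_percent = 100)$lineage
      expect_identical(got, lca_intersection_ref(unname(lin)))
    }
  })
})

test_that("the assigned node covers at least lca_percent of hit taxa", {
  pool <- ncyc:::LINEAGE_POOL
  withr::with_seed(72, {
    for (i in 1:100) {
      lin <- unname(sample(pool, sample(2:15, 1), replace = TRUE))
      pct <- sample(c(30, 50, 75, 100), 1)
      got <- assign_lca(lin, lca_percent = pct)
      if (nzchar(got$lineage)) {
        covered <- startsWith(paste0(lin, ";"), paste0(got$lineage, ";"))
        expect_gte(sum(covered) / length(lin), pct / 100 - 1e-9)
      }
    }
  })
})

test_that("min-support promotes weak taxa to their parents", {
  a <- tibble::tibble(
    read_id = paste0("r", 1:4),
    lineage = c(rep("Bacteria;Proteobacteria;Gammaproteobacteria", 2),
                "Bacteria;Proteobacteria;Deltaproteobacteria",
                "Bacteria;Proteobacteria;Deltaproteobacteria"),
    taxon = c("Gammaproteobacteria", "Gammaproteobacteria",
              "Deltaproteobacteria", "Deltaproteobacteria"),
    depth = 3L)
  # min_support 1 is a no-op
  expect_identical(apply_support(a, lca_config(min_support = 1)), a)

  b <- a
  b$lineage[3:4] <- c("Bacteria;Proteobacteria;Deltaproteobacteria",
                      "Bacteria;Firmicutes")
  b$taxon[4] <- "Firmicutes"
  b$depth[4] <- 2L
  out <- apply_support(b, lca_config(min_support = 2))
  # the singleton Delta read climbs until it reaches a supported node
  expect_false(any(out$lineage == "Bacteria;Proteobacteria;Deltaproteobacteria",
                   na.rm = TRUE))
  expect_equal(sum(out$lineage == "Bacteria", na.rm = TRUE) +
                 sum(is.na(out$lineage)), 2)

  # a root-level singleton with min_support 2 becomes unassigned
  r <- tibble::tibble(read_id = "r1", lineage = "", taxon = "root",
                      depth = 0L)
  out_r <- apply_support(r, lca_config(min_support = 2))
  expect_true(is.na(out_r$lineage))
})

test_that("classify_reads joins lineages, filters and assigns", {
  lineages <- c(s1 = "Bacteria;Proteobacteria;Gammaproteobacteria",
                s2 = "Bacteria;Proteobacteria;Deltaproteobacteria",
                s3 = "Archaea;Thaumarchaeota;Nitrososphaeria")
  hits <- tibble::tibble(
    read_id = c("r1", "r1", "r1", "r2", "r3"),
    ref_id = c("s1", "s1", "s2", "s3", "s1"),
    bit_score = c(100, 100, 100, 80, 40),
    evalue = 1e-12)
  out <- classify_reads(hits, lineages, lca_config(lca_percent = 50))
  # r1: 2 Gamma + 1 Delta -> Gamma covers 2/3
  expect_equal(out$taxon[out$read_id == "r1"], "Gammaproteobacteria")
  expect_equal(out$lineage[out$read_id == "r2"],
               "Archaea;Thaumarchaeota;Nitrososphaeria")
  # r3's only hit is below min_score 50: the read is unassigned (absent)
  expect_false("r3" %in% out$read_id)

  expect_error(classify_reads(hits, lineages[1:2], lca_config()),
               "no lineage")
})

test_that("noiseless reads classify to an ancestor-or-self of the truth", {
  refs <- small_refs()
  sim <- small_noiseless_sim()
  kept <- filter_by_length(sim$reads)
  ch <- search_reads(kept, refs$curated)
  ex <- kept[kept$read_id %in% unique(ch$read_id), ]
  bh <- search_reads(ex, refs$background)
  rec <- compute_bsr(ch, bh)
  keep <- apply_cutoffs(rec)$kept
  bg_lin <- setNames(refs$background$lineage, refs$background$ref_id)
  asg <- classify_reads(bh[bh$read_id %in% keep$read_id, ], bg_lin)
  truth <- sim$truth[match(asg$read_id, sim$truth$read_id), ]
  ok <- startsWith(paste0(truth$source_lineage, ";"),
                   paste0(asg$lineage, ";")) | asg$lineage == ""
  expect_gte(mean(ok), 0.99)
})
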