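# Shared fixtures. The heavy study-condition simulations are computed once
# per test run and cached; small fixtures are built fresh where used.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small reference set shared by fast unit tests
small_refs <- function() {
  memo("small_refs", make_reference_sets(
    seed = 11, n_families = 4, n_taxa_per_family = 2, divergence = 0.7,
    protein_len_range = c(100, 160), ssu_len = 900,
    n_background_extra = 4))
}

# a small noiseless sample over the small reference set
small_noiseless_sim <- function(n_reads = 400) {
  memo("small_noiseless_sim", {
    spec <- community_spec(
      "tiny", n_reads,
      family_fractions = c(narG = 0.06, napA = 0.05, nxrA = 0.04,
                           nirK = 0.05),
      ssu_fraction = 0.10, decoy_fraction = 0.08,
      error_model = error_model(0, 0, 1))
    simulate_reads(spec, small_refs(), seed = 21)
  })
}

# study-condition standard simulation: 10,000 reads, divergence-0.7 decoys,
# default error model, surface-zone composition
standard_refs <- function() memo("standard_refs",
                                 make_reference_sets(seed = 101))

standard_sim <- function() {
  memo("standard_sim", {
    spec <- default_zone_specs(n_reads = 10000)$OAZ
    simulate_reads(spec, standard_refs(), seed = 202)
  })
}

# full pipeline result on the standard simulation (cached; several
# acceptance blocks and sanity tests read different outputs from it)
standard_run <- function() {
  memo("standard_run", run_pipeline(standard_sim()$reads, standard_refs(),
                                    sample_id = "OAZ"))
}

# noiseless variant of the standard simulation: searches + BSR only
noiseless_bsr <- function() {
  memo("noiseless_bsr", {
    spec <- default_zone_specs(n_reads = 10000,
                               error_model = error_model(0, 0, 1))$OAZ
    sim <- simulate_reads(spec, standard_refs(), seed = 303)
    kept <- filter_by_length(sim$reads)
    ch <- search_reads(kept, standard_refs()$curated)
    ex <- kept[kept$read_id %in% unique(ch$read_id), , drop = FALSE]
    bh <- search_reads(ex, standard_refs()$background)
    list(sim = sim, curated_hits = ch, background_hits = bh,
         bsr = compute_bsr(ch, bh))
  })
}
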