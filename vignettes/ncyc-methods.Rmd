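---
title: "Profiling nitrogen-cycle marker genes in sediment metagenomes with ncyc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling nitrogen-cycle marker genes in sediment metagenomes with ncyc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncyc)
```

## The problem

Shotgun metagenomes from stratified sediments contain fragments of the
diagnostic genes of the nitrogen cycle — nitrate reductases (*narG*, *napA*),
nitrite:nitrate oxidoreductase (*nxrA*), nitrite reductases (*nirK*, *nirS*,
*nrfA*), nitric oxide reductase/dismutase (*nor*, *nod*), nitrous oxide
reductase (*nosZ*), hydrazine synthase (*hzsA*), ammonia monooxygenase
(*amoA*), hydroxylamine oxidoreductase (*hao*) and nitrogenase (*nifH*) —
mixed with SSU rRNA fragments and a large excess of unrelated DNA. `ncyc`
turns raw reads into per-gene, per-depth abundance profiles by:

1. **length QC** — keep reads strictly longer than 100 nt;
2. **SSU rRNA recruitment** — map reads to an SSU reference set, confirm by
   nucleotide similarity search, assign lineages, summarize composition;
3. **translated search** — six-frame Smith–Waterman of every read against a
   curated protein database of the marker families (E ≤ 10⁻⁶);
4. **bit-score-ratio (BSR) curation** — re-search recruited reads against a
   comprehensive "background" protein set and reject reads whose closest
   relative lies outside the target family;
5. **LCA classification** — MEGAN-style taxonomic binning of curated reads
   from their background hits;
6. **quantification** — normalized read counts (nrc), proportional gene
   distributions, marker-gene:16S ratios, per-genus identity breakdowns.

A synthetic-community generator produces three depth-zone samples with known
ground truth so every stage is testable end to end without any downloads.

## The statistics underneath

**Local alignment.** All searches use full Smith–Waterman (affine gaps,
Gotoh recurrences, implemented in C++). Protein searches score with BLOSUM62
(gap open 11, extend 1); a gap of length $L$ costs $o + Le$. Stop codons
translate to `*` and score −1000 against everything, so an alignment never
crosses a stop: the local alignment simply ends there. Traceback is
deterministic (diagonal ≻ gap-in-subject ≻ gap-in-query at equal score; the
reported alignment ends at the maximal cell with the smallest query, then
subject, coordinate), so identical inputs give byte-identical outputs.

**Karlin–Altschul statistics.** Raw scores $S$ become bit scores
$S' = (\lambda S - \ln K)/\ln 2$ and E-values $E = mn\,2^{-S'}$ with the
standard gapped BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$ (protein)
and $\lambda = 0.625$, $K = 0.41$ for the match +2 / mismatch −3 nucleotide
scheme of the SSU confirmation search. The search space uses
$m$ = translated frame length (residues) and $n$ = total database length —
the simplest published convention, chosen so results are reproducible
bit-for-bit; composition-based adjustments are out of scope. Cutoffs written in
the "10E−6" tool notation are read as $10^{-6}$; the cutoff is a
configurable field of `run_config()`.

**SSU mapping.** The recruitment stage scores match +1, mismatch −2, each
inserted read base −3, each deleted base −3 (linear per-base costs — the
stated parameters are per-operation costs with no open/extend split). A
mapping is accepted only if ≥ 50% of the read aligns (`length_fraction`)
and ≥ 80% of aligned columns are identities (`similarity_fraction`,
interpreted as identities over aligned columns, the mapping-tool
convention). Acceptance picks the best-scoring *acceptable* reference, ties
broken by reference id. An exact 16-mer prescreen skips reads sharing no
word with the reference set; at 80% identity over half a read an exact
16-mer survives with near certainty, while a 290-nt random read tests
~275 words against ~3×10⁴ reference words for a chance pass-through of
roughly 0.2% (at k = 12 the same arithmetic gives ~40%, which is why 16 is
the default). `prescreen_k = 0` disables it; the mapping-acceptance
monotonicity property is unaffected because the prescreen is
identity-blind.

**BSR curation.** For each read with a curated hit,
$\mathrm{BSR} = \max S'_\text{curated} / \max S'_\text{background}$.
Because the background set is constructed (and, for real data, assumed) to
be a superset of the curated proteins under one scoring scheme, BSR ≤ 1,
with true family members at 1 (their best background hit is the identical
curated protein) and out-of-family homologs well below. The ratio is
oriented curated/background so cutoffs live in (0, 1]; per-gene cutoffs are
mandatory configuration with default 0.8. Reads with no background hit keep
ratio 1 and are flagged — absence of a better generalist hit is no evidence
of a false positive.

**LCA classification.** Hits below 50 bits or above E = 0.01 are dropped;
per read, only hits within 1% of the best bit score are used (the
`top_percent` filter). "LCA percent 50" is implemented as greedy descent:
starting at the root, descend while **exactly one** child subtree covers
≥ 50% of the retained hits; if several children qualify (possible at
thresholds ≤ 50) the descent stops and the shallower node wins. At 100%
this reduces to the strict path-intersection LCA. `min_support` moves reads
on taxa with too few reads to the parent (the study value 1 is a no-op);
`max_support_percent = 0` and `min_complexity = 0` disable their filters,
and a non-zero `min_complexity` warns and is ignored. The *napA*/*narG*
split is resolved by the gene-family labels carried on curated references
rather than an external orthology resource — identical in effect when the
curated set is correctly labeled.

**Quantification.** The cross-sample unit is the normalized read count
$$\mathrm{nrc} = \frac{\text{gene read count} \times 10^9}
{\text{total metagenome read count} \times \text{average gene length (nt)}}$$
with the digit-grouping variant "100,00,00,000" of the source formula read
as 10⁹ — the only reading that puts nrc in the observed 0.5–92 range for
million-read samples and kb-scale genes. "Average gene length" is the mean
nucleotide length of the gene family's curated references (the averaging
set is not externally defined; it is configurable by supplying a different
database). Read counts entering nrc are post-curation counts. The
proportional panel divides each gene's nrc by the sample's summed nrc
including the 16S row — the denominator includes *all* analyzed genes, not
only displayed ones. Marker:16S ratios use the 16S nrc restricted to the
host group (e.g. *amoA* against Marine-Group-I 16S), approximating per
genome gene dosage.

## The synthetic community

`make_reference_sets()` builds the three databases from scratch: each
marker family descends from a random ancestral protein (default 120–260
residues) with members at 15% within-family divergence hosted by plausible
genera (anammox genes in *Brocadiales*, archaeal *amoA*/*nirK* in
*Nitrosopumilus*, and so on); coding sequences are reverse-translated with
random synonymous codons (genetic code 11). The background set is the
curated proteins plus one decoy homolog per member at 70% divergence
(default) plus unrelated random proteins. SSU references are generated
hierarchically (domain ancestors at 20% from a common root, genus
references at 10% within domain) so within-domain similarity exceeds
cross-domain similarity.

`simulate_reads()` plants fragments at configured read fractions using
deterministic largest-remainder quotas, so planted counts are exact
(`multinomial = TRUE` restores sampling). Read lengths are truncated-normal
(default mean 290 nt, sd 60, minimum 30 — matching the 289–296 nt per-zone
averages of Ion-Torrent-era sediment libraries, which the three default
zone specs use per zone); positions are uniform, strands random. The error
model applies substitutions at 0.004/base and indels at 0.004/base with a
3× multiplier inside homopolymer runs — about 1% total error, indel
dominated, Ion-PGM-like. Insertions duplicate the local base and deletions
drop it (homopolymer over/under-calls). These defaults were fixed from
platform realism plus a feasibility argument: an indel frameshifts a fixed
reading frame, so the per-codon break rate (~0.018) must leave clean
segments longer than the ~20 residues an E ≤ 10⁻⁶ hit needs — at these
rates essentially every planted read stays detectable, as on the real
platform.

The default three-zone study (`default_zone_specs()`) encodes the
qualitative depth structure of the emulated system: marker and SSU
fractions decline with depth, ammonia-oxidizer signal (*amoA*,
Marine-Group-I-like SSU) concentrates in the surface zone, anammox signal
(*hao*, *hzsA*, *Brocadiales* SSU) peaks in the middle zone. The absolute
fractions are free parameters of the synthetic study — the emulated system
is observational and provides no ground truth — so they were chosen once as
round, distinguishable values and are not tuned.

**What the generator does not emulate:** flowgram-level Ion-Torrent noise,
quality-score variation (constant Q30), chimeras, within-genome copy-number
variation, conserved/variable SSU domain structure, and real database
redundancy. Passing tests therefore demonstrate that the *pipeline logic*
is correct under controlled conditions, not that any particular real
sample's numbers are reproduced; the real-data values additionally depend
on multi-million-read libraries and specific reference-database releases.

## Numerical choices and degenerate inputs

* ">100 nt" is strict: a 100-nt read is removed, a 101-nt read kept.
  Mean lengths are reported rounded half-even to 2 decimals; an empty set
  reports `NA`.
* Hit tables are always ordered (query id, descending bit score, subject
  id) so runs are diffable; coordinates are 1-based inclusive, with
  query start > end marking minus-strand translated hits.
* Codons containing `N` translate to `X`, which scores via the BLOSUM62
  `X` column; residues outside the matrix alphabet are treated as `X`.
* Empty databases are errors; empty read sets and empty hit sets flow
  through as empty results. Reads with a background hit but no curated hit
  are excluded from BSR with a logged count.
* `assign_lca` at an exact 50/50 child split stops at the branch point
  (shallower node wins). Unsupported root-level reads become unassigned.
* Integer percentage shares (identity breakdowns) use largest-remainder
  apportionment so they sum to exactly 100.
* All simulation randomness flows through a single integer seed
  (`withr::with_seed`), so identical (spec, seed) pairs give byte-identical
  FASTQ and truth tables.

## Problem sizes

The shipped tests and the acceptance script exercise the study conditions
at desk scale: one 10,000-read surface-zone sample (with a noiseless twin
for the BSR-diagonal check), a 10,000-read gene-dosage sample (two *amoA*
fragments per Marine-Group-I SSU fragment at equal gene lengths, expecting
a marker:16S ratio near 2), and repeated 1,500-read samples for the
nrc-recovery correlation. These sizes keep full (unseeded) Smith–Waterman
affordable — the package favors exactness of the alignment surface over
speed, and the curated databases are small by construction.

## Known limitations

* Frame-shifted reads are recovered only through their longest in-frame
  segment, as with any fixed-frame translated search.
* The best-hit/LCA lineage assignment replaces phylogenetic tree placement;
  reads from taxa absent from the reference set are assigned to their
  nearest sampled relative.
* Per-gene BSR cutoffs for real data are a judgment call in the source
  method; here they are explicit configuration (default 0.8), and the
  simulated decoys justify the default only under the generator's
  divergence assumptions.
* E-values use fixed λ, K — no per-composition recomputation, no
  low-complexity masking.
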