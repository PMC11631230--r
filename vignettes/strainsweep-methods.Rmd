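---
title: "Methods: strain-resolved viral community dynamics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-resolved viral community dynamics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a suitable host strain is (re)introduced into a natural microbial
community, viruses that infect it — previously so rare that they sit below
the detection limit of shotgun metagenomics — can be selected and rise to
dominate their species-level population within weeks. Detecting such a
strain-level sweep from time-course metagenomes requires a chain of
analyses that each operate near the limits of read-level identity:
fragment recruitment at exact-identity tiers, metagenomic-island
detection, whole-genome viral taxonomy at the 95%/70% species/genus
thresholds, amplicon phylotype diversity, codon-level variant counting,
and whole-metagenome k-mer distances. `strainsweep` implements that chain
as a reproducible pipeline, driven by a synthetic community generator that
plants every structure the analysis is supposed to recover — so each stage
is testable against ground truth without any sequence download.

The study system being emulated is a hypersaline crystallizer pond spiked
with a *Salinibacter ruber* host strain: a viral genus of two species
(genomes 44–46 kb, GC ≈ 63%), one species split into nine intra-species
variant groups, a species-specific hypervariable island, a rare genotype
sweeping between 0 h and 672 h, and unrelated background reads.

## The synthetic community generator

`community_config()` + `simulate_genus()` build the genus from a single
random backbone:

* **Ancestry.** One backbone per genus; each species ancestor is derived
  from it, each variant-group ancestor from its species ancestor, and each
  genome from its group ancestor. Species 1 carries `n_groups` groups
  (default 9), the last being a singleton — the sweep genotype. All other
  species are singleton genomes, mirroring a genus in which one species is
  known from a single isolate.
* **Mutation model.** Divergence parameters are per-lineage probabilities
  of *resampling* a site from the genome-wide base composition
  (i.i.d. site resampling). Back-substitutions therefore occur, GC content
  is stationary, and the realized pairwise divergence has the closed form
  `planted_divergence(p1, p2, gc) = (p1 + p2 - p1*p2) * (1 - sum(q^2))`,
  which the generator's tests verify by direct site counting. Only
  substitutions are modelled — no indels — so identity arithmetic is exact
  and ungapped alignment suffices downstream.
* **Islands.** Island intervals diverge faster than the backbone at the
  species level (`island_divergence`, default 0.30 per lineage) *and* at
  the group level (`island_group_divergence`, default 0.10). The latter is
  essential: a metagenomic island is, by definition, a region that is
  hypervariable among co-existing variants of one species, so reads from
  other groups must fall below the 0.95 recruitment floor inside the
  island while staying above it on the backbone. With the defaults the
  planted within-species identity is ≈ 0.96 (above the 0.95 species
  threshold) and between-species identity ≈ 0.82 (inside the 0.70–0.95
  genus window); `simulate_genus()` verifies both post hoc and rejects
  configurations that break them. A degenerate all-zero-divergence
  configuration is allowed (all genomes identical) since no structure is
  requested.
* **ORFs.** Forward-strand ORFs of 750 nt are tiled every 1500 nt
  (~50% coding, matching the roughly-half-annotatable gene content of the
  real genomes) and planted as annotation. Coding regions are generated
  codon-wise excluding stop codons, with the codon GC parameter solved
  numerically so the genome-wide GC stays on target (0.63 ± 0.01).
  Mutations may later introduce internal stops — deliberately, since real
  strain variants carry pseudogenes.
* **Composition.** Per-time-point relative abundances over all read
  sources sum to 1: background (unrelated random genomes) 0.45, species 1
  in total 0.52, species 2 0.03. The species-1 total is held constant
  while the sweep genotype replaces its conspecifics — a within-species
  selective sweep, which is what the island-fill observation implies: at
  the end of the experiment the selected genotype's island variant
  dominates its species population. The absolute numbers are a desk-scale
  rescaling: at 5000 × 250 bp reads per sample they give the focal species
  ~14× coverage, comparable to the recruitment plots the analysis is
  designed around, whereas the real ponds' relative abundances (fractions
  of multi-gigabase metaviromes) are not reproducible at this read count
  and are out of scope.
* **Sweep trajectory.** The sweep genotype's abundance follows a logistic
  in time pinned to `f0` (default 1e-4: expected 0.5 reads per 5000-read
  sample at t0, i.e. below the detection limit) and `f_end` (default 0.5).
  The midpoint sits at the middle of the time course (336 h for 0–672 h).
  Placing it at the median *sampling time* (168 h) was considered and
  rejected: with f0 four orders of magnitude below f_end such a curve
  saturates by 336 h and the two final abundances become equal within
  binomial sampling noise, which would make the monotone rise of the
  sweep genotype undecidable at this sequencing depth.
* **Reads.** Uniform start positions, fixed read length (250 bp),
  per-base substitution errors (0.005; one of the three other bases).
  Read ids encode nothing about origin; origins live only in the truth
  record, which also stores per-time-point abundances and island
  coordinates for parameter-recovery tests. Each operation draws from a
  private RNG stream derived from the config seed plus a fixed offset,
  so regeneration is byte-identical and stages are independently
  reproducible.
* **Amplicons.** `simulate_amplicon_pool()` draws amplicon-length reads
  from named phylotype sequences at given frequencies with a default
  error rate of 0.001 — lower than the shotgun error rate, emulating
  quality-filtered, merged amplicon reads. At 100%-identity clustering
  every surviving error creates a new singleton phylotype, as in the real
  metabarcoding data, so the error rate directly controls phylotype
  inflation.

What the generator does *not* emulate: indels and structural variation,
quality-score error profiles, genome-length variation within the genus,
GC heterogeneity along the genome, chimeras, and host (16S) community
structure. Tests passing on this generator therefore demonstrate the
correctness of the analysis logic under the stated model, not robustness
to artefacts the model excludes.

## Fragment recruitment

`align_read_local()` is an ungapped seed-and-extend aligner: exact k-mer
seeds (default k = 15) on both strands locate candidate diagonals, and on
each diagonal the maximal-scoring ungapped segment (match +1, mismatch −1)
is found by a streaming maximum-subarray scan. Because the simulator is
substitution-only, ungapped alignment is lossless here. Ties are resolved
canonically — higher score, '+' strand first, smaller genome start,
shorter span; within a diagonal the shortest maximal segment, so aligned
spans begin and end with matches and carry no zero-sum flanks. The
acceptance suite checks exact agreement (score, coordinates, strand,
identity) with an independent per-diagonal dynamic-programming oracle on
1000 random instances, and the optimal score against Smith–Waterman with
gaps forbidden.

`recruit_best_hits()` keeps, per read, the single best placement across
genomes passing the read-coverage filter (≥ 0.70 of the read aligned;
the boundary is implemented as inclusive, a documented choice since the
source convention is ambiguous) and an identity filter. Identity is
matches / alignment columns over the aligned span. Abundance tiers follow
the recruitment conventions of the field:

* **genotype abundance** (`genotype_abundance()`): reads at 100% identity
  and ≥ 70% coverage; normalized abundance =
  (recruited nt / metagenome nt × 100) / genome size in Kbp; reports
  multiply by 1000 for display.
* **population capture** (`population_capture()`): denominator = reads at
  ≥ 95% identity (the species threshold), numerator = reads at exactly
  100% identity over the aligned span; the capture percentage estimates
  the fraction of the natural species-like population represented by the
  isolate genotype. Undetected populations (no reads ≥ 95%) report NA
  rather than 0.
* **fold change**: ratio of consecutive abundances; a zero previous
  abundance flags "below detection" and reports NA rather than infinity.

## Metagenomic islands

The published analyses identify islands visually on recruitment plots;
`detect_islands()` operationalizes that: depth profiles are computed at an
identity floor of 0.95, scanned in non-overlapping 500 bp windows, and
windows whose mean depth is ≤ 0.2 × the genome-wide *median* depth (median,
so the island itself cannot drag the reference level down) are merged;
runs ≥ 1000 bp are reported. Genomes whose median depth does not exceed 5×
are called absent rather than scanned. `island_timecourse()` re-scores t0
islands in every sample; an island whose depth ratio reaches 0.8
(inclusive) counts as filled. All five parameters are exposed in
`run_config()`.

## Taxonomy

* **Dereplication** (`dereplicate_genomes()`): genomes < 43 kb dropped;
  longest-first greedy retention, a candidate being redundant when it
  aligns to a retained genome at identity 1.0 over ≥ 80% of its length.
* **Intergenomic similarity** (`intergenomic_similarity()`): the shorter
  genome is fragmented into 1 kb windows every 500 bp, each placed with
  the read aligner; identity is the alignment-weighted mean, aligned
  fractions are union coverages, and the similarity is
  100 × identity × min(aligned fractions) — a deliberately simple,
  documented stand-in for whole-genome intergenomic-similarity tools
  ("VIRIDIC-style").
* **Species and genus** (`assign_species_genus()`): single-linkage
  connected components at ≥ 70 (genus) and, within genera, > 95
  (species) — the pairwise ICTV threshold rule operationalized as graph
  components; strictly-greater at species rank so a pair at exactly 95 is
  not one species.
* **AAI** (`pairwise_aai()`): all-vs-all positional protein identity over
  the aligned overlap (the shorter protein; no indels are modelled),
  reciprocal best matches retained, identities below 0.3 discarded as
  non-matches, proteins shorter than 50 aa excluded. The overlap
  denominator and the length floor mirror the local-alignment semantics
  and significance floor of reciprocal-best-match AAI tools; counting
  end-gaps instead (a "global" denominator) was tried and rejected
  because premature stop codons — which the mutation model produces
  naturally — then dominate the dissimilarities and group recovery
  collapses.
* **Groups** (`cluster_intraspecies_groups()`): dissimilarity
  d = 1 − AAI/100, average-linkage clustering, cut (by default) in the
  largest gap between consecutive merge heights; a fixed group count or
  cut height can be requested instead, since whether the original nine
  groups came from a fixed cut or visual inspection is not stated.
  Bray-Curtis over AAI profiles is available as `method = "bray_profile"`
  but is not the default: it compresses the planted 10× divergence
  contrast enough that the singleton sweep group becomes inseparable from
  within-group noise in a sizeable fraction of simulations. Each group's
  reference is its longest genome (ties: fewest ambiguous bases, then
  lexicographic id); "most complete" beyond length is not operationalized.

## Diversity

* **Phylotypes** (`phylotype_profile()`): reads sharing no exact 21-mer
  with the reference genomes are discarded (a deterministic stand-in for
  an alignment e-value filter), then survivors collapse at 100% identity
  and coverage — exact duplicates plus exact-substring containment on
  either strand, represented by the longest sequence. This is the chosen
  reading of "clustered at 100% identity and coverage"; abundance-sorted
  greedy containment is exactly what cd-hit-est's -c 1 -aS 1 does for
  equal-length-or-contained sequences.
* **Rarefaction** (`rarefy_phylotypes()`): a single draw without
  replacement to the target depth, deterministic per seed; no averaging,
  matching how the real samples were normalized to a common depth before
  diversity estimation.
* **Shannon** (`shannon_index()`): H′ = −Σ p ln p, natural log, via
  vegan.
* **Codon variants** (`orf_pileup()` + `codon_variant_counts()`): only
  reads spanning all three positions of a codon contribute to it. Codons
  below 5× coverage are skipped; an alternative codon is counted only
  with ≥ 4 supporting reads *and* ≥ 1% frequency (the percent reading of
  the frequency flag, matching the convention of the variant-counting
  tool these thresholds come from); each counted alternative is
  classified synonymous/nonsynonymous by the standard genetic code, and
  per-ORF totals sum read support, giving pN/(pN+pS) (NA when nothing is
  counted). Reverse-strand ORFs are handled by reverse-complementing
  codons into coding orientation.

## Metagenome distances

`minhash_sketch()` counts canonical k-mers (k = 21, the usual tool
default; the study's k is not stated), discards singletons
(multiplicity < 2, the read-mode error filter), hashes with a fixed
64-bit mixer truncated to 53 bits (so hash values are exact doubles in R),
and keeps the bottom 10000. `mash_distance()` estimates Jaccard similarity
from the bottom sketch of the merged hash sets and applies
D = −(1/k)·ln(2j/(1+j)), capping an empty intersection at D = 1. The
acceptance suite checks the sketch distance against an exact-Jaccard
oracle computed from full k-mer sets.

## Pipeline and determinism

`run_pipeline()` simulates an amended pond and an unamended control from
the same genomes (the control keeps the sweep genotype at f0; its read
stream uses a fixed seed offset so the two ponds are independent), then
runs taxonomy, competitive recruitment against the group references,
abundance and fold change for every reference, single-genome recruitment
against the sweep reference for islands/capture/codon variants, amplicon
diversity at a locus inside the island, and Mash distances between all
samples. All stage outputs are plain FASTA/FASTQ/BED/TSV/JSON, each
readable by the package's own readers; the log records the fully resolved
configuration and package version, and contains no timestamps, so a rerun
with the same config and seed is byte-identical. Stage outputs are always
recomputed (no caching): a full default run takes well under ten minutes
on one CPU, so content-hash caching would add failure modes without
meaningful savings.

Problem sizes used by the test suite: the default experiment (18 viral
genomes of ~45 kb, 5 time points × 5000 reads × 2 ponds) for end-to-end
checks; 20 independent seeds for sweep and taxonomy recovery; 200 pools
for capture calibration; 1000 random instances for the alignment oracle;
all 4096 reference/alternative codon pairs for the variant-count oracle;
20 genome pairs for sketch accuracy. These sizes make every stochastic
check sharp (multiple standard errors of margin) while keeping a full run
of the suite in the minutes range.

## Known limitations

* Substitution-only genetics: no indel or structural variation, hence no
  gapped alignment; applying the aligner to real reads with indels will
  fragment alignments and underestimate identity.
* The island caller assumes a single dominant reference per species and
  roughly uniform coverage outside islands; strong GC-coverage bias or
  repeat-driven multi-mapping (not modelled) would need a more robust
  denominator.
* The capture estimator equates "isolate genotype" with exact sequence
  identity over the aligned span; sequencing errors deflate it by a
  factor (1 − e)^L, which cancels in comparisons at a fixed read length
  but matters for absolute interpretation.
* Phylotype containment clustering is exact-match only; it does not
  denoise, by design — diversity estimates inherit the amplicon error
  rate.
* The VIRIDIC-style similarity and positional AAI are stand-ins with the
  same thresholds and monotonicity as the published tools, not
  re-implementations of their exact scores.
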