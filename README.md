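# strainsweep

Strain-resolved dynamics of viral communities from metagenomic read
recruitment.

## What this package is for

In natural microbial communities, most viral genotypes persist at
abundances far below the detection limit of shotgun metagenomics until a
susceptible host becomes available (the "bank model"). When such a host is
added to a community — for example a *Salinibacter ruber* strain spiked
into a hypersaline pond — the viruses that infect it can sweep from
undetectable to half of their species-level population within weeks.
Demonstrating that sweep from sequence data requires analyses that operate
at the strain level: read recruitment at exact-identity tiers,
metagenomic-island dynamics, whole-genome viral taxonomy, amplicon
phylotype diversity, codon-level variant counting, and metagenome-wide
k-mer distances.

`strainsweep` implements that analysis chain for R users — microbial
ecologists and viromics researchers who want to replay, test, or adapt
this kind of strain-level time-course analysis — together with a synthetic
viral-community generator that plants every structure the analysis must
recover, so the whole pipeline is testable against ground truth without
downloading a single read.

## The quantities at the core

* **Normalized genotype abundance.** Reads recruited at 100% identity
  over ≥ 70% of the read give
  `A = (recruited nt / metagenome nt × 100) / genome size (Kbp)`,
  the per-Kbp percentage of metagenome nucleotides assigned to one
  genotype; fold change between consecutive times is
  `A(t_n) / A(t_{n-1})`.
* **Population capture.** With reads at ≥ 95% identity defining a viral
  species-like population, `capture = 100 × n(identity = 1.0) /
  n(identity ≥ 0.95)` estimates the fraction of the natural population
  represented by a cultured isolate.
* **Metagenomic islands.** Windows whose depth falls to ≤ 0.2 of the
  genome median depth (merged, ≥ 1 kb) are islands — hypervariable
  regions among co-existing strains; an island is "filled" in a later
  sample when its depth ratio reaches 0.8.
* **Viral taxonomy.** VIRIDIC-style intergenomic similarity
  (identity × min aligned fraction) with ICTV thresholds — same species
  above 95%, same genus at 70% — and intra-species groups from
  average-linkage clustering of reciprocal-best-match amino-acid identity
  (AAI).
* **Diversity.** Amplicon phylotypes at 100% identity and coverage,
  rarefied to a common depth, summarized by Shannon's H′ = −Σ p ln p; and
  per-ORF counts of synonymous/nonsynonymous codon variants
  (coverage ≥ 5, ≥ 4 reads and ≥ 1% per variant) giving pN/(pN+pS).
* **Mash distance.** Bottom-s MinHash sketches of canonical 21-mers
  (multiplicity ≥ 2, s = 10000) and D = −(1/k)·ln(2j/(1+j)).

All read placement uses the package's ungapped seed-and-extend aligner
(exact 15-mer seeds, per-diagonal maximum-subarray extension), which the
test suite verifies against a full dynamic-programming oracle.

## Worked example

Simulate the default experiment (two ponds, five time points, 5000 reads
per sample) and run the full pipeline:

```r
library(strainsweep)
cfg <- run_config(community = community_config(seed = 1))
report <- run_pipeline(cfg)          # add out_dir = "run1" to write files
summary <- report$summary

cat("genera:", summary$n_genera, " species:", summary$n_species,
    " groups in species 1:", summary$n_groups[["species_1"]], "\n")
#> genera: 1  species: 2  groups in species 1: 9

# sweep genotype abundance in the amended pond (x1000 display scale)
round(1000 * summary$sweep_abundance$amended, 2)
#> t0000h t0072h t0168h t0336h t0672h
#>   0.90   0.00   4.95 167.36 301.42

# the island called at t0 fills by the end of the experiment
subset(report$island_status, pond == "amended",
       c(sample_id, ratio, status))
#>   sample_id   ratio status
#> 1    t0000h 0.00823 island
#> 2    t0072h 0.00449 island
#> 3    t0168h 0.03551 island
#> 4    t0336h 0.63881 island
#> 5    t0672h 0.93986 filled

# amplicon diversity at the island locus collapses as the sweep fixes
subset(report$shannon, pond == "amended",
       c(sample_id, n_phylotypes, shannon))
#>   sample_id n_phylotypes shannon
#> 1    t0000h          338   4.357
#> 2    t0072h          341   4.379
#> 3    t0168h          330   4.354
#> 4    t0336h          319   3.862
#> 5    t0672h          317   2.737
```

Reading the output: the taxonomy stage recovers one genus with two
species and the nine planted variant groups. At t0 the sweep genotype is
at (or below) the detection limit — its t0 "abundance" here comes from a
couple of reads near the 100%-identity boundary — then rises
monotonically from 72 h on. Its hypervariable island recruits almost
nothing at t0 (depth ratio 0.008) and is homogeneously covered (ratio
0.94 ≥ 0.8, "filled") at 672 h, while the same interval never fills in
the control pond. Shannon diversity of the island-locus amplicon drops by
~1.6 nats in the amended pond as one phylotype takes over, and stays flat
in the control.

A thin command-line wrapper is installed with the package
(`system.file("cli", "strainsweep", package = "strainsweep")`):

```sh
Rscript inst/cli/strainsweep run --config cfg.yaml --out run1
```

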