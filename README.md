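# skincat

Decision logic for building a skin-microbiome genome catalog from
metagenome-assembled genomes (MAGs) and for the multi-level mother–infant
microbial-sharing analyses that such a catalog enables. The package is
aimed at microbiome researchers who have already run the upstream tools
(assembly, binning, CheckM/CheckM2, GUNC, fastANI, Kraken/Bracken,
MUMmer, MLST callers, protein clustering) and need the downstream
decisions — quality tiering, dereplication, catalog statistics, community
contrasts, pan-genome enrichment, strain-sharing inference — as tested,
reusable functions. A ground-truth-labeled synthetic-data generator makes
the whole pipeline runnable and testable end-to-end with no downloads.

## What it computes

* **Genome quality tiers** (MIMAG-style): high quality requires
  completeness > 90%, contamination < 5%, the 5S/16S/23S rRNAs
  (5S/18S/26S for eukaryotes), and ≥ 18 of 20 standard tRNAs;
  near-complete meets the numeric bounds only; medium quality requires
  completeness > 50%, contamination < 10%, and quality score
  *Q = completeness − 5 × contamination* > 50, judged inclusively over a
  primary and a secondary estimator. GUNC-based chimera exclusion and the
  eukaryotic-viral contig filter are included, as are CheckV-style bins
  for viral sequences.
* **Two-stage dereplication**: single-linkage clustering on ANI edges at
  99.9% (redundancy removal), then species clustering at 95% ANI with
  aligned fraction ≥ 0.30, with scored representatives
  (*completeness − 5·contamination + contamination·het/100 +
  0.5·log₁₀ N50*) and novelty assessment against reference catalogs.
* **Catalog statistics**: species-discovery rarefaction (with singleton
  exclusion), per-sample classification improvement
  *(custom − ref)/ref × 100*, prevalence summaries.
* **Community analyses**: 800k-read depth filter, rarefying, richness
  (≥ 5 reads) and Shannon index, prevalence-filtered log-transformed
  Bray–Curtis, PCoA, related-vs-unrelated dyad contrasts and longitudinal
  within-individual contrasts (two-sided Wilcoxon rank-sum), kingdom
  composition with genome-size normalization.
* **Pan-genome**: core genes at conspecific frequency ≥ 90% over
  near-complete/high-quality genomes, per-species functional-category
  odds ratios (Haldane–Anscombe corrected) with a cross-species t-test on
  log-OR and Bonferroni correction, and catalog-overlap contrasts.
* **Strain sharing**: SNV density per kb with the two-genome occurrence
  rule, related-vs-unrelated pairwise SNV tests, SNV source partition
  (infant-only / mother-only / shared), a maternal-strain sharing-fraction
  estimator, MLST sequence-type assignment, and a mother–infant ST-sharing
  permutation test (Monte-Carlo with add-one correction, exact enumeration
  for ≤ 8 families).

## Worked example

```r
library(skincat)

cfg <- scenario_config(n_families = 20, n_species = 15,
                       depth_meanlog = log(1e5), genome_length = 2e5,
                       seed = 42)
bundle <- run_pipeline(cfg, "demo-out", min_reads = 4e4,
                       pangenome_min_genomes = 8, snv_min_genomes = 8)
cat(report(bundle), sep = "\n")
```

```
# Catalog pipeline summary
Seed: 42 (stochastic sections derive from this seed)

## Genome quality tiers
- prokaryote / high_quality: 13
- eukaryote / high_quality: 3
- prokaryote / near_complete: 83
- eukaryote / near_complete: 16
- prokaryote / medium_quality: 47
- eukaryote / medium_quality: 15
- prokaryote / fail: 28
- eukaryote / fail: 3

## Catalog
- nonredundant genomes: 103
- species-level clusters: 15

## Classification improvement
- median improvement: 20.4% (IQR 15.6-24.7)

## Mother-infant sharing
- community dyad test: median related 0.538 vs unrelated 0.606, p = 0.379
- species with SNV related-vs-unrelated p < 0.01: 6 of 6
- estimated maternal-strain sharing fraction: 0.85
- ST sharing: 12 families, permutation p = 0.000999
```

Reading the summary: 177 of 208 simulated MAGs receive a quality tier,
pass into the catalog, and collapse to 103 nonredundant genomes in 15
species clusters — matching
the generator's 15 ground-truth species. The custom-database
classification gain sits at its configured ~21% median. At the strain
level all 6 species with enough mother–infant pairs show significantly
fewer SNVs between related than unrelated pairs, the estimated
maternal-strain sharing fraction (0.85) tracks the configured
transmission probability (0.7) within its sampling error at 20 families,
and 12 of 20 families share a *C. acnes*-style sequence type, far more
than random mother–infant pairings allow (permutation p ≈ 0.001). The
community-level dyad contrast is underpowered at this scale (p = 0.38);
the full-size scenario in `analysis/` shows it clearly.

## The analysis workflow

The numbered drivers under `analysis/` run one full-scale study
(67 families, 40 species) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # scenario + ground truth
Rscript analysis/02_genome_qc.R     # chimera filter, tiers
Rscript analysis/03_dereplicate.R   # 99.9% / 95% clustering
Rscript analysis/04_catalog_stats.R # rarefaction, improvement, prevalence
Rscript analysis/05_community.R     # alpha/beta diversity, dyads, PCoA
Rscript analysis/06_pangenome.R     # core/accessory, enrichment
Rscript analysis/07_sharing.R       # SNV density, sharing, ST test
```

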