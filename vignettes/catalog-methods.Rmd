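---
title: "Methods: genome catalog construction and mother-infant sharing analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome catalog construction and mother-infant sharing analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(skincat)
```

# Scope and design

`skincat` implements the decision logic of a skin-microbiome
metagenome-assembled-genome (MAG) catalog build and its downstream
mother-infant sharing analyses. It deliberately consumes *abstracted
upstream outputs* -- per-genome quality metrics, pairwise ANI edge lists,
species count matrices, SNV call tables, MLST allele profiles, and gene
presence/absence matrices -- rather than raw sequence data. Everything a
completeness estimator, an aligner, or a binner would compute is an input;
everything that turns those inputs into a catalog and into sharing
inferences is implemented and tested here.

The repository is organised as an analysis workflow: numbered drivers
under `analysis/` run the stages over one simulated study
(`01_simulate` through `07_sharing`) and write their tables under
`results/`, while every computation lives in package functions so the
tests and `scripts/acceptance.R` can call them directly. The pipeline
orchestration the drivers narrate is also available programmatically as
`run_pipeline()` / `report()`; together with the drivers this is the
package's operational interface, and no separate shell command-line tool
is provided.

# Genome quality tiers

Quality tiering is a pure predicate over the quality table:

* **high quality**: completeness > 90, contamination < 5, presence of the
  5S/16S/23S rRNAs (5S/18S/26S for eukaryotes), and at least 18 of the 20
  standard tRNAs;
* **near complete**: completeness > 90 and contamination < 5 with the
  rRNA/tRNA requirement unmet;
* **medium quality**: completeness > 50, contamination < 10, and quality
  score (completeness − 5 × contamination) > 50. The medium rule is
  *inclusive over estimators*: it may be satisfied by either the primary
  (CheckM2-style) or the secondary (CheckM-style) estimates, whereas the
  two upper tiers are judged on the primary estimates only. For
  eukaryotic MAGs the medium tier omits the quality-score clause.

All comparisons are strict, exactly as the thresholds are written;
boundary values fall to the lower tier. Two points were genuinely open
and are package decisions: (i) a viral sequence with completeness exactly
50 is assigned to the low-quality bin (the printed definitions leave the
boundary unassigned); (ii) the chimera (GUNC) exclusion -- contamination
> 0.05, clade separation > 0.45, reference representation > 0.5 -- is
read as a conjunction of all three criteria, with `rule = "any"`
available as a sensitivity switch. Eukaryotic thresholds are
estimator-agnostic: the caller maps whichever estimator backs them onto
the primary columns.

# Dereplication and species clustering

Dereplication runs in two single-linkage stages on the ANI edge list:
redundancy removal at 99.9% ANI (no aligned-fraction gate, mirroring how
duplicate recoveries of one strain are collapsed) and species clustering
at 95% ANI with an aligned fraction of at least 0.30 relative to the
larger genome. Clusters are connected components; ids are deterministic
(numbered by smallest member id), and duplicate edge records resolve to
the maximum-ANI record. The representative score is the additive
dRep-style form

```
completeness − 5 × contamination
             + contamination × strain_heterogeneity / 100
             + 0.5 × log10(N50)
```

The exact weighting used for the published catalog is not stated; the
cited tool's default form is adopted and the weights are exposed as
arguments. Ties break lexicographically by genome id so the whole stage
is order-invariant. The edge list is assumed complete for pairs above
roughly 90% similarity (the usual pre-filtering step is out of scope).
Novelty against a reference catalog is membership: a query representative
is *known* iff its species-level component contains a reference genome.

# Catalog statistics

Rarefaction subsamples nonredundant genomes on a grid of 20 evenly spaced
sizes plus the endpoint. Each replicate draws one random permutation of
the genomes and reads all sizes off its prefixes -- the standard
species-accumulation device; prefixes are uniform subsets and every
replicate's curve is monotone, so the mean curve is monotone exactly.
Singleton species can be excluded before counting, either species backed
by one genome or by one distinct sample; both definitions appear in the
source material, so both are implemented (`by_sample` is the driver
default). Whether discovery curves subsample genomes or samples was not
fully specified; genomes are used, matching the curve's stated axis.

Classification improvement is the exact per-sample formula
`(custom − reference) / reference × 100`, summarised by median and
quartiles; samples with a zero reference fraction are excluded with a
warning.

# Community analyses

Samples under 800,000 classified reads are excluded, the rest rarefied
without replacement to the minimum retained total (the published depth is
unstated; the minimum is the conventional choice). Richness counts
species with at least 5 reads; Shannon uses natural logs. Beta diversity
removes species present in at most 20% of samples, log-transforms with
pseudocount 1 (natural log; the base is unstated upstream and is
config-exposed), and computes Bray-Curtis on the transformed values.
PCoA is classical scaling of the double-centred Gram matrix; negative
eigenvalues are truncated with their magnitude reported, and explained
proportions are positive eigenvalues over the sum of absolute
eigenvalues.

The dyad contrast compares, per infant, the dissimilarity to the own
mother against a summary over unrelated mothers, with a two-sided
Wilcoxon rank-sum test (exact when both groups have at most 25
observations and no ties; normal approximation with continuity
correction otherwise). The headline summary is the per-infant *median*
over all unrelated mothers. A calibration fact discovered during
development and verified by the test suite: under that summary the null
p-value is **conservative**, not uniform -- the median of many draws is
less variable than the single related draw, and each infant contributes
one value to both groups. The `unrelated_summary = "split"` variant
therefore assigns disjoint families to the related and unrelated groups
(one rotation-matched unrelated mother each), making the groups iid
under the null and the p-value uniform up to the exact test's
discreteness. The headline analyses use the median convention; the
calibration suite checks uniformity for the split variant and empirical
type-I control for the median variant.

# Pan-genome

Species qualify with at least ten near-complete or high-quality
nonredundant genomes. Gene frequencies are computed over qualifying
genomes only -- their completeness exceeds 90%, which keeps true-core
observed frequencies above the core threshold despite incomplete
assemblies; a switch admits all nonredundant genomes. Core genes are
those at frequency **at least** 0.90 (non-strict, because the rule is
"at least 90%", unlike the strict quality thresholds). Enrichment per
species and category is the odds ratio of the 2×2 table
(core/accessory × category/other categories), with the Haldane-Anscombe
0.5 correction when a cell is zero; across species each category gets a
two-tailed one-sample t-test of log odds ratios against 0, Bonferroni
corrected. Whether that cross-species test is one-sample or two-sample
is ambiguous in the source; one-sample is the default and a two-sample
variant (logit category proportions among core vs accessory genes) is
available by flag. Unannotated genes are excluded from the category axes.
Catalog overlap reuses the same machinery with specific-versus-shared as
the first axis, for species with at least five qualifying genomes per
catalog.

# Strain sharing

SNV records are positions on the species representative. An SNV
(position + alternate allele) counts for a genome only when it occurs in
at least two conspecific genomes; per-genome density is the retained
count over the representative length (per kb), species density the mean
over genomes (including genomes with no retained SNVs), and species need
at least ten conspecific genomes. The related-versus-unrelated contrast
is a two-sided rank-sum between SNV counts of own-mother pairs and
infant × other-mother pairs, for species with at least four related
pairs; unrelated pairs pool all infant × non-own-mother genome pairs by
default, with per-infant median collapsing available to mirror the
community dyad convention.

The maternal-strain sharing fraction classifies a family-species dyad as
shared when its (minimum) related SNV count falls below the 1st
percentile of the unrelated distribution; with two well-separated modes
this recovers the generator's transmission probability.

Sequence typing is exact 7-locus profile lookup; unmatched profiles are
"novel" with the Hamming distance to the nearest known profile reported
as an aid. The sharing statistic counts families whose infant and mother
ST sets intersect. Its significance comes from permuting the
mother-to-infant pairing (the natural exchangeable unit; what is permuted
is unstated upstream). Monte-Carlo mode uses
`p = (1 + #{null ≥ observed}) / (1 + n_perm)` with the add-one
correction and `n_perm = 1000`; with at most eight families the exact
mode enumerates all pairings and returns the exact tail probability with
a `≥` orientation.

# The synthetic scenario

The generator produces ground-truth-labeled data with the statistical
structure every stage assumes. Defaults are the emulated study design: 67
mother-infant families; infants swabbed at cheek and antecubital fossa,
about a third longitudinally at both 2-3 and 12 months, the rest at 12
months; mothers once at the antecubital fossa. No distributional
parameters for these structures are published, so all distributions below
are package decisions, fixed once and documented here:

* **Community**: per-species prevalence ~ Beta(1.3, 2.2), lognormal mean
  abundances, per-subject latent Gaussians with within-family correlation
  0.5 driving both carriage (via a prevalence threshold) and abundance;
  per-species site and age log-fold shifts (SD 1.0 and 0.7); sample
  depths lognormal around 2 million classified reads with about 4-5% of
  samples under the 800k inclusion threshold.
* **Recoveries**: MAG recovery probability logistic in log10 relative
  abundance; completeness a mixture of a high Beta mode on [70, 100] and
  a uniform tail on [40, 70]; contamination exponential (mean 2.5%)
  truncated at 15% -- chosen to populate every tier boundary; strain
  heterogeneity exponential with median near 0.17%; 2% of genomes are
  chimeric in their GUNC metrics.
* **ANI structure**: conspecific pairs 96-99.5, duplicate recoveries of
  one strain at or above 99.92, between-species 80-94; aligned fractions
  0.55-0.95 within species.
* **Strains**: infinite-sites evolution on a fixed coordinate system
  (length 1 Mb by default; no indels, no recurrent mutation beyond a
  saturation guard), so SNV calling is exact column comparison. Each
  lineage diverges from the species ancestor and each genome adds a
  private terminal branch; a transmitted infant (probability `q = 0.7`,
  near the observed two-thirds of culture-confirmed sharing pairs) sits
  on the maternal lineage. With `mu = 1e-6` per site per unit time,
  related pairs differ at about 100 sites and unrelated pairs at about
  5000 -- two well-separated modes like the observed pairwise SNV
  contrast.
* **Genes**: 40% of genes truly core (frequency 1), accessory
  frequencies U-shaped (Beta(0.45, 1.1)) realised as fixed-size random
  genome subsets so accessory genes never reach frequency 1; observed
  presence thinned by completeness. Category odds among accessory genes
  default to the usual pan-genome picture (replication/defense/
  transcription accessory-enriched; metabolism/translation
  core-enriched).
* **Typing**: 7 loci with 20 alleles each; each lineage owns a profile;
  individuals carry one or two lineages and contribute 4-12 isolates.
* **Classification fractions**: reference fraction Gaussian around 0.63;
  custom fraction applies a 21% relative uplift with per-sample noise,
  truncated so custom never falls below reference.

A single master seed drives named per-stage substreams, so adding or
re-running one stage never perturbs another, and identical configs are
byte-identical on disk. All tables round-trip losslessly through the TSV
writers.

What the generator does **not** emulate: read-level error, assembly
fragmentation and binning contamination at the contig level, recurrent
or selected mutations, homologous recombination, gene gain/loss linkage,
and taxonomic misclassification. Passing tests therefore demonstrate that
the decision logic is correct and well-calibrated under the stated
statistical structure -- not that the upstream tools whose outputs are
emulated behave well on real data.

# Problem sizes and numerical choices

The analysis drivers and the acceptance script run the default scenario
(67 families, 40 species, about 2,000 genomes and 250 samples); the test
suite uses scaled-down scenarios (typically 8-40 families, 10-15 species,
genome lengths 20-100 kb) chosen so the full suite completes in a few
minutes while keeping every contrast's signal-to-noise where the
properties under test are unambiguous. Monte-Carlo property tests fix
their seeds and state their replicate counts inline. Ties in rank-sum
tests switch to the normal approximation with continuity correction;
degenerate inputs (all-zero samples, empty clusters, saturated mutation
counts, missing GUNC metrics) follow the documented fallbacks rather
than erroring where a warning suffices.

# Known limitations

* The published catalog's headline numbers (9483 MAGs, 1056 species, 77%
  classification) depend on raw reads and reference databases and are not
  reproducible from abstracted inputs; the per-table tier-count
  reproductions require the catalog's supplementary quality tables as
  external downloads.
* The phylogenetic-diversity expansion percentage reported alongside
  novelty counts is not derivable from cluster labels alone; novelty
  counting is implemented, the percentage is not.
* The negative-binomial differential-abundance fit is out of scope; only
  its stated input filters (rarefied counts, 10% prevalence) and
  significance gates (adjusted p < 0.01, two-fold change) are carried as
  constants for downstream users.
* The dRep scoring weights and several distributional choices above are
  conventions, not published values; all are config-exposed.
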