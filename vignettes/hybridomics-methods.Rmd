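---
title: "Methods and design of the hybridomics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the hybridomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hybridomics` compares two parental accessions (labelled `MH` and `MA`
throughout) with their stabilized F4 hybrid across three molecular layers:
CCGG-site cytosine methylation scored by MSAP, gene expression from RNA-seq
counts, and SNPs with their predicted coding effects. This vignette explains
the models and rules each stage implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design choices made where several readings were defensible.

## MSAP methylation scoring

MSAP digests the same genomic DNA with the isoschizomers HpaII and MspI.
Both cut unmethylated CCGG; methylation of the internal cytosine blocks
HpaII but not MspI, hemi-methylation of the external cytosine blocks MspI
but not HpaII, and full methylation blocks both. Per site and individual
the paired presence/absence calls therefore map to states:

| HpaII | MspI | state |
|---|---|---|
| 1 | 1 | unmethylated |
| 0 | 1 | internal cytosine methylated |
| 1 | 0 | hemi-methylated |
| 0 | 0 | uninformative (fully methylated) |

An individual's *methylation level* is the number of sites where the two
patterns disagree divided by the number of sites with a band in at least
one pattern. Sites absent from both patterns contribute no bands, so the
default denominator excludes them (`denominator = "informative"`); counting
every site is available as `"all"`. This is the literal reading of the
polymorphic-over-total-bands ratio; a HpaII-only band count would be an
alternative summary, which we do not use.

Replicates are combined by strict-majority consensus: a site is
group-polymorphic when more than half of the group's replicates show a
band difference, and an exact tie counts as monomorphic. Replicate
aggregation has no canonical rule in MSAP practice; majority voting is the
simplest rule that is robust to a single discordant replicate, and ties are
resolved conservatively (no event).

A site is a *demethylation event* when it is consensus-polymorphic in at
least one parent group and not in the hybrid, and a *hypermethylation
event* when it is polymorphic in the hybrid and in neither parent.
Whether a demethylation call should require one polymorphic parent or
both is a genuine choice; at-least-one is the default
(`parent_rule = "any"`) and the stricter both-parents rule is available. The generator plants
demethylation sites polymorphic in both parents, so either rule recovers
them.

## The MSAP generator

`simulate_msap()` builds one consensus pattern per group and emits
replicates (identical at `noise_rate = 0`, otherwise corrupted by
independent symmetric per-band flips; no empirical replicate-noise level
is available, so noiseless is the default and `noise_rate` is the stress
dial). The default cohort is 740 CCGG sites split over three
selective primer pairs (265/200/275), four replicates per group, target
levels 85.6% / 82.4% / 74.5% for MH / MA / F4, and 50 planted
demethylation plus 26 hypermethylation events.

These targets are jointly infeasible if every site carries a band in every
group: parents exceeding the hybrid's level by ~8-11 percentage points over
740 sites would force far more than 50 parent-only polymorphic sites. The
generator reconciles them through fully methylated (0,0) loci: the more
methylated parents carry a few dozen bandless sites, which drop out of the
level denominator while staying monomorphic for event calling. This is the
biologically natural resolution — heavily methylated genomes have more
fully blocked CCGG sites — and it lets a noise-free cohort reproduce both
the levels (to within 1/740) and the exact planted event counts.

## Differential expression

Counts are normalized by median-of-ratios size factors (computed over genes
expressed in every sample, rescaled to geometric mean 1). The per-gene test
between two groups is a negative-binomial Wald test: group means come from
normalized counts; the NB dispersion `alpha` (variance `mu + alpha*mu^2`)
is estimated per gene by method of moments from the within-group variances
pooled across the two groups and floored at 1e-8; the effect is
`log2((mu_B + 0.5) / (mu_A + 0.5))` with a delta-method standard error; and
the p-value is the two-sided normal tail of the Wald ratio, BH-adjusted per
contrast. No empirical-Bayes dispersion shrinkage is applied — at the
simulated scale the moment estimator is sufficient for the calibration and
power properties the tests check, and the implementation stays transparent.

A gene is differentially expressed at `padj < 0.05` and `|log2fc| >= 1`
(the two-fold rule, boundary inclusive), using the conventional
significance direction. Three contrasts are always computed
(F4-vs-MH, F4-vs-MA, MH-vs-MA) and the reported DEG sets partition their
union: genes DE against both parents but not between the parents form the
parent-similar/hybrid-different set; the remaining genes DE against MH form
the F4-vs-MH set; genes DE only against MA form the F4-vs-MA set. A gene DE
against both parents that is *also* DE between the parents is assigned to
the F4-vs-MH set by this priority, so the three reported counts always
sum exactly to the reported total.

In place of a shrinkage-regularized log transform, downstream clustering
uses `log2(normalized + 1)`: monotone, exact at zero and asymptotically
log2. Clustering operates on row-wise Z-scores, so a variance-stabilizing
refinement would change little; the difference matters mostly for very
low counts, which the Z-scoring de-emphasizes anyway. This is a deliberate
divergence from rlog and is stated here rather than hidden.

## Cluster structure

DE genes are standardized per gene (mean 0, s.d. 1 across the nine
samples) so that clusters group expression *shapes*. The number of clusters
is chosen by the gap statistic: `gap(k) = mean_b log(W*_kb) - log(W_k)`
with `B` reference datasets drawn uniformly over each feature's observed
range, simulation error `s_k = sd_b * sqrt(1 + 1/B)`, and the 1-SE rule
(smallest `k` with `gap(k) >= gap(k+1) - s_{k+1}`). `W_k` is the total
within-cluster sum of squares from the best of several k-means runs;
k-means itself is `stats::kmeans` started from k-means++ centers, best of
`n_restarts` seeded restarts. The observed-data curve gets more restarts
(25) than each reference (5): the selection rule compares adjacent `W_k`
values, so an under-optimized data point distorts the decision, while
reference under-optimization is averaged over `B` draws.

Clusters map to four expression-pattern categories by their centroid's
per-group means relative to the hybrid with a dead zone of `delta = 0.5`
Z-units (half a Z-unit separates "shifted" from
"similar" comfortably at the simulated noise levels and is configurable):
one parent below the hybrid beyond `delta` with the other parent inside
`delta` is under-expressed-in-one-parent, and so on; both parents shifted
the same way with `|m_MH - m_MA| <= delta` gives the both-parent
categories; anything else is unassigned.

PCA of samples uses gene-centered SVD; sample distances are Euclidean with
complete-linkage ordering (samples pre-sorted lexicographically so equal
merges resolve deterministically).

The count generator plants eight archetypes realizing the four
categories with unequal multiplicity — four
one-parent-under clusters (three MH, one MA), two one-parent-over, one
under-both, one over-both. Two of the MH-under clusters carry a small
secondary shift in MA (±0.2-0.25 of the effect) so that all eight
archetypes remain distinct directions after Z-scoring while still
categorizing as one-parent clusters. Default cluster sizes
894/1207/894/894/894/362/250/1207 give category totals
3576/2414/362/250 (6602 DE genes) inside a 20,000-gene universe — the
universe is scaled down from the full annotation set since the null genes
only need to dominate normalization and false-positive accounting.

Cluster-recovery validation runs at deliberately well-separated settings:
log2 effect 3, dispersion 0.01, baseline means 2,000-10,000, 150 genes per
cluster (plus 1,800 null genes for unbiased size factors), `B = 15`,
`k_max = 10`, 100 seeded replicates. Two points matter. First,
normalization must see the null genes: estimating size factors on DE genes
alone biases them by composition and distorts every downstream profile.
Second, high baselines keep shot noise (`1/mu`) negligible against the
dispersion so that cluster scatter is near-isotropic in Z-space; strongly
anisotropic clusters let an extra k-means center keep harvesting variance
along the long axis, which inflates the gap curve past the true k. Real
data are messier on both counts, so passing these tests shows the
machinery is correct, not that eight clusters would be recovered from any
real cohort.

## Variants

Hard filtering follows the GATK-style exclusion semantics: a record is
removed when `QD < 2`, `FS > 60`, `MQ < 40` or `ReadPosRankSum < -8`,
the standard exclusion semantics for these annotations; the direction is
configurable. A missing annotation never
fails its clause. Genotype quality requires `GQ > 15` strictly in every
sample. Zygosity comes from allelic balance `AB = alt/(ref+alt)`: `AB` in
`[0.2, 0.8]` (inclusive) is heterozygous, above homozygous-alternate,
below homozygous-reference, zero depth is a no-call. A SNP is
group-consistent when all three replicates of the group carry the
alternate allele.
Indels and multiallelic records are skipped with a counter.

SNPs map to genes by 1-based closed interval containment (GFF3
convention); UTR hits are `MODIFIER`, CDS hits are classified by codon
translation (strand-aware, standard genetic code): synonymous `LOW`,
non-synonymous `MODERATE`, stop gained or lost `HIGH`; multi-gene hits
report the maximum severity. Genes whose CDS length is not a multiple of
three are flagged and their variants skipped.

Concordance asks whether a SNP's across-group presence pattern fits its
gene's expression category. For a parent-P-specific cluster a SNP matches
when consistent in P alone, or in the other parent and the hybrid but not
P. For hybrid-specific clusters the implemented rule — the hybrid's
consistency status differs from the parents' shared status — is the
natural analogue of the parent rule, and it is exposed as a plug-in
(`match_rule`) because other readings are defensible. The overall
percentage is reported rounded to the nearest integer, with the raw value
retained.

The variant generator writes one synthetic gene model per selected DE gene
(60 bp UTRs around a single-block 300 bp CDS, random strand) and authors
the affected codons so every planted effect class is realized exactly;
default effect-class proportions follow a 642:303:6:452 split and the
default concordant fraction is 0.73 (Bernoulli per SNP, so the
recovered percentage carries binomial sampling error). A configurable
fraction of extra records is planted inside each filter's fail region.

## Enrichment

GO over-representation uses the hypergeometric upper tail against a
user-supplied background, BH-corrected within each ontology (mirroring
per-ontology reporting; a global scope is available). No parent-term
propagation is applied — annotations are taken as given, which undercounts
broad terms relative to full GO tooling. The annotation generator plants
terms into chosen clusters at an elevated rate over a uniform baseline, so
planted terms are recoverable at FDR < 0.05 while null terms stay at the
nominal false-positive rate.

## Pipeline and reproducibility

`run_pipeline()` chains the stages from a single validated configuration
(YAML or list; unknown keys are rejected before anything runs) and writes
a JSON run summary whose counts are internally consistent (DEG partition
sums, cluster sizes sum to the clustered genes, matched plus unmatched
equals total). Every stochastic step derives its seed from the single
configured seed, so identical configurations reproduce identical outputs
byte for byte. `scripts/acceptance.R` runs exactly this pipeline at the
default study conditions (with a 10-cluster, `B = 15` gap scan to keep the
resampling tractable at the 6,600-gene scale) and reports the main
computed quantities.

## Known limitations

- MSAP replicate noise is a free parameter; with noise the consensus rule
  degrades gracefully, but there is no empirical noise level to calibrate
  against.
- The moment dispersion estimator is noisy at n = 3 and the test can be
  anticonservative for genes with outlier counts; the calibration suite
  bounds the aggregate false-positive rate, not per-gene behavior.
- Gap-statistic selection is validated on well-separated synthetic
  archetypes only; on diffuse real data the 1-SE rule can under- or
  over-count clusters.
- The effect classifier handles SNPs in single-transcript gene models;
  splice sites, frameshifts and isoform-specific effects are out of scope.
- Enrichment treats annotations as flat sets; no semantic reduction of
  redundant terms is performed.
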