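---
title: "Methods: compartment-structured microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-structured microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements, the assumptions behind it, the defaults and why they were
chosen, and what the synthetic-data tests do and do not demonstrate about
real data.

## The design and its container

The package targets a paired common-garden design: plants of three
genotypes grown in two soil origins, with up to four community samples per
plant — rhizosphere soil, root endosphere, nodule endosphere, leaf.
`otu_table()` couples the OTU x sample count matrix with a per-sample
design key; the sample-name dialect `<soil><genotype><replicate><compartment>`
(e.g. `C96bN`) is parsed by `parse_sample_name()`, and `plant_id`
(soil x genotype x replicate) links the compartments of one plant for all
paired analyses. Readers accept plain TSV, the mothur "shared" layout, and
BIOM v1 JSON.

Rare OTUs are removed by a dataset-wide total-count filter
(`filter_rare_otus()`, default `min_total = 10`). Published amplicon
analyses rarely state this cutoff; 10 reads over the whole dataset is a
common convention, and the threshold is an explicit argument so replication
runs can tune it.

## Subsampling estimators

Unequal sequencing effort is equalized by rarefaction *inside* every
estimator: each iteration draws a fixed number of reads per sample without
replacement (multivariate hypergeometric — the distribution of subsampling
sequences from a finite pool of reads), computes the statistic, and the
iteration mean is reported. Defaults are a depth of 1500 reads and 1000
iterations. Samples below the depth are excluded with a warning rather than
resampled with replacement; that choice trades a little power for unbiased
estimators.

Alpha diversity uses the bias-corrected Simpson concentration
$\hat D = \sum_i n_i(n_i-1) / (N(N-1))$ (chosen for compatibility with the
common mothur implementation), reported as $1-\hat D$, and Simpson evenness
$E_D = (1/\hat D)/S_{obs}$. $E_D$ can exceed 1 for tiny, very even draws —
a documented property of the bias correction, not an error.

Responses are variance-stabilized before ANOVA: logit for the two
proportions, Box-Cox for richness with fixed per-compartment exponents
(rhizosphere $\lambda = 1.6$, root $0$, leaf $-0.2$, nodule $-0.2$);
`estimate_box_cox_lambda()` offers a profile-likelihood estimate for new
data. Logit inputs of exactly 0 or 1 — possible for evenness on degenerate
draws — are clamped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 1/(2 \cdot \text{depth})$ (half a count at the rarefaction
depth) and a warning.

`factorial_anova()` is a fixed-effects, sequential (Type I) SS analysis:
on the balanced target design the partition is order-invariant. Unbalanced
data are analysed with a warning instead of an error, because sequential
projections remain well-defined and replication runs routinely lose a few
samples to the depth filter. Tukey HSD (`tukey_hsd()`) runs on the
*transformed* scale — the scale on which the ANOVA assumptions were
arranged — and emits a compact letter display via insert-and-absorb.

## Ordination and variance partitioning

`iterative_bray_curtis()` applies the same subsampling frame to
$BC(x,y) = \sum_i |x_i-y_i| / \sum_i (x_i+y_i)$ and averages the matrix
element-wise; downstream tests run once on the averaged matrix (one test,
not one per iteration).

`nmds()` minimizes Kruskal stress-1 by iterative majorization with
monotone regression (vegan's `monoMDS` engine under `metaMDS`). The
literature phrase "1000 iterations" for NMDS is ambiguous between restarts
and optimizer steps; the package treats random restarts as the quality
dimension that matters (default 16–32, configurable) with up to 500
majorization steps each, and returns the best start, centred and rotated
to principal axes with deterministic sign.

The modified PVCA partitions community variation in three steps:

1. ordinate into the first $k$ NMDS axes (default 10);
2. per axis, fit by REML the all-random variance-component model
   `score ~ (1|soil) + (1|genotype) + (1|compartment) + (1|soil:genotype) +
   (1|soil:compartment) + (1|genotype:compartment) + (1|three-way)` and
   convert the component variances (non-negative by construction) plus the
   residual to percentages;
3. average the per-axis percentages with weights proportional to each
   axis's $R^2$ — the squared Pearson correlation between observed
   dissimilarities and distances computed from that axis alone — and
   rescale to total 100.

The REML fits use `lme4::lmer`; singular fits (component estimated at
zero) are expected and harmless here because only the variance partition is
interpreted, never the significance of a random term. Axes whose fit fails
outright are dropped with a warning and the weights renormalized. The
single-axis $R^2$ convention is one of several defensible definitions (the
per-axis values of a $k$-dimensional configuration do not sum to 1); it is
isolated in `axis_r_squared()` so it can be swapped.

`permanova()` implements Anderson's one-way pseudo-F directly —
$SS_{total} = \tfrac1N\sum_{i<j} d_{ij}^2$, within-group sums weighted by
group size, permutation p-values with the $(b+1)/(m+1)$ estimator — rather
than delegating, so that small instances can be enumerated exhaustively
(`exhaustive = TRUE`, two groups); the test suite cross-checks it against
`vegan::adonis2`. PerMANOVAs are run one-way within each compartment
because the compartments are so different that a pooled test is dominated
by that axis.

## Paired effect sizes, core taxa, presence sets

For a compartment pair (A, B) and each of the `top_n = 20` most abundant
OTUs, the per-plant effect size is $(rel_A - rel_B)/(rel_A + rel_B)$:
$+1$/-$1$ mean exclusive occurrence in A/B, and plants where the OTU is
absent from both samples are excluded from that OTU's set (treating such
pairs as 0 would shrink the quintiles toward the centre with no
information). Per OTU the quintiles and a two-sided paired Wilcoxon
signed-rank test are reported (exact for $n \le 25$ without ties, normal
approximation with tie correction otherwise).

Core taxa are OTUs present (>= 1 read) in strictly more than 50% of a
compartment's samples; compartment presence for the Venn accounting is
strictly more than 10 reads summed within the compartment. Both thresholds
are arguments. Monte-Carlo chi-square tests (`monte_carlo_chi_square()`)
simulate the null with both margins fixed (Patefield sampling), 10,000
replications by default.

## Null-model assembly inference

`raup_crick()` follows the randomization recipe for Raup-Crick beta
diversity: null assemblages preserve each sample's observed richness and
draw species without replacement with probability proportional to their
occurrence frequency in a reference set. The species pool defaults to the
samples of the two compartments being paired (`pool = "pair_compartments"`),
on the logic that a nodule can realistically recruit what occurs in roots
and nodules of the experiment; `pool = "all"` is available. With
$p = (\#\{\text{null} > \text{obs}\} + 0.5\,\#\{\text{ties}\}) / R$,
$\beta_{RC} = 2p - 1$; $\beta_{RC} < -0.95$ flags pairs sharing more taxa
than chance (deterministic establishment) at two-tailed $\alpha = 0.05$.
The comparison statistic is the shared-species count.

Co-occurrence structure is tested with the COMBO metric — the number of
distinct presence/absence column vectors across samples — against SIM-style
null matrices. The default `sim6` preserves total matrix fill, treats
species as equiprobable, and weights samples by their observed richness
(the stated rationale for that algorithm choice); `sim2` and `sim4`
preserve per-species occurrence counts. One practical caveat discovered in
testing: with hundreds of OTUs over a few dozen samples every null column
vector is unique, the null COMBO distribution is a point mass, and the SES
is undefined — `cooccurrence_ses()` errors on such degenerate nulls, and
the pipeline stage restricts the nodule matrix to OTUs present in at least
25% of nodule samples (and still reports NA with a warning if degeneracy
persists). Co-occurrence conclusions therefore apply to the prevalent
community, not to rare taxa.

## SparCC

`sparcc_correlations()` implements sparse compositional correlation
inference from scratch: per-sample fractions with a pseudocount of 1
(resampled from a Dirichlet posterior and averaged over `n_resamples`
draws), log-ratio variances $t_{ij}$, basis variances solved from the
linear system implied by the sparsity assumption, correlations
$\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2\omega_i\omega_j)$,
and up to 10 rounds of excluding the strongest pair above a threshold of
0.1 and re-solving. Negative basis-variance solutions are clamped to a
small positive value with a warning. Permutation p-values shuffle each
OTU's counts independently across samples (point-estimate fractions during
permutations, for speed). The pre-filter default — mean count >= 1 and
prevalence >= 20% — encodes the usual filtering advice for compositional
networks; it is recorded in the result's `filter_spec`.

A calibration note: on independent data with $P$ OTUs and $n$ samples the
maximum null $|\rho|$ over all $P(P-1)/2$ pairs scales like
$c/\sqrt{n}$ with $c \approx 3\text{–}4.5$ purely from sampling noise, so
"largest observed correlation" is not a useful significance yardstick —
use the permutation p-values.

## Replicon content

`replicon_ratio()` divides each plasmid's reads per megabase by the
chromosome's reads per megabase; under the single-dominant-symbiont
assumption this estimates the fraction of symbiont cells carrying the
plasmid. Samples with fewer than 20 rpoB reads are excluded as
low-signal. Input is a per-replicon count table;
`aggregate_replicon_counts()` sums per-feature (coding-sequence) counts
into it, which presumes coding-sequence counts are an unbiased proxy for
whole-replicon coverage. Compartments are compared by a two-sided
Wilcoxon-Mann-Whitney test on the per-sample ratios, summarized by medians
and quartiles.

## The synthetic-community generator

`generate_experiment()` is first-class, tested code that encodes the study
conditions the analysis assumes:

* a lognormal rank-abundance base profile (`sigma_base = 1.5`, 300 OTUs);
* per-sample depths lognormal around 20,000 reads;
* OTU1 dominance forced per compartment (rhizosphere 0.10, root 0.30,
  leaf 0.40, nodule 0.85) — a single symbiont dominant everywhere and
  overwhelming in nodules;
* Dirichlet-multinomial sampling with per-compartment concentrations
  (rhizosphere 150, root 40, leaf 40, nodule 12), the single knob that
  produces the rhizosphere > root/leaf > nodule diversity gradient with
  realistic overdispersion (a plain multinomial would understate
  sample-to-sample variation);
* soil effects as per-OTU lognormal multipliers (`sigma_soil = 1`) applied
  *only* in the rhizosphere, genotype multipliers (`sigma_geno = 0.5`)
  *only* in the root endosphere — effects shift abundance ratios rather
  than excluding taxa. Because the soil and genotype signals are each
  confined to one compartment, they surface in the PVCA as
  soil x compartment and genotype x compartment interactions, with the
  soil interaction the larger — the rank order the analysis is meant to
  detect. (An alternative recipe propagates the rhizosphere's soil effects
  into the root and the root's genotype effects into the leaf; that was
  rejected here because it contradicts the compartment-confined structure
  the generator is supposed to plant.)
* with `nodule_from_root = TRUE`, a plant's nodule expectation is its own
  realized root composition re-weighted to the nodule dominance target, so
  nodules are nested subsamples of their root community. The nodule
  concentration default (12) gives nodule richness around 8–15 OTUs —
  in line with a nodule community carrying a core of tolerated taxa —
  and makes the nested signal detectable by Raup-Crick (at much lower
  concentration, nodules contain only the 2–3 globally ubiquitous taxa and
  the null model matches them by frequency alone).

What passing tests on this generator show: the pipeline recovers planted
compartment-confined effects, the nested-colonization signal, dominance
targets, and nominal type-I error when no effects are planted. What they
do not show: robustness to real-data features the generator omits —
taxonomic correlation structure among OTUs, chimeras and contamination,
compartment-specific sequencing biases, zero-inflation beyond the
Dirichlet-multinomial, and uneven replication.

## Numerical and testing choices

Tests and the acceptance script scale the frame down (e.g. 40–80 OTUs,
2–4 replicates, tens of subsampling iterations, hundreds of permutations)
— iteration means stabilize quickly at these sizes, and the properties
under test (exact-oracle agreement, calibration bands, planted-structure
recovery) are size-robust; the full-scale defaults remain 1500 x 1000
subsampling, 999 permutations, 1000 Raup-Crick replicates, 10,000
co-occurrence iterations, and SparCC 10 x 1000. All stochastic functions
take a `seed` argument applied to a locally restored RNG state;
`run_pipeline()` derives per-stage seeds from one master seed and records
them in its manifest. Exact tests are used wherever the instance allows
(Fisher; Wilcoxon variants below the tie/size limits; optional exhaustive
PerMANOVA), and the test suite verifies them against brute-force
enumeration oracles.

Known limitations: PerMANOVA is one-way only (by design); exhaustive
enumeration covers two groups; NMDS-based PVCA percentages depend mildly on
the ordination (restarts and the $R^2$ convention), so cross-implementation
comparisons should expect a few percentage points of drift; SparCC p-values
are permutation-based and floor at $1/(B+1)$; and the mothur-compatible
"shared" reader ignores the `label` column (single-level tables only).
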