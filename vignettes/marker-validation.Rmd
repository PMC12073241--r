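---
title: "Validating dormancy markers for pre-harvest sprouting resistance"
author: "sproutval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating dormancy markers for pre-harvest sprouting resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutval)
```

## Scope and model

`sproutval` validates candidate KASP markers for pre-harvest sprouting
(PHS) resistance in an inbred wheat panel phenotyped across several
environments. The phenotype is the germination index of a staged
germination test,

$$GI = \frac{6\,n_3 + 3\,n_6}{6\,N},$$

with $n_3$ seeds germinated by day 3, $n_6$ between days 3 and 6 and
$N$ seeds tested. The weights privilege early germination, so GI is a
unitless dormancy score in $[0,1]$; low GI = strong dormancy = PHS
resistance. `n6` is stored as the *incremental* day-6 count because the
formula weights the day-6 cohort separately; readers holding cumulative
counts must convert first. Plots tested with $N \neq 40$ are accepted —
the statistic generalizes — but flagged, since the resolution of GI
(multiples of $1/(2N)$) depends on $N$.

### Mixed models

Within one environment the trial is an RCBD,
$Y_{ik} = \mu + g_i + r_k + \varepsilon_{ik}$; across environments

$$Y_{ijk} = \mu + g_i + e_j + r_{k(j)} + (ge)_{ij} + \varepsilon_{ijk},$$

with all effects random. Both are fitted by REML (`lme4`); the genotype
BLUP $\mu + \hat g_i$ is the shrunken genotype mean and is the response
carried into every downstream marker analysis. Entry-mean broad-sense
heritability is

$$h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{g\times e}/e +
\sigma^2_\varepsilon/(er)}.$$

Design choices worth stating:

* **REML with EMS anchoring.** On balanced data REML must coincide with
  the closed-form expected-mean-squares (ANOVA) estimator at an
  interior optimum. We compute the EMS solution for balanced layouts
  and hand it to the optimizer as the starting value (and tighten the
  optimizer's convergence tolerances), which makes that identity hold
  to ~1e-8 in practice; the EMS path is also exposed directly
  (`emsComponents()`, `method = "anova"`) and is used automatically
  when the residual variance is exactly zero, where iterative REML is
  degenerate. Negative EMS solutions are truncated at zero with a
  message.
* **Replicate effects** are random in the within-environment model by
  default (`repRandom = FALSE` gives fixed blocks); the replicate
  stratum is not part of the reported four-term variance decomposition
  (genotype, environment, interaction, residual), matching how such
  tables are conventionally printed.
* **Environment means** are compared on per-environment BLUPs with a
  two-way fixed model and Tukey's HSD at $\alpha = 0.05$
  (Tukey–Kramer under imbalance). Letters are assigned walking from
  the highest mean downward, the convention of environment-mean
  tables; haplotype tables walk from the lowest mean upward. Both use
  the same compact-letter-display routine (below).

### Marker QC

Filters run in a fixed cascade — missing rate, then heterozygosity,
then monomorphy, then minor allele frequency — and an excluded marker
carries the *first* failing reason, so per-reason counts are
unambiguous and the cascade is idempotent. The thresholds are not
universal constants; the defaults (`maxMissing = 0.20`,
`maxHet = 0.05`, `minMaf = 0.03`) were chosen to separate the
qualitatively distinct bands seen in real KASP panels: assays with
70–96% missing calls are failures while 10–16% missingness is usable;
heterozygosity beyond a few percent in an inbred panel indicates assay
cross-amplification; a MAF of 2% among 200 genotypes leaves too few
minor-class homozygotes to estimate an effect. All three are
config-exposed. MAF is computed over homozygous calls only, consistent
with the downstream analysis, which treats heterozygous calls as
artefacts and sets them to missing (`dropHeterozygotes()`).

Assays designed on the complementary DNA strand report complemented
alleles; `harmonizeStrand()` maps flagged markers through A↔T/C↔G. The
map is an involution and refuses indel-coded alleles. Complete-LD
detection declares two markers redundant when their allele classes
partition the jointly typed genotypes identically (squared allelic
correlation 1, both markers polymorphic over the shared set, at least
two shared genotypes); groups are equivalence classes via union–find
and the member with the fewest missing calls represents the group in
multi-marker models.

### Association, stability, model selection

Per marker and environment, genotype BLUPs are regressed on a 0/1
indicator of the *tolerant* allele class — the class with the lower
mean GI in that fit, so the slope equals the class-mean difference and
is $\le 0$ by construction. Effects are also expressed relative to the
susceptible-class mean, and PVE is $R^2 \times 100$. A marker is
*stable* when significant ($p < 0.05$, no multiplicity correction,
matching the field's single-marker treatment; Bonferroni is available)
in at least two environments with the same tolerant allele throughout —
a marker whose direction flips between environments is rejected however
small its p-values.

All-subsets regression runs over the stable markers after collapsing
complete-LD groups (keeping both members would make every containing
subset singular). The AIC convention is the least-squares form
$n\ln(\mathrm{RSS}/n) + 2(k+1)$; the Gaussian constant is identical
across models and dropped, so only differences and ranks are
meaningful — absolute AIC values are not comparable across software.
Genotypes missing a call at any pool marker are removed once, giving a
common genotype set so AICs are comparable across subsets. Singular
subsets are skipped with a message; AIC ties below $10^{-9}$ go to the
smaller subset, then lexicographic order.

A note on what AIC ranking can promise: with a single true effect and
$p-1$ independent null companions, the probability that the top-ranked
model is *exactly* the single-marker model is roughly
$P(\chi^2_1 < 2)^{p-1} \approx 0.36$ at $p = 7$ — AIC admits a ~16%
chance per null predictor of paying its penalty. What holds with high
probability, and what the tests assert, is that the top model
*contains* the planted marker and that the planted single-marker model
beats every subset excluding it.

### Haplotypes and selection efficiency

For each top multi-marker model, genotypes with complete homozygous
calls at the model's markers are partitioned by allele combination.
Classes with one member are flagged rare and excluded from mean
comparisons (a single cultivar cannot support a class mean). Class
LSMeans come from the mixed model

$$Y_{ijk} = \mu + hap_i + e_j + (hap \times e)_{ij} + g_{k(i)} +
\varepsilon_{ijk},$$

haplotype, environment and interaction fixed and genotype-within-
haplotype random, fitted to per-environment BLUPs (raw plot GI is a
config option). Pairwise comparisons use the Tukey–Kramer adjustment
with *containment* degrees of freedom — genotypes minus classes, the
genotype stratum — chosen because it is exactly reproducible without
iterative df approximations (Kenward–Roger or Satterthwaite would also
be defensible). The compact letter display is computed from the
adjusted p-values as the maximal cliques of the non-significance graph,
which guarantees the two defining properties: groups sharing a letter
are never significantly different, and any non-significant pair shares
a letter.

Selection efficiency compares the best haplotype class against the
tolerant class of the best single marker: a two-sided Welch t-test on
member BLUPs, and each set's overlap with the top-20% most dormant
genotypes ($\lfloor 0.2n \rfloor$ lowest across-environment BLUPs, ties
broken by identifier order). One structural fact shapes interpretation:
when the haplotype extends the best marker, its class is a *subset* of
the marker class, so its raw overlap count can never exceed the
marker's. The quantity that can improve — and does, under a real
secondary effect — is the selection *rate*: top-20% hits per selected
genotype. The package reports the counts descriptively and the tests
assert the rate comparison; no significance test is attached to the
count difference by default because the choice of test for such
correlated counts is genuinely open.

## The synthetic study

The generator emulates the study design the pipeline targets: 200
genotypes × 4 environments × 2 replicates, 40-seed germination tests,
grand-mean GI 0.35, and variance components genotype 0.031,
environment 0.015, interaction 0.018, residual 0.003 (GI²) — an
implied $h^2$ of 0.86. The replicate-within-environment stratum,
rarely reported, is set to a nominal 0.001. The default 38-marker
panel plants one major dormancy locus (−0.14 GI at tolerant frequency
0.58, the frequency typical of modern European cultivars at the major
4A dormancy gene), a closely linked marker, several −0.01…−0.03 loci,
two complete-LD pairs, null markers across the frequency spectrum
(down to 4%), two strand-flagged assays, and the contamination bands
of a real KASP run: six assays at 70–96% missing, two with gross
heterozygosity (32.5%, 65.5%), seven monomorphic, one at MAF 2%.

Choices that matter when interpreting test results:

* **Exact-count sampling.** Allele-class sizes, missing and
  heterozygous cells are assigned at their configured *counts* to
  random positions, rather than drawn binomially per cell. Realized
  frequencies then match targets to rounding, and the QC composition
  of the default panel (22 retained of 38, 6/2/7/1 per reason) is
  invariant to the seed. Marker contributions to the genetic value are
  centred, so the grand mean stays at $\mu$; the polygenic background
  is $\sigma^2_g$ minus the variance the planted loci contribute.
* **Binomial germination counts.** Given the latent plot mean $m$,
  counts are $n_3 \sim \mathrm{Bin}(N, \pi_3)$ and
  $n_6 \sim \mathrm{Bin}(N - n_3, \pi_3)$ with
  $\pi_3 = (3 - \sqrt{9 - 8m})/2$, the closed-form root of
  $E[GI] = \pi_3(3 - \pi_3)/2 = m$. A beta-binomial switch adds
  overdispersion; it is off by default. This sampling adds ~0.0045
  GI² of plot-level noise at $m = 0.35$, which lands in the residual
  stratum: the *realized* residual exceeds the nominal 0.003, and real
  germination tests that report residuals below the binomial floor are
  telling us seed fates within a plot are positively coordinated —
  a feature the generator does not emulate.
* **Truncation.** Latent means are truncated to $[0.02, 0.98]$,
  mirroring observed GI ranges. In low-mean environments this clips a
  noticeable fraction of plots (6–18% per seed) and attenuates
  recovered variance components by roughly 10–20%.

Consequently the recovery tests are calibrated to what these
conditions support: over 50 seeds, the median $|h^2 - 0.864|$ is
≈ 0.02 (tested at ≤ 0.03 — the $\sigma^2_\varepsilon/(er)$ term makes
$h^2$ nearly insensitive to the binomial inflation), genotype and
interaction components recover within 25% median relative error, and
the planted −0.14 effect is recovered within ±0.04 (median), the
residual bias being BLUP shrinkage plus truncation. The environment
component is *not* held to 25%: with four environments it has ~3
degrees of freedom, so its median relative error is ~40% for any
estimator. Passing tests on this generator demonstrate the pipeline's
statistical machinery, not robustness to features the generator lacks:
population structure, genotype-specific dispersion, spatial field
trends, recombination-based partial LD.

## Problem sizes and runtime

The test suite simulates at the full study scale (200 × 4 × 2) for the
recovery experiments (50 seeds, shared across test files via a cache),
100 seeds for the AIC-ranking and familywise-error experiments at
n = 200 and 60 genotypes per null Tukey–Kramer fit, and smaller
balanced layouts (4–25 genotypes) where closed-form oracles — direct
Henderson solves, dense REML likelihood search, two-class OLS algebra —
are the comparison. The complete suite runs in about a minute on one
CPU; `runPipeline()` on the default study takes ~10 s.

## Known limitations

* Inbred panels only: heterozygous calls are treated as artefacts, and
  no phasing is attempted.
* No kinship or population-structure correction — this is candidate
  marker validation, not GWAS.
* Variance components with few levels (environment, replicate) are
  reported but intrinsically imprecise; the replicate stratum is often
  estimated at zero.
* Letters from the clique-based display can differ cosmetically (not
  substantively) from insert-absorb implementations when the
  non-significance graph is non-interval.
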