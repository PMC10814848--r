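---
title: "Reference-gene stability: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkgstab)
```

# The problem

RT-qPCR quantifies a transcript by the cycle number (Ct) at which its
amplification signal crosses a threshold; expression scales as
$E^{-Ct}$ with amplification efficiency $E \in (1, 2]$. Relative
quantification references every target gene to a housekeeping gene (HKG)
assumed constant across the compared conditions. That assumption is
empirical and frequently wrong — culture media, treatments and donors all
move "housekeeping" transcripts — so candidate normalizers must be
validated on the very dataset they will normalize. This package
implements the four validation algorithms in common use, a consensus over
them, and a downstream analysis of how much the normalizer choice itself
distorts fold-change conclusions.

All algorithms operate on a complete genes × samples Ct grid
(`ct_matrix`). Missing cells are rejected in strict mode or removed by
listwise sample deletion in permissive mode; nothing is imputed, because
every statistic below is defined on complete columns.

# The four stability algorithms

**geNorm.** Relative quantities $q_{gs} = E_g^{\min_s Ct_{gs} - Ct_{gs}}$
anchor each gene at 1 in its most abundant sample. The stability measure
is $M_g = \frac{1}{G-1}\sum_{h \neq g} \mathrm{SD}_s\!\left[\log_2
(q_{gs}/q_{hs})\right]$: a gene co-regulated with the other candidates has
near-constant pairwise ratios and a small $M$. The conventional
"acceptably stable" flag is $M < 1.5$. Ranking proceeds by stepwise
exclusion: the gene with the largest $M$ is removed and $M$ recomputed on
the remainder until two genes are left. Those two cannot be separated —
with a single pairwise ratio both genes have the same SD — so they are
reported as a structurally tied best pair, both at rank 1, the next gene
at rank 3. The reported per-gene value is its $M$ at the round of its
exclusion. The key assumption (and known weakness) is that co-regulated
gene pairs reinforce each other; the consensus over four algorithms
mitigates this.

**NormFinder.** On log2 quantities the ungrouped model is additive,
$y_{gs} = \alpha_g + \beta_s + \varepsilon_{gs}$ with
$\mathrm{Var}(\varepsilon_{gs}) = \sigma_g^2$, fit by double centering.
Because the row/column means absorb part of every gene's noise, the naive
residual variance $s_g^2 = \sum_s r_{gs}^2/(n-1)$ is biased; with
$\hat T = \frac{G}{G-1}\sum_h s_h^2$ the corrected estimate is
$$\hat\sigma_g^2 = \max\!\Big(0,\ \tfrac{G}{G-2}\big(s_g^2 - \hat T/G^2\big)\Big),$$
which is unbiased under the model (the truncation at zero is the only
departure), and the stability value is $\hat\sigma_g$. This needs
$G \ge 3$. The ungrouped estimator is the default even when condition
labels exist: the pipeline analyses strata as small as a single condition
(four samples), where no grouping structure remains, and using one
estimator everywhere keeps strata comparable. A grouped variant is
explicit opt-in (`groups =`): per group, the same bias-corrected
intragroup variance plus a shrunken absolute intergroup deviation
$\tilde d_{ga} = d_{ga}\,\hat\gamma^2_a/(\hat\gamma^2_a +
\hat\sigma^2_{ga}/n_a)$, combined as the mean over groups of
$|\tilde d_{ga}| + \hat\sigma_{ga}/\sqrt{n_a}$. The grouped formulation
follows the model-based intergroup/intragroup decomposition in spirit;
exact applet-level agreement is not claimed and the variant is not used
by any default path.

**BestKeeper.** Purely descriptive, on raw Ct: per-gene geometric and
arithmetic mean, extrema, a dispersion statistic, and the Pearson
correlation of each gene with the "index" (the per-sample geometric mean
of Ct across candidates). The original applet's "SD[± Ct]" is the *mean
absolute deviation* from the mean Ct, not the sample SD; the MAD dialect
is therefore the default and the sample-SD dialect a config option (both
are always tabulated). Ranking uses the dispersion only; the index
correlations are reported but deliberately not folded into the rank,
since their role in published rankings is ambiguous. Note that BestKeeper
is the only algorithm sensitive to sample-wise global shifts (e.g.
loading differences), which is intrinsic to judging stability on raw Ct.

**Comparative ΔCt.** $S_g = \frac{1}{G-1}\sum_{h\neq g}
\mathrm{SD}_s[Ct_{gs} - Ct_{hs}]$. At $E = 2$ for all genes this
coincides numerically with geNorm's $M$ on the all-genes-in round (both
are averages of pairwise log-ratio SDs); the two algorithms still differ
in their rankings because geNorm re-estimates after each exclusion. Both
are retained as separate columns because the consensus convention uses
all four.

All SDs use the $n-1$ denominator; all logarithms are base 2. Lower is
better, and all values are $\ge 0$, for every algorithm.

# Consensus

Each algorithm's values are converted to ascending competition ranks
("min" method: tied values share the smallest applicable rank, the next
distinct value skips the absorbed ranks). Ties are decided on unrounded
values; geNorm's final pair is a structural tie by construction, giving
ranks 1, 1, 3, …. The consensus statistic is the geometric mean of each
gene's four ranks (order: ΔCt, BestKeeper, NormFinder, geNorm), sorted
ascending. Competition ranking (rather than fractional/mean ranking) is
used because published consensus tables of this kind are only consistent
with the tied geNorm pair both holding rank 1 and the next gene holding
rank 3. A tie between genes on the geometric mean itself is broken
alphabetically and flagged — determinism is preferred over an arbitrary
stable-sort order. `consensus_from_orderings()` applies the identical
machinery when only printed per-algorithm orderings (not raw values) are
available, taking list position as the value to rank.

# Normalizer impact (ΔΔCt)

Per donor, $FC = E^{-(\Delta Ct_{num} - \Delta Ct_{ref})}$ with
$\Delta Ct = Ct_{target} - Ct_{hkg}$ within each condition; with per-gene
efficiencies the target and normalizer each use their own $E$ (Pfaffl
form), which reduces to $2^{-\Delta\Delta Ct}$ at the default $E = 2$.
Fold changes are computed from single paired samples per donor — the
design being emulated has one sample per donor × condition — and never
averaged across replicates first. The worst/best ratio
$FC_W/FC_B$ per donor depends only on the two normalizers' between-
condition behaviour (the target cancels algebraically; this is asserted
as a property test), and ratios ≥ 2 are flagged, the threshold being a
config default rather than a constant.

Merged-donor significance uses a two-sided one-sample t-test of the raw
fold changes against a hypothetical mean of 1, $t = (\overline{FC} -
1)/(s/\sqrt n)$, df $= n-1$, with tiers ns/*/**/***/**** at 0.05, 0.01,
0.001, 0.0001. Testing raw ratios against 1 is statistically awkward
(fold changes are not symmetric around 1), but it is the convention of
the workflow being reproduced, so it is the default; a log2-scale variant
(mean of $\log_2 FC$ vs 0) is provided behind `log_scale = TRUE` and is
never used implicitly. Because both the arithmetic and geometric mean of
merged fold changes are defensible summaries for display, both are
reported; the t-test is always on the raw per-donor values. Degenerate
inputs are defined, not crashed: zero SD with mean at the null gives
$t = 0, p = 1$; zero SD off the null reports $p = 0$ with a warning.

# Synthetic data: what it emulates, what it does not

`default_study_config()` states the emulated world once:

* 5 HKGs (ACTB, EF1A, GAPDH, RPLP0, TBP) with baseline mean Ct 12.72,
  10.19, 11.42, 11.07, 20.51 cycles — the all-samples means of the
  motivating ASC study — and per-condition additive shifts equal to that
  study's per-condition means minus the all-samples means (a few tenths
  of a cycle).
* 3 conditions (FBS, X1, X2) × 4 donors (ASC1–ASC4), 12 samples.
* Donor offsets $\sim N(0, 0.3^2)$ Ct, drawn once per donor and shared
  across all genes and conditions — the simplest mechanism that
  reproduces donor-dominant clustering of serum-free samples.
* Per-gene Gaussian residual noise, SD 0.3 Ct. Between-donor and
  residual variance components are not published for the motivating
  study, so 0.3 cycles was chosen once as a realistic magnitude for
  passage-matched qPCR on preamplified cDNA; it is a plausibility
  choice, clearly not a literature value, and is not revisited.
* 3 target genes with condition-dependent log2 fold shifts vs FBS
  (defaults LIF −1/−1.5, CCL5 +0.5/+0.5, IL6 −3/−4; baselines 16/18/14
  Ct), additive in Ct (= multiplicative in expression, matching ΔΔCt
  algebra).

Gaussian noise on the cycle scale is the standard qPCR error model
(multiplicative on expression); a heavier-tailed Student-t option exists
for robustness experiments. The generator deliberately does **not**
simulate amplification curves, efficiency variation between wells,
preamplification bias, or gene-specific donor interactions. Consequently
a green pipeline test establishes that the algorithms and their
aggregation behave correctly under the stated additive model — it does
not certify behaviour under miscalibrated efficiencies or strongly
non-Gaussian noise, and it cannot validate the emulated study's own
laboratory values, which would require its deposited raw data.

Every stochastic draw derives from a mandatory integer seed; generation
restores the session RNG state.

# Numerical and interface choices

* Ct validity bound: $(0, 45]$ cycles (common instrument maximum),
  configurable; efficiencies $(1, 2]$, default exactly 2.
* CSV writers print doubles with 17 significant digits so write/read
  round trips are exact; report CSVs print the consensus to 2 decimals
  (as such tables are conventionally shown) while JSON twins keep full
  precision.
* Exact ties for worst gene during geNorm exclusion are broken by matrix
  order (first such gene excluded) — measure-zero with continuous data,
  deterministic when engineered.
* Stability algorithms are tested against independent brute-force
  reimplementations (explicit double loops) at tolerance $10^{-10}$ on
  random matrices; the t-test against `stats::t.test` at $10^{-10}$.
* Strata that fail an algorithm's preconditions (fewer than 3 genes,
  fewer than 2 samples, degenerate groups) abort that stratum with a
  logged error; the run continues, and the error is recorded on the
  result.

# Known limitations

* The geNorm/ΔCt family rewards co-regulation; a pair of genes under a
  shared promoter would rank artificially well in half the columns. The
  consensus dampens but does not eliminate this.
* BestKeeper's MAD-vs-SD dialect changes values (not usually ranks);
  published tables rarely state which was used.
* The grouped NormFinder variant follows the published model but exact
  numerical agreement with any specific applet build is not asserted.
* With four donors, merged-donor t-tests have three degrees of freedom;
  tier boundaries should be read accordingly.
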