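---
title: "Methylation plasticity analysis with mplkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation plasticity analysis with mplkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplkit)
```

## The model

Array methylomics reports each CpG site in each sample as a beta value
$\beta = \mathrm{Meth}/(\mathrm{Meth}+\mathrm{Unmeth}+\kappa_0)$, the
methylated fraction of total probe signal, with a stabilizing offset
$\kappa_0 = 100$ that keeps the ratio defined when both intensities are
small ($\beta \in [0,1)$, and $\beta = 0$ exactly when the methylated
signal is zero). A value of 0.5 marks balanced methylated and
unmethylated signal.

`mplkit` works at the level of a site's beta-value *distribution* across
the samples of one study dataset (samples sharing tissue, cell type and
condition). Three distribution-level questions are posed per site:

1. **How plastic is it?** Methylation plasticity (MPL) is the spread of
   the distribution. Four scores are offered: the interquartile range
   Q75−Q25 (default), the wider quantile range Q95−Q5, the sample
   standard deviation, and the extreme difference max−min. The IQR is
   the recommended score: it is robust to outliers and leaves half of
   the data outside the range as sample support for the claimed
   variability, whereas the extreme difference cannot distinguish one
   outlying array from a genuine extreme.
2. **Which way does it lean?** Counts of values in $[0, 0.5)$ and
   $(0.5, 1]$ are tested against equal expectation with a one-degree-of-
   freedom $\chi^2$ goodness-of-fit test. A significant excess above 0.5
   makes a methylation-tendency site (MTS); below, an unmethylation-
   tendency site (UTS); otherwise the site is nonbiased (NTS). A strict
   variant requires *all* values on one side. A site switching between
   MTS and UTS across conditions (an *inversion*) is the strongest form
   of differential methylation.
3. **Does it split?** Some sites aggregate into 2–3 discrete clusters —
   genotype-driven (one cluster per genotype of a probe-proximal SNP, at
   Hardy–Weinberg proportions), sex-linked, or condition-driven. A
   Duda–Hart homogeneity test decides whether one cluster suffices; if
   not, k-medoids clustering with silhouette-selected $k$ recovers the
   components, and combinations of split sites stratify the cohort into
   up to $\prod_i k_i$ groups.

The r-beta profile makes all three visible at once: beta values are
rounded to two decimals, binned onto the grid $0.00, 0.01, \dots, 1.00$,
and the proportion of samples at each of the 101 grid points is plotted.
The proportions sum to exactly 1; spread shows as curve width, tendency
as peak position, and split methylation as multiple peaks.

## Parameters and defaults

| Parameter | Default | Where | Rationale |
|---|---|---|---|
| beta offset | 100 | `compute_beta` | conventional stabilizer against small denominators |
| tendency α | 0.05 | `classify_tendency` | standard significance level |
| minimum n for a call | 4 | `classify_tendency` | "more than 3 samples"; χ² counts are meaningless below this |
| Duda–Hart α | 0.001 | `duda_hart` | the documented default of the homogeneity criterion; conservative so that split calls are rare, as they are genome-wide |
| k search range | 2–10 | `select_k` | documented default of silhouette-based k selection |
| MPL method / threshold | iqr / 0.5 | `high_plasticity_sites` | IQR per the rationale above; 0.5 marks extreme plasticity (a ~0.06% tail genome-wide) |
| peak smoothing window | 5 bins | `profile_peaks` | see below |
| peak prominence | 0.01 | `profile_peaks` | see below |
| Mann–Whitney mode | auto | `mann_whitney` | exact when both groups ≤ 25 and tie-free, else normal approximation with tie correction and continuity correction |
| component concentration κ | 50 | `site_spec` | Beta(μκ, (1−μ)κ) noise with per-component sd ≈ 0.05–0.07, the spread real array replicates show |

## Numerical choices

**Rounding.** The r-beta grid uses round-half-to-even at two decimals
(base `round`), centralized in `round_beta()` so a half-up rule would be
a one-line change. Proportions are bin counts over the non-missing count,
so they sum to 1 exactly.

**Values exactly at 0.5.** The two tendency intervals $[0,0.5)$ and
$(0.5,1]$ both exclude 0.5; such values are counted separately
(`n_half`) and enter neither χ² count. An input consisting only of 0.5s
is NTS with $p = 1$ by convention (and a message). The alternatives —
binning 0.5 up or down — would silently bias calls at heavily
intermediate sites.

**No continuity correction in the tendency χ².** Yates' correction
applies to 2×2 contingency tables, not to the one-degree-of-freedom
goodness-of-fit form used here; the uncorrected statistic also matches
the worked arithmetic (20 values on one side of 0.5 give
$\chi^2 = 20$, $p \approx 7.7\times 10^{-6}$).

**Quantile conventions.** Five-number summaries use Tukey hinges
(`fivenum`); the quantile ranges use type-7 linear interpolation
(`quantile`'s default), which differs from the hinges for some n. Both
are reported; the IQR score is defined from the type-7 quartiles. The
exact quantile algorithm behind the published Q95–Q5 figures is not
documented anywhere we know of; type-7 is the default of the upstream
environment and is flagged here as an assumption.

**Exact 1-D k-medoids instead of BUILD+SWAP.** In one dimension the
optimal k-medoids clusters are contiguous runs of the sorted values, so
the global optimum of the PAM objective (total absolute distance to the
nearest medoid, medoids being data points) is found exactly by dynamic
programming over split points, with interval medoids at lower medians
and cost ties broken to the leftmost split. This matters: the classical
BUILD+SWAP local search can stall. For the values
{0.1, 0.349, 0.432, 0.511, 0.587, 0.587, 0.6} at $k=2$, BUILD starts at
{0.1, 0.511} (cost 0.482) and no *single* swap improves it — the global
optimum {0.349, 0.587} (cost 0.421) is reachable only through a
cost-neutral intermediate — so generic PAM returns a local optimum. The
DP is deterministic, always at least as good, and makes the
exhaustive-search equivalence in the test suite an identity rather than
a hope. Silhouette widths are likewise computed exactly from prefix sums
and are cross-checked against `cluster::silhouette` in the tests.

**Duda–Hart power.** The homogeneity statistic is the ratio of the
2-cluster within-group sum of squares to the total sum of squares,
rejected below $1 - 2/\pi - z_\alpha\sqrt{2(1-8/\pi^2)/n}$. Its power
depends on how much of the variance a *single* split can explain. A
balanced trimodal site (Hardy–Weinberg proportions 0.25/0.50/0.25 at
means 0.04/0.45/0.89) keeps a ratio around 0.34 because either 2-split
leaves one pair of components merged; the critical value only rises past
that near $n \approx 5000$. Genotype-trimodal sites are therefore
expected to be *missed* by the two-stage split detector in cohorts of a
few hundred samples, and detected in the multi-thousand-sample cohorts
where they were originally described. Bimodal sites (sex-linked, or a
0.3 condition shift) are detected already at $n \approx 60$. This is a
property of the published procedure itself, not of this implementation;
the benchmark suite accounts for it by validating genotype-cluster
proportions conditional on the true component count ($k=3$ k-medoids on
the generator's Hardy–Weinberg sites) while measuring cluster-*number*
recovery across all sites.

**Peak detection.** The profile is smoothed with a 5-bin moving average,
zero-padded at the grid edges (mass outside [0,1] is zero; partial
windows would inflate the bases of edge-adjacent peaks, and
low-methylation components sit very close to the 0.00 edge). Peaks are
local maxima with topographic prominence ≥ 0.01: at κ = 50, true
mixture-component peaks have prominence ≈ 0.02 and up (≈ 0.019 for a
component at mean 0.04, squeezed against the edge), while multinomial
sampling ripple at a few hundred samples stays below 0.001, so 0.01
separates the two with an order of magnitude on either side. No
quantitative peak definition exists in the literature this package
follows; the default is calibrated to agree with `select_k` cluster
counts on well-separated mixtures.

**QC is per sample.** A sample containing any beta value below 0, above
1, or missing is dropped whole; sites are never dropped. The filter is
idempotent and reports each dropped sample with its reasons.

## The synthetic generator

`generate()` draws per-site Beta mixtures: single components for
MTS-/UTS-/NTS-like sites; three components at Hardy–Weinberg genotype
proportions $q^2/2pq/p^2$ for `split_hwe` sites; two sex-keyed
components for `split_sex` sites (sex is Bernoulli per sample and
recorded in the sample sheet). Draws at exactly 0 or 1 are nudged into
$[10^{-6}, 1-10^{-6}]$. Output is fully reproducible from the seed.

`preset_corpus()` fixes the study conditions used throughout the
benchmark suite: 1000 sites × 200 samples in two balanced condition
groups — 60% MTS-like (means 0.70–0.92), 35% UTS-like (0.08–0.30), 3%
nonbiased (0.50), 1.5% Hardy–Weinberg trimodal (0.04/0.45/0.89,
$q=0.5$, the canonical genotype-split means), 0.5% sex-linked
(0.54/0.82, the reported female/male medians of an X-linked split
site) — with 50 engineered differential sites whose means shift by 0.30
between conditions while staying on one side of 0.5, so tendency truth
labels remain defined. These sizes keep the full pipeline (QC through
stratification) under a couple of minutes on one CPU while leaving all
recovery statistics well away from their thresholds.

What the generator does *not* emulate: Infinium I/II probe-type
chemistry, batch effects, cell-type composition heterogeneity, spatial
correlation between neighbouring CpGs, and the genome-wide abundance
imbalance of a real manifest. Passing recovery tests on this generator
therefore demonstrates the statistical machinery (binning, testing,
clustering, correction) under the package's distributional assumptions —
not robustness to array artefacts, which belongs to upstream
preprocessing.

## Known limitations

- Tendency calls assume exchangeable samples within a dataset; family
  structure or repeated measures would miscalibrate the χ².
- The Duda–Hart stage bounds split detection power as described above;
  balanced trimodal sites need thousands of samples.
- The Mann–Whitney test compares distributions; with strongly unequal
  variances its rejection is not purely a location difference.
- Preprocessed (submitter-normalized) and uniformly processed matrices
  are treated identically; provenance stays in metadata, and
  cross-dataset comparisons of mixed-provenance values are the user's
  responsibility.
- SNP-probe filtering is available through the annotation table but off
  by default: genotype-driven split methylation is a signal here, not an
  artefact.
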