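---
title: "Testing large genomic regions for differential methylation with redundancy analysis"
author: "methylRDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing large genomic regions for differential methylation with redundancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylRDA)
```

## The problem

Methylation changes driven by structural variants or other broad-acting
factors can span hundreds of kilobases to megabases. Scanning methods that
assemble differentially methylated regions (DMRs) from runs of concordant
probes answer a different question — *where are the small DMRs?* — and
struggle when a large region mixes hyper- and hypomethylated CpGs whose
effects cancel on average. methylRDA answers the targeted question: *is
this particular region, of any size, differentially methylated with
respect to one or more outcome variables?*

## The model

Let $Y$ be the $n \times k$ matrix of M-values of the $k$ CpGs in the
target region over $n$ samples, and $X$ the $n \times m$ centered design
matrix of outcomes (dummy-coded factors and/or numeric variables).
Redundancy analysis (RDA) is multivariate multiple regression followed by
ordination:

1. each CpG column of the centered $Y$ is regressed on all columns of
   $X$, giving a fitted matrix $\hat Y$ and residuals $Y - \hat Y$;
2. a PCA of $\hat Y$ yields the RDA components (we use the SVD of
   $\hat Y$; component signs are fixed by making the largest-magnitude
   CpG loading of each component positive, so output is reproducible).

The association strength is
$R^2 = \mathrm{SS}_{\mathrm{fit}} / \mathrm{SS}_{\mathrm{tot}}$, the
fraction of the total centered variance of the region captured by the
design. Because an $R^2$ does not depend on region size or (beyond
sampling noise) on $n$, it is comparable across regions and experiments.
The underlying assumptions are linearity between M-values and the design
and homoscedasticity; M-values (logit2 of the methylation proportion) are
used precisely because beta values in (0, 1) violate the Gaussian working
assumptions, and a two-level factor satisfies linearity trivially.

CpGs are centered but not scaled by default (covariance-based RDA, the
convention of constrained-ordination software); unit-variance scaling is
available via `scale = TRUE`.

### Partial (covariate-adjusted) models

Covariates named in `encodeDesign(..., covariates =)` form a conditioning
block $Z$ (for example surrogate variables supplied as ordinary columns).
Both $Y$ and $X$ are residualised on $Z$ before step 1, so the fitted
variance is the part attributable to the outcomes beyond the covariates.
By default the reported $R^2$ keeps the *total* pre-conditioning variance
in the denominator,
$R^2 = \mathrm{SS}_{\mathrm{fit}} / \mathrm{SS}_{\mathrm{tot}}$,
so adding covariates can only shrink it — the behaviour one expects when
comparing a crude against an adjusted model of the same region. The
alternative convention
$\mathrm{SS}_{\mathrm{fit}} / (\mathrm{SS}_{\mathrm{fit}} +
\mathrm{SS}_{\mathrm{res}})$ is available through
`r2Denominator = "conditioned"`.

## Inference

**Permutation pseudo-F.** The statistic is
$F = (\mathrm{SS}_{\mathrm{fit}}/m) /
(\mathrm{SS}_{\mathrm{res}}/(n - m - q - 1))$ with $q$ conditioning
columns. Under the null the sample-to-outcome pairing is exchangeable, so
`rdaPermTest()` permutes the rows of the predictor block (jointly across
predictor columns — equivalent to re-sampling the outcome labels), keeps
covariates attached to their samples, re-residualises the permuted
predictors on $Z$, and recomputes $F$. The p-value uses the add-one
formula $p = (1 + \#\{F_\pi \ge F_{\mathrm{obs}}\})/(B + 1)$; ties count
as exceedances (conservative), the smallest attainable p is $1/(B+1)$,
and the default $B = 10{,}000$ resolves p-values below $10^{-4}$. With
covariates present, permuting predictors under the full model is one of
two defensible schemes (the other being residual permutation under the
reduced model); for the simple exchangeable designs this package targets
they agree asymptotically, and the simpler scheme is used.

**Random-region null for $R^2$.** A significant permutation test says the
region is associated with the outcome; it does not say the association is
*specific* to the region. `regionR2Null()` asks how often a random region
with the same number of CpGs anywhere in the genome reaches the observed
$R^2$: windows of exactly $k$ consecutive annotated probes (never
crossing a chromosome boundary) are drawn uniformly with replacement,
windows overlapping the target are excluded by default so the null is not
contaminated by the tested signal, and the exceedance probability uses
the same add-one formula. Probe-count matching (rather than bp-width
matching) is deliberate: the null statistic's distribution depends on the
dimension $k$ of the outcome matrix, not on the bp span, which varies
with local probe density.

## The simulator

`simulateDataset()` emulates a 450K-style single-chromosome experiment:
8432 CpGs on a 51 Mb pseudo-chromosome, beta values drawn independently
per CpG from Beta$(a_j, b_j)$. The default parameter set
(`defaultCpGParameters()`) is a declared synthetic stand-in for
parameters estimated from a real cohort (which are not public): per-CpG
means come from a three-component mixture — hypomethylated
(mean $\sim$ Beta(2, 18), weight 0.45), hypermethylated (Beta(18, 2),
weight 0.40), intermediate (Beta(5, 5), weight 0.15) — reproducing the
bimodal marginal of array data, and precisions $\nu = a + b$ are
log-uniform on [50, 500], spanning noisy to tight probes.
`fitCpGParameters()` provides the method-of-moments route when reference
beta values are available.

A replicate places a target region of the configured width uniformly at
random (anchored at an annotated CpG, so placement probability follows
probe density), turns a fraction of its CpGs into DMPs (count rounded
half up, positions uniform without replacement), and shifts the Beta mean
of each DMP by the effect size in group 2, preserving $\nu$. The shift
direction is random per DMP by default — large real DMRs contain probes
associated in both directions, and a mixed-direction region is exactly
the case scanning methods handle worst — with `direction = "up"/"down"`
available. Shifted means are clamped to [0.02, 0.98] (a shift that would
leave the interval flips sign when the opposite direction is feasible),
keeping the Beta parameters well conditioned.

What the simulator does *not* emulate: spatial correlation between
neighbouring CpGs, Infinium I/II chemistry differences, batch effects and
cell-composition heterogeneity. Null-behaviour results (type-I error,
null $R^2$ level) are insensitive to these, but absolute power and
absolute target-region $R^2$ values depend on the (unpublished) real
per-CpG parameters; the benchmark therefore treats absolute $R^2$
magnitudes as qualitative, while orderings (effect size, DMP fraction)
and the irrelevance of region width are reproducible properties.

Seeds follow a fixed hierarchy (master seed → scenario → replicate →
stream), so any grid cell reruns independently and identical seeds give
bit-identical datasets.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 1e-6 | beta clipping bound before logit2; keeps M-values finite |
| `minCpgs` | 3 | smallest analyzable region; fewer CpGs make a degenerate multivariate outcome |
| `nperm` | 10,000 | permutations; smallest attainable p is 1/(nperm+1) |
| `nRegions` | 10,000 | random windows for the regional null |
| `scale` | FALSE | unit-variance scaling of CpGs before RDA |
| `r2Denominator` | "total" | denominator convention under conditioning |
| `effect` | 0.3 / 0.1 / 0.05 | difference in mean beta at DMPs (grid) |
| `dmpFraction` | 0.30 / 0.10 | fraction of region CpGs made DMPs (grid) |

Missing beta values: rows containing any NA are dropped at construction
with a message; no imputation. Beta values at 0 or 1 are clipped inward
by `epsilon`. Both policies are declared defaults, not estimated ones.

## Numerical notes

- The fit uses QR projections throughout; no normal equations. Rank
  deficiency of the design (also after residualisation on covariates) is
  an error, not a silent drop.
- The variance decomposition
  $\mathrm{SS}_{\mathrm{cond}} + \mathrm{SS}_{\mathrm{fit}} +
  \mathrm{SS}_{\mathrm{res}} = \mathrm{SS}_{\mathrm{tot}}$ is enforced to
  1e-8 relative tolerance by the result class itself.
- Components with singular value below $10^{-10}$ times the largest are
  dropped; eigenvalues are $d_i^2/(n-1)$ and sum to
  $\mathrm{SS}_{\mathrm{fit}}/(n-1)$.
- An exactly zero residual SS yields an infinite pseudo-F with a warning
  rather than an error; permutation draws that reach it count as
  exceedances.

## A worked check of the null level

With one balanced binary factor and Gaussian noise, the expected null
$R^2$ of a region is $1/(n-1)$ regardless of $k$ — at $n = 40$ that is
$0.0256$. The package's own benchmark reproduces this: random signal-free
windows at $n = 40$ average an $R^2$ of about 0.026, and the permutation
test rejects about 5% of null regions at $\alpha = 0.05$. These two
facts, together with power against the simulated DMR scenarios, are
recomputed from scratch by `scripts/acceptance.R` and by the test suite
(reduced problem sizes: 200 windows for the null level, 400 null tests at
199 permutations for type-I error, 20 replicates per grid cell for the
orderings, 50 replicates for power — sizes chosen to put Monte-Carlo
error well below the effects being checked).

## Known limitations

- Independent CpGs in the simulator overstate the effective dimension of
  real regions; real 450K data are locally correlated.
- The regional null compares probe-count-matched windows; if the target
  region's probe density is atypical (e.g. a CpG-island-dense promoter),
  matched windows may differ in genomic character.
- The permutation scheme assumes freely exchangeable samples; family
  structure or other dependence requires restricted permutations, which
  are not implemented.
- Factors with unbalanced groups are handled, but a level with very few
  samples makes both the pseudo-F and the RDA plot unstable.
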