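---
title: "Quantifying cross-trait polygenic overlap: models and methods"
author: "pleiomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-trait polygenic overlap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiomix)
```

## The problem

Two complex traits can share most of their causal variants while showing only
a modest genetic correlation: effects that agree at some shared variants and
disagree at others cancel in the genome-wide average. pleiomix implements the
two complementary analyses used to characterise this situation from GWAS
summary statistics alone:

* a **bivariate causal mixture model** that estimates how many variants
  influence each trait, how many influence both, and how correlated the
  shared effects are; and
* the **conditional / conjunctional false discovery rate** (condFDR/conjFDR)
  machinery that borrows power across traits to localise the shared signal
  to individual loci, followed by FUMA-style locus definition.

Everything operates on per-SNP z-scores plus an LD reference; no genotypes
are needed.

## The bivariate causal mixture model

Each variant belongs to one of four components: null, causal for trait 1
only (probability $\pi_1$), causal for trait 2 only ($\pi_2$), or causal for
both ($\pi_{12}$). Causal effects per standardized genotype are
$\beta_t \sim N(0, \sigma_{\beta t}^2)$; within the shared component the two
effects are bivariate normal with correlation $\rho_{12}$. The observed
z-scores mix the local true signal through LD with residual noise:

$$z_{tj} = \sqrt{n_t} \sum_k r_{jk}\,\beta_{tk} + \epsilon_{tj},\qquad
\mathrm{Var}(\epsilon_{tj}) = \sigma_{0t}^2,\quad
\mathrm{Corr}(\epsilon_{1j}, \epsilon_{2j}) = \rho_0 .$$

$\sigma_0^2 > 1$ captures residual inflation; $\rho_0$ captures correlated
noise from overlapping samples.

### Likelihood by characteristic-function inversion

Because each LD partner contributes an independent two-point mixture, the
characteristic function of $(z_1, z_2)$ at a variant is an analytically
exact product over its neighbourhood, e.g. in one dimension

$$\varphi_j(t) = e^{-\sigma_0^2 t^2/2}\prod_{k \in LD(j)}
\left[(1-\pi) + \pi\, e^{-n r_{jk}^2 \sigma_\beta^2 t^2 / 2}\right],$$

and the density follows by numerical inversion on a fixed trapezoidal
t-grid. For these rapidly decaying CFs the trapezoid rule is spectrally
accurate; the practical limits are (i) the grid extent, which must cover the
CF's support, and (ii) aliasing: a grid of spacing $\Delta t$ periodizes the
density with period $2\pi/\Delta t$. We therefore evaluate densities only
for $|z| \le$ `zMax` (default 12) and give variants beyond the cap a
**censored-likelihood** contribution $\log P(|z| > z_{max})$, computed from
the same grid through the box integral
$\int_{-c}^{c} \cos(t z)\,dz = 2\sin(tc)/t$. This keeps the strongest
association signals in the fit — simply discarding them visibly depresses
$\hat{\sigma}_\beta^2$ and the implied heritability — without ever
evaluating the inversion grid outside its reliable range. Defaults
(`mixerOptions()`): 1-D grid of 512 points on $[0, 16]$; 2-D half-plane grid
with spacing 0.175 up to $t = 9$, giving an aliasing period of ~36.

Two implementation details make the likelihood cheap enough to optimize
directly. Neighbourhood $r^2$ values are binned into 24 geometric bins
(counts are exact; each bin is represented by the mean $r^2$ it contains),
and variants with identical bin-count profiles share a single CF evaluation.
On block-structured panels this collapses $10^4$ variants to a few dozen
unique profiles. Sample sizes enter through the per-trait median $N$ — the
customary summary-level simplification.

### Fitting

`fitUnivariate()` maximizes the likelihood over
$(\pi, \sigma_\beta^2, \sigma_0^2)$ with Nelder–Mead from data-driven
multistarts (a coarse $\pi$ grid with moment-matched $\sigma_\beta^2$), on a
random-pruned subset ($r^2 < 0.1$) capped at `maxVariants`. `fitBivariate()`
then fixes the per-trait variances at their univariate estimates and
optimizes $(\pi_1, \pi_2, \pi_{12}, \rho_{12}, \rho_0)$ — a 9-parameter
problem reduced to 5. Point estimates are medians over `pruneReps` pruning
draws and standard errors the spread across draws, so the uncertainty
reported reflects the random-pruning process. Model fit is summarized by
AIC differences against two constrained fits: no shared component and
maximal admissible overlap.

Optimization bounds: $\pi$ components live on a scaled-logistic transform in
$(0, 0.5)$, correlations on $\tanh$, and $\sigma_0^2 \in [0.8, 2.5]$. The
class validity for fitted parameters allows $\sigma_0^2$ slightly below 1,
since sampling noise can push a perfectly calibrated GWAS below the
theoretical floor.

### Derived summaries

* `nExplaining90()` — the number of causal variants explaining 90% of SNP
  heritability. The default *realized-effect* definition takes the smallest
  set of variants whose Gaussian-order-statistic tail captures 90% of
  $\sum \beta^2$: solving $2[t\phi(t) + 1 - \Phi(t)] = 0.9$ gives a
  multiplier $2(1 - \Phi(t^*)) \approx 0.446$ on $\pi M$. The alternative
  *expected-contribution* definition ($0.9\,\pi M$) is available via
  `method = "expected"`; which convention an individual published analysis
  used is rarely derivable from the text, so both are shipped and the
  default documented.
* `modelRg()` — $r_g = \rho_{12}\pi_{12} / \sqrt{(\pi_1+\pi_{12})(\pi_2+\pi_{12})}$.
* `concordantFraction()` — the orthant probability
  $1/2 + \arcsin(\rho_{12})/\pi$ of same-sign shared effects.
* `fitLdscRg()` — an LD-score-regression genetic correlation as an
  independent check: slopes of $z^2$ and $z_1 z_2$ on the LD score, block
  jackknife errors, and a single shared heteroskedasticity weight
  $1/[\ell(1 + n_1 h_1^2 \ell/M)(1 + n_2 h_2^2 \ell/M)]$ for all three
  regressions (which also makes a duplicated trait return $r_g = 1$
  exactly). No $\chi^2$ cap is applied by default: with weights in place a
  cap only censors true signal, though the `chisqMax` argument remains for
  real-data artefacts.

## condFDR and conjFDR

The conditional FDR of trait 1 given trait 2 is estimated as
$condFDR(p_1 \mid p_2 \le s) = p_1 / \hat{F}(p_1 \mid p_2 \le s)$ with
$\hat{F}$ the stratified empirical cdf of $p_1$ within nested secondary
strata (thresholds $-\log_{10} p_2 \in \{0, 0.25, \ldots, 3\}$). This is
the conservative form: no $\hat\pi_0$ correction is applied to the
numerator. The cdf is averaged over `pruneIters` random prunings at
$r^2 < 0.1$ so that LD does not distort the empirical quantiles, and the
long-range-LD regions (extended MHC chr6:25–35 Mb, chr8 inversion 7–13 Mb)
are excluded from *estimation* while remaining available to *queries* —
published cross-trait analyses do report MHC loci.

Numerical safeguards, all deterministic and documented:

* strata holding fewer than `minStratumSize` (100) pruned SNPs inherit the
  nearest coarser stratum's cdf — with a handful of SNPs the conditional cdf
  is noise and conditioning on it forfeits the method's conservatism (an
  empty stratum is the limiting case of the same rule);
* the condFDR surface uses $\max(\hat F, 1/(n_s + 1))$, is
  monotone-enforced along the $p_1$ axis by a running maximum toward larger
  $p_1$, and is clamped to $(0, 1]$;
* queries interpolate bilinearly in $(-\log_{10} p_1, -\log_{10} p_2)$ and
  clamp beyond-grid coordinates to the edge cells, which is conservative for
  $p_2$ beyond the finest stratum.

The conjunctional FDR is the maximum of the two reciprocal condFDRs, an
upper bound on the FDR of joint association; `discover()` flags SNPs below
the 0.05 threshold. `conditionalQQ()` provides the companion visual:
observed versus expected $-\log_{10} p_1$ quantiles within nested $p_2$
strata, whose successive leftward deflections signal cross-trait enrichment.

## FUMA-style loci

From the flagged SNPs, `defineLoci()` chains the FUMA tiers with their
customary thresholds (all three configurable, since the protocol is cited
in the literature without numbers): independent significant SNPs by greedy
clumping at $r^2 \ge 0.6$ (ties broken by position — deterministic), lead
SNPs by re-clumping the independent set at $r^2 \ge 0.1$, candidate SNPs as
*all* panel variants at $r^2 \ge 0.6$ with an independent significant SNP,
locus intervals spanning each cluster's candidates, and merging of
same-chromosome intervals closer than 250 kb. Lead-SNP concordance
($z_1 z_2 > 0$) is counted per lead SNP, and a locus is labelled `+` only
when all its leads agree — published tables count concordance over lead
SNPs, and with possibly several leads per locus the per-lead convention is
the one that reproduces their "$k/n$" arithmetic. Physical overlap between
two locus sets uses closed-interval intersection on GRanges.

## The synthetic-data generator

`simulatePair()` is the generative counterpart of the mixture model and the
ground truth for every calibration test: labels i.i.d. from
$(1 - \pi_1 - \pi_2 - \pi_{12}, \pi_1, \pi_2, \pi_{12})$, shared effects
bivariate normal, signal propagated through the panel's signed $r$, and
residuals bivariate normal across traits but **independent across SNPs** —
exactly the model the likelihood assumes. Effects are per-standardized
genotype with no allele-frequency weighting. `makeBlockPanel()` builds
AR(1) blocks ($r = \rho^{|j-k|}$, truncated below $10^{-3}$) laid out with
consistent physical coordinates; a vector-valued $\rho$ yields the
heterogeneous LD-score distribution real genomes have, which is also what
makes the LD-score regression well-conditioned.

What the generator does *not* emulate: LD-correlated sampling noise across
neighbouring SNPs, allele-frequency- or annotation-dependent architectures,
case/control ascertainment, population stratification, and multi-allelic or
strand-ambiguous messiness beyond what `harmonize()` handles. Passing tests
therefore demonstrate correctness of the estimators under the model's own
assumptions and their calibration under block LD — not robustness to every
artefact of real GWAS data.

## Problem sizes and determinism

The calibration suite runs at the conditions the methods are meant for —
$M = 10^5$ variants in blocks of 50, $n = 10^5$, $\pi = 3\times 10^{-3}$
per component, $\rho_{12} = 0.6$ — with replicate counts (3 for mixture
recovery, 10–20 for calibration rates) chosen to keep a full test run in a
routine sitting. Fitting subsets are capped at 5000 variants with a single
pruning draw in tests (`pruneReps = 20` remains the analysis default). All
randomness flows from explicit integer seeds: simulation, pruning orders,
subsampling and grid construction are reproducible bit-for-bit, which is
also asserted (identical configuration and seed give byte-identical
discovery and locus tables). An R-level RNG guard restores the caller's
`.Random.seed`, so library calls have no side effects on user scripts.

## Known limitations

* The composite (pruned-subset, per-variant independent) likelihood is an
  approximation; its parameter spread across pruning draws is reported as
  the SE, mirroring how the published analyses report uncertainty.
* Per-trait effect variances are fixed at univariate estimates during the
  bivariate fit; misfit there propagates (the AIC comparators flag gross
  cases).
* condFDR leakage at desk scale: with few truly-joint SNPs the empirical
  false-discovery proportion of conjFDR under complete independence
  approaches its nominal bound from below only as the panel grows; the
  minimum-stratum-size rule is what keeps it conservative at $M = 10^5$.
* No liftover, INDELs, or multi-ancestry support; SNVs on one genome build.
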