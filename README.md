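# pleiomix

Cross-trait polygenic overlap analysis from GWAS summary statistics: a
bivariate causal mixture model, conditional Q–Q plots, conditional and
conjunctional false discovery rates (condFDR/conjFDR), and FUMA-style
genomic locus definition — with a synthetic-data generator that makes the
whole pipeline testable end to end against known ground truth.

## Who this is for

Statistical geneticists with two (or more) sets of GWAS summary statistics
(per-SNP z-scores or beta/SE, p-values, sample sizes) and an LD reference,
who want to go beyond a single genetic-correlation number: *how many*
variants are shared between two traits, *how correlated* are the shared
effects, and *which loci* drive the overlap.

## The models in brief

**Bivariate causal mixture.** Each SNP is null, causal for trait 1 only
(π₁), trait 2 only (π₂), or shared (π₁₂). Causal effects are
β_t ~ N(0, σ²_βt); shared pairs are bivariate normal with correlation ρ₁₂.
Observed z-scores fold in LD and residual noise:

    z_tj = √n_t Σ_k r_jk β_tk + ε_tj,   Var(ε) = σ²_0t, Corr(ε₁, ε₂) = ρ₀

The likelihood of the signed z-scores is computed by inverting the model's
exact characteristic function on a fixed grid and maximized by
derivative-free optimization over random-pruned SNP subsets. Derived
summaries: the number of variants explaining 90% of SNP heritability per
Venn component (≈ 0.446·πM under the realized-effect definition), the
model-implied genetic correlation r_g = ρ₁₂π₁₂/√((π₁+π₁₂)(π₂+π₁₂)), and the
concordant-effect fraction ½ + arcsin(ρ₁₂)/π. An LD-score-regression r_g
with block-jackknife errors is included as an independent check.

**condFDR / conjFDR.** The conditional FDR of trait 1 given trait 2,
condFDR(p₁|p₂) = p₁ / F̂(p₁ | p₂ ≤ s), uses stratified empirical cdfs
averaged over random LD prunings; the conjunctional FDR is the maximum of
the two reciprocal condFDRs, an upper bound on the FDR of joint
association. SNPs with conjFDR < 0.05 seed FUMA-style loci: independent
significant SNPs (clump at r² ≥ 0.6), lead SNPs (r² ≥ 0.1), candidate SNPs,
intervals merged below 250 kb, and per-lead effect-direction concordance.

## Worked example

```r
library(pleiomix)

# synthetic study: 1e5 SNPs in LD blocks, two traits sharing half of their
# causal variants with effect correlation 0.6
pan <- makeBlockPanel(n_blocks = 2000, block_size = 50, rho = 0.6, seed = 1)
truth <- new("BivariateMixtureParams", pi1 = 3e-3, pi2 = 3e-3, pi12 = 3e-3,
    sigmaBetaSq1 = 1e-3, sigmaBetaSq2 = 1e-3, rho12 = 0.6,
    sigma0Sq1 = 1, sigma0Sq2 = 1, rho0 = 0)
sim  <- simulatePair(pan, truth, n1 = 1e5, n2 = 1e5, seed = 1001)
pair <- harmonize(sim$trait1, sim$trait2)

opts <- mixerOptions(pruneReps = 1, maxVariants = 5000, nStarts = 1)
u1 <- fitUnivariate(sim$trait1, pan, opts, seed = 41)
u2 <- fitUnivariate(sim$trait2, pan, opts, seed = 81)
bv <- fitBivariate(pair, pan, list(u1, u2), opts, seed = 121)
bv
#> MixerFit (bivariate): logLik = -15441.19, AIC = 30892.38, n = 5000
#>   pi1           0.002445
#>   pi2           0.002917
#>   pi12          0.003286
#>   sigmaBetaSq1  0.001377
#>   sigmaBetaSq2  0.0009835
#>   rho12         0.4177
#>   sigma0Sq1     0.973
#>   sigma0Sq2     1.005
#>   rho0          0.006035

p <- fitParams(bv)
p@pi12 / (p@pi1 + p@pi12)   # estimated shared fraction of trait 1 (truth 0.5)
#> [1] 0.5733909
nExplaining90(p, M = 1e5)[["shared"]]  # shared variants explaining 90% of shared h2
#> [1] 146.0947
concordantFraction(p@rho12)  # fraction of shared effects with the same sign
#> [1] 0.637162
```

The fitted π's say roughly half of trait 1's causal variants also influence
trait 2 (truth: 0.5), ~146 shared variants (0.446 × π̂₁₂ × M) carry 90% of
the shared-component heritability, and ~64% of shared effects agree in sign
(truth: 71% at ρ₁₂ = 0.6; one replicate at desk scale carries visible
sampling noise — medians across replicates are what the test suite checks).
For reporting at publication scale, `formatVenn(6600, 2000)` renders a
Venn-component count as `"6.6 (2.0)"` (thousands, SD in parentheses).

Discovery end of the pipeline:

```r
grids <- buildFdrGrids(pair, pan, pruneIters = 10, seed = 5)
disc  <- discover(pair, grids, threshold = 0.05)
loci  <- defineLoci(disc, pan)
effectDirectionConcordance(loci, pair)$fraction
```

`runAll(config)` chains every stage and writes a report bundle (Venn table,
Q–Q and Manhattan plots, discovery and locus TSVs, JSON summary); a thin
CLI wrapper lives in `exec/pleiomix`.

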