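#' Synthetic block-diagonal LD panel
#'
#' Builds an AR(1)-within-block panel: inside a block the signed correlation
#' decays as `rho^|j-k|`; across blocks it is exactly zero. Blocks are laid
#' out across chromosomes 1-22 (cycling) with 2 Mb gaps, 5 kb between
#' adjacent variants, so physical distance and LD structure are consistent.
#' Correlations below 1e-3 in magnitude are truncated to keep the panel
#' sparse.
#'
#' @param n_blocks number of independent LD blocks.
#' @param block_size variants per block (`n_blocks * block_size <= 1e6`).
#' @param rho AR(1) decay parameter in \[0, 1); 0 gives an identity panel.
#'   A vector is recycled across blocks, giving heterogeneous LD (and a
#'   spread of LD scores, as in real genomes).
#' @param seed recorded in the panel's provenance; construction itself is
#'   deterministic.
#' @return an [LDPanel-class] of `n_blocks * block_size` variants.
#' @examples
#' pan <- makeBlockPanel(10, 10, rho = 0.8, seed = 1)
#' range(ldScores(pan))
#' @export
makeBlockPanel <- function(n_blocks, block_size, rho, seed = 1L) {
    stopifnot(all(rho >= 0), all(rho < 1), n_blocks * block_size <= 1e6)
    rhoBlock <- rep_len(rho, n_blocks)
    m <- n_blocks * block_size
    blockOf <- rep(seq_len(n_blocks), each = block_size)
    blocksPerChr <- ceiling(n_blocks / 22)
    chrom <- ((blockOf - 1L) %/% blocksPerChr) + 1L
    blockOnChr <- (blockOf - 1L) %% blocksPerChr
    posInBlock <- rep(seq_len(block_size), n_blocks)
    bp <- 1e6 + blockOnChr * (block_size * 5000 + 2e6) + (posInBlock - 1L) * 5000
    variants <- data.frame(
        SNP = sprintf("snp%07d", seq_len(m)),
        CHR = as.integer(chrom), BP = as.integer(bp))

    ii <- jj <- integer(0); xx <- numeric(0)
    allStarts <- (seq_len(n_blocks) - 1L) * block_size
    for (rv in unique(rhoBlock)) {
        starts <- allStarts[rhoBlock == rv]
        bw <- if (rv == 0) 0L else min(block_size - 1L, floor(log(1e-3) / log(rv)))
        for (d in seq_len(bw)) {
            nIn <- block_size - d
            i <- rep(starts, each = nIn) + rep(seq_len(nIn), length(starts))
            ii <- c(ii, i); jj <- c(jj, i + d); xx <- c(xx, rep(rv^d, length(i)))
        }
    }
    R <- Matrix::sparseMatrix(i = c(ii, jj, seq_len(m)), j = c(jj, ii, seq_len(m)),
        x = c(xx, xx, rep(1, m)), dims = c(m, m))
    pan <- LDPanel(variants, R, window = 1e6)
    pan@variants$seed <- NULL
    attr(pan@variants, "seed") <- seed
    pan
}

# deterministic non-palindromic allele pairs for synthetic variants
.synthAlleles <- function(m) {
    pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2, byrow = TRUE)
    idx <- ((seq_len(m) - 1L) %% 4L) + 1L
    list(a1 = pairs[idx, 1], a2 = pairs[idx, 2])
}

#' Simulate a bivariate GWAS summary-statistics pair with known truth
#'
#' Generates per-SNP z-scores for two traits under the four-component causal
#' mixture the analysis assumes. Each variant is independently null,
#' causal for trait 1 only, causal for trait 2 only, or shared, with
#' probabilities `(1 - pi1 - pi2 - pi12, pi1, pi2, pi12)`. Causal effects are
#' normal with variances `sigmaBetaSq1/2` (per standardized genotype); shared
#' effects are bivariate normal with correlation `rho12`. Observed z-scores
#' are \eqn{z_{tj} = \sqrt{n_t} \sum_k r_{jk} \beta_{tk} + \epsilon_{tj}}
#' with residuals bivariate normal across traits (variances `sigma0Sq1/2`,
#' correlation `rho0`) and independent across SNPs; \eqn{p = 2\Phi(-|z|)}.
#'
#' @param panel an [LDPanel-class] supplying `r` and variant coordinates.
#' @param params a [BivariateMixtureParams-class].
#' @param n1,n2 per-trait sample sizes.
#' @param nOverlap individuals shared between the two GWAS; when positive it
#'   overrides `rho0` with `nOverlap / sqrt(n1 * n2)`.
#' @param seed integer seed; all randomness derives from it.
#' @param effectSign +1 or -1; -1 negates every effect and residual draw,
#'   negating z deterministically (useful for sign-symmetry checks).
#' @param labels trait labels for the two output tables.
#' @return list with elements `trait1`, `trait2` ([SummaryStats-class]),
#'   `truth` (data.frame: `SNP`, `label` in
#'   \{null, causal1, causal2, shared\}, `beta1`, `beta2`) and `meta` (all
#'   parameters plus the seed and effective `rho0`).
#' @export
simulatePair <- function(panel, params, n1, n2, nOverlap = 0, seed = 1L,
                         effectSign = 1, labels = c("trait1", "trait2")) {
    stopifnot(is(panel, "LDPanel"), is(params, "BivariateMixtureParams"))
    p <- as.list(params)
    if (p$pi1 + p$pi2 + p$pi12 > 1) stop("pi1 + pi2 + pi12 must be <= 1")
    rho0 <- if (nOverlap > 0) nOverlap / sqrt(n1 * n2) else p$rho0
    m <- nVariants(panel)
    sim <- withSeed(seed, {
        lab <- sample.int(4L, m, replace = TRUE,
            prob = c(1 - p$pi1 - p$pi2 - p$pi12, p$pi1, p$pi2, p$pi12)) - 1L
        b1 <- b2 <- numeric(m)
        i1 <- lab == 1L; i2 <- lab == 2L; i12 <- lab == 3L
        b1[i1] <- rnorm(sum(i1), 0, sqrt(p$sigmaBetaSq1))
        b2[i2] <- rnorm(sum(i2), 0, sqrt(p$sigmaBetaSq2))
        if (any(i12)) {
            x <- rnorm(sum(i12)); y <- rnorm(sum(i12))
            b1[i12] <- sqrt(p$sigmaBetaSq1) * x
            b2[i12] <- sqrt(p$sigmaBetaSq2) * (p$rho12 * x + sqrt(1 - p$rho12^2) * y)
        }
        u <- rnorm(m); v <- rnorm(m)
        e1 <- sqrt(p$sigma0Sq1) * u
        e2 <- sqrt(p$sigma0Sq2) * (rho0 * u + sqrt(1 - rho0^2) * v)
        list(lab = lab, b1 = effectSign * b1, b2 = effectSign * b2,
            e1 = effectSign * e1, e2 = effectSign * e2)
    })
    z1 <- sqrt(n1) * as.numeric(panel@R %*% sim$b1) + sim$e1
    z2 <- sqrt(n2) * as.numeric(panel@R %*% sim$b2) + sim$e2
    al <- .synthAlleles(m)
    mkTab <- function(z, n, label) {
        tab <- data.frame(SNP = panel@variants$SNP, CHR = panel@variants$CHR,
            BP = panel@variants$BP, A1 = al$a1, A2 = al$a2,
            Z = z, P = pmax(2 * pnorm(-abs(z)), 1e-300), N = n)
        new("SummaryStats", traitLabel = label, table = tab, qcLog = list())
    }
    truth <- data.frame(SNP = panel@variants$SNP,
        label = c("null", "causal1", "causal2", "shared")[sim$lab + 1L],
        beta1 = sim$b1, beta2 = sim$b2)
    list(trait1 = mkTab(z1, n1, labels[1]), trait2 = mkTab(z2, n2, labels[2]),
        truth = truth,
        meta = c(p, list(rho0Effective = rho0, n1 = n1, n2 = n2,
            nOverlap = nOverlap, seed = seed, effectSign = effectSign)))
}

#' Write a simulated pair to disk
#'
#' Canonical sumstats TSVs for both traits, a truth TSV (`SNP label beta1
#' beta2`) and a YAML run-metadata file holding every parameter and the seed.
#'
#' @param sim result of [simulatePair()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        trait1 = file.path(dir, paste0(traitLabel(sim$trait1), ".sumstats.tsv")),
        trait2 = file.path(dir, paste0(traitLabel(sim$trait2), ".sumstats.tsv")),
        truth = file.path(dir, "truth.tsv"),
        meta = file.path(dir, "simulation_meta.yaml"))
    writeSumstats(sim$trait1, paths[["trait1"]])
    writeSumstats(sim$trait2, paths[["trait2"]])
    utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(sim$meta, paths[["meta"]])
    invisible(paths)
}
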