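# shared fixture builders: everything is generated in code at test time

# an LD panel from a dense symmetric correlation matrix, one chromosome
panelFromDense <- function(R, chrom = 1L, bp = NULL) {
    m <- nrow(R)
    if (is.null(bp)) bp <- seq(1e6, by = 5e4, length.out = m)
    LDPanel(data.frame(SNP = sprintf("s%03d", seq_len(m)), CHR = chrom,
        BP = as.integer(bp)), R)
}

# canonical sumstats from a z vector aligned to a panel
sumstatsFromZ <- function(panel, z, n = 1e5, label = "trait") {
    v <- panelVariants(panel)
    m <- nrow(v)
    pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2, byrow = TRUE)
    idx <- ((seq_len(m) - 1L) %% 4L) + 1L
    new("SummaryStats", traitLabel = label, table = data.frame(
        SNP = v$SNP, CHR = v$CHR, BP = v$BP, A1 = pairs[idx, 1], A2 = pairs[idx, 2],
        Z = z, P = pmax(2 * pnorm(-abs(z)), 1e-300), N = n), qcLog = list())
}

pairFromZ <- function(panel, z1, z2, n = 1e5) {
    new("HarmonizedPair", trait1 = sumstatsFromZ(panel, z1, n, "t1"),
        trait2 = sumstatsFromZ(panel, z2, n, "t2"), log = list())
}

pairFromSim <- function(sim) {
    new("HarmonizedPair", trait1 = sim$trait1, trait2 = sim$trait2, log = list())
}

bivParams <- function(pi1 = 3e-3, pi2 = 3e-3, pi12 = 3e-3, sb1 = 1e-3, sb2 = sb1,
                      rho12 = 0, s01 = 1, s02 = 1, rho0 = 0) {
    new("BivariateMixtureParams", pi1 = pi1, pi2 = pi2, pi12 = pi12,
        sigmaBetaSq1 = sb1, sigmaBetaSq2 = sb2, rho12 = rho12,
        sigma0Sq1 = s01, sigma0Sq2 = s02, rho0 = rho0)
}

uniParams <- function(pi = 3e-3, sb = 1e-3, s0 = 1) {
    new("UnivariateMixtureParams", pi = pi, sigmaBetaSq = sb, sigma0Sq = s0)
}

# fast mixture-fit options used across tests (small subsets, single pruning
# draw, one refined optimizer start)
fastFitOptions <- function(...) {
    do.call(mixerOptions, utils::modifyList(
        list(pruneReps = 1, maxVariants = 5000, nStarts = 1), list(...)))
}

# write a small sumstats file and return its path
writeTempSumstats <- function(df, sep = "\t") {
    path <- tempfile(fileext = ".tsv")
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    path
}
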