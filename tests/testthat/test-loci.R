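# discovery table with given significance pattern on a panel
.mkDisc <- function(panel, conjfdr, flag = conjfdr < 0.05, z1 = NULL, z2 = NULL) {
    v <- panelVariants(panel)
    m <- nrow(v)
    if (is.null(z1)) z1 <- rep(2, m)
    if (is.null(z2)) z2 <- rep(2, m)
    data.frame(SNP = v$SNP, CHR = v$CHR, BP = v$BP, Z1 = z1, Z2 = z2,
        P1 = 0.5, P2 = 0.5, CONDFDR12 = conjfdr, CONDFDR21 = conjfdr,
        CONJFDR = conjfdr, FLAG = flag)
}

test_that("independent significant and lead SNPs follow the clumping tiers", {
    # single significant variant is its own tier
    pan1 <- makeBlockPanel(1, 3, rho = 0, seed = 1)
    disc <- .mkDisc(pan1, c(0.01, 1, 1))
    is1 <- independentSignificant(disc, pan1)
    expect_equal(is1$indices, 1L)
    expect_equal(leadSnps(is1$indices, pan1, disc$CONJFDR), 1L)

    # two ind-sig SNPs with r2 = 0.05: both lead
    R <- matrix(c(1, sqrt(0.05), sqrt(0.05), 1), 2)
    pan2 <- panelFromDense(R)
    disc2 <- .mkDisc(pan2, c(0.01, 0.02))
    is2 <- independentSignificant(disc2, pan2)
    expect_equal(sort(is2$indices), c(1L, 2L))
    expect_equal(sort(leadSnps(is2$indices, pan2, disc2$CONJFDR)), c(1L, 2L))

    # 6-SNP toy with mixed r2, hand-worked greedy outcome:
    # r2: (1,2) = 0.7, (2,3) = 0.7, (1,3) = 0.3, (4,5) = 0.2, all else ~ 0
    r <- diag(6)
    r[1, 2] <- r[2, 1] <- sqrt(0.7); r[2, 3] <- r[3, 2] <- sqrt(0.7)
    r[1, 3] <- r[3, 1] <- sqrt(0.3); r[4, 5] <- r[5, 4] <- sqrt(0.2)
    pan6 <- panelFromDense(r)
    disc6 <- .mkDisc(pan6, c(1e-8, 1e-6, 1e-4, 1e-3, 1e-2, 0.04))
    is6 <- independentSignificant(disc6, pan6)     # 1 absorbs 2; 3, 4, 5, 6 stay
    expect_equal(sort(is6$indices), c(1L, 3L, 4L, 5L, 6L))
    # lead tier at r2 >= 0.1: 1 absorbs 3 (0.3), 4 absorbs 5 (0.2), 6 alone
    expect_equal(sort(leadSnps(is6$indices, pan6, disc6$CONJFDR)), c(1L, 4L, 6L))
})

test_that("locus definition matches hand-worked merging cases", {
    # isolated significant SNP with no LD partners: single-SNP locus
    pan <- makeBlockPanel(1, 3, rho = 0, seed = 1)
    disc <- .mkDisc(pan, c(1, 0.01, 1))
    loci <- defineLoci(disc, pan)
    expect_length(loci, 1L)
    expect_equal(GenomicRanges::start(loci), GenomicRanges::end(loci))
    expect_equal(unlist(S4Vectors::mcols(loci)$leadSnps), panelVariants(pan)$SNP[2],
        ignore_attr = TRUE)

    # two single-SNP clusters 200 kb apart merge under the 250 kb rule
    R <- diag(2)
    pan2 <- panelFromDense(R, bp = c(1e6, 1.2e6))
    loci2 <- defineLoci(.mkDisc(pan2, c(0.01, 0.02)), pan2)
    expect_length(loci2, 1L)
    expect_equal(GenomicRanges::start(loci2), 1e6)
    expect_equal(GenomicRanges::end(loci2), 1.2e6)

    # 260 kb apart: two loci ("closer than" is strict)
    pan3 <- panelFromDense(R, bp = c(1e6, 1.26e6))
    expect_length(defineLoci(.mkDisc(pan3, c(0.01, 0.02)), pan3), 2L)
})

test_that("locus definition equals a brute-force oracle on random instances", {
    bruteLoci <- function(disc, dense, bp, candR2 = 0.6, mergeKb = 250) {
        sig <- which(disc$FLAG)
        if (!length(sig)) return(NULL)
        # greedy clump at candR2 among significant
        reps <- integer(0); un <- sig[order(disc$CONJFDR[sig], bp[sig])]
        assigned <- logical(length(bp))
        for (j in un) {
            if (assigned[j]) next
            reps <- c(reps, j)
            absorb <- which(dense[j, ]^2 >= candR2 & !assigned & disc$FLAG)
            assigned[absorb] <- TRUE; assigned[j] <- TRUE
        }
        # candidate intervals then interval merge
        iv <- t(vapply(reps, function(s) {
            cand <- which(dense[s, ]^2 >= candR2)
            c(min(bp[cand]), max(bp[cand]))
        }, numeric(2)))
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        out <- iv[1, , drop = FALSE]
        for (k in seq_len(nrow(iv))[-1]) {
            gap <- iv[k, 1] - out[nrow(out), 2] - 1
            if (gap < mergeKb * 1000) {
                out[nrow(out), 2] <- max(out[nrow(out), 2], iv[k, 2])
            } else out <- rbind(out, iv[k, ])
        }
        out
    }
    for (s in 1:100) {
        set.seed(s)
        m <- sample(5:50, 1)
        nb <- max(1, m %/% 8)
        pan <- makeBlockPanel(nb, ceiling(m / nb), rho = runif(1, 0, 0.95), seed = s)
        pan <- pan[seq_len(m)]
        keepOne <- panelVariants(pan)$CHR == panelVariants(pan)$CHR[1]
        pan <- pan[which(keepOne)]          # single chromosome keeps the oracle simple
        mm <- nVariants(pan)
        cj <- 10^runif(mm, -6, 0)
        disc <- .mkDisc(pan, cj)
        loci <- defineLoci(disc, pan, flagRegions = NULL)
        oracle <- bruteLoci(disc, as.matrix(panelMatrix(pan)), panelVariants(pan)$BP)
        if (is.null(oracle)) {
            expect_length(loci, 0L)
        } else {
            expect_equal(GenomicRanges::start(loci), unname(oracle[, 1]))
            expect_equal(GenomicRanges::end(loci), unname(oracle[, 2]))
        }
    }
})

test_that("locus invariants hold on simulated discoveries", {
    pan <- makeBlockPanel(100, 50, rho = 0.7, seed = 1)
    sim <- simulatePair(pan, bivParams(pi1 = 1e-3, pi2 = 1e-3, pi12 = 4e-3,
        sb1 = 2e-3, sb2 = 2e-3, rho12 = 0.8), 1e5, 1e5, seed = 23)
    pair <- pairFromSim(sim)
    grids <- buildFdrGrids(pair, pan, pruneIters = 5, seed = 2, exclude = NULL)
    disc <- discover(pair, grids)
    loci <- defineLoci(disc, pan)
    expect_gt(length(loci), 0L)
    mc <- S4Vectors::mcols(loci)
    # tiers nest: lead <= indSig <= candidates; minConjFDR below threshold
    for (l in seq_along(loci)) {
        expect_true(all(mc$leadSnps[[l]] %in% mc$indSigSnps[[l]]))
        expect_true(all(mc$indSigSnps[[l]] %in% mc$candidateSnps[[l]]))
    }
    expect_true(all(mc$minConjfdr < 0.05))
    # loci are pairwise non-overlapping within one analysis
    expect_true(all(GenomicRanges::countOverlaps(loci, loci) == 1L))
    # every significant SNP belongs to exactly one locus's candidate list
    counts <- table(factor(unlist(mc$candidateSnps),
        levels = disc$SNP))[disc$SNP[disc$FLAG]]
    expect_true(all(counts == 1L))
    # determinism of the full chain
    loci2 <- defineLoci(discover(pair, grids), pan)
    expect_identical(as.data.frame(loci2), as.data.frame(loci))
})

test_that("effect-direction concordance counts lead SNPs and labels loci", {
    # 106 independent flagged SNPs, 93 with concordant directions: 88%
    pan <- makeBlockPanel(106, 1, rho = 0, seed = 1)
    z2 <- c(rep(2, 93), rep(-2, 13))
    disc <- .mkDisc(pan, rep(0.01, 106), z1 = rep(2, 106), z2 = z2)
    loci <- defineLoci(disc, pan, flagRegions = NULL)
    expect_length(loci, 106L)
    pair <- pairFromZ(pan, disc$Z1, disc$Z2)
    conc <- effectDirectionConcordance(loci, pair)
    expect_equal(conc$nConcordant, 93L)
    expect_equal(conc$nLeads, 106L)
    expect_equal(round(100 * conc$fraction), 88)
    expect_equal(sum(conc$locusLabels == "+"), 93L)
    expect_equal(sum(conc$locusLabels == "+/-"), 13L)

    # all concordant: fraction 1, every locus labelled "+"
    discAll <- .mkDisc(pan, rep(0.01, 106), z1 = rep(-1, 106), z2 = rep(-3, 106))
    lociAll <- defineLoci(discAll, pan, flagRegions = NULL)
    concAll <- effectDirectionConcordance(lociAll, pairFromZ(pan, discAll$Z1, discAll$Z2))
    expect_equal(concAll$fraction, 1)
    expect_true(all(concAll$locusLabels == "+"))

    # z = 0 leads are excluded with a warning
    discZ <- .mkDisc(pan, rep(0.01, 106), z1 = c(0, rep(2, 105)), z2 = rep(2, 106))
    lociZ <- defineLoci(discZ, pan, flagRegions = NULL)
    expect_warning(cz <- effectDirectionConcordance(lociZ, pairFromZ(pan, discZ$Z1, discZ$Z2)),
        "z = 0")
    expect_equal(cz$nLeads, 105L)
})

test_that("physical locus overlap uses closed intervals", {
    gr <- function(chr, lo, hi) GenomicRanges::GRanges(chr, IRanges::IRanges(lo, hi))
    a <- gr(c("1", "2"), c(100, 500), c(200, 600))
    expect_equal(nrow(overlapLoci(a, a)), 2L)
    # shared endpoint counts
    b <- gr("1", 200, 300)
    expect_equal(nrow(overlapLoci(a, b)), 1L)
    expect_equal(nrow(overlapLoci(gr("1", 100, 199), gr("1", 200, 300))), 0L)
    # random interval sets match the all-pairs brute force
    set.seed(11)
    for (r in 1:20) {
        la <- sort(sample(1:1000, 8)); lb <- sort(sample(1:1000, 8))
        A <- gr("3", la[c(1, 3, 5, 7)], la[c(2, 4, 6, 8)])
        B <- gr("3", lb[c(1, 3, 5, 7)], lb[c(2, 4, 6, 8)])
        ov <- overlapLoci(A, B)
        brute <- sum(outer(seq_len(4), seq_len(4), Vectorize(function(i, j)
            la[2 * i - 1] <= lb[2 * j] && lb[2 * j - 1] <= la[2 * i])))
        expect_equal(nrow(ov), brute)
    }
})
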