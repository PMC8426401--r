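#' Independent significant SNPs
#'
#' Greedy clumping of the conjFDR-significant SNPs at the FUMA assignment
#' threshold (r-squared 0.6): the most significant unassigned SNP becomes a
#' representative and absorbs significant SNPs in LD with it.
#'
#' @param discoveries discovery table from [discover()], row-aligned to the
#'   panel.
#' @param panel an [LDPanel-class].
#' @param r2Threshold assignment threshold (FUMA default 0.6).
#' @return list with `indices` (independent significant SNP row indices, in
#'   selection order) and `assignment` (representative row index per
#'   significant SNP, `NA` elsewhere).
#' @export
independentSignificant <- function(discoveries, panel, r2Threshold = 0.6) {
    stopifnot(nrow(discoveries) == nVariants(panel))
    sig <- which(discoveries$FLAG)
    if (!length(sig)) return(list(indices = integer(0), assignment = rep(NA_integer_, nrow(discoveries))))
    scores <- rep(NA_real_, nrow(discoveries))
    scores[sig] <- discoveries$CONJFDR[sig]
    cl <- greedyClump(scores, panel, r2Threshold, candidates = sig)
    list(indices = cl$representatives, assignment = cl$assignment)
}

#' Lead SNPs
#'
#' Greedy clumping of the independent significant SNPs at r-squared 0.1;
#' the representatives are the lead SNPs.
#'
#' @param indSig integer indices of independent significant SNPs.
#' @param panel an [LDPanel-class].
#' @param scores per-panel-variant significance (lower is better), e.g. the
#'   `CONJFDR` column of the discovery table.
#' @param r2Threshold FUMA default 0.1.
#' @return integer vector of lead SNP indices (subset of `indSig`).
#' @export
leadSnps <- function(indSig, panel, scores, r2Threshold = 0.1) {
    if (!length(indSig)) return(integer(0))
    sc <- rep(NA_real_, nVariants(panel))
    sc[indSig] <- scores[indSig]
    greedyClump(sc, panel, r2Threshold, candidates = indSig)$representatives
}

#' Define genomic loci from conjFDR discoveries (FUMA protocol)
#'
#' Chains the FUMA tiers: independent significant SNPs (clump at r2 >= 0.6
#' among significant SNPs), candidate SNPs (all panel SNPs, significant or
#' not, with r2 >= 0.6 to an independent significant SNP), per-cluster
#' intervals spanning the candidates' min/max positions, merging of
#' same-chromosome intervals closer than `mergeKb`, and lead SNPs (clump of
#' the independent significant set at r2 >= 0.1). Loci overlapping
#' complex-LD regions are flagged, not removed.
#'
#' @inheritParams independentSignificant
#' @param candidateR2 candidate/assignment threshold (0.6).
#' @param leadR2 lead-SNP threshold (0.1).
#' @param mergeKb merge loci on the same chromosome closer than this (kb).
#' @param flagRegions regions that set the `inComplexLD` flag
#'   ([defaultExcludedRegions()]).
#' @return a [GenomicRanges::GRanges] with one range per locus (1-based
#'   inclusive `bpMin`-`bpMax` over candidate SNPs) and metadata columns:
#'   `nIndSig`, `nCandidates`, `indSigSnps`, `leadSnps`, `candidateSnps`
#'   (CharacterLists of SNP ids), `minConjfdr`, `leadZ1`, `leadZ2`
#'   (comma-joined per-lead z-scores), `inComplexLD`.
#' @export
defineLoci <- function(discoveries, panel, candidateR2 = 0.6, leadR2 = 0.1,
                       mergeKb = 250, flagRegions = defaultExcludedRegions()) {
    is0 <- independentSignificant(discoveries, panel, candidateR2)
    if (!length(is0$indices)) {
        return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(as.character(1:22))))
    }
    indSig <- is0$indices
    v <- panel@variants
    # candidate sets: every variant at r2 >= candidateR2 with an ind-sig SNP
    Rsub <- panel@R[, indSig, drop = FALSE]
    candSets <- lapply(seq_along(indSig), function(s) {
        col <- Rsub[, s]
        which(col^2 >= candidateR2)
    })
    clLo <- vapply(candSets, function(cs) min(v$BP[cs]), numeric(1))
    clHi <- vapply(candSets, function(cs) max(v$BP[cs]), numeric(1))
    clusters <- GenomicRanges::GRanges(as.character(v$CHR[indSig]),
        IRanges::IRanges(clLo, clHi))
    loci <- GenomicRanges::reduce(clusters, min.gapwidth = mergeKb * 1000)
    hit <- GenomicRanges::findOverlaps(clusters, loci)
    clusterLocus <- integer(length(indSig))
    clusterLocus[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)

    leads <- leadSnps(indSig, panel, discoveries$CONJFDR, leadR2)
    nl <- length(loci)
    indSigL <- candL <- leadL <- vector("list", nl)
    minFdr <- numeric(nl); z1s <- z2s <- character(nl); flag <- logical(nl)
    for (l in seq_len(nl)) {
        cl <- which(clusterLocus == l)
        is <- indSig[cl]
        cand <- sort(unique(unlist(candSets[cl])))
        myLeads <- intersect(leads, is)
        if (!length(myLeads)) myLeads <- is[which.min(discoveries$CONJFDR[is])]
        myLeads <- myLeads[order(discoveries$CONJFDR[myLeads], v$CHR[myLeads], v$BP[myLeads])]
        indSigL[[l]] <- discoveries$SNP[is]
        candL[[l]] <- discoveries$SNP[cand]
        leadL[[l]] <- discoveries$SNP[myLeads]
        sigCand <- cand[discoveries$FLAG[cand]]
        minFdr[l] <- min(discoveries$CONJFDR[sigCand])
        z1s[l] <- paste(sprintf("%.3f", discoveries$Z1[myLeads]), collapse = ",")
        z2s[l] <- paste(sprintf("%.3f", discoveries$Z2[myLeads]), collapse = ",")
        chromL <- as.integer(as.character(GenomeInfoDb::seqnames(loci)[l]))
        flag[l] <- .insideAnyRegion(chromL, GenomicRanges::start(loci)[l],
            GenomicRanges::end(loci)[l], flagRegions)
    }
    S4Vectors::mcols(loci) <- S4Vectors::DataFrame(
        nIndSig = lengths(indSigL), nCandidates = lengths(candL),
        indSigSnps = IRanges::CharacterList(indSigL),
        leadSnps = IRanges::CharacterList(leadL),
        candidateSnps = IRanges::CharacterList(candL),
        minConjfdr = minFdr, leadZ1 = z1s, leadZ2 = z2s, inComplexLD = flag)
    loci
}

.insideAnyRegion <- function(chrom, lo, hi, regions) {
    if (is.null(regions) || !nrow(regions)) return(FALSE)
    any(regions$chrom == chrom & lo <= regions$hi & hi >= regions$lo)
}

#' Effect-direction concordance of lead SNPs
#'
#' A lead SNP is concordant iff its harmonized z-scores satisfy
#' \eqn{z_1 z_2 > 0}. The fraction is computed over lead SNPs; a locus is
#' labelled `"+"` when all of its lead SNPs are concordant and `"+/-"`
#' otherwise. Lead SNPs with z = 0 in either trait are excluded with a
#' warning.
#'
#' @param loci GRanges from [defineLoci()].
#' @param pair the [HarmonizedPair-class] the discoveries came from.
#' @return list with `fraction` (concordant lead SNPs / lead SNPs),
#'   `nConcordant`, `nLeads`, `locusLabels` (`"+"` / `"+/-"` per locus) and
#'   `leads` (per-lead data.frame: SNP, z1, z2, concordant).
#' @export
effectDirectionConcordance <- function(loci, pair) {
    t1 <- pair@trait1@table; t2 <- pair@trait2@table
    leadIds <- unlist(S4Vectors::mcols(loci)$leadSnps)
    i <- match(leadIds, t1$SNP)
    z1 <- t1$Z[i]; z2 <- t2$Z[i]
    zero <- z1 == 0 | z2 == 0
    if (any(zero)) warning(sum(zero), " lead SNP(s) with z = 0 excluded from concordance")
    conc <- (z1 * z2 > 0)[!zero]
    perLocus <- vapply(S4Vectors::mcols(loci)$leadSnps, function(ids) {
        j <- match(ids, t1$SNP)
        zz <- t1$Z[j] * t2$Z[j]
        zz <- zz[zz != 0]
        if (!length(zz)) NA_character_ else if (all(zz > 0)) "+" else "+/-"
    }, character(1))
    list(fraction = mean(conc), nConcordant = sum(conc), nLeads = length(conc),
        locusLabels = perLocus,
        leads = data.frame(SNP = leadIds[!zero], z1 = z1[!zero], z2 = z2[!zero],
            concordant = conc))
}

#' Physical overlap between two locus sets
#'
#' Pairs of loci whose 1-based inclusive `[bpMin, bpMax]` intervals
#' intersect on the same chromosome (a shared endpoint counts as overlap).
#'
#' @param lociA,lociB GRanges from [defineLoci()].
#' @return data.frame with one row per overlapping pair: indices into both
#'   sets, chromosome, and both intervals.
#' @export
overlapLoci <- function(lociA, lociB) {
    hit <- GenomicRanges::findOverlaps(lociA, lociB)
    qa <- S4Vectors::queryHits(hit); sb <- S4Vectors::subjectHits(hit)
    data.frame(indexA = qa, indexB = sb,
        chrom = as.character(GenomeInfoDb::seqnames(lociA))[qa],
        bpMinA = GenomicRanges::start(lociA)[qa], bpMaxA = GenomicRanges::end(lociA)[qa],
        bpMinB = GenomicRanges::start(lociB)[sb], bpMaxB = GenomicRanges::end(lociB)[sb])
}
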