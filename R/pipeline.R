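#' Read, validate and write a run configuration
#'
#' A run configuration is a named list (YAML on disk) driving [runAll()].
#' Recognized keys and defaults: `sumstats1`, `sumstats2` (paths),
#' `columnMap1/2`, `traitLabels`, `panelPrefix` (see [readLDPanel()]),
#' `outdir`, `seed` (1), `conjfdrThreshold` (0.05), `qqThresholds`
#' (1, 0.1, 0.01, 0.001), `pruneR2` (0.1), `pruneIters` (100), `clumpR2`
#' (0.6), `leadR2` (0.1), `mergeKb` (250), `excludeRegions` ("default"),
#' `dropAmbiguous` (TRUE), `mixer` (overrides for [mixerOptions()]),
#' `runMixer`, `runLdsc` (TRUE), `writePlots` (TRUE). The configuration
#' round-trips unchanged through [writeRunConfig()]/[readRunConfig()].
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
    validateRunConfig(yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @param config configuration list.
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' @rdname readRunConfig
#' @export
validateRunConfig <- function(config) {
    defaults <- list(seed = 1L, conjfdrThreshold = 0.05,
        qqThresholds = c(1, 0.1, 0.01, 0.001), pruneR2 = 0.1, pruneIters = 100L,
        clumpR2 = 0.6, leadR2 = 0.1, mergeKb = 250, excludeRegions = "default",
        dropAmbiguous = TRUE, mixer = list(), runMixer = TRUE, runLdsc = TRUE,
        writePlots = TRUE, traitLabels = NULL)
    for (nm in names(defaults)) if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    with(config, {
        stopifnot(conjfdrThreshold > 0, conjfdrThreshold <= 1,
            pruneR2 > 0, pruneR2 < 1, clumpR2 > 0, clumpR2 <= 1,
            leadR2 > 0, leadR2 <= 1, mergeKb >= 0, pruneIters >= 1,
            all(qqThresholds > 0 & qqThresholds <= 1))
    })
    config
}

.configRegions <- function(x) {
    if (is.null(x)) return(NULL)
    if (identical(x, "default")) return(defaultExcludedRegions())
    if (identical(x, "none")) return(NULL)
    as.data.frame(x)
}

.subsetPair <- function(pair, idx) {
    new("HarmonizedPair", trait1 = .subsetSumstats(pair@trait1, idx),
        trait2 = .subsetSumstats(pair@trait2, idx), log = pair@log)
}

.writeTsv <- function(df, path, schemaNote) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# columns: ", schemaNote), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Format a Venn-component variant count
#'
#' Counts rendered in thousands with one decimal, SD in parentheses when
#' available: `formatVenn(6600, 2000)` gives `"6.6 (2.0)"`;
#' `formatVenn(11500)` gives `"11.5"`.
#'
#' @param estimate variant count.
#' @param sd its standard error (variant count), or `NA`/missing.
#' @return display string.
#' @export
formatVenn <- function(estimate, sd = NA_real_) {
    stopifnot(estimate >= 0)
    if (is.na(sd)) sprintf("%.1f", estimate / 1000)
    else sprintf("%.1f (%.1f)", estimate / 1000, sd / 1000)
}

#' Run the full cross-trait overlap pipeline
#'
#' Executes harmonization, region exclusion for fitting, univariate and
#' bivariate mixture fits, conditional Q-Q in both directions, condFDR grid
#' construction, conjFDR discovery, FUMA-style locus definition,
#' effect-direction concordance and LD-score-regression rg, writing a report
#' bundle to `config$outdir`: `venn.tsv`, `mixer_fit.json`, `qq_*.tsv` (+
#' plots), `discovery.tsv`, `loci.tsv`, `concordance.tsv`, `manhattan.png`
#' and `summary.json` (versions, seeds, parameters, stage log). Every output
#' table starts with a `# columns:` schema comment. Identical configuration
#' and seed give byte-identical tables.
#'
#' @param config configuration list (see [readRunConfig()]); `sumstats1/2`
#'   and `panelPrefix` may be replaced by in-memory objects via the
#'   `pair`/`panel` arguments.
#' @param pair optional pre-built [HarmonizedPair-class] (skips reading).
#' @param panel optional [LDPanel-class].
#' @return invisible list with all in-memory results and `paths` of the
#'   written files.
#' @export
runAll <- function(config, pair = NULL, panel = NULL) {
    config <- validateRunConfig(config)
    outdir <- config$outdir %||% stop("config$outdir is required")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stage <- "setup"
    log <- list(package = "pleiomix",
        version = as.character(utils::packageVersion("pleiomix")),
        seed = config$seed)
    paths <- character(0)
    fail <- function(e) stop("pipeline stage '", stage, "' failed: ",
        conditionMessage(e), call. = FALSE)
    tryCatch({
        stage <- "read"
        if (is.null(panel)) panel <- readLDPanel(config$panelPrefix)
        if (is.null(pair)) {
            t1 <- readSumstats(config$sumstats1, config$columnMap1,
                traitLabel = config$traitLabels[1] %||% "trait1")
            t2 <- readSumstats(config$sumstats2, config$columnMap2,
                traitLabel = config$traitLabels[2] %||% "trait2")
            stage <- "harmonize"
            pair <- harmonize(t1, t2, dropAmbiguous = config$dropAmbiguous)
        }
        stage <- "align"
        al <- matchToPanel(pair, panel)
        pair <- al$x; panel <- al$panel
        log$nShared <- nVariants(pair)
        regions <- .configRegions(config$excludeRegions)

        mixFit <- NULL
        if (isTRUE(config$runMixer)) {
            stage <- "mixer"
            fitKeep <- if (is.null(regions)) seq_len(nVariants(pair))
                       else which(!inRegions(pair@trait1, regions))
            pairFit <- .subsetPair(pair, fitKeep)
            panelFit <- panel[fitKeep]
            mopts <- do.call(mixerOptions, config$mixer)
            u1 <- fitUnivariate(pairTrait(pairFit, "trait1"), panelFit, mopts,
                seed = config$seed)
            u2 <- fitUnivariate(pairTrait(pairFit, "trait2"), panelFit, mopts,
                seed = config$seed + 500L)
            biv <- fitBivariate(pairFit, panelFit, list(u1, u2), mopts,
                seed = config$seed + 1000L)
            M <- nVariants(panel)
            counts <- nExplaining90(biv@params, M)
            seCounts <- biv@se[c("pi1", "pi2", "pi12")] * M *
                (counts[["shared"]] / max(biv@params@pi12 * M, .Machine$double.eps))
            venn <- data.frame(
                component = c("unique1", "unique2", "shared"),
                n_variants = as.numeric(counts),
                se = as.numeric(seCounts),
                display = vapply(1:3, function(i)
                    formatVenn(counts[[i]], seCounts[[i]]), character(1)))
            paths["venn"] <- .writeTsv(venn, file.path(outdir, "venn.tsv"),
                "component n_variants(explaining 90% h2) se display(thousands)")
            mixFit <- list(uni1 = u1, uni2 = u2, biv = biv,
                rg = modelRg(biv@params),
                concordant = concordantFraction(biv@params@rho12),
                dice = diceCoefficient(biv@params))
            jsonlite::write_json(list(
                univariate1 = as.list(u1@params), univariate2 = as.list(u2@params),
                bivariate = as.list(biv@params), se = as.list(biv@se),
                loglik = biv@loglik, aic = biv@aic, deltaAIC = as.list(biv@details$deltaAIC),
                modelRg = mixFit$rg, concordantFraction = mixFit$concordant,
                dice = mixFit$dice, venn = venn$display),
                file.path(outdir, "mixer_fit.json"), auto_unbox = TRUE, digits = NA)
            paths["mixer"] <- file.path(outdir, "mixer_fit.json")
        }

        stage <- "qq"
        qq1 <- conditionalQQ(pair, 1, config$qqThresholds)
        qq2 <- conditionalQQ(pair, 2, config$qqThresholds)
        for (q in list(qq1, qq2)) {
            nm <- paste0("qq_", gsub("[^A-Za-z0-9]", "_", q@primary))
            df <- do.call(rbind, lapply(names(q@curves), function(s)
                cbind(stratum = s, q@curves[[s]])))
            paths[nm] <- .writeTsv(df, file.path(outdir, paste0(nm, ".tsv")),
                "stratum expected(-log10 p) observed(-log10 p)")
            if (isTRUE(config$writePlots) && isTRUE(unname(capabilities("png")))) {
                f <- file.path(outdir, paste0(nm, ".png"))
                ggplot2::ggsave(f, plotConditionalQQ(q), width = 5, height = 4, dpi = 120)
                paths[paste0(nm, "_plot")] <- f
            }
        }

        stage <- "fdr-grid"
        grids <- buildFdrGrids(pair, panel, pruneIters = config$pruneIters,
            seed = config$seed, exclude = regions, r2Threshold = config$pruneR2)
        stage <- "discovery"
        disc <- discover(pair, grids, config$conjfdrThreshold)
        paths["discovery"] <- .writeTsv(
            within(disc, {
                CONDFDR12 <- sprintf("%.6g", CONDFDR12)
                CONDFDR21 <- sprintf("%.6g", CONDFDR21)
                CONJFDR <- sprintf("%.6g", CONJFDR)
            }),
            file.path(outdir, "discovery.tsv"),
            "SNP CHR BP Z1 Z2 P1 P2 CONDFDR12 CONDFDR21 CONJFDR FLAG")
        if (isTRUE(config$writePlots) && isTRUE(unname(capabilities("png")))) {
            f <- file.path(outdir, "manhattan.png")
            ggplot2::ggsave(f, plotManhattan(disc, config$conjfdrThreshold),
                width = 7, height = 3, dpi = 120)
            paths["manhattan"] <- f
        }

        stage <- "loci"
        loci <- defineLoci(disc, panel, candidateR2 = config$clumpR2,
            leadR2 = config$leadR2, mergeKb = config$mergeKb,
            flagRegions = .configRegions(config$excludeRegions))
        stage <- "concordance"
        conc <- if (length(loci)) effectDirectionConcordance(loci, pair) else NULL
        lociDf <- if (length(loci)) data.frame(
            Chr = as.character(GenomeInfoDb::seqnames(loci)),
            MinBP = GenomicRanges::start(loci), MaxBP = GenomicRanges::end(loci),
            LeadSNPs = vapply(S4Vectors::mcols(loci)$leadSnps, paste, character(1), collapse = ","),
            ConjFDR = sprintf("%.3g", S4Vectors::mcols(loci)$minConjfdr),
            Direction = conc$locusLabels,
            NIndSig = S4Vectors::mcols(loci)$nIndSig,
            NCandidates = S4Vectors::mcols(loci)$nCandidates,
            InComplexLD = S4Vectors::mcols(loci)$inComplexLD)
          else data.frame(Chr = character(), MinBP = integer(), MaxBP = integer(),
            LeadSNPs = character(), ConjFDR = character(), Direction = character(),
            NIndSig = integer(), NCandidates = integer(), InComplexLD = logical())
        paths["loci"] <- .writeTsv(lociDf, file.path(outdir, "loci.tsv"),
            "Chr MinBP MaxBP LeadSNPs ConjFDR(min) Direction(+ concordant, +/- discordant) NIndSig NCandidates InComplexLD")
        if (!is.null(conc)) {
            paths["concordance"] <- .writeTsv(conc$leads,
                file.path(outdir, "concordance.tsv"),
                "SNP z1 z2 concordant(z1*z2>0)")
            log$concordanceFraction <- conc$fraction
        }
        log$nDiscovered <- sum(disc$FLAG)
        log$nLoci <- length(loci)

        ldsc <- NULL
        if (isTRUE(config$runLdsc)) {
            stage <- "ldsc"
            ldsc <- fitLdscRg(pair, ldScores(panel))
            log$ldscRg <- ldsc$rg; log$ldscRgSe <- ldsc$se; log$ldscRgP <- ldsc$p
        }

        stage <- "summary"
        log$parameters <- config[setdiff(names(config), c("outdir"))]
        jsonlite::write_json(log, file.path(outdir, "summary.json"),
            auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
        paths["summary"] <- file.path(outdir, "summary.json")
        invisible(list(pair = pair, panel = panel, mixer = mixFit, qq = list(qq1, qq2),
            grids = grids, discoveries = disc, loci = loci, concordance = conc,
            ldsc = ldsc, log = log, paths = paths))
    }, error = fail)
}
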