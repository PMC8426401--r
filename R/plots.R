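#' Plot conditional Q-Q curves
#'
#' Observed versus expected -log10 p of the primary trait, one curve per
#' secondary-trait stratum; the dashed identity line is the global null.
#' Successive upward/leftward deflections with tightening strata indicate
#' cross-trait enrichment.
#'
#' @importFrom rlang .data
#' @param qq a [QQCurves-class].
#' @param maxExpected truncate curves at this expected -log10 p (display
#'   only).
#' @return a ggplot object.
#' @export
plotConditionalQQ <- function(qq, maxExpected = 8) {
    df <- do.call(rbind, lapply(names(qq@curves), function(nm) {
        d <- qq@curves[[nm]]
        d$stratum <- nm
        d
    }))
    df <- df[df$expected <= maxExpected, ]
    df$stratum <- factor(df$stratum, levels = names(qq@curves))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
            colour = .data$stratum)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
        ggplot2::geom_line() +
        ggplot2::labs(x = expression(Expected ~ -log[10](p)),
            y = expression(Observed ~ -log[10](p)),
            colour = "Secondary stratum",
            title = paste("Conditional Q-Q:", qq@primary)) +
        ggplot2::theme_minimal()
}

#' Manhattan-style plot of conjFDR values
#'
#' -log10 conjFDR by genomic position, chromosomes concatenated; the dotted
#' line marks the significance threshold.
#'
#' @param discoveries discovery table from [discover()].
#' @param threshold conjFDR threshold drawn as a dotted line.
#' @return a ggplot object.
#' @export
plotManhattan <- function(discoveries, threshold = 0.05) {
    d <- discoveries
    offs <- c(0, cumsum(tapply(d$BP, d$CHR, max)))
    d$x <- d$BP + offs[match(d$CHR, sort(unique(d$CHR)))]
    d$y <- -log10(d$CONJFDR)
    d$chrCol <- factor(d$CHR %% 2)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$chrCol)) +
        ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
        ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 3) +
        ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
        ggplot2::labs(x = "Genomic position (chromosomes concatenated)",
            y = expression(-log[10](conjFDR))) +
        ggplot2::theme_minimal()
}
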