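#' Test windows for differential binding
#'
#' Fits a negative binomial GLM to every window using an abundance-dependent
#' dispersion trend, estimates quasi-likelihood dispersions from the GLM
#' deviances, shrinks them towards their own abundance trend with
#' empirical-Bayes moderation, and computes a QL F-test P-value per window
#' for the requested contrast.
#'
#' @param x A \code{"window_counts"} object of (filtered) windows, with any
#'   normalization already attached.
#' @param design Full-rank design matrix (libraries x coefficients).
#' @param coef Column index/indices (or names) of \code{design} to drop
#'   under the null. Ignored when \code{contrast} is given.
#' @param contrast Numeric contrast vector over the coefficients defining a
#'   single-df null hypothesis.
#' @param abundance Optional precomputed per-window abundances; computed
#'   with \code{\link{average_abundance}} otherwise (one definition shared
#'   by filtering and both dispersion trends).
#' @param prior_count Pseudocount for the abundance computation.
#' @param robust Passed to the EB shrinkage step.
#' @param ... Further arguments for
#'   \code{\link{estimate_dispersion_trend}}.
#'
#' @return Object of class \code{"window_test"}: a per-window table
#'   (\code{$table} with chrom, start, end, logFC, F, p_value,
#'   ave_log_abundance, shrunk_s2) plus the dispersion fits.
#' @export
window_test <- function(x, design, coef = ncol(design), contrast = NULL,
                        abundance = NULL, prior_count = 2, robust = TRUE,
                        ...) {
    stopifnot(inherits(x, "window_counts"))
    design <- as.matrix(design)
    n <- ncol(x$counts)
    if (nrow(design) != n)
        stop("design matrix rows must match the number of libraries")
    if (qr(design)$rank < ncol(design))
        stop("design matrix is not of full rank")
    if (n - ncol(design) < 1L)
        stop("at least one residual degree of freedom is required")

    if (!is.null(contrast)) {
        contrast <- as.numeric(contrast)
        stopifnot(length(contrast) == ncol(design))
        reform <- limma::contrastAsCoef(design, contrast, first = FALSE)
        design_full <- reform$design
        test_cols <- reform$coef
    } else {
        if (is.character(coef)) coef <- match(coef, colnames(design))
        if (any(is.na(coef)) || any(coef < 1) || any(coef > ncol(design)))
            stop("invalid 'coef'")
        design_full <- design
        test_cols <- coef
    }
    design_null <- design_full[, -test_cols, drop = FALSE]
    df_test <- length(test_cols)

    if (is.null(abundance)) abundance <- average_abundance(x, prior_count)
    off <- .glm_offsets(x)

    trend <- estimate_dispersion_trend(x$counts, design_full, abundance,
                                       offset = off, ...)
    phi <- trend(abundance)
    full <- nb_glm_fit(x$counts, design_full, offset = off, dispersion = phi)
    null <- nb_glm_fit(x$counts, design_null, offset = off, dispersion = phi)
    qld <- ql_dispersions(full$deviance, full$df_residual, abundance,
                          robust = robust)
    d0 <- if (length(qld$df_prior) == 1L) qld$df_prior else qld$df_prior
    ft <- ql_f_test(full$deviance, null$deviance, df_test, qld$shrunk_s2,
                    d0, full$df_residual)

    logFC <- full$coefficients[, test_cols[1]] / log(2)
    tab <- data.frame(chrom = x$regions$chrom, start = x$regions$start,
                      end = x$regions$end, logFC = logFC,
                      F = ft$statistic, p_value = ft$p_value,
                      ave_log_abundance = abundance,
                      shrunk_s2 = qld$shrunk_s2)
    rownames(tab) <- NULL
    structure(list(table = tab, dispersion_trend = trend, ql = qld,
                   design = design_full, test_cols = test_cols,
                   df_test = df_test, df_residual = full$df_residual,
                   coefficients = full$coefficients),
              class = "window_test")
}

# Per-entry natural-log offsets implied by the normalization state.
.glm_offsets <- function(x) {
    if (!is.null(x$offsets)) {
        log(mean(x$lib.sizes)) + log(2) * x$offsets
    } else {
        log(x$lib.sizes * x$norm.factors)
    }
}

#' @export
print.window_test <- function(x, ...) {
    cat("window_test:", nrow(x$table), "windows,",
        x$df_test, "df contrast\n")
    cat("  prior df (d0):", format(x$ql$df_prior[1]),
        " residual df:", x$df_residual, "\n")
    cat("  windows with p < 0.05:", sum(x$table$p_value < 0.05), "\n")
    invisible(x)
}

#' @export
summary.window_test <- function(object, ...) {
    out <- list(n = nrow(object$table),
                df_prior = object$ql$df_prior[1],
                df_residual = object$df_residual,
                p_summary = summary(object$table$p_value),
                logFC_summary = summary(object$table$logFC))
    class(out) <- "summary.window_test"
    out
}

#' @export
print.summary.window_test <- function(x, ...) {
    cat("Window-level QL F-tests on", x$n, "windows\n")
    cat("prior df:", format(x$df_prior), " residual df:", x$df_residual, "\n")
    cat("p-values:\n"); print(x$p_summary)
    cat("log2 fold changes:\n"); print(x$logFC_summary)
    invisible(x)
}

#' @export
coef.window_test <- function(object, ...) {
    object$coefficients / log(2)
}

#' MA-style plot of window-level results
#'
#' @param x A \code{"window_test"} object.
#' @param p_cutoff Highlight windows with p below this value.
#' @param ... Passed to \code{plot}.
#' @export
plot.window_test <- function(x, p_cutoff = 0.05, ...) {
    tab <- x$table
    sig <- tab$p_value < p_cutoff
    graphics::plot(tab$ave_log_abundance, tab$logFC, pch = 16, cex = 0.3,
                   col = ifelse(sig, "red", "grey40"),
                   xlab = "average log2 CPM", ylab = "log2 fold change", ...)
    graphics::abline(h = 0, lty = 2)
    invisible(x)
}
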