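#' Abundance-dependent trend in the NB dispersions
#'
#' Estimates how the negative binomial dispersion varies with average
#' abundance. Windows are grouped into abundance bins; within each bin the
#' Cox-Reid adjusted profile likelihood, evaluated on a shared dispersion
#' grid with per-window GLM fits, is summed and maximized (with quadratic
#' interpolation on the log-dispersion grid). The per-bin estimates are
#' smoothed against abundance and returned as a callable trend; evaluation
#' outside the observed abundance range returns the nearest boundary value.
#'
#' With fewer than \code{min_windows} windows a single global estimate is
#' used for all abundances.
#'
#' @param y Count matrix (windows x libraries).
#' @param design Full-rank design matrix.
#' @param abundance Per-window average log2-CPM from
#'   \code{\link{average_abundance}}.
#' @param offset Log-scale offsets as in \code{\link{nb_glm_fit}}.
#' @param grid_length Number of points of the dispersion grid.
#' @param grid_range Range of the dispersion grid (both ends > 0).
#' @param nbins Number of abundance bins; by default chosen from the window
#'   count (at most 20, at least ~200 windows per bin).
#' @param min_windows Below this count a global estimate is returned
#'   (default 200).
#'
#' @return A function mapping abundance to dispersion, with attributes
#'   \code{bin_abundance} and \code{bin_dispersion}.
#' @export
estimate_dispersion_trend <- function(y, design, abundance, offset = NULL,
                                      grid_length = 15L,
                                      grid_range = c(1e-6, 5),
                                      nbins = NULL, min_windows = 200L) {
    y <- as.matrix(y)
    W <- nrow(y)
    if (ncol(y) - ncol(design) < 1L)
        stop("no residual degrees of freedom: dispersion is inestimable")
    stopifnot(length(abundance) == W)
    grid <- 10^seq(log10(grid_range[1]), log10(grid_range[2]),
                   length.out = grid_length)
    if (is.null(nbins)) nbins <- max(1L, min(20L, floor(W / 200)))
    if (W < min_windows) nbins <- 1L

    apl <- matrix(0, W, grid_length)
    beta <- NULL
    for (g in seq_along(grid)) {
        fit <- nb_glm_fit(y, design, offset = offset, dispersion = grid[g],
                          beta_start = beta)
        beta <- fit$coefficients
        apl[, g] <- nb_loglik(y, fit$fitted, grid[g]) -
            .cr_adjust(fit$weights, as.matrix(design))
    }

    if (nbins > 1L) {
        br <- stats::quantile(abundance, probs = seq(0, 1, length.out = nbins + 1))
        br <- unique(br)
        bin <- cut(abundance, breaks = br, include.lowest = TRUE)
    } else bin <- factor(rep(1L, W))
    lx <- log10(grid)
    bins <- levels(bin)
    phi_b <- numeric(length(bins))
    ab_b <- numeric(length(bins))
    for (b in seq_along(bins)) {
        idx <- which(bin == bins[b])
        s <- colSums(apl[idx, , drop = FALSE])
        m <- which.max(s)
        if (m == 1L || m == grid_length) {
            phi_b[b] <- grid[m]
        } else {
            # quadratic interpolation around the grid maximum
            x1 <- lx[m - 1]; x2 <- lx[m]; x3 <- lx[m + 1]
            y1 <- s[m - 1]; y2 <- s[m]; y3 <- s[m + 1]
            denom <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
            if (abs(denom) < 1e-12) {
                phi_b[b] <- grid[m]
            } else {
                xs <- x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) -
                                  (x2 - x3)^2 * (y2 - y1)) / denom
                xs <- min(max(xs, x1), x3)
                phi_b[b] <- 10^xs
            }
        }
        ab_b[b] <- stats::median(abundance[idx])
    }

    if (length(bins) >= 5L) {
        sm <- stats::lowess(ab_b, log(phi_b), f = 2 / 3)
        vals <- exp(stats::approx(sm$x, sm$y, xout = ab_b, rule = 2,
                                  ties = mean)$y)
    } else vals <- phi_b

    fn <- if (length(bins) == 1L) {
        v <- vals[1]
        function(a) rep(v, length(a))
    } else {
        af <- stats::approxfun(ab_b, vals, rule = 2, ties = mean)
        function(a) af(a)
    }
    attr(fn, "bin_abundance") <- ab_b
    attr(fn, "bin_dispersion") <- vals
    fn
}

#' Quasi-likelihood dispersions with empirical-Bayes shrinkage
#'
#' The raw QL dispersion of each window is the residual deviance of the NB
#' GLM fit divided by its residual degrees of freedom. An abundance-
#' dependent trend is fitted to the raw values and each estimate is shrunk
#' towards the trend, with weights determined by a prior degrees of freedom
#' d0 estimated by moment-matching the spread of the log dispersions around
#' the trend to a scaled F distribution (via \code{limma::squeezeVar}).
#' d0 = Inf collapses every estimate onto the trend; d0 = 0 leaves the raw
#' values untouched.
#'
#' @param deviance Per-window residual deviances from the full-model fit.
#' @param df_resid Residual degrees of freedom (libraries - coefficients,
#'   >= 1).
#' @param abundance Per-window average log2-CPM (trend covariate).
#' @param robust Passed to \code{limma::squeezeVar}.
#' @param s2_floor Lower bound applied to raw dispersions (guards saturated
#'   fits with zero deviance).
#'
#' @return List of class \code{"ql_dispersions"}: \code{s2} (raw),
#'   \code{trend} (prior value per window), \code{trend_fn} (callable over
#'   abundance), \code{df_prior} (d0, possibly Inf), \code{shrunk_s2} and
#'   \code{df_resid}.
#' @export
ql_dispersions <- function(deviance, df_resid, abundance, robust = TRUE,
                           s2_floor = 1e-8) {
    if (df_resid < 1L) stop("residual degrees of freedom must be >= 1")
    if (all(deviance <= 0))
        warning("all deviances are zero; QL dispersions set to the floor")
    s2 <- pmax(deviance / df_resid, s2_floor)
    n <- length(s2)
    if (n >= 10L) {
        sv <- limma::squeezeVar(s2, df = df_resid, covariate = abundance,
                                robust = robust)
    } else {
        sv <- limma::squeezeVar(s2, df = df_resid, robust = FALSE)
    }
    d0 <- sv$df.prior
    d0[is.finite(d0) & d0 > 1e6] <- 1e6
    trend <- rep_len(sv$var.prior, n)
    d0v <- rep_len(d0, n)
    shrunk <- ifelse(is.finite(d0v),
                     (d0v * trend + df_resid * s2) / (d0v + df_resid),
                     trend)
    ord <- order(abundance)
    trend_fn <- if (n >= 2L && length(unique(abundance)) >= 2L)
        stats::approxfun(abundance[ord], trend[ord], rule = 2, ties = mean)
    else function(a) rep(trend[1], length(a))
    structure(list(s2 = s2, trend = trend, trend_fn = trend_fn,
                   df_prior = if (length(d0) == 1L) d0 else d0v,
                   shrunk_s2 = shrunk, df_resid = df_resid),
              class = "ql_dispersions")
}

#' Quasi-likelihood F-test for differential binding
#'
#' Compares nested NB GLM fits. The numerator is the deviance difference per
#' tested coefficient; the denominator is the EB-shrunk QL dispersion. The
#' reference distribution is F with (df_test, d0 + df_resid) degrees of
#' freedom, which accounts for the uncertainty of the dispersion estimate;
#' infinite d0 recovers a chi-squared/df reference.
#'
#' @param dev_full,dev_null Residual deviances of the full and null fits
#'   (the null model must be nested in the full model).
#' @param df_test Number of constraints tested (>= 1).
#' @param shrunk_s2 EB-moderated QL dispersions from
#'   \code{\link{ql_dispersions}}.
#' @param df_prior Prior degrees of freedom d0 (scalar, possibly Inf).
#' @param df_resid Residual degrees of freedom of the full fit.
#'
#' @return List with \code{statistic} (F) and \code{p_value}.
#' @export
ql_f_test <- function(dev_full, dev_null, df_test, shrunk_s2, df_prior,
                      df_resid) {
    if (df_test < 1L) stop("'df_test' must be >= 1")
    Fstat <- pmax(dev_null - dev_full, 0) / df_test / shrunk_s2
    df2 <- df_prior + df_resid
    p <- stats::pf(Fstat, df_test, df2, lower.tail = FALSE)
    list(statistic = Fstat, p_value = p)
}
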