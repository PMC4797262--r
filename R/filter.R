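#' Average log2 counts-per-million abundance
#'
#' Per-region abundance summary across libraries on a log2 CPM scale, used
#' for background filtering and as the covariate of the dispersion trends.
#' Counts are first adjusted to a common (mean) effective library size and
#' averaged; the pseudocount, expressed in counts-per-million units, is
#' added once to that averaged rate — never to raw per-library counts — so
#' the statistic is invariant to a joint rescaling of all counts and
#' library sizes.
#'
#' @param x A \code{"window_counts"} object with positive library sizes.
#' @param prior_count Pseudocount in CPM units added to the averaged rate
#'   (> 0).
#'
#' @return Numeric vector of per-region average log2-CPM values.
#' @export
average_abundance <- function(x, prior_count = 2) {
    stopifnot(inherits(x, "window_counts"))
    if (length(prior_count) != 1L || is.na(prior_count) || prior_count <= 0)
        stop("'prior_count' must be a single positive value")
    eff <- x$lib.sizes * x$norm.factors
    if (any(eff <= 0)) stop("effective library sizes must be positive")
    mean_lib <- mean(eff)
    scaled <- x$counts %*% (mean_lib / eff) / ncol(x$counts)
    as.numeric(log2(scaled / mean_lib * 1e6 + prior_count))
}

#' Global background abundance rescaled to window width
#'
#' The median average abundance of large genomic bins estimates the
#' non-specific background. For comparison with window abundances, bin
#' count rates are downscaled by the ratio of the bin width to the
#' effective window width before the pseudocount is added, so the scaled
#' values are exactly the abundances that windows of background coverage
#' would show under the same pseudocount. (Downscaling the abundance by
#' log2 of the width ratio after adding the pseudocount would understate
#' the background for narrow windows, where counts and pseudocount are of
#' comparable size.) The effective width is
#' \code{window_width + frag_len - 1}: an extended fragment is counted
#' whenever its 5' end lies within frag_len - 1 bp of the window, so
#' windows collect reads from a correspondingly wider footprint.
#'
#' @param bin_counts A \code{"window_counts"} object of bin-level counts
#'   (e.g. 2 kbp bins).
#' @param window_width Window width in bp.
#' @param frag_len Average fragment length in bp used during counting.
#' @param prior_count Pseudocount, matching the one used for the window
#'   abundances.
#'
#' @return Scalar background abundance on the window-equivalent log2-CPM
#'   scale.
#' @export
scaled_background <- function(bin_counts, window_width, frag_len,
                              prior_count = 2) {
    stopifnot(inherits(bin_counts, "window_counts"))
    if (nrow(bin_counts$counts) == 0L) stop("no bins supplied")
    if (length(prior_count) != 1L || is.na(prior_count) || prior_count <= 0)
        stop("'prior_count' must be a single positive value")
    bin_width <- bin_counts$width
    eff_width <- window_width + frag_len - 1
    if (bin_width <= eff_width)
        stop("bin width must exceed the effective window width")
    scale <- bin_width / eff_width
    eff <- bin_counts$lib.sizes * bin_counts$norm.factors
    if (any(eff <= 0)) stop("effective library sizes must be positive")
    mean_lib <- mean(eff)
    scaled <- bin_counts$counts %*% (mean_lib / eff) / ncol(bin_counts$counts)
    ab <- log2(scaled / scale / mean_lib * 1e6 + prior_count)
    stats::median(ab)
}

#' Filter windows against the scaled background
#'
#' Retains windows whose average abundance is at least
#' \code{min_log2fc} log2 units (default 1, i.e. two-fold or greater) above
#' the scaled background estimate. Filtering depends only on abundances, not
#' on the design or contrast, so type I error control downstream is
#' unaffected.
#'
#' @param ave_log_abundance Per-window abundances from
#'   \code{\link{average_abundance}}.
#' @param background Scalar from \code{\link{scaled_background}} (same
#'   scale).
#' @param min_log2fc Minimum log2 increase over background (default 1).
#'
#' @return Logical keep-mask over windows.
#' @export
filter_windows <- function(ave_log_abundance, background, min_log2fc = 1) {
    ave_log_abundance >= background + min_log2fc
}
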