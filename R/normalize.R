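#' Trimmed mean of M-values normalization factors
#'
#' Scaling normalization between libraries computed from doubly trimmed
#' log-ratios against a reference library, without precision weighting.
#' Applied to large-bin counts this removes composition biases; applied to
#' high-abundance windows it corrects for differences in immunoprecipitation
#' efficiency. Factors multiply the library sizes ("effective library
#' sizes") and have geometric mean 1.
#'
#' @param x A \code{"window_counts"} object with at least two libraries.
#' @param logratio_trim Fraction trimmed from each tail of the M-values
#'   (default 0.3).
#' @param abs_trim Fraction trimmed from each tail of the A-values
#'   (default 0.05).
#' @param ref_library Reference library index, or NULL to pick the library
#'   whose 75th percentile count rate is closest to the mean across
#'   libraries.
#'
#' @return List of class \code{"normalization_result"} with elements
#'   \code{norm_factors}, \code{mode} and \code{offsets} (NULL here).
#' @export
tmm_factors <- function(x, logratio_trim = 0.3, abs_trim = 0.05,
                        ref_library = NULL) {
    stopifnot(inherits(x, "window_counts"))
    y <- x$counts
    if (ncol(y) < 2L) stop("TMM requires at least two libraries")
    zero <- which(colSums(y) == 0)
    if (length(zero))
        stop("library with all-zero counts: ", paste(zero, collapse = ", "))
    lib <- x$lib.sizes
    rate <- sweep(y, 2, lib, "/")
    if (is.null(ref_library)) {
        f75 <- apply(rate, 2, function(r) stats::quantile(r[r > 0], 0.75))
        ref_library <- which.min(abs(f75 - mean(f75)))
    }
    f <- vapply(seq_len(ncol(y)), function(j) {
        if (j == ref_library) return(1)
        .tmm_pair(y[, j], y[, ref_library], lib[j], lib[ref_library],
                  logratio_trim, abs_trim)
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    structure(list(norm_factors = f, mode = "tmm", offsets = NULL,
                   ref_library = ref_library),
              class = "normalization_result")
}

# Unweighted doubly-trimmed mean of M-values for one library vs reference.
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
    keep <- obs > 0 & ref > 0
    o <- obs[keep] / n_obs
    r <- ref[keep] / n_ref
    M <- log2(o / r)
    A <- 0.5 * log2(o * r)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]
    if (!length(M) || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1
    hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    2^mean(M[keep2])
}

#' Loess offsets for trended biases
#'
#' Non-linear normalization removing systematic differences between
#' libraries that vary with abundance. For each library a loess curve of M
#' (log2 count of that library minus the mean log2 count across libraries,
#' i.e. versus an average pseudo-reference) is fitted against the average
#' abundance A, and the fitted values, recentred so each region's offsets
#' have zero mean across libraries, become per-entry log2-scale offsets for
#' the GLM. Counts themselves are never modified. Loess offsets subsume
#' library-size scaling and are mutually exclusive with TMM factors.
#'
#' @param x A \code{"window_counts"} object with at least 50 regions.
#' @param span Loess span in (0, 1] (default 0.5).
#' @param prior_count Pseudocount used in the log transformation.
#'
#' @return List of class \code{"normalization_result"} with
#'   \code{offsets} (regions x libraries matrix, log2 scale, zero row
#'   means), \code{norm_factors} all 1, \code{mode = "loess"}.
#' @export
loess_offsets <- function(x, span = 0.5, prior_count = 0.5) {
    stopifnot(inherits(x, "window_counts"))
    if (length(span) != 1L || is.na(span) || span <= 0 || span > 1)
        stop("'span' must be in (0, 1]")
    y <- x$counts
    if (nrow(y) < 50L) stop("at least 50 regions required for a stable fit")
    ly <- log2(y + prior_count)
    A <- rowMeans(ly)
    off <- matrix(0, nrow(y), ncol(y))
    o <- order(A)
    for (j in seq_len(ncol(y))) {
        M <- ly[, j] - A
        fit <- stats::lowess(A[o], M[o], f = span)
        off[, j] <- stats::approx(fit$x, fit$y, xout = A, rule = 2,
                                  ties = mean)$y
    }
    off <- off - rowMeans(off)
    structure(list(norm_factors = rep(1, ncol(y)), mode = "loess",
                   offsets = off), class = "normalization_result")
}

#' Attach a normalization result to a count matrix
#'
#' @param x A \code{"window_counts"} object.
#' @param norm A \code{"normalization_result"} from \code{\link{tmm_factors}}
#'   or \code{\link{loess_offsets}}.
#' @return The updated \code{"window_counts"}.
#' @export
apply_normalization <- function(x, norm) {
    stopifnot(inherits(x, "window_counts"),
              inherits(norm, "normalization_result"))
    if (norm$mode == "loess") {
        if (!is.null(norm$offsets) &&
            nrow(norm$offsets) != nrow(x$counts))
            stop("offset matrix does not match the count matrix")
        if (any(x$norm.factors != 1))
            stop("TMM factors and loess offsets are mutually exclusive")
        x$offsets <- norm$offsets
    } else {
        if (!is.null(x$offsets))
            stop("TMM factors and loess offsets are mutually exclusive")
        x$norm.factors <- norm$norm_factors
    }
    x
}

#' @export
print.normalization_result <- function(x, ...) {
    cat("normalization (", x$mode, ")\n", sep = "")
    if (x$mode == "loess")
        cat("  per-entry log2 offsets for", ncol(x$offsets), "libraries\n")
    else
        cat("  factors:", paste(format(round(x$norm_factors, 4)),
                                collapse = ", "), "\n")
    invisible(x)
}
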