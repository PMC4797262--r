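#' Cluster adjacent windows into candidate regions
#'
#' Single left-to-right pass per chromosome: a window joins the current
#' cluster when the gap between its start and the cluster's right boundary
#' is at most \code{tolerance} and the resulting span would not exceed
#' \code{max_width}; otherwise a new cluster is started at that window
#' (greedy splitting, which protects against chaining). Abutting windows
#' (gap 0) always merge at tolerance 0.
#'
#' @param windows data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, sorted by chromosome then start (error otherwise).
#' @param tolerance Maximum allowed gap in bp (>= 0), where gap =
#'   next start - current cluster end.
#' @param max_width Maximum cluster span in bp.
#'
#' @return Integer vector of cluster ids (1-based, increasing along the
#'   input).
#' @export
merge_windows <- function(windows, tolerance = 100, max_width = 5000) {
    stopifnot(tolerance >= 0, max_width >= 1)
    n <- nrow(windows)
    if (n == 0L) return(integer(0))
    chrom <- as.character(windows$chrom)
    start <- windows$start; end <- windows$end
    new_chrom <- c(TRUE, chrom[-1] != chrom[-n])
    if (n > 1L && any(!new_chrom[-1] & diff(start) < 0))
        stop("windows must be sorted by chromosome then start")
    cl <- integer(n)
    nextid <- 0L
    i <- 1L
    while (i <= n) {
        # one tolerance-chain starting at i, split greedily by max_width
        nextid <- nextid + 1L
        cstart <- start[i]
        cend <- end[i]
        cl[i] <- nextid
        j <- i + 1L
        while (j <= n && chrom[j] == chrom[j - 1L] &&
               start[j] - cend <= tolerance) {
            if (max(end[j], cend) - cstart > max_width) {
                nextid <- nextid + 1L
                cstart <- start[j]
                cend <- end[j]
            } else {
                cend <- max(cend, end[j])
            }
            cl[j] <- nextid
            j <- j + 1L
        }
        i <- j
    }
    cl
}

#' Simes' combined P-value
#'
#' Combines the P-values of a region's member windows into a single value
#' representing the evidence against the global null that no member window
#' is differentially bound: with sorted p(1) <= ... <= p(n), the combined
#' value is min_j n * p(j) / j, capped at 1.
#'
#' @param p Numeric vector of member P-values in [0, 1] (length >= 1).
#' @return Scalar combined P-value.
#' @export
simes_combine <- function(p) {
    if (!length(p)) stop("at least one P-value is required")
    if (any(is.na(p)) || any(p < 0 | p > 1)) stop("P-values must be in [0, 1]")
    n <- length(p)
    ps <- sort(p)
    min(1, min(n * ps / seq_len(n)))
}

# Vectorized grouped Simes over an integer cluster assignment; returns the
# combined p per cluster (named by cluster id order of first appearance)
# and, for the direction summary, the per-cluster threshold p(j*) at the
# minimizing index.
.simes_grouped <- function(p, cluster) {
    ord <- order(cluster, p)
    pc <- p[ord]; cc <- cluster[ord]
    lens <- rle(cc)$lengths
    rank_in <- sequence(lens)
    n_in <- rep(lens, lens)
    adj <- n_in * pc / rank_in
    first <- !duplicated(cc)
    grp <- cumsum(first)
    comb <- rep(Inf, max(grp))
    thresh <- rep(NA_real_, max(grp))
    o <- order(grp, adj)
    g2 <- grp[o]
    keep <- !duplicated(g2)
    comb[g2[keep]] <- pmin(1, adj[o][keep])
    thresh[g2[keep]] <- pc[o][keep]
    ids <- cc[first]
    list(ids = ids, combined = comb, threshold = thresh)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Standard step-up adjustment (via \code{stats::p.adjust}) applied to the
#' combined region-level P-values, controlling the FDR across reported
#' regions.
#'
#' @param p Numeric vector of P-values (length >= 1).
#' @return Vector of BH-adjusted values.
#' @export
bh_adjust <- function(p) {
    if (!length(p)) stop("at least one P-value is required")
    stats::p.adjust(p, method = "BH")
}

#' Summarize clustered windows into regions
#'
#' Clusters the tested windows, combines member P-values with Simes'
#' method, applies BH correction across regions, and reports the best
#' (most significant) window of each region together with a direction
#' summary derived from the logFC signs of the members at or below the
#' Simes-minimizing P-value.
#'
#' @param test A \code{"window_test"} object or a data.frame with columns
#'   chrom, start, end, logFC, p_value.
#' @param tolerance Merge tolerance in bp (default 100).
#' @param max_width Maximum region span in bp (default 5000).
#'
#' @return data.frame of class \code{"db_regions"}: chrom, start, end,
#'   n_windows, combined_p, fdr, best_start, best_end, best_p, best_logFC,
#'   direction.
#' @export
region_results <- function(test, tolerance = 100, max_width = 5000) {
    tab <- if (inherits(test, "window_test")) test$table else test
    ord <- order(tab$chrom, tab$start, tab$end)
    tab <- tab[ord, , drop = FALSE]
    cl <- merge_windows(tab, tolerance = tolerance, max_width = max_width)
    if (!length(cl))
        return(structure(data.frame(), class = c("db_regions", "data.frame")))

    sg <- .simes_grouped(tab$p_value, cl)
    nw <- as.integer(table(cl)[as.character(sg$ids)])
    cstart <- tapply(tab$start, cl, min)[as.character(sg$ids)]
    cend <- tapply(tab$end, cl, max)[as.character(sg$ids)]
    cchrom <- tab$chrom[!duplicated(cl)]

    # best window: min p, ties by larger |logFC|, then leftmost start
    bo <- order(cl, tab$p_value, -abs(tab$logFC), tab$start)
    bfirst <- bo[!duplicated(cl[bo])]
    bidx <- bfirst[match(sg$ids, cl[bfirst])]

    # direction from members with p <= the Simes-minimizing member p-value
    thr <- sg$threshold[match(cl, sg$ids)]
    contrib <- tab$p_value <= thr
    pos <- tapply(contrib & tab$logFC > 0, cl, any)[as.character(sg$ids)]
    neg <- tapply(contrib & tab$logFC < 0, cl, any)[as.character(sg$ids)]
    dir <- ifelse(pos & neg, "mixed", ifelse(pos, "up", "down"))

    out <- data.frame(chrom = cchrom, start = as.numeric(cstart),
                      end = as.numeric(cend), n_windows = nw,
                      combined_p = sg$combined,
                      fdr = bh_adjust(sg$combined),
                      best_start = tab$start[bidx],
                      best_end = tab$end[bidx],
                      best_p = tab$p_value[bidx],
                      best_logFC = tab$logFC[bidx],
                      direction = dir)
    rownames(out) <- NULL
    class(out) <- c("db_regions", "data.frame")
    out
}

#' Write regions as BED6
#'
#' Scores are -10*log10(combined P-value), capped at 1000.
#'
#' @param regions A \code{"db_regions"} data.frame.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
    score <- pmin(1000, round(-10 * log10(pmax(regions$combined_p, 1e-300))))
    bed <- data.frame(regions$chrom, regions$start, regions$end,
                      paste0("region", seq_len(nrow(regions))), score, ".")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
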