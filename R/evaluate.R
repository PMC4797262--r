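#' Score detected regions against simulation truth
#'
#' A detected region is a true positive iff it overlaps (>= 1 bp) the DB
#' subinterval of any true DB site; overlap elsewhere in a site footprint
#' does not count. Observed FDR is the fraction of detected regions that
#' are not true positives (NA when nothing is detected); detection power is
#' the fraction of true DB sites whose DB subinterval is overlapped by at
#' least one detected region.
#'
#' @param detected data.frame of detected regions (chrom, start, end;
#'   0-based half-open), e.g. a thresholded \code{"db_regions"} table.
#' @param truth Truth list from a simulator (\code{sites} and
#'   \code{db_subintervals}).
#'
#' @return List of class \code{"db_performance"}: \code{observed_fdr},
#'   \code{power}, \code{n_detected}, \code{n_true_db},
#'   \code{n_true_positive}.
#' @export
score_regions <- function(detected, truth) {
    sites <- truth$sites
    subs <- truth$db_subintervals
    # simulators guarantee site footprints are disjoint
    for (chr in unique(sites$chrom)) {
        s <- sites[sites$chrom == chr, ]
        s <- s[order(s$start), ]
        if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
            stop("overlapping truth site records")
    }
    db_sites <- unique(subs$site)
    n_true_db <- length(db_sites)
    n_det <- if (is.null(detected)) 0L else nrow(detected)
    if (n_det == 0L) {
        return(structure(list(observed_fdr = NA_real_, power = 0,
                              n_detected = 0L, n_true_db = n_true_db,
                              n_true_positive = 0L),
                         class = "db_performance"))
    }
    tp <- logical(n_det)
    hit_site <- logical(nrow(subs))
    for (chr in unique(detected$chrom)) {
        didx <- which(detected$chrom == chr)
        sidx <- which(subs$chrom == chr)
        if (!length(sidx)) next
        dr <- IRanges::IRanges(start = detected$start[didx] + 1L,
                               end = detected$end[didx])
        sr <- IRanges::IRanges(start = subs$start[sidx] + 1L,
                               end = subs$end[sidx])
        ov <- IRanges::findOverlaps(dr, sr)
        tp[didx[unique(S4Vectors::queryHits(ov))]] <- TRUE
        hit_site[sidx[unique(S4Vectors::subjectHits(ov))]] <- TRUE
    }
    detected_sites <- unique(subs$site[hit_site])
    structure(list(observed_fdr = 1 - sum(tp) / n_det,
                   power = length(detected_sites) / n_true_db,
                   n_detected = n_det, n_true_db = n_true_db,
                   n_true_positive = sum(tp)),
              class = "db_performance")
}

#' @export
print.db_performance <- function(x, ...) {
    cat("detected regions:", x$n_detected,
        " true positives:", x$n_true_positive, "\n")
    cat("observed FDR:", format(x$observed_fdr),
        " power:", format(x$power),
        "(", x$n_true_db, "true DB sites )\n")
    invisible(x)
}

#' Replicated simulation study of FDR and power
#'
#' Runs simulate -> count -> filter -> test -> cluster -> score for several
#' seeds and aggregates observed FDR and power (mean and standard error
#' over replicates) at one or more nominal FDR thresholds. Replicates with
#' zero detections contribute power 0 and are excluded from the FDR mean;
#' the count of exclusions is reported.
#'
#' @param mode Simulation mode ("complex", "sharp", "sharp_fixed").
#' @param n_replicates Number of simulated datasets (>= 1).
#' @param seeds Integer seeds, one per replicate (default 1:n_replicates).
#' @param scale Site-count scale factor passed to the simulator.
#' @param config Pipeline configuration (see \code{\link{default_config}}).
#' @param thresholds Nominal FDR thresholds at which regions are called
#'   (default: the config's nominal_fdr).
#'
#' @return List of class \code{"replicate_study"} with \code{per_replicate}
#'   (long data.frame) and \code{summary} (per threshold: mean/SE of FDR
#'   and power, number of excluded replicates).
#' @export
replicate_study <- function(mode, n_replicates = 3, seeds = NULL, scale = 1,
                            config = default_config(), thresholds = NULL) {
    stopifnot(n_replicates >= 1)
    if (is.null(seeds)) seeds <- seq_len(n_replicates)
    stopifnot(length(seeds) == n_replicates)
    if (is.null(thresholds)) thresholds <- config$nominal_fdr
    rows <- list()
    for (r in seq_len(n_replicates)) {
        sim <- simulate_dataset(mode, scale = scale, seed = seeds[r])
        res <- tryCatch(run_pipeline_sim(sim, config),
                        error = function(e)
                            stop("replicate with seed ", seeds[r],
                                 " failed: ", conditionMessage(e)))
        for (t in thresholds) {
            det <- res$regions[res$regions$fdr <= t, , drop = FALSE]
            sc <- score_regions(det, sim$truth)
            rows[[length(rows) + 1L]] <-
                data.frame(seed = seeds[r], threshold = t,
                           observed_fdr = sc$observed_fdr,
                           power = sc$power, n_detected = sc$n_detected)
        }
    }
    per <- do.call(rbind, rows)
    se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    summ <- do.call(rbind, lapply(thresholds, function(t) {
        d <- per[per$threshold == t, ]
        fdrs <- d$observed_fdr[!is.na(d$observed_fdr)]
        data.frame(threshold = t,
                   mean_fdr = if (length(fdrs)) mean(fdrs) else NA_real_,
                   se_fdr = se(fdrs),
                   mean_power = mean(d$power), se_power = se(d$power),
                   n_excluded = sum(is.na(d$observed_fdr)))
    }))
    structure(list(per_replicate = per, summary = summ, mode = mode,
                   scale = scale), class = "replicate_study")
}

#' @export
print.replicate_study <- function(x, ...) {
    cat("replicate study:", x$mode, "simulation, scale", x$scale, "\n")
    print(x$summary, row.names = FALSE)
    invisible(x)
}
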