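#' Default pipeline configuration
#'
#' All defaults follow the published analysis settings: 150 bp windows at
#' 50 bp spacing, 100 bp read extension, background filtering against 2 kbp
#' bins at a two-fold threshold, composition normalization (when requested)
#' on 10 kbp bins, 100 bp merge tolerance, 5 kbp maximum region width and a
#' nominal FDR of 0.05. Normalization defaults to "none" (library sizes
#' only), appropriate when no composition bias is expected.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
    list(width = 150, spacing = 50, frag_len = 100,
         paired = FALSE, max_span = 600,
         filter_bin_width = 2000, norm_bin_width = 10000,
         filter_fold = 2, normalization = "none",
         merge_tolerance = 100, max_region_width = 5000,
         nominal_fdr = 0.05, prior_count = 2,
         min_mapq = 0, dedup = FALSE)
}

.validate_config <- function(config) {
    defs <- default_config()
    unknown <- setdiff(names(config), names(defs))
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    out <- utils::modifyList(defs, config)
    pos_keys <- c("width", "spacing", "frag_len", "max_span",
                  "filter_bin_width", "norm_bin_width", "filter_fold",
                  "max_region_width", "prior_count")
    for (k in pos_keys) {
        v <- out[[k]]
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
            stop("configuration key '", k, "' must be a positive number")
    }
    for (k in c("merge_tolerance", "min_mapq")) {
        v <- out[[k]]
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
            stop("configuration key '", k, "' must be a non-negative number")
    }
    if (!is.numeric(out$nominal_fdr) || out$nominal_fdr <= 0 ||
        out$nominal_fdr > 1)
        stop("configuration key 'nominal_fdr' must be in (0, 1]")
    if (!out$normalization %in% c("none", "tmm", "loess"))
        stop("configuration key 'normalization' must be none, tmm or loess")
    if (!is.logical(out$paired) || !is.logical(out$dedup))
        stop("configuration keys 'paired' and 'dedup' must be logical")
    out
}

#' Load a pipeline configuration from a YAML file
#'
#' Absent keys take the defaults of \code{\link{default_config}}; unknown
#' keys are rejected; invalid values raise errors naming the key. An empty
#' file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    if (!is.list(cfg)) stop("configuration file must contain a key-value map")
    .validate_config(cfg)
}

#' Write a configuration to a YAML file
#'
#' @param config Configuration list.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
    yaml::write_yaml(.validate_config(config), path)
    invisible(path)
}

#' Run the full differential binding pipeline
#'
#' Composes the per-stage functions: fragment inference, window and bin
#' counting, background filtering, optional normalization, window-level QL
#' F-tests and region-level aggregation with Simes + BH. The run is
#' deterministic given inputs and configuration.
#'
#' @param reads Read table (chrom, pos, strand, library) for single-end
#'   data, or NULL when \code{fragments} or \code{bam_files} are given.
#' @param fragments Pre-computed fragment table (chrom, start, end,
#'   library), e.g. from paired-end inference; overrides \code{reads}.
#' @param bam_files BAM paths (one per library) read with
#'   \code{\link{read_bam_reads}}.
#' @param chrom_lengths Named chromosome lengths; taken from the BAM header
#'   when BAMs are supplied.
#' @param design Design matrix (libraries x coefficients).
#' @param coef,contrast Null hypothesis specification passed to
#'   \code{\link{window_test}}.
#' @param config Configuration list (see \code{\link{default_config}}).
#'
#' @return Object of class \code{"windowdb_result"}: \code{windows} (tested
#'   windows), \code{regions} (clustered results with FDR), \code{config},
#'   \code{log} (per-stage counts) and the \code{"window_test"} fit.
#' @export
run_pipeline <- function(reads = NULL, fragments = NULL, bam_files = NULL,
                         chrom_lengths = NULL, design, coef = ncol(design),
                         contrast = NULL, config = default_config()) {
    config <- .validate_config(config)
    if (!is.null(bam_files)) {
        chrom_lengths <- bam_chrom_lengths(bam_files[1])
        reads <- read_bam_reads(bam_files, min_mapq = config$min_mapq,
                                dedup = config$dedup)
    }
    if (is.null(chrom_lengths))
        stop("'chrom_lengths' is required when no BAM files are given")
    if (is.null(fragments)) {
        if (is.null(reads) || nrow(reads) == 0L)
            stop("counting stage: no reads supplied")
        fragments <- reads_to_fragments(reads, config$frag_len,
                                        chrom_lengths)
    }
    if (nrow(fragments) == 0L) stop("counting stage: no fragments supplied")
    n_lib <- nrow(design)

    grid <- window_grid(chrom_lengths, config$width, config$spacing)
    wc <- count_windows(fragments, grid, n_libraries = n_lib)
    if (any(wc$lib.sizes == 0))
        stop("counting stage: library with no fragments")
    bins <- count_bins(fragments, config$filter_bin_width, chrom_lengths,
                       n_libraries = n_lib)

    abund <- average_abundance(wc, config$prior_count)
    bg <- scaled_background(bins, config$width, config$frag_len,
                            config$prior_count)
    keep <- filter_windows(abund, bg, log2(config$filter_fold))
    if (!any(keep)) stop("filtering stage: no windows retained")
    kept <- subset_counts(wc, keep)
    kept_abund <- abund[keep]

    if (config$normalization == "tmm") {
        nbins <- count_bins(fragments, config$norm_bin_width, chrom_lengths,
                            n_libraries = n_lib)
        kept <- apply_normalization(kept, tmm_factors(nbins))
        kept_abund <- average_abundance(kept, config$prior_count)
    } else if (config$normalization == "loess") {
        kept <- apply_normalization(kept, loess_offsets(kept))
    }

    wt <- window_test(kept, design, coef = coef, contrast = contrast,
                      abundance = kept_abund,
                      prior_count = config$prior_count)
    reg <- region_results(wt, tolerance = config$merge_tolerance,
                          max_width = config$max_region_width)
    n_sig <- sum(reg$fdr <= config$nominal_fdr)

    structure(list(windows = wt$table, regions = reg, config = config,
                   fit = wt,
                   log = list(n_windows_total = nrow(wc$counts),
                              n_windows_kept = sum(keep),
                              background_abundance = bg,
                              n_regions = nrow(reg),
                              n_significant = n_sig)),
              class = "windowdb_result")
}

#' Run the pipeline on a simulated dataset
#'
#' Convenience wrapper: builds the two-group design from the simulator
#' output and tests the group contrast.
#'
#' @param sim Output of \code{\link{simulate_dataset}}.
#' @param config Pipeline configuration.
#' @return A \code{"windowdb_result"}.
#' @export
run_pipeline_sim <- function(sim, config = default_config()) {
    group <- factor(sim$group)
    design <- stats::model.matrix(~group)
    run_pipeline(reads = sim$reads, chrom_lengths = sim$chrom_lengths,
                 design = design, coef = 2L, config = config)
}

#' @export
print.windowdb_result <- function(x, ...) {
    cat("windowdb pipeline result\n")
    cat("  windows: ", x$log$n_windows_kept, " retained of ",
        x$log$n_windows_total, "\n", sep = "")
    cat("  regions: ", x$log$n_regions, " (", x$log$n_significant,
        " at FDR <= ", x$config$nominal_fdr, ")\n", sep = "")
    invisible(x)
}

#' @export
summary.windowdb_result <- function(object, ...) {
    cat("windowdb pipeline result\n")
    cat("config: width", object$config$width, "spacing",
        object$config$spacing, "frag_len", object$config$frag_len,
        "normalization", object$config$normalization, "\n")
    print(object$log[c("n_windows_total", "n_windows_kept", "n_regions",
                       "n_significant")])
    top <- object$regions[order(object$regions$combined_p), ]
    cat("top regions:\n")
    print(utils::head(top[, c("chrom", "start", "end", "n_windows",
                              "combined_p", "fdr", "direction")], 5),
          row.names = FALSE)
    invisible(object)
}

#' @export
plot.windowdb_result <- function(x, ...) {
    plot(x$fit, p_cutoff = x$config$nominal_fdr, ...)
}
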