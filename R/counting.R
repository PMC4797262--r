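#' Construct a sliding-window grid
#'
#' Defines a regular tiling of the genome with fixed-width windows whose start
#' positions are separated by a fixed spacing. All coordinates are 0-based
#' half-open; the last window on each chromosome is clipped at the chromosome
#' end. When \code{spacing <= width} every base is covered by at least one
#' window.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param width Window width in bp (>= 1).
#' @param spacing Distance between adjacent window starts in bp (>= 1).
#'   Defaults to \code{width}, which gives a non-overlapping tiling (bins).
#'
#' @return An object of class \code{"window_grid"}.
#' @export
window_grid <- function(chrom_lengths, width, spacing = width) {
    if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
        stop("'chrom_lengths' must be a named vector")
    if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
    width <- as.integer(width); spacing <- as.integer(spacing)
    if (is.na(width) || width < 1L) stop("'width' must be >= 1")
    if (is.na(spacing) || spacing < 1L) stop("'spacing' must be >= 1")
    structure(list(chrom_lengths = chrom_lengths, width = width,
                   spacing = spacing), class = "window_grid")
}

#' Enumerate the windows of a grid
#'
#' @param grid A \code{"window_grid"}.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), ordered by chromosome then start.
#' @export
grid_windows <- function(grid) {
    stopifnot(inherits(grid, "window_grid"))
    out <- lapply(names(grid$chrom_lengths), function(chr) {
        len <- grid$chrom_lengths[[chr]]
        starts <- seq.int(0L, len - 1L, by = grid$spacing)
        data.frame(chrom = chr, start = starts,
                   end = pmin(starts + grid$width, len))
    })
    do.call(rbind, out)
}

#' Impute a fragment by directional read extension
#'
#' Single-end reads are extended to the average fragment length in the
#' direction of the alignment: a forward read with 5' position p becomes
#' [p, p + frag_len) and a reverse read whose 5' end (rightmost aligned base)
#' is at p becomes [p - frag_len + 1, p + 1). Fragments are clipped to the
#' chromosome. Vectorized over reads.
#'
#' @param pos Integer vector of 5' read positions (0-based).
#' @param strand Character vector, "+" or "-".
#' @param frag_len Average fragment length in bp (>= 1).
#' @param chrom_len Chromosome length in bp.
#'
#' @return A data.frame with columns \code{start}, \code{end} (0-based
#'   half-open).
#' @export
extend_read <- function(pos, strand, frag_len, chrom_len) {
    if (length(frag_len) != 1L || is.na(frag_len) || frag_len < 1)
        stop("'frag_len' must be a single value >= 1")
    if (any(pos < 0 | pos >= chrom_len))
        stop("read positions must lie within [0, chrom_len)")
    fwd <- strand == "+"
    start <- ifelse(fwd, pos, pos - frag_len + 1)
    end <- ifelse(fwd, pos + frag_len, pos + 1)
    data.frame(start = pmax(start, 0), end = pmin(end, chrom_len))
}

#' Form fragments from read pairs
#'
#' A pair yields a fragment when the two reads are on the same chromosome,
#' inward-facing (the forward read lies to the left of the reverse read) and
#' the spanned interval does not exceed \code{max_span}. Other pairs are
#' rejected with a categorized reason; rejections are data, not errors.
#'
#' @param read1,read2 data.frames with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{strand}, one row per mate.
#' @param max_span Maximum allowed fragment span in bp (e.g. 600).
#'
#' @return A data.frame with columns \code{status} ("ok",
#'   "inter_chromosomal", "outward_facing", "over_span"), \code{chrom},
#'   \code{start}, \code{end} (NA where rejected).
#' @export
pair_to_fragment <- function(read1, read2, max_span) {
    n <- nrow(read1)
    stopifnot(nrow(read2) == n)
    status <- rep("ok", n)
    s1f <- read1$strand == "+"
    # orient so 'fwd' is the forward mate, 'rev' the reverse mate
    fwd_start <- ifelse(s1f, read1$start, read2$start)
    rev_end <- ifelse(s1f, read2$end, read1$end)
    status[read1$strand == read2$strand] <- "outward_facing"
    status[status == "ok" & fwd_start > ifelse(s1f, read2$start, read1$start)] <-
        "outward_facing"
    status[read1$chrom != read2$chrom] <- "inter_chromosomal"
    span <- rev_end - fwd_start
    status[status == "ok" & span > max_span] <- "over_span"
    ok <- status == "ok"
    data.frame(status = status,
               chrom = ifelse(ok, read1$chrom, NA_character_),
               start = ifelse(ok, fwd_start, NA_real_),
               end = ifelse(ok, rev_end, NA_real_))
}

#' Extend a table of reads into fragments
#'
#' @param reads data.frame with columns \code{chrom}, \code{pos} (0-based 5'
#'   position), \code{strand}, \code{library}.
#' @param frag_len Average fragment length in bp.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{library}.
#' @export
reads_to_fragments <- function(reads, frag_len, chrom_lengths) {
    bad <- setdiff(unique(reads$chrom), names(chrom_lengths))
    if (length(bad))
        stop("reads on unknown chromosome(s): ", paste(bad, collapse = ", "))
    len <- unname(chrom_lengths[reads$chrom])
    ivl <- extend_read(reads$pos, reads$strand, frag_len, Inf)
    data.frame(chrom = reads$chrom,
               start = pmax(ivl$start, 0),
               end = pmin(ivl$end, len),
               library = reads$library)
}

.new_count_matrix <- function(regions, counts, lib_sizes, width = NA_integer_,
                              spacing = NA_integer_) {
    structure(list(regions = regions, counts = counts,
                   lib.sizes = as.numeric(lib_sizes),
                   norm.factors = rep(1, length(lib_sizes)),
                   offsets = NULL, width = width, spacing = spacing),
              class = "window_counts")
}

#' Construct a count matrix object
#'
#' Container for region-level fragment counts: an ordered set of genomic
#' intervals, a non-negative integer matrix (regions x libraries),
#' per-library totals and normalization state (factors with geometric mean
#' 1, or per-entry loess offsets).
#'
#' @param regions data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param counts Non-negative matrix, rows matching \code{regions}.
#' @param lib_sizes Per-library totals; defaults to the column sums.
#' @param width,spacing Optional grid metadata in bp.
#' @return A \code{"window_counts"} object.
#' @export
window_counts <- function(regions, counts, lib_sizes = colSums(counts),
                          width = NA_integer_, spacing = NA_integer_) {
    counts <- as.matrix(counts)
    stopifnot(nrow(regions) == nrow(counts),
              length(lib_sizes) == ncol(counts))
    if (any(counts < 0)) stop("counts must be non-negative")
    .new_count_matrix(regions, counts, lib_sizes, width = width,
                      spacing = spacing)
}

#' Count fragments overlapping each window
#'
#' Every fragment with at least 1 bp overlap contributes to a window's count.
#' Library sizes are the per-library totals over all fragments supplied,
#' regardless of whether they overlap any window.
#'
#' @param fragments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{library} (positive integer index).
#' @param grid A \code{"window_grid"}.
#' @param n_libraries Number of libraries (columns); defaults to the largest
#'   library index present.
#'
#' @return A \code{"window_counts"} object: window coordinates, an integer
#'   counts matrix (windows x libraries), per-library totals and unit
#'   normalization factors.
#' @export
count_windows <- function(fragments, grid, n_libraries = NULL) {
    stopifnot(inherits(grid, "window_grid"))
    bad <- setdiff(unique(fragments$chrom), names(grid$chrom_lengths))
    if (length(bad))
        stop("fragment(s) on chromosome(s) absent from grid: ",
             paste(bad, collapse = ", "))
    if (is.null(n_libraries))
        n_libraries <- if (nrow(fragments)) max(fragments$library) else 1L
    regions <- grid_windows(grid)
    counts <- matrix(0L, nrow(regions), n_libraries)
    lib_sizes <- numeric(n_libraries)
    if (nrow(fragments)) {
        tab <- tabulate(fragments$library, nbins = n_libraries)
        lib_sizes <- as.numeric(tab)
        for (chr in unique(regions$chrom)) {
            widx <- which(regions$chrom == chr)
            win <- IRanges::IRanges(start = regions$start[widx] + 1L,
                                    end = regions$end[widx])
            fr <- fragments[fragments$chrom == chr, , drop = FALSE]
            if (!nrow(fr)) next
            for (l in seq_len(n_libraries)) {
                fl <- fr[fr$library == l, , drop = FALSE]
                if (!nrow(fl)) next
                q <- IRanges::IRanges(start = fl$start + 1L, end = fl$end)
                counts[widx, l] <- counts[widx, l] +
                    IRanges::countOverlaps(win, q)
            }
        }
    }
    .new_count_matrix(regions, counts, lib_sizes,
                      width = grid$width, spacing = grid$spacing)
}

#' Count fragments into non-overlapping genomic bins
#'
#' Equivalent to \code{count_windows} with \code{spacing = width}; used for
#' background estimation (2 kbp bins) and composition normalization (10 kbp
#' bins).
#'
#' @inheritParams count_windows
#' @param bin_width Bin width in bp.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A \code{"window_counts"} object.
#' @export
count_bins <- function(fragments, bin_width, chrom_lengths,
                       n_libraries = NULL) {
    count_windows(fragments, window_grid(chrom_lengths, bin_width, bin_width),
                  n_libraries = n_libraries)
}

#' @export
print.window_counts <- function(x, ...) {
    cat("window_counts:", nrow(x$counts), "regions x", ncol(x$counts),
        "libraries\n")
    if (!is.na(x$width))
        cat("  width:", x$width, "bp, spacing:", x$spacing, "bp\n")
    cat("  library sizes:", paste(format(x$lib.sizes), collapse = ", "), "\n")
    cat("  norm factors: ",
        paste(format(round(x$norm.factors, 4)), collapse = ", "),
        if (!is.null(x$offsets)) " (+ loess offsets)" else "", "\n", sep = "")
    invisible(x)
}

#' Subset a count matrix by region
#'
#' @param x A \code{"window_counts"} object.
#' @param keep Logical or integer index over regions.
#' @return The subsetted \code{"window_counts"}.
#' @export
subset_counts <- function(x, keep) {
    stopifnot(inherits(x, "window_counts"))
    x$regions <- x$regions[keep, , drop = FALSE]
    rownames(x$regions) <- NULL
    x$counts <- x$counts[keep, , drop = FALSE]
    if (!is.null(x$offsets)) x$offsets <- x$offsets[keep, , drop = FALSE]
    x
}

#' Write a count matrix as TSV
#'
#' @param x A \code{"window_counts"} object.
#' @param path Output file path.
#' @export
write_counts <- function(x, path) {
    stopifnot(inherits(x, "window_counts"))
    df <- cbind(x$regions, as.data.frame(x$counts))
    names(df)[-(1:3)] <- paste0("lib", seq_len(ncol(x$counts)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
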