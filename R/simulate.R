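#' Simulate non-specific background coverage
#'
#' The genome is partitioned into bins; each bin k receives an NB count per
#' library with mean mu_k ~ Uniform(mu_range) and dispersion phi_k drawn
#' from an inverse chi-squared distribution (1/chisq(df)), the same (mu_k,
#' phi_k) being reused in every library so the background carries no
#' differential signal. Read 5' positions are uniform within the bin and
#' strands are assigned 50/50.
#'
#' @param chrom_len Chromosome length in bp (last partial bin allowed).
#' @param n_libraries Number of libraries.
#' @param bin_width Bin width in bp (default 2000).
#' @param mu_range Range of the uniform bin means (default c(10, 50)).
#' @param disp_df Degrees of freedom of the inverse chi-squared dispersion
#'   distribution (default 20).
#' @param fixed_dispersion If non-NULL, use this constant dispersion for
#'   every bin instead of sampling.
#' @param seed Optional RNG seed.
#'
#' @return data.frame of reads: chrom, pos (0-based 5' position), strand,
#'   library.
#' @export
simulate_background <- function(chrom_len, n_libraries, bin_width = 2000,
                                mu_range = c(10, 50), disp_df = 20,
                                fixed_dispersion = NULL, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n_bins <- ceiling(chrom_len / bin_width)
    bin_start <- (seq_len(n_bins) - 1) * bin_width
    bin_w <- pmin(bin_start + bin_width, chrom_len) - bin_start
    mu_k <- stats::runif(n_bins, mu_range[1], mu_range[2])
    phi_k <- if (is.null(fixed_dispersion))
        1 / stats::rchisq(n_bins, disp_df) else rep(fixed_dispersion, n_bins)
    out <- vector("list", n_libraries)
    for (l in seq_len(n_libraries)) {
        cnt <- stats::rnbinom(n_bins, mu = mu_k, size = 1 / phi_k)
        tot <- sum(cnt)
        pos <- rep(bin_start, cnt) +
            floor(stats::runif(tot) * rep(bin_w, cnt))
        strand <- ifelse(stats::runif(tot) < 0.5, "+", "-")
        out[[l]] <- data.frame(chrom = "chr1", pos = pos, strand = strand,
                               library = l)
    }
    do.call(rbind, out)
}

#' Simulate complex (histone-mark-like) differential binding
#'
#' Binding sites spaced uniformly 10-20 kbp apart are each composed of
#' three overlapping subintervals of width w offset by w/2 (site footprint
#' 2w). Per subinterval and library, an NB(mean, phi_i) read count is drawn,
#' with the site dispersion phi_i ~ 1/chisq(disp_df); read 5' positions are
#' w*X + s_j with X ~ Beta(2, 2) and s_j the subinterval start, and strands
#' are random. Differential binding is introduced by removing all reads of
#' one or two randomly chosen subintervals from both libraries of one group,
#' for \code{n_db_per_group} disjoint sites per group; the balanced removal
#' introduces no composition bias. Ground truth records the removed
#' subintervals.
#'
#' @param n_sites Number of binding sites (default 20000).
#' @param spacing Range of inter-site spacings in bp (default 10-20 kbp).
#' @param subint_width Subinterval width w in bp (default 500).
#' @param mu Mean reads per subinterval per library (default 30).
#' @param disp_df Inverse chi-squared degrees of freedom (default 20).
#' @param n_db_per_group DB sites per group (default 500).
#' @param n_reps Replicates per group (default 2; two groups).
#' @param seed Optional RNG seed.
#'
#' @return List with \code{reads}, \code{truth} (list of \code{sites} and
#'   \code{db_subintervals}), \code{chrom_len}, \code{group} (per-library
#'   group labels) and \code{params}.
#' @export
simulate_complex <- function(n_sites = 20000, spacing = c(10000, 20000),
                             subint_width = 500, mu = 30, disp_df = 20,
                             n_db_per_group = 500, n_reps = 2, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    w <- subint_width
    stopifnot(spacing[1] > 2 * w, 2 * n_db_per_group <= n_sites)
    gaps <- stats::runif(n_sites, spacing[1], spacing[2])
    site_start <- round(cumsum(gaps))
    chrom_len <- site_start[n_sites] + 2 * w + spacing[2]
    phi <- 1 / stats::rchisq(n_sites, disp_df)
    group <- rep(1:2, each = n_reps)
    n_lib <- length(group)

    db_idx <- sample.int(n_sites, 2 * n_db_per_group)
    removal_group <- rep(1:2, each = n_db_per_group) # group losing the reads
    n_removed <- sample(1:2, 2 * n_db_per_group, replace = TRUE)
    removed_sub <- lapply(n_removed, function(k) sample.int(3, k))

    # per-(site, subinterval) removal masks, one per group
    sub_site <- rep(seq_len(n_sites), each = 3)
    sub_start <- rep(site_start, each = 3) + rep(c(0, w / 2, w), n_sites)
    mask <- list(logical(n_sites * 3), logical(n_sites * 3))
    for (i in seq_along(db_idx)) {
        g <- removal_group[i]
        at <- (db_idx[i] - 1) * 3 + removed_sub[[i]]
        mask[[g]][at] <- TRUE
    }

    reads <- vector("list", n_lib)
    for (l in seq_len(n_lib)) {
        cnt <- stats::rnbinom(n_sites * 3, mu = mu,
                              size = rep(1 / phi, each = 3))
        cnt[mask[[group[l]]]] <- 0L
        tot <- sum(cnt)
        pos <- rep(sub_start, cnt) +
            pmin(floor(w * stats::rbeta(tot, 2, 2)), w - 1)
        strand <- ifelse(stats::runif(tot) < 0.5, "+", "-")
        reads[[l]] <- data.frame(chrom = "chr1", pos = pos, strand = strand,
                                 library = l)
    }

    is_db <- logical(n_sites)
    direction <- rep(NA_integer_, n_sites)
    is_db[db_idx] <- TRUE
    direction[db_idx] <- removal_group
    sites <- data.frame(site = seq_len(n_sites), chrom = "chr1",
                        start = site_start, end = site_start + 2 * w,
                        db = is_db, direction = direction)
    db_sub <- do.call(rbind, lapply(seq_along(db_idx), function(i) {
        s <- db_idx[i]
        data.frame(site = s, chrom = "chr1",
                   start = site_start[s] + (removed_sub[[i]] - 1) * w / 2,
                   end = site_start[s] + (removed_sub[[i]] - 1) * w / 2 + w,
                   direction = removal_group[i])
    }))
    if (is.null(db_sub))
        db_sub <- data.frame(site = integer(0), chrom = character(0),
                             start = numeric(0), end = numeric(0),
                             direction = integer(0))
    list(reads = do.call(rbind, reads),
         truth = list(sites = sites, db_subintervals = db_sub),
         chrom_len = chrom_len, group = group,
         params = list(mode = "complex", n_sites = n_sites, mu = mu,
                       subint_width = w, disp_df = disp_df,
                       n_db_per_group = n_db_per_group))
}

#' Simulate sharp (transcription-factor-like) differential binding
#'
#' Each site is a point binding location c_i with strand-bimodal coverage:
#' forward-read 5' positions fall at c_i - f*X and reverse-read positions at
#' c_i + f*X with X ~ Beta(2, 2) and f the average fragment length, so the
#' reads face inward and their extensions pile up over the site. Counts per
#' site, group and library are NB(mu_ig, phi_i). Differential sites change
#' intensity only; equal numbers in each direction keep the composition
#' balanced. The truth subinterval of a DB site is its footprint
#' [c_i - f, c_i + f).
#'
#' @param n_sites Number of sites (default 20000).
#' @param spacing Range of inter-site spacings (default 10-20 kbp).
#' @param frag_len Average fragment length f in bp (default 100).
#' @param mu_nondb Mean for non-DB sites in every group (default 30).
#' @param mu_db Means (gaining group, losing group) for DB sites (default
#'   c(45, 15)).
#' @param n_db_per_group DB sites per direction (default 500).
#' @param disp_df Inverse chi-squared df for site dispersions (default 20).
#' @param fixed_dispersion If non-NULL, constant dispersion for all sites.
#' @param n_reps Replicates per group (default 2).
#' @param seed Optional RNG seed.
#'
#' @return As \code{\link{simulate_complex}}.
#' @export
simulate_sharp <- function(n_sites = 20000, spacing = c(10000, 20000),
                           frag_len = 100, mu_nondb = 30, mu_db = c(45, 15),
                           n_db_per_group = 500, disp_df = 20,
                           fixed_dispersion = NULL, n_reps = 2, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    f <- frag_len
    stopifnot(spacing[1] > 2 * f, 2 * n_db_per_group <= n_sites)
    gaps <- stats::runif(n_sites, spacing[1], spacing[2])
    centre <- round(cumsum(gaps))
    chrom_len <- centre[n_sites] + f + spacing[2]
    phi <- if (is.null(fixed_dispersion))
        1 / stats::rchisq(n_sites, disp_df) else rep(fixed_dispersion, n_sites)
    group <- rep(1:2, each = n_reps)
    n_lib <- length(group)

    db_idx <- sample.int(n_sites, 2 * n_db_per_group)
    up_group <- rep(1:2, each = n_db_per_group) # group with the higher mean
    mu_mat <- matrix(mu_nondb, n_sites, 2)
    mu_mat[cbind(db_idx, up_group)] <- mu_db[1]
    mu_mat[cbind(db_idx, 3 - up_group)] <- mu_db[2]

    reads <- vector("list", n_lib)
    for (l in seq_len(n_lib)) {
        cnt <- stats::rnbinom(n_sites, mu = mu_mat[, group[l]],
                              size = 1 / phi)
        tot <- sum(cnt)
        cc <- rep(centre, cnt)
        fwd <- stats::runif(tot) < 0.5
        d <- floor(f * stats::rbeta(tot, 2, 2))
        pos <- ifelse(fwd, cc - 1 - d, cc + 1 + d)
        reads[[l]] <- data.frame(chrom = "chr1", pos = pmax(pos, 0),
                                 strand = ifelse(fwd, "+", "-"), library = l)
    }

    is_db <- logical(n_sites)
    direction <- rep(NA_integer_, n_sites)
    is_db[db_idx] <- TRUE
    direction[db_idx] <- up_group
    sites <- data.frame(site = seq_len(n_sites), chrom = "chr1",
                        start = centre - f, end = centre + f,
                        db = is_db, direction = direction)
    db_sub <- if (length(db_idx)) {
        data.frame(site = db_idx, chrom = "chr1",
                   start = centre[db_idx] - f, end = centre[db_idx] + f,
                   direction = up_group)
    } else {
        data.frame(site = integer(0), chrom = character(0),
                   start = numeric(0), end = numeric(0),
                   direction = integer(0))
    }
    list(reads = do.call(rbind, reads),
         truth = list(sites = sites, db_subintervals = db_sub),
         chrom_len = chrom_len, group = group,
         params = list(mode = "sharp", n_sites = n_sites,
                       mu_nondb = mu_nondb, mu_db = mu_db,
                       frag_len = f, disp_df = disp_df,
                       fixed_dispersion = fixed_dispersion,
                       n_db_per_group = n_db_per_group))
}

#' Simulate a complete ChIP-seq dataset with background
#'
#' Composes one of the binding simulators with the genomic background and
#' pools the reads. \code{scale} multiplies the number of sites and DB
#' sites (and thereby the genome length) for desk-scale runs; all
#' distributional parameters stay at the published study conditions.
#'
#' @param mode "complex", "sharp" or "sharp_fixed" (the constant-dispersion
#'   TF variant: phi = 0.05 everywhere, non-DB mean 10, DB means 20 vs 0).
#' @param scale Multiplier on the number of sites (default 1).
#' @param seed RNG seed for the whole dataset.
#' @param n_reps Replicates per group.
#'
#' @return List with pooled \code{reads}, \code{truth}, \code{chrom_len},
#'   \code{chrom_lengths} (named, for counting), \code{group} and
#'   \code{params}.
#' @export
simulate_dataset <- function(mode = c("complex", "sharp", "sharp_fixed"),
                             scale = 1, seed = NULL, n_reps = 2) {
    mode <- match.arg(mode)
    if (!is.null(seed)) set.seed(seed)
    n_sites <- max(10L, round(20000 * scale))
    n_db <- max(1L, round(500 * scale))
    sim <- switch(mode,
        complex = simulate_complex(n_sites = n_sites,
                                   n_db_per_group = n_db, n_reps = n_reps),
        sharp = simulate_sharp(n_sites = n_sites, n_db_per_group = n_db,
                               n_reps = n_reps),
        sharp_fixed = simulate_sharp(n_sites = n_sites,
                                     n_db_per_group = n_db,
                                     mu_nondb = 10, mu_db = c(20, 0),
                                     fixed_dispersion = 0.05,
                                     n_reps = n_reps))
    bg <- simulate_background(sim$chrom_len, n_libraries = length(sim$group),
                              fixed_dispersion =
                                  if (mode == "sharp_fixed") 0.05 else NULL)
    sim$reads <- rbind(sim$reads, bg)
    sim$chrom_lengths <- c(chr1 = sim$chrom_len)
    sim$params$scale <- scale
    sim$params$seed <- seed
    sim
}

#' Write simulated reads to disk
#'
#' \code{format = "table"} writes one TSV with all libraries.
#' \code{format = "sam"} / \code{"bam"} writes one coordinate-sorted
#' alignment file per library (fixed read length, dummy base calls); BAM
#' output is converted and indexed with Rsamtools.
#'
#' @param reads Read table as produced by the simulators.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param prefix Output path prefix.
#' @param format "table", "sam" or "bam".
#' @param read_length Simulated read length in bp for SAM/BAM records
#'   (default 50; counting re-extends reads to the fragment length, so this
#'   only affects the alignment records).
#'
#' @return Character vector of the paths written.
#' @export
write_reads <- function(reads, chrom_lengths, prefix,
                        format = c("table", "sam", "bam"),
                        read_length = 50L) {
    format <- match.arg(format)
    if (format == "table") {
        path <- paste0(prefix, ".tsv")
        utils::write.table(reads, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(path))
    }
    libs <- sort(unique(reads$library))
    if (!length(libs)) libs <- 1L
    paths <- character(0)
    for (l in libs) {
        r <- reads[reads$library == l, , drop = FALSE]
        sam <- paste0(prefix, "_lib", l, ".sam")
        .write_sam(r, chrom_lengths, sam, read_length)
        if (format == "bam") {
            dest <- Rsamtools::asBam(sam, paste0(prefix, "_lib", l),
                                     overwrite = TRUE,
                                     indexDestination = TRUE)
            unlink(sam)
            paths <- c(paths, dest)
        } else paths <- c(paths, sam)
    }
    invisible(paths)
}

.write_sam <- function(r, chrom_lengths, path, read_length) {
    len <- unname(chrom_lengths[r$chrom])
    fwd <- r$strand == "+"
    left <- ifelse(fwd, r$pos, pmax(r$pos - read_length + 1, 0))
    right <- ifelse(fwd, pmin(r$pos + read_length, len), r$pos + 1)
    qlen <- pmax(right - left, 1)
    ord <- order(r$chrom, left)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 paste0("@SQ\tSN:", names(chrom_lengths), "\tLN:",
                        as.integer(chrom_lengths))), con)
    if (nrow(r)) {
        rec <- paste(paste0("r", seq_len(nrow(r))[ord]),
                     ifelse(fwd[ord], 0L, 16L), r$chrom[ord],
                     left[ord] + 1L, 50L, paste0(qlen[ord], "M"),
                     "*", 0L, 0L,
                     strrep("A", qlen[ord]), "*", sep = "\t")
        writeLines(rec, con)
    }
    invisible(path)
}

#' Chromosome lengths from a BAM header
#'
#' @param file BAM path.
#' @return Named numeric vector.
#' @export
bam_chrom_lengths <- function(file) {
    h <- Rsamtools::scanBamHeader(file)[[1]]$targets
    out <- as.numeric(h)
    names(out) <- names(h)
    out
}

#' Read single-end alignments from BAM files
#'
#' Extracts mapped primary alignments as 0-based 5' read positions, one
#' library per file. Secondary and supplementary alignments are skipped;
#' reads below the mapping-quality threshold, and (optionally) marked
#' duplicates, are dropped.
#'
#' @param files BAM paths, one per library.
#' @param min_mapq Minimum mapping quality (default 0 = keep all).
#' @param dedup Drop alignments flagged as duplicates (default FALSE:
#'   duplicates are kept).
#'
#' @return Read table (chrom, pos, strand, library).
#' @export
read_bam_reads <- function(files, min_mapq = 0, dedup = FALSE) {
    out <- vector("list", length(files))
    for (i in seq_along(files)) {
        flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                       isSecondaryAlignment = FALSE,
                                       isSupplementaryAlignment = FALSE,
                                       isDuplicate = if (dedup) FALSE else NA)
        param <- Rsamtools::ScanBamParam(flag = flag,
                                         what = c("rname", "strand", "pos",
                                                  "qwidth"),
                                         mapqFilter = min_mapq)
        b <- Rsamtools::scanBam(files[i], param = param)[[1]]
        if (!length(b$pos)) {
            out[[i]] <- data.frame(chrom = character(0), pos = numeric(0),
                                   strand = character(0),
                                   library = integer(0))
            next
        }
        fwd <- as.character(b$strand) == "+"
        pos0 <- ifelse(fwd, b$pos - 1L, b$pos - 1L + b$qwidth - 1L)
        out[[i]] <- data.frame(chrom = as.character(b$rname), pos = pos0,
                               strand = ifelse(fwd, "+", "-"), library = i)
    }
    do.call(rbind, out)
}
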