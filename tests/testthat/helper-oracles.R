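# Independent literal oracles, deliberately written as plain loops so they
# share no code path with the package implementations.

# brute-force any-overlap counting: double loop over windows and fragments
brute_count <- function(fragments, windows, n_libraries) {
    out <- matrix(0L, nrow(windows), n_libraries)
    for (w in seq_len(nrow(windows))) {
        for (f in seq_len(nrow(fragments))) {
            if (fragments$chrom[f] == windows$chrom[w] &&
                fragments$start[f] < windows$end[w] &&
                fragments$end[f] > windows$start[w]) {
                l <- fragments$library[f]
                out[w, l] <- out[w, l] + 1L
            }
        }
    }
    out
}

# literal Simes formula
oracle_simes <- function(p) {
    ps <- sort(p)
    n <- length(ps)
    best <- Inf
    for (j in seq_len(n)) best <- min(best, n * ps[j] / j)
    min(1, best)
}

# literal BH step-up with running minimum
oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- 1
    for (i in rev(seq_len(m))) {
        running <- min(running, m * p[o[i]] / i)
        adj[o[i]] <- running
    }
    adj
}

# literal unweighted doubly-trimmed mean of M-values for two libraries
oracle_tmm_pair <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, abs_trim = 0.05) {
    keep <- obs > 0 & ref > 0
    M <- log2((obs[keep] / n_obs) / (ref[keep] / n_ref))
    A <- 0.5 * log2((obs[keep] / n_obs) * (ref[keep] / n_ref))
    ok <- is.finite(M) & is.finite(A)
    M <- M[ok]; A <- A[ok]
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    2^mean(M[sel])
}

# literal greedy clustering: scalar walk re-implementing the merge rule
oracle_merge <- function(windows, tolerance, max_width) {
    n <- nrow(windows)
    cl <- integer(n)
    id <- 0L
    cstart <- cend <- NA_real_
    cchrom <- ""
    for (i in seq_len(n)) {
        newc <- i == 1L || windows$chrom[i] != cchrom ||
            windows$start[i] - cend > tolerance ||
            max(cend, windows$end[i]) - cstart > max_width
        if (newc) {
            id <- id + 1L
            cstart <- windows$start[i]
            cend <- windows$end[i]
            cchrom <- windows$chrom[i]
        } else {
            cend <- max(cend, windows$end[i])
        }
        cl[i] <- id
    }
    cl
}

# small random fragment sets on a toy genome
random_fragments <- function(n, chrom_lengths, n_libraries, max_len = 300) {
    chrom <- sample(names(chrom_lengths), n, replace = TRUE)
    len <- pmin(unname(chrom_lengths[chrom]), sample(max_len, n, replace = TRUE))
    start <- floor(runif(n) * (unname(chrom_lengths[chrom]) - len))
    data.frame(chrom = chrom, start = start, end = start + len,
               library = sample(n_libraries, n, replace = TRUE))
}

make_cm <- function(counts, lib_sizes = colSums(counts)) {
    counts <- as.matrix(counts)
    window_counts(data.frame(chrom = "chr1",
                             start = seq_len(nrow(counts)) * 1000,
                             end = seq_len(nrow(counts)) * 1000 + 150),
                  counts, lib_sizes)
}
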