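test_that("simulators are byte-deterministic under a fixed seed", {
    a <- simulate_complex(n_sites = 100, n_db_per_group = 5, seed = 42)
    b <- simulate_complex(n_sites = 100, n_db_per_group = 5, seed = 42)
    expect_identical(a, b)
    c1 <- simulate_sharp(n_sites = 100, n_db_per_group = 5, seed = 42)
    c2 <- simulate_sharp(n_sites = 100, n_db_per_group = 5, seed = 42)
    expect_identical(c1, c2)
    d1 <- simulate_dataset("sharp_fixed", scale = 0.005, seed = 9)
    d2 <- simulate_dataset("sharp_fixed", scale = 0.005, seed = 9)
    expect_identical(d1, d2)
})

test_that("complex simulator recovers its NB and dispersion parameters", {
    sim <- simulate_complex(n_sites = 1000, n_db_per_group = 0, seed = 43)
    # mean reads per subinterval per library among non-DB sites
    per_lib <- nrow(sim$reads) / 4
    expect_gt(per_lib / 3000, 29)
    expect_lt(per_lib / 3000, 31)
    # dispersion draws: mean of 1/chisq_20 is 1/18
    set.seed(44)
    phi <- 1 / rchisq(10000, 20)
    expect_equal(mean(phi), 1 / 18, tolerance = 0.002 * 18)
    # reads stay within the site footprints
    truth <- sim$truth$sites
    idx <- findInterval(sim$reads$pos, truth$start)
    expect_true(all(sim$reads$pos >= truth$start[idx] &
                    sim$reads$pos < truth$end[idx]))
})

test_that("complex DB removal is balanced and truth is disjoint", {
    sim <- simulate_complex(n_sites = 2000, n_db_per_group = 100, seed = 45)
    tot <- tapply(rep(1, nrow(sim$reads)), sim$reads$library, sum)
    g1 <- tot[1] + tot[2]; g2 <- tot[3] + tot[4]
    expect_lt(abs(g1 - g2) / (g1 + g2), 0.02)
    # no site is DB in both groups; every DB site has >= 1 truth subinterval
    tr <- sim$truth
    expect_equal(anyDuplicated(tr$db_subintervals$site[
        !duplicated(paste(tr$db_subintervals$site,
                          tr$db_subintervals$direction))]), 0)
    expect_true(all(tr$sites$site[tr$sites$db] %in% tr$db_subintervals$site))
    # site footprints disjoint
    s <- tr$sites[order(tr$sites$start), ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
})

test_that("sharp reads face inward around their binding site", {
    sim <- simulate_sharp(n_sites = 500, n_db_per_group = 25, seed = 46)
    centre <- cumsum(numeric(0)) # centres recoverable from truth footprints
    mid <- (sim$truth$sites$start + sim$truth$sites$end) / 2
    idx <- findInterval(sim$reads$pos, sim$truth$sites$start)
    cc <- mid[idx]
    fwd <- sim$reads$strand == "+"
    expect_true(all(sim$reads$pos[fwd] < cc[fwd]))
    expect_true(all(sim$reads$pos[!fwd] > cc[!fwd]))
})

test_that("sharp DB sites show the configured intensity ratio", {
    sim <- simulate_sharp(n_sites = 4000, n_db_per_group = 500, seed = 47)
    tr <- sim$truth$sites
    # count reads per site per group
    idx <- findInterval(sim$reads$pos, tr$start)
    g <- ifelse(sim$reads$library <= 2, 1, 2)
    up1 <- which(tr$db & tr$direction == 1)
    n1 <- sum(idx %in% up1 & g == 1) / (2 * length(up1))
    n2 <- sum(idx %in% up1 & g == 2) / (2 * length(up1))
    expect_equal(n1 / n2, 3, tolerance = 0.15)
})

test_that("fixed-dispersion variant matches the NB variance identity", {
    sim <- simulate_sharp(n_sites = 4000, n_db_per_group = 0, mu_nondb = 10,
                          mu_db = c(20, 0), fixed_dispersion = 0.05,
                          seed = 48)
    tr <- sim$truth$sites
    idx <- findInterval(sim$reads$pos, tr$start)
    cnt <- tabulate(idx + (sim$reads$library - 1) * nrow(tr),
                    nbins = 4 * nrow(tr))
    expect_gt(mean(cnt), 9.7); expect_lt(mean(cnt), 10.3)
    expect_gt(var(cnt), 13.5); expect_lt(var(cnt), 16.5)
})

test_that("background is shared between groups with the configured mean", {
    reads <- simulate_background(6e6, n_libraries = 4, seed = 49)
    n_bins <- 3000
    bin <- floor(reads$pos / 2000) + 1
    cnt <- matrix(0, n_bins, 4)
    for (l in 1:4)
        cnt[, l] <- tabulate(bin[reads$library == l], nbins = n_bins)
    expect_gt(mean(cnt), 29); expect_lt(mean(cnt), 31)
    lr <- log2(rowMeans(cnt[, 1:2]) / rowMeans(cnt[, 3:4]))
    expect_lt(abs(mean(lr[is.finite(lr)])), 0.02)
    # shared (mu, phi): between-library correlation positive in aggregate
    expect_gt(cor(cnt[, 1], cnt[, 3]), 0.3)
})

test_that("alignment output round-trips through BAM and counting", {
    sim <- simulate_complex(n_sites = 40, n_db_per_group = 2, seed = 50)
    cl <- c(chr1 = sim$chrom_len)
    pre <- file.path(tempdir(), "rt")
    paths <- write_reads(sim$reads, cl, pre, format = "bam")
    expect_length(paths, 4)
    back <- read_bam_reads(paths)
    g <- window_grid(cl, 150, 50)
    direct <- count_windows(reads_to_fragments(sim$reads, 100, cl), g, 4)
    via_bam <- count_windows(reads_to_fragments(back, 100, cl), g, 4)
    expect_identical(direct$counts, via_bam$counts)
    expect_equal(direct$lib.sizes, via_bam$lib.sizes)
})

test_that("edge reads and empty libraries survive alignment writing", {
    reads <- data.frame(chrom = "chr1", pos = c(0, 999),
                        strand = c("+", "-"), library = c(1L, 1L))
    pre <- file.path(tempdir(), "edge")
    paths <- write_reads(reads, c(chr1 = 1000), pre, format = "bam")
    back <- read_bam_reads(paths)
    expect_equal(sort(back$pos), c(0, 999))
    # a library with no reads still yields a valid, readable file
    empty <- reads[integer(0), ]
    p2 <- write_reads(empty, c(chr1 = 1000), file.path(tempdir(), "mt"),
                      format = "bam")
    expect_equal(nrow(read_bam_reads(p2)), 0)
})
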