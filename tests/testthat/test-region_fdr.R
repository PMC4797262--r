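test_that("gap-based merging follows the documented arithmetic", {
    w <- data.frame(chrom = "chr1", start = c(0, 200, 500),
                    end = c(150, 350, 650))
    expect_equal(merge_windows(w, tolerance = 100, max_width = 5000),
                 c(1L, 1L, 2L))
    # tolerance 0: non-abutting windows stay separate, abutting merge
    w2 <- data.frame(chrom = "chr1", start = c(0, 150, 400),
                     end = c(150, 300, 500))
    expect_equal(merge_windows(w2, tolerance = 0, max_width = 5000),
                 c(1L, 1L, 2L))
    w3 <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 0),
                     end = c(100, 100))
    expect_equal(merge_windows(w3, 100, 5000), c(1L, 2L))
    expect_error(merge_windows(w[c(2, 1, 3), ], 100, 5000), "sorted")
})

test_that("max-width splitting matches a literal greedy re-implementation", {
    for (n in c(60, 150, 400)) {
        w <- data.frame(chrom = "chr1",
                        start = seq(0, by = 50, length.out = n),
                        end = seq(150, by = 50, length.out = n))
        cl <- merge_windows(w, tolerance = 100, max_width = 5000)
        expect_equal(cl, oracle_merge(w, 100, 5000))
        spans <- tapply(w$end, cl, max) - tapply(w$start, cl, min)
        expect_true(all(spans <= 5000))
        expect_equal(length(cl), n) # every window assigned
    }
    # random irregular windows
    set.seed(30)
    st <- sort(sample(0:50000, 300))
    w <- data.frame(chrom = "chr1", start = st, end = st + sample(50:300, 300,
                                                                  TRUE))
    expect_equal(merge_windows(w, 100, 2000), oracle_merge(w, 100, 2000))
})

test_that("Simes combination follows the formula and its bounds", {
    expect_equal(simes_combine(0.01), 0.01)
    expect_equal(simes_combine(c(0.01, 0.04, 0.9)), 0.03)
    expect_equal(simes_combine(rep(0.4, 7)), 0.4)
    expect_error(simes_combine(numeric(0)), "at least one")
    expect_error(simes_combine(c(0.5, 1.2)), "0, 1")
    set.seed(31)
    for (i in 1:50) {
        p <- runif(sample(1:8, 1))
        cp <- simes_combine(p)
        expect_equal(cp, oracle_simes(p))
        expect_gte(cp, min(p))
        expect_lte(cp, length(p) * min(p) + 1e-12)
    }
})

test_that("Simes is valid under the global null (Monte Carlo)", {
    set.seed(32)
    B <- 4000
    cp <- replicate(B, simes_combine(runif(5)))
    for (alpha in c(0.01, 0.05, 0.1)) {
        mc_se <- sqrt(alpha * (1 - alpha) / B)
        expect_lte(mean(cp <= alpha), alpha + 3 * mc_se)
    }
})

test_that("BH adjustment matches the literal step-up oracle", {
    expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bh_adjust(0.3), 0.3)
    set.seed(33)
    for (i in 1:20) {
        p <- runif(sample(1:200, 1))
        adj <- bh_adjust(p)
        expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
        for (t in c(0.05, 0.2))
            expect_equal(which(adj <= t), which(oracle_bh(p) <= t))
    }
})

test_that("region summaries pick best windows and directions correctly", {
    tab <- data.frame(chrom = "chr1",
                      start = c(0, 50, 100, 1000),
                      end = c(150, 200, 250, 1150),
                      logFC = c(0.2, -1.5, 0.4, 2),
                      p_value = c(0.5, 0.001, 0.2, 0.04))
    reg <- region_results(tab, tolerance = 100, max_width = 5000)
    expect_equal(nrow(reg), 2)
    expect_equal(reg$n_windows, c(3L, 1L))
    expect_equal(reg$best_start, c(50, 1000))
    expect_equal(reg$combined_p[1], simes_combine(c(0.5, 0.001, 0.2)))
    expect_equal(reg$fdr, bh_adjust(reg$combined_p))
    expect_equal(reg$direction, c("down", "up"))
    # tie on p: larger |logFC| wins
    tab2 <- data.frame(chrom = "chr1", start = c(0, 50), end = c(150, 200),
                       logFC = c(0.2, -1.5), p_value = c(0.1, 0.1))
    reg2 <- region_results(tab2)
    expect_equal(reg2$best_logFC, -1.5)
    # combined p respects Simes bounds region-wise
    expect_true(all(reg$combined_p >= c(0.001, 0.04)))
    expect_true(all(reg$fdr >= reg$combined_p))
})

test_that("grouped Simes equals the scalar version on random clusterings", {
    set.seed(34)
    p <- runif(500)
    cl <- sort(sample(1:80, 500, replace = TRUE))
    tab <- data.frame(chrom = "chr1",
                      start = seq(0, by = 500, length.out = 500),
                      end = seq(150, by = 500, length.out = 500),
                      logFC = rnorm(500), p_value = p)
    tab$start <- tab$start + cumsum(c(0, diff(cl))) * 1e6 # isolate clusters
    tab$end <- tab$start + 150
    reg <- region_results(tab, tolerance = 1000, max_width = 1e9)
    expect_equal(nrow(reg), length(unique(cl)))
    manual <- vapply(split(p, cl), simes_combine, numeric(1))
    expect_equal(reg$combined_p, unname(manual))
})

test_that("no regions are called on a fully null genome at FDR 0.05", {
    set.seed(35)
    reads <- simulate_background(8e6, n_libraries = 4)
    sim <- list(reads = reads, chrom_lengths = c(chr1 = 8e6),
                group = rep(1:2, each = 2))
    res <- run_pipeline_sim(sim)
    expect_lte(sum(res$regions$fdr <= 0.05), 2)
})
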