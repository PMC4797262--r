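two_group <- stats::model.matrix(~gl(2, 2))

test_that("NB GLM reproduces closed-form two-group fits", {
    fit <- nb_glm_fit(c(10, 10, 20, 20), two_group, offset = 0, dispersion = 0)
    expect_equal(unname(fit$fitted[1, ]), c(10, 10, 20, 20), tolerance = 1e-7)
    expect_equal(unname(fit$coefficients[1, 2]) / log(2), 1, tolerance = 1e-7)
    # constant counts: zero contrast, deviance matches the constant-fit form
    y <- c(15, 15, 15, 15)
    fit2 <- nb_glm_fit(y, two_group, offset = 0, dispersion = 0.1)
    expect_equal(unname(fit2$coefficients[1, 2]), 0, tolerance = 1e-8)
    expect_equal(fit2$deviance[1], nb_deviance(y, rep(15, 4), 0.1),
                 tolerance = 1e-8)
    expect_equal(fit2$deviance[1], 0, tolerance = 1e-8)
})

test_that("NB GLM agrees with black-box likelihood maximization", {
    set.seed(20)
    for (i in 1:6) {
        phi <- runif(1, 0.01, 0.4)
        y <- rnbinom(4, mu = exp(rnorm(1, 3.5)), size = 1 / phi)
        off <- rnorm(4, 10, 0.2)
        fit <- nb_glm_fit(y, two_group, offset = off, dispersion = phi)
        nll <- function(b)
            -sum(dnbinom(y, size = 1 / phi,
                         mu = exp(off + as.vector(two_group %*% b)),
                         log = TRUE))
        o <- optim(c(-7, 0), nll, method = "BFGS",
                   control = list(reltol = 1e-15, maxit = 500))
        o <- optim(o$par, nll, method = "BFGS",
                   control = list(reltol = 1e-15, maxit = 500))
        expect_lt(max(abs(fit$coefficients[1, ] - o$par)), 1e-6)
    }
})

test_that("GLM setup rejects rank-deficient designs", {
    X <- cbind(1, c(0, 0, 1, 1), c(0, 0, 2, 2))
    expect_error(nb_glm_fit(c(1, 2, 3, 4), X), "full rank")
})

test_that("dispersion trend recovers a constant truth and the Poisson limit", {
    set.seed(21)
    W <- 10000
    mu <- exp(runif(W, log(10), log(300)))
    y <- matrix(rnbinom(W * 4, mu = rep(mu, 4), size = 1 / 0.05), W, 4)
    A <- log2(rowMeans(y) + 2)
    tr <- estimate_dispersion_trend(y, two_group, A)
    expect_true(all(tr(A) >= 0.03 & tr(A) <= 0.07))
    # clamp outside the observed abundance range
    expect_equal(tr(min(A) - 10), tr(min(A)))
    expect_equal(tr(max(A) + 10), tr(max(A)))
    yp <- matrix(rpois(W * 4, rep(mu, 4)), W, 4)
    trp <- estimate_dispersion_trend(yp, two_group, log2(rowMeans(yp) + 2))
    expect_true(all(trp(A) <= 0.01))
    # saturated designs leave no residual df
    X4 <- diag(4)
    expect_error(estimate_dispersion_trend(y[1:300, ], X4, A[1:300]),
                 "residual")
})

test_that("EB shrinkage obeys its limiting and convex-combination contracts", {
    set.seed(22)
    # identical raw dispersions force d0 = Inf and shrunk == trend
    dev <- rep(2, 500)
    q <- ql_dispersions(dev, 2, runif(500, 3, 8), robust = FALSE)
    expect_true(is.infinite(q$df_prior[1]))
    expect_equal(q$shrunk_s2, q$trend)
    # heterogeneous data: shrunk lies between raw and trend, at the stated
    # weights (a log-normal scale mixture guarantees a finite prior df)
    dev2 <- rchisq(2000, 2) * exp(rnorm(2000, 0, 0.8))
    A <- runif(2000, 3, 8)
    q2 <- ql_dispersions(dev2, 2, A, robust = FALSE)
    d0 <- q2$df_prior[1]
    expect_true(is.finite(d0))
    manual <- (d0 * q2$trend + 2 * q2$s2) / (d0 + 2)
    expect_equal(q2$shrunk_s2, manual, tolerance = 1e-12)
    lo <- pmin(q2$s2, q2$trend) - 1e-12
    hi <- pmax(q2$s2, q2$trend) + 1e-12
    expect_true(all(q2$shrunk_s2 >= lo & q2$shrunk_s2 <= hi))
})

test_that("QL dispersions recover unit scale with a strong prior", {
    set.seed(23)
    sim_s2 <- function(W) {
        mu <- exp(runif(W, log(30), log(200)))
        y <- matrix(rnbinom(W * 4, mu = rep(mu, 4), size = 1 / 0.05), W, 4)
        A <- log2(rowMeans(y) + 2)
        tr <- estimate_dispersion_trend(y, two_group, A)
        fit <- nb_glm_fit(y, two_group, dispersion = tr(A))
        ql_dispersions(fit$deviance, fit$df_residual, A, robust = FALSE)
    }
    q_small <- sim_s2(1000)
    q_big <- sim_s2(10000)
    expect_gt(mean(q_big$shrunk_s2), 0.85)
    expect_lt(mean(q_big$shrunk_s2), 1.15)
    # no QL heterogeneity in truth: the prior df dominates the residual df
    expect_gt(q_big$df_prior[1], 10 * q_big$df_resid)
    expect_gt(q_small$df_prior[1], 10 * q_small$df_resid)
})

test_that("QL F-test handles degenerate and invariance cases", {
    # zero deviance difference
    ft <- ql_f_test(c(3, 3), c(3, 3), 1, c(1, 1), 10, 2)
    expect_equal(ft$statistic, c(0, 0))
    expect_equal(ft$p_value, c(1, 1))
    expect_error(ql_f_test(1, 2, 0, 1, 10, 2), "df_test")
    # common library-size scaling leaves p-values unchanged
    set.seed(24)
    y <- matrix(rnbinom(200 * 4, mu = 50, size = 10), 200, 4)
    cm1 <- make_cm(y, lib_sizes = rep(1e6, 4))
    cm2 <- make_cm(y, lib_sizes = rep(3e6, 4))
    t1 <- window_test(cm1, two_group, coef = 2)
    t2 <- window_test(cm2, two_group, coef = 2)
    # invariance is exact for the F statistics; the CPM-scale pseudocount in
    # the abundance covariate perturbs the fitted trends very slightly
    expect_lt(max(abs(t1$table$p_value - t2$table$p_value)), 0.005)
    # swapping group labels negates logFC, keeps p
    cm3 <- make_cm(y[, c(3, 4, 1, 2)], lib_sizes = rep(1e6, 4))
    t3 <- window_test(cm3, two_group, coef = 2)
    expect_equal(t3$table$logFC, -t1$table$logFC, tolerance = 1e-5)
    expect_equal(t3$table$p_value, t1$table$p_value, tolerance = 1e-6)
})

test_that("type I error of the window-level test is near-nominal", {
    set.seed(25)
    W <- 10000
    mu <- exp(runif(W, log(10), log(100)))
    lib <- c(9.5e5, 1.05e6, 1e6, 9.8e5)
    y <- matrix(rnbinom(W * 4, mu = rep(mu, 4) *
                            rep(lib / 1e6, each = W), size = 1 / 0.05), W, 4)
    cm <- make_cm(y, lib_sizes = lib)
    wt <- window_test(cm, two_group, coef = 2)
    expect_lte(mean(wt$table$p_value < 0.05), 0.055)
})

test_that("contrast vectors reproduce coefficient tests", {
    set.seed(26)
    y <- matrix(rnbinom(400, mu = 40, size = 8), 100, 4)
    cm <- make_cm(y)
    t_coef <- window_test(cm, two_group, coef = 2)
    t_con <- window_test(cm, two_group, contrast = c(0, 1))
    expect_equal(t_con$table$p_value, t_coef$table$p_value, tolerance = 1e-6)
    expect_equal(t_con$table$logFC, t_coef$table$logFC, tolerance = 1e-6)
})
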