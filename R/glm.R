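#' Negative binomial GLM deviance
#'
#' Residual deviance 2*(saturated - fitted log-likelihood) of counts under a
#' negative binomial model with variance mu + dispersion*mu^2; the Poisson
#' limit is used where the dispersion is (numerically) zero.
#'
#' @param y Count matrix (windows x libraries) or vector.
#' @param mu Fitted means, same shape as \code{y}.
#' @param dispersion Scalar or per-window vector of NB dispersions.
#' @return Numeric vector of per-window residual deviances.
#' @export
nb_deviance <- function(y, mu, dispersion = 0) {
    if (is.null(dim(y))) { y <- rbind(y); mu <- rbind(mu) }
    mu <- pmax(mu, 1e-10)
    phi <- rep_len(dispersion, nrow(y))
    ymat <- y
    phimat <- matrix(phi, nrow(y), ncol(y))
    t1 <- ifelse(ymat > 0, ymat * log(ymat / mu), 0)
    pois <- phimat < 1e-12
    t2 <- matrix(0, nrow(y), ncol(y))
    t2[pois] <- ymat[pois] - mu[pois]
    if (any(!pois)) {
        np <- !pois
        t2[np] <- (ymat[np] + 1 / phimat[np]) *
            (log1p(phimat[np] * ymat[np]) - log1p(phimat[np] * mu[np]))
    }
    unname(rowSums(2 * (t1 - t2)))
}

#' Negative binomial log-likelihood
#'
#' @inheritParams nb_deviance
#' @return Per-window log-likelihood totals.
#' @export
nb_loglik <- function(y, mu, dispersion = 0) {
    if (is.null(dim(y))) { y <- rbind(y); mu <- rbind(mu) }
    mu <- pmax(mu, 1e-10)
    phi <- rep_len(dispersion, nrow(y))
    ll <- matrix(0, nrow(y), ncol(y))
    phimat <- matrix(phi, nrow(y), ncol(y))
    pois <- phimat < 1e-12
    ll[pois] <- stats::dpois(y[pois], mu[pois], log = TRUE)
    if (any(!pois)) {
        np <- !pois
        ll[np] <- stats::dnbinom(y[np], size = 1 / phimat[np], mu = mu[np],
                                 log = TRUE)
    }
    unname(rowSums(ll))
}

.expand_offset <- function(offset, W, n) {
    if (is.null(offset)) offset <- 0
    if (is.matrix(offset)) {
        stopifnot(nrow(offset) == W, ncol(offset) == n)
        offset
    } else if (length(offset) == n) {
        matrix(offset, W, n, byrow = TRUE)
    } else if (length(offset) == 1L) {
        matrix(offset, W, n)
    } else stop("'offset' must be a scalar, per-library vector or matrix")
}

# Solve the per-window weighted least squares systems (X' W X) b = X' W z.
# w, z: W x n matrices; X: n x p design. Closed forms for p <= 2, row loop
# otherwise.
.wls_solve <- function(w, z, X) {
    p <- ncol(X)
    rhs <- (w * z) %*% X
    if (p == 1L) {
        M <- w %*% (X[, 1]^2)
        return(rhs / pmax(M, 1e-300))
    }
    if (p == 2L) {
        a <- w %*% (X[, 1]^2)
        b <- w %*% (X[, 1] * X[, 2])
        d <- w %*% (X[, 2]^2)
        det <- a * d - b * b
        bad <- !is.finite(det) | det <= 1e-300
        det[bad] <- 1
        out <- cbind((d * rhs[, 1] - b * rhs[, 2]) / det,
                     (a * rhs[, 2] - b * rhs[, 1]) / det)
        if (any(bad)) {
            for (i in which(bad)) {
                M <- crossprod(X, w[i, ] * X) + diag(1e-8, p)
                out[i, ] <- solve(M, rhs[i, ])
            }
        }
        return(out)
    }
    out <- matrix(0, nrow(w), p)
    for (i in seq_len(nrow(w))) {
        M <- crossprod(X, w[i, ] * X)
        out[i, ] <- tryCatch(solve(M, rhs[i, ]),
                             error = function(e)
                                 solve(M + diag(1e-8, p), rhs[i, ]))
    }
    out
}

# 0.5 * log det(X' W X) per window (Cox-Reid adjustment).
.cr_adjust <- function(w, X) {
    p <- ncol(X)
    if (p == 1L) {
        M <- as.numeric(w %*% (X[, 1]^2))
        return(0.5 * log(pmax(M, 1e-300)))
    }
    if (p == 2L) {
        a <- as.numeric(w %*% (X[, 1]^2))
        b <- as.numeric(w %*% (X[, 1] * X[, 2]))
        d <- as.numeric(w %*% (X[, 2]^2))
        return(0.5 * log(pmax(a * d - b * b, 1e-300)))
    }
    vapply(seq_len(nrow(w)), function(i) {
        M <- crossprod(X, w[i, ] * X)
        0.5 * as.numeric(determinant(M, logarithm = TRUE)$modulus)
    }, numeric(1))
}

#' Fit negative binomial GLMs with a log link across windows
#'
#' Maximizes the NB log-likelihood for every window simultaneously by
#' iteratively reweighted least squares with step halving, sharing one
#' design matrix across windows. Convergence is declared when the relative
#' deviance change falls below \code{tol} (default 1e-8) or after
#' \code{maxit} iterations.
#'
#' @param y Count matrix (windows x libraries); a vector is treated as one
#'   window.
#' @param design Full-rank design matrix (libraries x coefficients).
#' @param offset Log-scale offsets: scalar, per-library vector, or a
#'   windows x libraries matrix (typically log effective library sizes, plus
#'   loess offsets when used).
#' @param dispersion NB dispersion: scalar or per-window vector; 0 gives the
#'   Poisson limit.
#' @param tol Relative deviance convergence tolerance.
#' @param maxit Maximum IRLS iterations.
#' @param beta_start Optional starting coefficients (windows x
#'   coefficients).
#'
#' @return List with \code{coefficients} (windows x coefficients, natural
#'   log scale), \code{fitted} (means), \code{deviance}, \code{df_residual},
#'   \code{iterations} and \code{converged}.
#' @export
nb_glm_fit <- function(y, design, offset = NULL, dispersion = 0,
                       tol = 1e-8, maxit = 50L, beta_start = NULL) {
    if (is.null(dim(y))) y <- rbind(y)
    y <- as.matrix(y)
    X <- as.matrix(design)
    n <- ncol(y); W <- nrow(y); p <- ncol(X)
    if (qr(X)$rank < p) stop("design matrix is not of full rank")
    if (n - p < 0) stop("more coefficients than libraries")
    if (any(dispersion < 0)) stop("dispersion must be >= 0")
    off <- .expand_offset(offset, W, n)
    if (any(!is.finite(off))) stop("offsets must be finite")
    phi <- rep_len(dispersion, W)

    if (is.null(beta_start)) {
        z0 <- log(pmax(y, 0.5)) - off
        beta <- z0 %*% X %*% solve(crossprod(X))
    } else beta <- as.matrix(beta_start)

    eta <- off + tcrossprod(beta, X)
    eta <- pmin(pmax(eta, -45), 45)
    mu <- exp(eta)
    dev <- nb_deviance(y, mu, phi)
    conv <- FALSE
    iter <- 0L
    phimat <- matrix(phi, W, n)
    for (iter in seq_len(maxit)) {
        musafe <- pmax(mu, 1e-10)
        w <- musafe / (1 + phimat * musafe)
        z <- (eta - off) + (y - musafe) / musafe
        beta_new <- .wls_solve(w, z, X)
        # damped update: halve the step where the deviance would increase
        step <- rep(1, W)
        for (h in 0:10) {
            beta_try <- beta + step * (beta_new - beta)
            eta_try <- pmin(pmax(off + tcrossprod(beta_try, X), -45), 45)
            mu_try <- exp(eta_try)
            dev_try <- nb_deviance(y, mu_try, phi)
            worse <- dev_try > dev * (1 + 1e-12) + 1e-12
            if (!any(worse) || h == 10L) break
            step[worse] <- step[worse] / 2
        }
        delta <- abs(dev - dev_try) / (abs(dev) + 0.1)
        beta <- beta_try; eta <- eta_try; mu <- mu_try; dev <- dev_try
        if (max(delta) < tol) { conv <- TRUE; break }
    }
    list(coefficients = beta, fitted = mu, deviance = dev,
         df_residual = n - p, iterations = iter, converged = conv,
         weights = pmax(mu, 1e-10) / (1 + phimat * pmax(mu, 1e-10)))
}
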