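## Model core: segment likelihood, sequential coupling prior, closed-form
## marginal likelihood and all full conditional distributions of the
## edge-wise coupled NH-DBN.
##
## Notation. For segment h the response vector is y_h (length T_h) and the
## design matrix X_h (T_h x P) has a first column of ones. The prior of the
## segment-h coefficient vector is N(mu_h, sigma^2 * Sigma_h) with
##   h = 1:  mu_1 = 0,                    Sigma_1 = lambda_u I
##   h > 1:  mu_h = delta (*) btilde_{h-1},
##           Sigma_h = diag{lambda_c delta + lambda_u (1 - delta)}
## where (*) is the elementwise product and btilde_h is the posterior
## expectation of beta_h, computed sequentially and treated downstream as a
## fixed vector. All quantities are computed in log space; quadratic forms
## and determinants of I + X Sigma X' use the rank-P identities
##   det(I + X S X') = det(S) det(S^{-1} + X'X)
##   r'(I + X S X')^{-1} r = r'r - (X'r)' (S^{-1} + X'X)^{-1} (X'r)
## so nothing larger than P x P is ever factorized.

#' Segment a lagged regression problem at a set of changepoints
#'
#' Splits the response vector and design matrix into contiguous segments.
#' Transition `t` belongs to segment `h` iff `tau_{h-1} < t <= tau_h`, with
#' the boundary convention `tau_0 = 1`, `tau_H = T` (the first time point is
#' always part of segment 1). Changepoints live on `S = {2, ..., T-1}`.
#'
#' @param y numeric response vector of length T.
#' @param X numeric design matrix (T x P) whose first column is all ones.
#' @param tau integer changepoint positions (strictly increasing), possibly
#'   empty for a single segment.
#'
#' @return A list with components `y` (list of segment responses), `X` (list
#'   of segment designs), `tau`, `T`, `P` and `H`.
#' @examples
#' X <- cbind(1, rnorm(8))
#' sd <- segmentDesign(rnorm(8), X, tau = c(3, 6))
#' lengths(sd$y)  # 3, 3, 2
#' @export
segmentDesign <- function(y, X, tau = integer(0)) {
    X <- as.matrix(X)
    T <- length(y)
    stopifnot(nrow(X) == T)
    tau <- as.integer(tau)
    if (length(tau)) {
        if (is.unsorted(tau, strictly = TRUE))
            stop("changepoints must be strictly increasing")
        if (any(tau < 2L) || any(tau > T - 1L))
            stop("changepoints must lie in {2, ..., T-1}")
    }
    seg <- findInterval(seq_len(T) - 1L, tau) + 1L  # 1 + #{tau_j < t}
    H <- length(tau) + 1L
    list(y = split(y, seg), X = lapply(split(seq_len(T), seg),
                                       function(i) X[i, , drop = FALSE]),
         tau = tau, T = T, P = ncol(X), H = H)
}

## internal: per-segment coupling row. delta may be a vector (same indicators
## for every segment, the edge-wise model) or a matrix with H rows whose row h
## applies to segment h (row 1 is ignored: segment 1 is always uncoupled).
.deltaRow <- function(delta, h, P) {
    d <- if (is.matrix(delta)) delta[h, ] else delta
    if (length(d) != P) stop("delta length ", length(d),
                             " does not match design column count ", P)
    d
}

#' Prior moments of one segment's coefficient vector
#'
#' Returns the prior mean and the diagonal of the prior scale matrix for
#' segment `h`: the first segment is always re-initialized at zero with scale
#' `lambdaU`; later segments inherit `delta * betaTildePrev` as mean, with
#' per-coordinate scale `lambdaC` where coupled and `lambdaU` where not.
#'
#' @param h segment index (1-based).
#' @param delta 0/1 coupling indicators, one per design column.
#' @param lambdaU,lambdaC positive variance parameters.
#' @param betaTildePrev posterior expectation of the previous segment's
#'   coefficients; required for `h > 1`.
#'
#' @return list with `mu` (prior mean) and `sigmaDiag` (diagonal of Sigma_h).
#' @export
segmentPriorMoments <- function(h, delta, lambdaU, lambdaC,
                                betaTildePrev = NULL) {
    if (lambdaU <= 0 || lambdaC <= 0)
        stop("lambdaU and lambdaC must be strictly positive")
    P <- length(delta)
    if (h == 1L)
        return(list(mu = rep(0, P), sigmaDiag = rep(lambdaU, P)))
    if (is.null(betaTildePrev))
        stop("betaTildePrev is required for h > 1")
    if (length(betaTildePrev) != P)
        stop("betaTildePrev and delta must have equal length")
    list(mu = delta * betaTildePrev,
         sigmaDiag = lambdaC * delta + lambdaU * (1 - delta))
}

## internal: walk the segments once, computing the sequential btilde chain and
## (optionally) the residual quadratic form and log-determinant contributions.
.chainStats <- function(sd, delta, lambdaU, lambdaC) {
    H <- sd$H; P <- sd$P
    btilde <- vector("list", H)
    mus <- vector("list", H)
    sig <- vector("list", H)
    quad <- 0; logdet <- 0
    btPrev <- rep(0, P)
    for (h in seq_len(H)) {
        dh <- .deltaRow(delta, h, P)
        pm <- segmentPriorMoments(h, dh, lambdaU, lambdaC,
                                  betaTildePrev = if (h > 1L) btPrev)
        Xh <- sd$X[[h]]; yh <- sd$y[[h]]
        M <- crossprod(Xh) + diag(1 / pm$sigmaDiag, P)
        R <- chol(M)
        r <- yh - as.vector(Xh %*% pm$mu)
        Xtr <- crossprod(Xh, r)
        w <- backsolve(R, Xtr, transpose = TRUE)
        quad <- quad + sum(r^2) - sum(w^2)
        logdet <- logdet + 2 * sum(log(diag(R))) + sum(log(pm$sigmaDiag))
        rhs <- pm$mu / pm$sigmaDiag + crossprod(Xh, yh)
        bt <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
        btilde[[h]] <- as.vector(bt)
        mus[[h]] <- pm$mu; sig[[h]] <- pm$sigmaDiag
        btPrev <- btilde[[h]]
    }
    list(btilde = btilde, quad = quad, logdet = logdet, mu = mus,
         sigmaDiag = sig)
}

#' Sequential posterior-expectation chain
#'
#' Computes `btilde_h = (Sigma_h^{-1} + X_h'X_h)^{-1} (Sigma_h^{-1} mu_h +
#' X_h'y_h)` for `h = 1..H`, each segment's prior mean built from the previous
#' segment's `btilde` (with `btilde_0 = 0`). The chain is deterministic given
#' the data, the indicators and the variance parameters; downstream it is
#' treated as a vector of fixed constants, never as a random quantity.
#'
#' @param sd segmented data from [segmentDesign()].
#' @param delta coupling indicators (vector, or matrix with one row per
#'   segment for segment-wise variants).
#' @param lambdaU,lambdaC positive variance parameters.
#'
#' @return list of numeric vectors, one per segment.
#' @export
posteriorExpectationChain <- function(sd, delta, lambdaU, lambdaC) {
    .chainStats(sd, delta, lambdaU, lambdaC)$btilde
}

#' Residual quadratic form of the collapsed model
#'
#' `Delta^2 = sum_h (y_h - X_h mu_h)' (I + X_h Sigma_h X_h')^{-1}
#' (y_h - X_h mu_h)`, the total squared prediction error of the prior means
#' under the marginal covariance of each segment. This is the data-dependent
#' term of the marginal likelihood and of the collapsed noise-variance update.
#'
#' @inheritParams posteriorExpectationChain
#' @return nonnegative scalar.
#' @export
deltaSquared <- function(sd, delta, lambdaU, lambdaC) {
    .chainStats(sd, delta, lambdaU, lambdaC)$quad
}

#' Log marginal likelihood with coefficients and noise variance integrated out
#'
#' Evaluates, entirely in log space,
#' \deqn{p(y_1,...,y_H | \lambda_u, \lambda_c, \delta) =
#'   \frac{\Gamma(T/2 + a_\sigma)}{\Gamma(a_\sigma)} \pi^{-T/2}
#'   (2 b_\sigma)^{a_\sigma} (2 b_\sigma + \Delta^2)^{-(T/2 + a_\sigma)}
#'   \prod_h \det(I + X_h \Sigma_h X_h')^{-1/2}}
#' the closed-form marginal of the piece-wise linear regression with
#' Gaussian-inverse-Gamma priors and sequential edge-wise coupling.
#'
#' @inheritParams posteriorExpectationChain
#' @param hyper an [EwcHyper-class] object.
#' @return scalar log marginal likelihood.
#' @export
logMarginalLikelihood <- function(sd, delta, lambdaU, lambdaC,
                                  hyper = ewcHyperparams()) {
    cs <- .chainStats(sd, delta, lambdaU, lambdaC)
    T <- sd$T
    a <- hyper@aSigma; b <- hyper@bSigma
    out <- lgamma(T / 2 + a) - lgamma(a) - (T / 2) * log(pi) +
        a * log(2 * b) - (T / 2 + a) * log(2 * b + cs$quad) - 0.5 * cs$logdet
    if (!is.finite(out))
        stop("non-finite log marginal likelihood (degenerate inputs)")
    out
}

#' Draw the segment coefficient vectors from their full conditionals
#'
#' `beta_h ~ N(C_h (Sigma_h^{-1} mu_h + X_h'y_h), sigma2 C_h)` with
#' `C_h = (Sigma_h^{-1} + X_h'X_h)^{-1}`, drawn segment by segment with the
#' prior means built from the fixed posterior-expectation chain.
#'
#' @inheritParams posteriorExpectationChain
#' @param sigma2 current noise variance.
#' @return list of coefficient vectors, one per segment.
#' @export
sampleBeta <- function(sd, delta, lambdaU, lambdaC, sigma2) {
    H <- sd$H; P <- sd$P
    cs <- .chainStats(sd, delta, lambdaU, lambdaC)
    out <- vector("list", H)
    for (h in seq_len(H)) {
        M <- crossprod(sd$X[[h]]) + diag(1 / cs$sigmaDiag[[h]], P)
        R <- tryCatch(chol(M), error = function(e)
            stop("full conditional covariance for segment ", h,
                 " is not positive definite: ", conditionMessage(e)))
        mean <- cs$btilde[[h]]  # btilde_h is exactly C_h (Sigma^-1 mu + X'y)
        out[[h]] <- mean + sqrt(sigma2) * backsolve(R, rnorm(P))
    }
    out
}

#' Collapsed draw of the noise variance
#'
#' With all coefficient vectors integrated out, the precision has the full
#' conditional `sigma^-2 ~ GAM(a_sigma + T/2, b_sigma + Delta^2/2)`.
#'
#' @inheritParams logMarginalLikelihood
#' @return a draw of `sigma2`.
#' @export
sampleSigma2 <- function(sd, delta, lambdaU, lambdaC,
                         hyper = ewcHyperparams()) {
    d2 <- deltaSquared(sd, delta, lambdaU, lambdaC)
    prec <- rgamma(1, shape = hyper@aSigma + sd$T / 2,
                   rate = hyper@bSigma + d2 / 2)
    1 / prec
}

#' Coupling bookkeeping for the variance-parameter updates
#'
#' Computes the sums of squares and coefficient counts entering the full
#' conditionals of `lambdaU` and `lambdaC`:
#' `Du2` sums the squared uncoupled coefficients (all of segment 1 plus the
#' delta = 0 coordinates of later segments), `Dc2` the squared deviations of
#' coupled coordinates from the inherited posterior expectations; `ku` and
#' `kc` count the coefficients in each group, with `ku + kc = H * P` always.
#'
#' @param beta list of segment coefficient vectors.
#' @param btilde posterior-expectation chain (see
#'   [posteriorExpectationChain()]).
#' @param delta coupling indicators (vector or per-segment matrix).
#' @return list with `Du2`, `Dc2`, `ku`, `kc`.
#' @export
couplingSums <- function(beta, btilde, delta) {
    H <- length(beta); P <- length(beta[[1L]])
    Du2 <- sum(beta[[1L]]^2); Dc2 <- 0
    ku <- P; kc <- 0L
    for (h in seq_len(H)[-1L]) {
        dh <- .deltaRow(delta, h, P)
        u <- dh == 0
        Du2 <- Du2 + sum(beta[[h]][u]^2)
        Dc2 <- Dc2 + sum((beta[[h]][!u] - btilde[[h - 1L]][!u])^2)
        ku <- ku + sum(u); kc <- kc + sum(!u)
    }
    list(Du2 = Du2, Dc2 = Dc2, ku = as.integer(ku), kc = as.integer(kc))
}

#' Draw the variance parameters from their full conditionals
#'
#' `lambda_u^-1 ~ GAM(a_u + ku/2, b_u + sigma^-2 Du2 / 2)` and
#' `lambda_c^-1 ~ GAM(a_c + kc/2, b_c + sigma^-2 Dc2 / 2)`. With no coupled
#' coefficients (`kc = 0`) the coupling strength is refreshed from its prior.
#' Draws are floored at 1e-12 to keep the prior scale matrices invertible.
#'
#' @inheritParams couplingSums
#' @param sigma2 current noise variance.
#' @param hyper an [EwcHyper-class] object.
#' @return list with `lambdaU` and `lambdaC`.
#' @export
sampleLambdas <- function(beta, btilde, delta, sigma2,
                          hyper = ewcHyperparams()) {
    cs <- couplingSums(beta, btilde, delta)
    lu <- 1 / rgamma(1, shape = hyper@aU + cs$ku / 2,
                     rate = hyper@bU + cs$Du2 / (2 * sigma2))
    lc <- 1 / rgamma(1, shape = hyper@aC + cs$kc / 2,
                     rate = hyper@bC + cs$Dc2 / (2 * sigma2))
    list(lambdaU = max(lu, 1e-12), lambdaC = max(lc, 1e-12))
}

#' Gibbs update of the coupling indicators
#'
#' Each indicator is resampled from its collapsed full conditional
#' `delta_i ~ BER(theta_i)` with
#' `theta_i = p L(delta_{i<-1}) / (p L(delta_{i<-1}) + (1-p) L(delta_{i<-0}))`
#' where `L` is the marginal likelihood with coefficients and noise variance
#' integrated out. Flipping one indicator changes the prior means of all later
#' segments, so the whole posterior-expectation chain is re-propagated inside
#' each evaluation. The sweep visits indices 0..k in order (or a random
#' permutation).
#'
#' @inheritParams logMarginalLikelihood
#' @param randomSweep permute the update order.
#' @return updated 0/1 indicator vector.
#' @export
sampleDelta <- function(sd, delta, lambdaU, lambdaC,
                        hyper = ewcHyperparams(), randomSweep = FALSE) {
    P <- sd$P
    stopifnot(length(delta) == P)
    p <- hyper@pCouple
    ord <- if (randomSweep) sample.int(P) else seq_len(P)
    for (i in ord) {
        if (p <= 0) { delta[i] <- 0; next }
        if (p >= 1) { delta[i] <- 1; next }
        d1 <- delta; d1[i] <- 1
        d0 <- delta; d0[i] <- 0
        l1 <- logMarginalLikelihood(sd, d1, lambdaU, lambdaC, hyper)
        l0 <- logMarginalLikelihood(sd, d0, lambdaU, lambdaC, hyper)
        theta <- 1 / (1 + exp(l0 - l1) * (1 - p) / p)
        delta[i] <- as.numeric(runif(1) < theta)
    }
    delta
}

#' Conditional coupling probability of a single indicator
#'
#' The Bernoulli probability used by [sampleDelta()] for coordinate `i`,
#' exposed for diagnostics and exact small-problem checks.
#'
#' @inheritParams sampleDelta
#' @param i coordinate index (1 = intercept).
#' @return scalar probability that `delta_i = 1` given the rest.
#' @export
deltaConditionalProb <- function(sd, delta, i, lambdaU, lambdaC,
                                 hyper = ewcHyperparams()) {
    p <- hyper@pCouple
    if (p <= 0) return(0)
    if (p >= 1) return(1)
    d1 <- delta; d1[i] <- 1
    d0 <- delta; d0[i] <- 0
    l1 <- logMarginalLikelihood(sd, d1, lambdaU, lambdaC, hyper)
    l0 <- logMarginalLikelihood(sd, d0, lambdaU, lambdaC, hyper)
    1 / (1 + exp(l0 - l1) * (1 - p) / p)
}
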