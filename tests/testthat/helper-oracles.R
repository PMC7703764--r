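## Independent oracles used across the suite. These deliberately avoid the
## package's computational shortcuts: dense matrix formulas with explicit
## inversion, elementwise loops, exhaustive enumeration and numerical
## integration.

# random segmented regression instance
randomInstance <- function(T = 12L, k = 2L, H = 2L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    X <- cbind(1, matrix(rnorm(T * k), T, k))
    y <- rnorm(T)
    tau <- if (H > 1L) sort(sample(seq(3L, T - 2L), H - 1L)) else integer(0)
    while (length(tau) && any(diff(c(1L, tau, T)) < 2L))
        tau <- sort(sample(seq(3L, T - 2L), H - 1L))
    delta <- rbinom(k + 1L, 1L, 0.5)
    list(y = y, X = X, tau = tau, delta = delta,
         lambdaU = exp(runif(1, -1, 1)), lambdaC = exp(runif(1, -2, 0)),
         sd = segmentDesign(y, X, tau))
}

# dense evaluation of the marginal likelihood: explicit T_h x T_h matrices,
# solve() and determinant(), sequential posterior-expectation chain
bruteLogMarginal <- function(y, X, tau, delta, lambdaU, lambdaC,
                             hyper = ewcHyperparams()) {
    P <- ncol(X)
    T <- length(y)
    seg <- findInterval(seq_len(T) - 1L, tau) + 1L
    quad <- 0; ld <- 0
    btPrev <- rep(0, P)
    for (h in seq_len(max(seg))) {
        rows <- which(seg == h)
        Xh <- X[rows, , drop = FALSE]; yh <- y[rows]
        if (h == 1L) { mu <- rep(0, P); S <- diag(lambdaU, P) } else {
            mu <- delta * btPrev
            S <- diag(lambdaC * delta + lambdaU * (1 - delta), P)
        }
        V <- diag(length(rows)) + Xh %*% S %*% t(Xh)
        r <- yh - as.vector(Xh %*% mu)
        quad <- quad + as.numeric(t(r) %*% solve(V) %*% r)
        ld <- ld + as.numeric(determinant(V)$modulus)
        btPrev <- as.vector(solve(solve(S) + crossprod(Xh),
                                  solve(S) %*% mu + crossprod(Xh, yh)))
    }
    a <- hyper@aSigma; b <- hyper@bSigma
    lgamma(T / 2 + a) - lgamma(a) - T / 2 * log(pi) + a * log(2 * b) -
        (T / 2 + a) * log(2 * b + quad) - 0.5 * ld
}

bruteDeltaSquared <- function(y, X, tau, delta, lambdaU, lambdaC) {
    P <- ncol(X); T <- length(y)
    seg <- findInterval(seq_len(T) - 1L, tau) + 1L
    quad <- 0; btPrev <- rep(0, P)
    for (h in seq_len(max(seg))) {
        rows <- which(seg == h)
        Xh <- X[rows, , drop = FALSE]; yh <- y[rows]
        if (h == 1L) { mu <- rep(0, P); S <- diag(lambdaU, P) } else {
            mu <- delta * btPrev
            S <- diag(lambdaC * delta + lambdaU * (1 - delta), P)
        }
        V <- diag(length(rows)) + Xh %*% S %*% t(Xh)
        r <- yh - as.vector(Xh %*% mu)
        quad <- quad + as.numeric(t(r) %*% solve(V) %*% r)
        btPrev <- as.vector(solve(solve(S) + crossprod(Xh),
                                  solve(S) %*% mu + crossprod(Xh, yh)))
    }
    quad
}

# elementwise loop evaluation of the coupling sums
bruteCouplingSums <- function(beta, btilde, delta) {
    H <- length(beta); P <- length(beta[[1]])
    Du2 <- 0; Dc2 <- 0; ku <- 0L; kc <- 0L
    for (i in seq_len(P)) {
        Du2 <- Du2 + beta[[1]][i]^2
        ku <- ku + 1L
    }
    for (h in 2:H) for (i in seq_len(P)) {
        if (delta[i] == 0) {
            Du2 <- Du2 + beta[[h]][i]^2; ku <- ku + 1L
        } else {
            Dc2 <- Dc2 + (beta[[h]][i] - btilde[[h - 1]][i])^2; kc <- kc + 1L
        }
    }
    list(Du2 = Du2, Dc2 = Dc2, ku = ku, kc = kc)
}

# marginal likelihood by direct numerical integration: tensor-grid quadrature
# over each segment's coefficient vector, trapezoid over log sigma2.
quadratureLogMarginal <- function(y, X, tau, delta, lambdaU, lambdaC,
                                  hyper = ewcHyperparams(),
                                  nBeta = 181L, nSigma = 121L, span = 9) {
    P <- ncol(X); T <- length(y)
    seg <- findInterval(seq_len(T) - 1L, tau) + 1L
    a <- hyper@aSigma; b <- hyper@bSigma
    ls2 <- seq(log(1e-4), log(1e4), length.out = nSigma)
    # per-sigma2 log integral over beta for one segment
    segIntegral <- function(rows, mu, sdiag, s2) {
        Xh <- X[rows, , drop = FALSE]; yh <- y[rows]
        grids <- lapply(seq_len(P), function(j)
            seq(mu[j] - span * sqrt(s2 * sdiag[j]),
                mu[j] + span * sqrt(s2 * sdiag[j]), length.out = nBeta))
        steps <- vapply(grids, function(g) g[2] - g[1], 0)
        B <- as.matrix(expand.grid(grids))
        rss <- colSums((yh - Xh %*% t(B))^2)
        lpost <- -length(rows) / 2 * log(2 * pi * s2) - rss / (2 * s2) -
            P / 2 * log(2 * pi * s2) - 0.5 * sum(log(sdiag)) -
            colSums((t(B) - mu)^2 / (2 * s2 * sdiag))
        m <- max(lpost)
        m + log(sum(exp(lpost - m))) + sum(log(steps))
    }
    logf <- vapply(ls2, function(u) {
        s2 <- exp(u)
        btPrev <- rep(0, P)
        tot <- 0
        for (h in seq_len(max(seg))) {
            rows <- which(seg == h)
            if (h == 1L) { mu <- rep(0, P); sdiag <- rep(lambdaU, P) } else {
                mu <- delta * btPrev
                sdiag <- lambdaC * delta + lambdaU * (1 - delta)
            }
            tot <- tot + segIntegral(rows, mu, sdiag, s2)
            Xh <- X[rows, , drop = FALSE]; yh <- y[rows]
            btPrev <- as.vector(
                solve(diag(1 / sdiag, P) + crossprod(Xh),
                      mu / sdiag + crossprod(Xh, yh)))
        }
        # inverse-gamma prior density of sigma2, plus the log-scale Jacobian
        tot + a * log(b) - lgamma(a) - (a + 1) * u - b / s2 + u
    }, 0)
    step <- ls2[2] - ls2[1]
    m <- max(logf)
    m + log(sum(exp(logf - m)) - 0.5 * (exp(logf[1] - m) +
                                        exp(logf[length(logf)] - m))) +
        log(step)
}

# all changepoint layouts with H segments on transitions 1..T
enumTauLayouts <- function(T, H) {
    if (H == 1L) return(list(integer(0)))
    pos <- seq(2L, T - 1L)
    cmb <- combn(pos, H - 1L)
    lapply(seq_len(ncol(cmb)), function(j) as.integer(cmb[, j]))
}

# equal-probability quadrature grid for lambda with lambda^-1 ~ GAM(a, b)
lambdaGrid <- function(a, b, G = 64L) {
    1 / qgamma((seq_len(G) - 0.5) / G, shape = a, rate = b)
}

# log-sum-exp
lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
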