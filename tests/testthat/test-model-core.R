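test_that("segment prior moments follow the edge-wise coupling rule", {
    # first segment: always re-initialized at zero with scale lambdaU
    pm <- segmentPriorMoments(1, delta = c(1, 0, 1), lambdaU = 2, lambdaC = 0.1)
    expect_equal(pm$mu, c(0, 0, 0))
    expect_equal(pm$sigmaDiag, rep(2, 3))

    # fully coupled later segment inherits the whole chain value
    bt <- c(0.3, -1.2)
    pm <- segmentPriorMoments(2, delta = c(1, 1), lambdaU = 2, lambdaC = 0.1,
                              betaTildePrev = bt)
    expect_equal(pm$mu, bt)
    expect_equal(pm$sigmaDiag, rep(0.1, 2))

    # elementwise mixture
    pm <- segmentPriorMoments(2, delta = c(1, 0), lambdaU = 2, lambdaC = 0.1,
                              betaTildePrev = c(0.4, -0.2))
    expect_equal(pm$mu, c(0.4, 0))
    expect_equal(pm$sigmaDiag, c(0.1, 2))

    expect_error(segmentPriorMoments(1, c(1, 0), lambdaU = -1, lambdaC = 0.1),
                 "positive")
    expect_error(segmentPriorMoments(2, c(1, 0), 1, 1), "betaTildePrev")
})

test_that("posterior expectation chain matches conjugate updates and limits", {
    set.seed(101)
    # no signal: posterior mean equals the (zero) prior mean
    sd0 <- segmentDesign(rnorm(8), matrix(0, 8, 2), integer(0))
    expect_equal(posteriorExpectationChain(sd0, c(0, 0), 1, 1)[[1]], c(0, 0))

    # flat-prior limit reproduces ordinary least squares
    X <- cbind(1, rnorm(10))
    y <- 2 - 0.7 * X[, 2] + rnorm(10, 0, 0.1)
    sd1 <- segmentDesign(y, X)
    bt <- posteriorExpectationChain(sd1, c(0, 0), lambdaU = 1e10,
                                    lambdaC = 1)[[1]]
    expect_equal(bt, as.vector(solve(crossprod(X), crossprod(X, y))),
                 tolerance = 1e-6)

    # two-segment instance vs. an independent conjugate-update oracle
    for (seed in 1:5) {
        inst <- randomInstance(T = 12, k = 2, H = 2, seed = seed)
        got <- posteriorExpectationChain(inst$sd, inst$delta, inst$lambdaU,
                                         inst$lambdaC)
        P <- ncol(inst$X)
        seg <- findInterval(seq_along(inst$y) - 1L, inst$tau) + 1L
        btPrev <- rep(0, P)
        for (h in 1:2) {
            rows <- which(seg == h)
            Xh <- inst$X[rows, , drop = FALSE]; yh <- inst$y[rows]
            if (h == 1) { mu <- rep(0, P); S <- diag(inst$lambdaU, P) } else {
                mu <- inst$delta * btPrev
                S <- diag(inst$lambdaC * inst$delta +
                          inst$lambdaU * (1 - inst$delta), P)
            }
            btPrev <- as.vector(solve(solve(S) + crossprod(Xh),
                                      solve(S) %*% mu + crossprod(Xh, yh)))
            expect_equal(got[[h]], btPrev, tolerance = 1e-10)
        }
    }
})

test_that("Delta^2 matches dense evaluation and degenerate cases", {
    # zero residuals
    X <- cbind(1, rnorm(9))
    sdz <- segmentDesign(rep(0, 9), X * 0, c(4L))
    expect_equal(deltaSquared(sdz, c(0, 0), 1, 1), 0)

    # single segment, no design signal: quadratic form collapses to y'y
    y <- rnorm(7)
    sd1 <- segmentDesign(y, matrix(0, 7, 2))
    expect_equal(deltaSquared(sd1, c(1, 1), 0.5, 0.2), sum(y^2))

    for (seed in 11:16) {
        inst <- randomInstance(T = 14, k = 2, H = 3, seed = seed)
        expect_equal(deltaSquared(inst$sd, inst$delta, inst$lambdaU,
                                  inst$lambdaC),
                     bruteDeltaSquared(inst$y, inst$X, inst$tau, inst$delta,
                                       inst$lambdaU, inst$lambdaC),
                     tolerance = 1e-10)
    }
})

test_that("log marginal likelihood matches the dense formula and is stable", {
    for (seed in 21:28) {
        inst <- randomInstance(T = 15, k = 2, H = sample(1:3, 1), seed = seed)
        expect_equal(
            logMarginalLikelihood(inst$sd, inst$delta, inst$lambdaU,
                                  inst$lambdaC),
            bruteLogMarginal(inst$y, inst$X, inst$tau, inst$delta,
                             inst$lambdaU, inst$lambdaC),
            tolerance = 1e-9)
    }
})

test_that("log marginal likelihood invariances", {
    inst <- randomInstance(T = 12, k = 1, H = 2, seed = 31)
    base <- logMarginalLikelihood(inst$sd, inst$delta, inst$lambdaU,
                                  inst$lambdaC)

    # permuting time points within a segment leaves the value unchanged
    seg <- findInterval(seq_along(inst$y) - 1L, inst$tau) + 1L
    perm <- unlist(lapply(split(seq_along(inst$y), seg), sample))
    sdP <- segmentDesign(inst$y[perm], inst$X[perm, ], inst$tau)
    expect_equal(logMarginalLikelihood(sdP, inst$delta, inst$lambdaU,
                                       inst$lambdaC), base)

    # single segment: value independent of delta and lambdaC
    sd1 <- segmentDesign(inst$y, inst$X)
    vals <- sapply(list(c(0, 0), c(1, 0), c(1, 1)), function(d)
        logMarginalLikelihood(sd1, d, inst$lambdaU, inst$lambdaC))
    expect_equal(vals[2], vals[1])
    expect_equal(vals[3], vals[1])
    expect_equal(logMarginalLikelihood(sd1, c(1, 1), inst$lambdaU, 99),
                 vals[1])

    # with delta = 0 the segments do not communicate: reversing the segment
    # order leaves the value unchanged; with coupling it generally does not
    instB <- randomInstance(T = 12, k = 1, H = 2, seed = 32)
    segB <- findInterval(seq_along(instB$y) - 1L, instB$tau) + 1L
    ord <- c(which(segB == 2), which(segB == 1))
    tauR <- sum(segB == 2)
    sdR <- segmentDesign(instB$y[ord], instB$X[ord, ], tauR)
    d0 <- c(0, 0); d1 <- c(1, 1)
    expect_equal(
        logMarginalLikelihood(sdR, d0, instB$lambdaU, instB$lambdaC),
        logMarginalLikelihood(instB$sd, d0, instB$lambdaU, instB$lambdaC))
    expect_false(isTRUE(all.equal(
        logMarginalLikelihood(sdR, d1, instB$lambdaU, instB$lambdaC),
        logMarginalLikelihood(instB$sd, d1, instB$lambdaU, instB$lambdaC))))
})

test_that("log marginal likelihood agrees with direct numerical integration", {
    # H = 2, k = 1, 3 points per segment; quadrature over (beta_1, beta_2,
    # sigma2) is the independent route
    set.seed(41)
    T <- 6L
    X <- cbind(1, rnorm(T))
    y <- 0.5 + 0.8 * X[, 2] + rnorm(T, 0, 0.4)
    tau <- 3L
    for (delta in list(c(0, 0), c(1, 1), c(1, 0))) {
        lu <- 0.8; lc <- 0.3
        got <- logMarginalLikelihood(segmentDesign(y, X, tau), delta, lu, lc)
        oracle <- quadratureLogMarginal(y, X, tau, delta, lu, lc)
        expect_lt(abs(got - oracle), 1e-3)
    }
})

test_that("sampleBeta recovers the prior and the closed-form moments", {
    set.seed(51)
    # zero design, delta = 0: draws come from the N(0, sigma2 lambdaU I) prior
    sd0 <- segmentDesign(rep(0, 8), matrix(0, 8, 2), 4L)
    draws <- replicate(4000, unlist(sampleBeta(sd0, c(0, 0), lambdaU = 0.5,
                                               lambdaC = 9, sigma2 = 2)))
    expect_equal(unname(rowMeans(draws)), rep(0, 4), tolerance = 0.08)
    expect_equal(unname(apply(draws, 1, var)), rep(1, 4), tolerance = 0.12)

    # fixed instance: empirical mean and covariance vs. closed form
    inst <- randomInstance(T = 10, k = 1, H = 2, seed = 52)
    s2 <- 0.7
    draws <- replicate(20000, unlist(sampleBeta(inst$sd, inst$delta,
                                                inst$lambdaU, inst$lambdaC,
                                                s2)))
    cs <- posteriorExpectationChain(inst$sd, inst$delta, inst$lambdaU,
                                    inst$lambdaC)
    expect_equal(unname(rowMeans(draws)), unlist(cs), tolerance = 0.03)
    # covariance of segment-2 block equals sigma2 * C_2
    seg <- findInterval(seq_along(inst$y) - 1L, inst$tau) + 1L
    X2 <- inst$X[seg == 2, , drop = FALSE]
    S2 <- inst$lambdaC * inst$delta + inst$lambdaU * (1 - inst$delta)
    C2 <- solve(diag(1 / S2) + crossprod(X2))
    emp <- cov(t(draws[3:4, ]))
    expect_equal(emp, s2 * C2, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("collapsed sigma2 draw follows Gamma(a + T/2, b + Delta^2/2)", {
    inst <- randomInstance(T = 10, k = 1, H = 2, seed = 61)
    h <- ewcHyperparams()
    d2 <- deltaSquared(inst$sd, inst$delta, inst$lambdaU, inst$lambdaC)
    set.seed(62)
    prec <- replicate(20000, 1 / sampleSigma2(inst$sd, inst$delta,
                                              inst$lambdaU, inst$lambdaC, h))
    shp <- h@aSigma + length(inst$y) / 2
    rt <- h@bSigma + d2 / 2
    expect_equal(mean(prec), shp / rt, tolerance = 0.02)
    expect_equal(var(prec), shp / rt^2, tolerance = 0.06)

    # distributional equality with a brute-force two-stage Gibbs sampler that
    # alternates beta | sigma2 and sigma2 | beta (uncollapsed route)
    set.seed(63)
    nG <- 6000
    s2 <- 1
    P <- ncol(inst$X); T <- length(inst$y)
    H2 <- length(inst$tau) + 1L
    chainDraws <- numeric(nG)
    for (g in seq_len(nG)) {
        beta <- sampleBeta(inst$sd, inst$delta, inst$lambdaU, inst$lambdaC, s2)
        bt <- posteriorExpectationChain(inst$sd, inst$delta, inst$lambdaU,
                                        inst$lambdaC)
        seg <- findInterval(seq_len(T) - 1L, inst$tau) + 1L
        ss <- 0
        for (hh in seq_len(H2)) {
            rows <- which(seg == hh)
            Xh <- inst$X[rows, , drop = FALSE]
            if (hh == 1) { mu <- rep(0, P); sdg <- rep(inst$lambdaU, P) } else {
                mu <- inst$delta * bt[[hh - 1]]
                sdg <- inst$lambdaC * inst$delta +
                    inst$lambdaU * (1 - inst$delta)
            }
            ss <- ss + sum((inst$y[rows] - Xh %*% beta[[hh]])^2) +
                sum((beta[[hh]] - mu)^2 / sdg)
        }
        s2 <- 1 / rgamma(1, h@aSigma + (T + H2 * P) / 2, rate = h@bSigma + ss / 2)
        chainDraws[g] <- s2
    }
    collapsed <- replicate(nG, sampleSigma2(inst$sd, inst$delta, inst$lambdaU,
                                            inst$lambdaC, h))
    ks <- suppressWarnings(ks.test(chainDraws[-(1:500)], collapsed))
    expect_gt(ks$p.value, 0.01)
})

test_that("coupling sums and counts match the loop oracle", {
    # delta = 0: no coupled coefficients, ku + kc = H (k + 1)
    beta <- replicate(3, rnorm(3), simplify = FALSE)
    bt <- replicate(3, rnorm(3), simplify = FALSE)
    cs <- couplingSums(beta, bt, rep(0, 3))
    expect_equal(cs$ku, 9L); expect_equal(cs$kc, 0L)
    cs <- couplingSums(beta, bt, rep(1, 3))
    expect_equal(cs$ku, 3L); expect_equal(cs$kc, 6L)

    for (seed in 71:74) {
        set.seed(seed)
        H <- sample(2:4, 1); P <- sample(2:4, 1)
        beta <- replicate(H, rnorm(P), simplify = FALSE)
        bt <- replicate(H, rnorm(P), simplify = FALSE)
        delta <- rbinom(P, 1, 0.5)
        got <- couplingSums(beta, bt, delta)
        want <- bruteCouplingSums(beta, bt, delta)
        expect_equal(got$Du2, want$Du2)
        expect_equal(got$Dc2, want$Dc2)
        expect_equal(got$ku, want$ku)
        expect_equal(got$kc, want$kc)
        expect_equal(got$ku + got$kc, H * P)
    }

    # lambdaC is refreshed from its prior when nothing is coupled
    set.seed(75)
    h <- ewcHyperparams()
    draws <- replicate(20000, sampleLambdas(beta[1:2], bt[1:2],
                                            rep(0, length(beta[[1]])),
                                            sigma2 = 1, h)$lambdaC)
    # 1/lambdaC ~ GAM(aC, bC): compare the mean of the precision
    expect_equal(mean(1 / draws), h@aC / h@bC, tolerance = 0.05)
})

test_that("coupling-indicator update: degenerate and flat cases", {
    inst <- randomInstance(T = 10, k = 1, H = 1, seed = 81)
    h <- ewcHyperparams()
    # single segment: conditional coupling probability equals the prior p
    expect_equal(deltaConditionalProb(inst$sd, c(0, 0), 1, inst$lambdaU,
                                      inst$lambdaC, h), 0.5)
    expect_equal(deltaConditionalProb(inst$sd, c(1, 0), 2, inst$lambdaU,
                                      inst$lambdaC, h), 0.5)

    # degenerate prior pins the indicators
    h1 <- ewcHyperparams(pCouple = 1)
    h0 <- ewcHyperparams(pCouple = 0)
    inst2 <- randomInstance(T = 10, k = 1, H = 2, seed = 82)
    set.seed(83)
    expect_equal(sampleDelta(inst2$sd, c(0, 0), inst2$lambdaU, inst2$lambdaC,
                             h1), c(1, 1))
    expect_equal(sampleDelta(inst2$sd, c(1, 1), inst2$lambdaU, inst2$lambdaC,
                             h0), c(0, 0))
})

test_that("repeated conditional indicator draws match the exact probability", {
    inst <- randomInstance(T = 10, k = 1, H = 2, seed = 91)
    h <- ewcHyperparams()
    theta <- deltaConditionalProb(inst$sd, c(0, 1), 1, inst$lambdaU,
                                  inst$lambdaC, h)
    set.seed(92)
    n <- 4000
    hits <- 0
    for (r in seq_len(n)) {
        d <- sampleDelta(inst$sd, c(0, 1), inst$lambdaU, inst$lambdaC, h)
        # the sweep updates coordinate 1 first, conditioned on delta_2 = 1
        hits <- hits + (d[1] == 1)
    }
    expect_lt(abs(hits / n - theta), 3 * sqrt(theta * (1 - theta) / n) + 0.01)
})
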