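test_that("changepoint prior normalizes over enumerated layouts", {
    h <- ewcHyperparams()
    # single segment: p(tau | H) = 1, so only the Poisson term remains
    lpH1 <- dpois(1, 1, log = TRUE) - log(1 - dpois(0, 1))
    expect_equal(changepointLogPrior(integer(0), T = 10), lpH1)

    for (case in list(c(6, 2), c(10, 2), c(10, 3))) {
        T <- case[1]; H <- case[2]
        lps <- vapply(enumTauLayouts(T, H), function(tau) {
            lp <- changepointLogPrior(tau, T)
            lp - (dpois(H, 1, log = TRUE) - log(1 - dpois(0, 1)))
        }, 0)
        expect_equal(sum(exp(lps)), 1, tolerance = 1e-12)
    }

    expect_error(changepointLogPrior(c(1L), T = 10), "S = ")
    expect_error(changepointLogPrior(c(5L, 3L), T = 10), "increasing")
})

test_that("proposal ratios are reversible in log space", {
    set.seed(7)
    T <- 20L
    for (r in 1:20) {
        tau <- sort(sample(seq(3L, T - 2L), sample(0:3, 1)))
        while (length(tau) > 1 && any(diff(tau) < 2))
            tau <- sort(sample(seq(3L, T - 2L), sample(0:3, 1)))
        mv <- sample(c("birth", "death", "reallocate"), 1)
        prop <- proposeChangepointMove(tau, T, mv)
        if (prop$noop) next
        # construct the exact reverse move and check ratio negation
        if (mv == "birth") {
            new <- setdiff(prop$tau, tau)
            free <- ewcnet:::.birthPositions(tau, T, 2L)
            expect_equal(prop$logProposalRatio,
                         log(length(free)) - log(length(prop$tau)))
            # reverse death ratio
            freeRev <- ewcnet:::.birthPositions(tau, T, 2L)
            revRatio <- log(length(prop$tau)) - log(length(freeRev))
            expect_equal(revRatio, -prop$logProposalRatio)
        } else if (mv == "death") {
            freeRev <- ewcnet:::.birthPositions(prop$tau, T, 2L)
            revRatio <- log(length(freeRev)) - log(length(tau))
            expect_equal(revRatio, -prop$logProposalRatio)
        } else {
            expect_equal(prop$logProposalRatio, 0)
        }
    }
    # covariate moves
    for (r in 1:20) {
        n <- 6L
        pi <- sample(seq_len(n), sample(0:3, 1))
        mv <- sample(c("add", "delete", "exchange"), 1)
        prop <- proposeCovariateMove(pi, n, mv)
        if (prop$noop) next
        if (mv == "add") {
            rev <- log(length(prop$pi)) - log(n - length(prop$pi) + 1L)
            expect_equal(rev, -prop$logProposalRatio)
        } else if (mv == "delete") {
            rev <- log(n - length(prop$pi)) - log(length(prop$pi) + 1L)
            expect_equal(rev, -prop$logProposalRatio)
        } else {
            expect_equal(prop$logProposalRatio, 0)
        }
    }
})

test_that("inadmissible moves are no-ops", {
    expect_true(proposeChangepointMove(integer(0), 10, "death")$noop)
    expect_true(proposeChangepointMove(integer(0), 10, "reallocate")$noop)
    # saturated layout: no room for another changepoint at minSegLen = 2
    expect_true(proposeChangepointMove(c(3L, 5L, 7L), 9, "birth")$noop)
    expect_true(proposeCovariateMove(1:3, 5, "add", faninMax = 3)$noop)
    expect_true(proposeCovariateMove(integer(0), 5, "delete")$noop)
    expect_true(proposeCovariateMove(integer(0), 5, "exchange")$noop)
})

test_that("mhAccept implements the standard log rule", {
    expect_true(mhAccept(-10, -10))       # identical target: accept
    expect_true(mhAccept(-10, -5))        # uphill: accept
    expect_false(mhAccept(-10, -Inf))     # impossible proposal
    set.seed(1)
    acc <- mean(replicate(20000, mhAccept(-10, -11)))
    expect_equal(acc, exp(-1), tolerance = 0.02)
})

test_that("chains are deterministic given the seed and obey the schedule", {
    set.seed(5)
    X <- matrix(rnorm(48), 16, 3)
    y <- 0.8 * X[, 2] + rnorm(16, 0, 0.3)
    cfg <- chainConfig(nIter = 1200, burnIn = 600, thin = 6, seed = 99)
    a <- runChain(y, X, cfg)
    b <- runChain(y, X, cfg)
    expect_identical(a@pi, b@pi)
    expect_identical(a@tau, b@tau)
    expect_identical(a@delta, b@delta)
    expect_identical(a@lambdaU, b@lambdaU)
    expect_identical(a@logML, b@logML)
    expect_length(a@pi, snapshotCount(cfg))  # (1200 - 600) / 6 = 100

    # default schedule: 500 snapshots
    expect_identical(snapshotCount(chainConfig()), 500L)
})

test_that("fixed changepoints are never moved; M1 refuses them", {
    set.seed(6)
    X <- matrix(rnorm(40), 20, 2)
    y <- rnorm(20)
    cfg <- chainConfig(nIter = 600, burnIn = 300, thin = 3, seed = 4,
                      fixedTau = c(7L, 14L))
    fit <- runChain(y, X, cfg)
    expect_true(all(vapply(fit@tau, identical, TRUE, c(7L, 14L))))
    expect_error(runChain(y, X, chainConfig(fixedTau = 5L),
                          variant = variantSpec("M1")), "M1")

    # M1 never has changepoints
    fitM1 <- runChain(y, X, chainConfig(nIter = 400, burnIn = 200, thin = 2,
                                        seed = 4), variant = variantSpec("M1"))
    expect_true(all(lengths(fitM1@tau) == 0L))
})

test_that("fan-in bound is respected across all snapshots", {
    set.seed(8)
    X <- matrix(rnorm(120), 20, 6)
    y <- X[, 1] - X[, 2] + 0.5 * X[, 3] + 0.5 * X[, 4] + rnorm(20, 0, 0.1)
    fit <- runChain(y, X, chainConfig(nIter = 2000, burnIn = 500, thin = 5,
                                      seed = 10))
    expect_true(all(lengths(fit@pi) <= 3L))
})

test_that("with the coupling prior pinned to zero the chain is the uncoupled model", {
    set.seed(9)
    X <- matrix(rnorm(40), 20, 2)
    y <- 0.7 * X[, 1] + rnorm(20, 0, 0.3)
    cfg <- chainConfig(nIter = 800, burnIn = 400, thin = 4, seed = 12,
                      fixedTau = 10L)
    fit <- runChain(y, X, cfg, hyper = ewcHyperparams(pCouple = 0))
    # indicators all zero, and every snapshot's marginal likelihood equals
    # the uncoupled-prior evaluation bitwise
    expect_true(all(vapply(fit@delta, function(d) all(d == 0), TRUE)))
    for (w in seq(1, 100, by = 9)) {
        piw <- fit@pi[[w]]
        Xw <- cbind(1, X[, piw, drop = FALSE])
        sdw <- segmentDesign(y, Xw, fit@tau[[w]])
        expect_equal(fit@logML[w],
                     logMarginalLikelihood(sdw, rep(0, ncol(Xw)),
                                           fit@lambdaU[w], fit@lambdaC[w]),
                     tolerance = 1e-12)
    }
})

test_that("snapshot log marginal likelihoods cross-check against the R route", {
    set.seed(13)
    X <- matrix(rnorm(60), 20, 3)
    y <- 0.9 * X[, 3] + rnorm(20, 0, 0.3)
    fit <- runChain(y, X, chainConfig(nIter = 1000, burnIn = 500, thin = 10,
                                      seed = 17))
    for (w in seq_along(fit@pi)) {
        piw <- fit@pi[[w]]
        Xw <- cbind(1, X[, piw, drop = FALSE])
        sdw <- segmentDesign(y, Xw, fit@tau[[w]])
        expect_equal(fit@logML[w],
                     logMarginalLikelihood(sdw, fit@delta[[w]],
                                           fit@lambdaU[w], fit@lambdaC[w]),
                     tolerance = 1e-10)
    }
})
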