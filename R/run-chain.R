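#' Run one per-response RJMCMC chain
#'
#' Samples the posterior of one node's lagged regression: covariate set,
#' changepoint set, coupling indicators and variance parameters, by
#' Gibbs-within-reversible-jump MCMC. Each iteration performs a full Gibbs
#' sweep (collapsed noise-variance draw, coefficient draw, variance-parameter
#' draws, indicator sweep) followed by one changepoint move (birth, death or
#' reallocation, type uniform) and one covariate move (addition, deletion or
#' exchange). Runs are deterministic given `config@seed`.
#'
#' @param y numeric response vector (length T): the lagged response values.
#' @param X numeric matrix (T x n) of candidate covariate values at the
#'   preceding time points.
#' @param config a [ChainConfig-class]. With `fixedTau` set, no changepoint
#'   moves are performed; with `fixedPi` set, no covariate moves.
#' @param hyper an [EwcHyper-class].
#' @param variant a [VariantSpec-class]; default the edge-wise coupled model.
#' @param response,candidates optional names recorded in the result.
#'
#' @return A [ChainSample-class] with `snapshotCount(config)` snapshots.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), ncol = 2)
#' y <- 0.8 * X[, 1] + rnorm(20, 0, 0.3)
#' fit <- runChain(y, X, chainConfig(nIter = 2000, burnIn = 1000, thin = 10,
#'                                   seed = 7))
#' mean(vapply(fit@pi, function(p) 1L %in% p, logical(1)))
#' @export
runChain <- function(y, X, config = chainConfig(), hyper = ewcHyperparams(),
                     variant = variantSpec("EWC"), response = "y",
                     candidates = NULL) {
    X <- as.matrix(X)
    T <- length(y)
    if (nrow(X) != T) stop("nrow(X) must equal length(y)")
    if (T < 4) stop("need at least 4 usable transitions")
    if (is.null(candidates))
        candidates <- colnames(X) %||% paste0("X", seq_len(ncol(X)))
    if (variant@name == "M1" && !is.null(config@fixedTau) &&
        length(config@fixedTau))
        stop("the homogeneous model (M1) has no changepoints; ",
             "fixedTau cannot be combined with it")
    tau <- config@fixedTau
    if (!is.null(tau) && length(tau) &&
        (any(tau < 2L) || any(tau > T - 1L)))
        stop("fixedTau positions must lie in {2, ..., T-1}")
    pi0 <- config@fixedPi
    if (!is.null(pi0) && length(pi0) &&
        (any(pi0 < 1L) || any(pi0 > ncol(X))))
        stop("fixedPi indices out of range")
    set.seed(config@seed)
    res <- .cppRunChain(
        y, X, .variantCode(variant@name), variant@trafo,
        config@nIter, config@burnIn, config@thin,
        !is.null(tau), if (is.null(tau)) integer(0) else tau,
        !is.null(pi0), if (is.null(pi0)) integer(0) else pi0,
        config@minSegLen, config@randomSweep,
        hyper@aSigma, hyper@bSigma, hyper@aU, hyper@bU, hyper@aC, hyper@bC,
        hyper@pCouple, hyper@poissonMean, hyper@faninMax)
    methods::new("ChainSample",
                 pi = res$pi, tau = res$tau, delta = res$delta,
                 segDelta = res$segDelta, lambdaU = res$lambdaU,
                 lambdaC = res$lambdaC, logML = res$logML,
                 acceptance = res$acceptance, response = response,
                 candidates = candidates, T = as.integer(T),
                 variant = variant@name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the per-node lagged regression tasks of a dynamic network
#'
#' For response `Z_j` the data point at transition `t` pairs the response
#' value at time `t + 1` with the shifted values of the candidate covariates
#' at time `t`; a dataset with `T + 1` time points yields `T` transitions.
#' By default autoregressive self-loops are excluded, so each node has the
#' other `N - 1` variables as candidates.
#'
#' @param dataset a [NetworkTimeSeries-class].
#' @param allowSelfLoops keep the response among its own candidates.
#' @return list of tasks, each with `response` (name), `y`, `X`,
#'   `candidates` (names) and `candidateIndex` (variable indices).
#' @export
buildRegressionTasks <- function(dataset, allowSelfLoops = FALSE) {
    z <- tsValues(dataset)
    N <- nrow(z); TP <- ncol(z)
    if (TP < 5L) stop("need at least 5 time points (4 transitions)")
    T <- TP - 1L
    lapply(seq_len(N), function(j) {
        idx <- if (allowSelfLoops) seq_len(N) else setdiff(seq_len(N), j)
        list(response = rownames(z)[j],
             y = z[j, 2L:TP],
             X = t(z[idx, 1L:T, drop = FALSE]),
             candidates = rownames(z)[idx],
             candidateIndex = idx)
    })
}

#' Infer a network from a multivariate time series
#'
#' Runs one RJMCMC chain per node (and per independent chain replicate),
#' merges the sampled covariate sets into posterior graph samples and scores
#' every directed edge by the fraction of samples containing it. Chain `c`
#' uses seed `config@seed + c - 1`; scores from independent chains are
#' averaged with equal weights and the coupling-state tallies pooled.
#'
#' @param dataset a [NetworkTimeSeries-class].
#' @param config a [ChainConfig-class].
#' @param hyper an [EwcHyper-class].
#' @param variant a [VariantSpec-class].
#' @param nChains number of independent chains.
#' @param allowSelfLoops include each node among its own candidates.
#'
#' @return A [NetworkFit-class].
#' @export
inferNetwork <- function(dataset, config = chainConfig(),
                         hyper = ewcHyperparams(),
                         variant = variantSpec("EWC"), nChains = 1L,
                         allowSelfLoops = FALSE) {
    tasks <- buildRegressionTasks(dataset, allowSelfLoops)
    vars <- variableNames(dataset)
    chains <- lapply(seq_len(nChains), function(ci) {
        cfg <- config
        cfg@seed <- config@seed + as.integer(ci) - 1L
        lapply(tasks, function(tk)
            runChain(tk$y, tk$X, cfg, hyper, variant,
                     response = tk$response, candidates = tk$candidates))
    })
    scores <- .mergeEdgeScores(chains, tasks, vars)
    methods::new("NetworkFit", chains = chains, scores = scores,
                 variables = vars, variant = variant@name,
                 allowSelfLoops = isTRUE(allowSelfLoops))
}

## internal: merge per-node chain samples into an EdgeScores object
.mergeEdgeScores <- function(chains, tasks, vars) {
    N <- length(vars)
    hits <- matrix(0, N, N, dimnames = list(vars, vars))
    cTally <- uTally <- hits
    Wtot <- 0L
    for (chain in chains) {
        W <- length(chain[[1L]]@pi)
        if (any(vapply(chain, function(s) length(s@pi), 0L) != W))
            stop("snapshot count differs between nodes")
        Wtot <- Wtot + W
        for (j in seq_along(chain)) {
            smp <- chain[[j]]
            cidx <- tasks[[j]]$candidateIndex
            for (w in seq_len(W)) {
                piw <- smp@pi[[w]]
                if (!length(piw)) next
                src <- cidx[piw]
                hits[src, j] <- hits[src, j] + 1
                dw <- smp@delta[[w]]
                if (length(dw) == length(piw) + 1L && !anyNA(dw)) {
                    d <- dw[-1L]
                    cTally[src, j] <- cTally[src, j] + d
                    uTally[src, j] <- uTally[src, j] + (1 - d)
                }
            }
        }
    }
    methods::new("EdgeScores", scores = hits / Wtot, coupledTally = cTally,
                 uncoupledTally = uTally, nSnapshots = as.integer(Wtot))
}

#' Extract the edge-score matrix of a fit
#'
#' @param fit a [NetworkFit-class] or [EdgeScores-class].
#' @return numeric matrix of marginal edge posterior probabilities.
#' @export
edgeScores <- function(fit) {
    if (methods::is(fit, "NetworkFit")) fit@scores@scores else fit@scores
}

#' Extract and label the top-scoring edges
#'
#' Edges are ranked by score and the top `topK` extracted (ties broken by
#' source then target index, deterministically); alternatively all edges with
#' score above `threshold` are taken. Each edge is labelled from the pooled
#' coupling-state tallies of the snapshots containing it by the 2:1
#' posterior-odds rule: "coupled" if the coupled probability is more than
#' twice the uncoupled one, "uncoupled" for the reverse, otherwise "mix".
#'
#' @param fit a [NetworkFit-class] or [EdgeScores-class].
#' @param topK number of edges to extract (default 20).
#' @param threshold optional score threshold used instead of `topK`.
#' @return data.frame with columns from, to, score, pCoupled, label.
#' @export
labelEdges <- function(fit, topK = 20L, threshold = NULL) {
    es <- if (methods::is(fit, "NetworkFit")) fit@scores else fit
    s <- es@scores
    vars <- rownames(s) %||% as.character(seq_len(nrow(s)))
    ij <- which(s > 0, arr.ind = TRUE)
    ord <- order(-s[ij], ij[, 1L], ij[, 2L])
    ij <- ij[ord, , drop = FALSE]
    if (is.null(threshold)) {
        if (nrow(ij) < topK)
            warning("only ", nrow(ij), " edges have nonzero score; ",
                    "returning fewer than ", topK)
        ij <- ij[seq_len(min(topK, nrow(ij))), , drop = FALSE]
    } else {
        ij <- ij[s[ij] > threshold, , drop = FALSE]
    }
    cT <- es@coupledTally[ij]
    uT <- es@uncoupledTally[ij]
    pC <- ifelse(cT + uT > 0, cT / (cT + uT), NA_real_)
    label <- ifelse(is.na(pC), "mix",
             ifelse(pC > 2 * (1 - pC), "coupled",
             ifelse((1 - pC) > 2 * pC, "uncoupled", "mix")))
    data.frame(from = vars[ij[, 1L]], to = vars[ij[, 2L]],
               score = s[ij], pCoupled = pC, label = label,
               stringsAsFactors = FALSE)
}

#' Posterior probability of a changepoint at each admissible position
#'
#' For every position `t` in `S = {2, ..., T-1}` the fraction of snapshots
#' whose changepoint set contains `t`. For a node-level sample pass a
#' [ChainSample-class]; for a fit the per-node vectors are returned as a
#' matrix (nodes in rows).
#'
#' @param x a [ChainSample-class] or [NetworkFit-class].
#' @return named numeric vector (or matrix) of probabilities.
#' @export
changepointPosterior <- function(x) {
    if (methods::is(x, "NetworkFit")) {
        rows <- lapply(seq_along(x@variables), function(j) {
            taus <- unlist(lapply(x@chains, function(ch) ch[[j]]@tau),
                           recursive = FALSE)
            .cpFractions(taus, x@chains[[1L]][[j]]@T)
        })
        out <- do.call(rbind, rows)
        rownames(out) <- x@variables
        return(out)
    }
    .cpFractions(x@tau, x@T)
}

.cpFractions <- function(tauList, T) {
    s <- seq(2L, T - 1L)
    counts <- tabulate(unlist(tauList), nbins = T)
    out <- counts[s] / length(tauList)
    names(out) <- s
    rbind(out)[1L, ]
}
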