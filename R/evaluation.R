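## Evaluation: precision-recall reconstruction accuracy against a known
## network, Gelman-Rubin convergence monitoring, and the paired AUC-difference
## simulation driver.

#' Precision-recall curve and AUC of an edge-score matrix
#'
#' Sweeps the threshold over the distinct score values (largest first); at
#' each threshold the edges scoring at least that value are extracted and the
#' precision `T/n` and recall `T/M` computed against the `M` true edges.
#' The area under the curve is the trapezoid over the achieved recall range,
#' anchored at recall 0 with the first threshold's precision; thresholds
#' extracting no edges are skipped. Self-pairs are excluded unless
#' `includeDiagonal`.
#'
#' @param scores numeric N x N score matrix (entry (i, j) scores edge i -> j),
#'   or an [EdgeScores-class] / [NetworkFit-class].
#' @param truth a network structure (see [networkStructure()]) or an N x N 0/1
#'   adjacency matrix in the same orientation.
#' @param includeDiagonal score self-loops as candidate edges.
#' @return list with `curve` (data.frame threshold, n, tp, precision, recall)
#'   and `auc`.
#' @examples
#' truth <- matrix(0, 3, 3); truth[1, 2] <- truth[2, 3] <- 1
#' precisionRecallAuc(truth, truth)$auc  # 1: perfect ranking
#' @export
precisionRecallAuc <- function(scores, truth, includeDiagonal = FALSE) {
    if (methods::is(scores, "NetworkFit") || methods::is(scores, "EdgeScores"))
        scores <- edgeScores(scores)
    adj <- .asAdjacency(truth, rownames(scores))
    if (!all(dim(adj) == dim(scores)))
        stop("truth and score dimensions disagree")
    keep <- if (includeDiagonal) rep(TRUE, length(scores)) else
        as.vector(row(scores) != col(scores))
    s <- as.vector(scores)[keep]
    a <- as.vector(adj)[keep]
    M <- sum(a)
    if (M < 1) stop("the true network must have at least one edge")
    th <- sort(unique(s), decreasing = TRUE)
    rows <- lapply(th, function(v) {
        sel <- s >= v
        n <- sum(sel)
        if (n == 0) return(NULL)
        tp <- sum(a[sel])
        data.frame(threshold = v, n = n, tp = tp,
                   precision = tp / n, recall = tp / M)
    })
    curve <- do.call(rbind, rows)
    rec <- c(0, curve$recall)
    prec <- c(curve$precision[1L], curve$precision)
    auc <- sum(diff(rec) * (head(prec, -1L) + prec[-1L]) / 2)
    list(curve = curve, auc = auc)
}

## internal: structure or matrix -> adjacency matrix over `vars`
.asAdjacency <- function(truth, vars = NULL) {
    if (is.matrix(truth)) return(truth)
    if (is.list(truth) && !is.null(truth$parents)) {
        nodes <- truth$nodes
        adj <- matrix(0, length(nodes), length(nodes),
                      dimnames = list(nodes, nodes))
        for (v in nodes) adj[truth$parents[[v]], v] <- 1
        if (!is.null(vars)) adj <- adj[vars, vars]
        return(adj)
    }
    stop("truth must be an adjacency matrix or a network structure")
}

#' Potential scale reduction factors of edge-score trajectories
#'
#' Classic between-/within-chain variance ratio computed per edge from the
#' running (cumulative) edge-indicator means of each chain:
#' `PSRF = sqrt((W + B) / W)` with `W` the mean within-chain variance and `B`
#' the variance of the chain means. Identical chains give exactly 1; chains
#' stuck on disjoint parts of the graph space give values far above 1.
#' Edges whose trajectories are constant and identical across chains carry no
#' information and are reported as 1.
#'
#' @param trajectories a list of numeric matrices (one per chain, snapshots in
#'   rows, edges in columns) of running edge-score estimates; see
#'   [scoreTrajectories()].
#' @param threshold convergence threshold on the PSRF (default 1.01).
#' @return list with `psrf` (per-edge values) and `fractionBelow`.
#' @export
psrf <- function(trajectories, threshold = 1.01) {
    m <- length(trajectories)
    if (m < 2L) stop("need at least two chains")
    n <- nrow(trajectories[[1L]])
    if (any(vapply(trajectories, nrow, 0L) != n))
        stop("chains must have equal length")
    E <- ncol(trajectories[[1L]])
    within <- colMeans(do.call(rbind, lapply(trajectories, function(x)
        apply(x, 2L, stats::var))))
    means <- do.call(rbind, lapply(trajectories, colMeans))
    between <- apply(means, 2L, stats::var)
    r <- sqrt((within + between) / within)
    r[within == 0 & between == 0] <- 1
    r[within == 0 & between > 0] <- Inf
    names(r) <- colnames(trajectories[[1L]])
    list(psrf = r, fractionBelow = mean(r < threshold))
}

#' Running edge-score trajectories of a fit
#'
#' For each chain of a [NetworkFit-class], the cumulative estimate of every
#' directed edge score after `w = 1..W` snapshots — the input monitored by
#' [psrf()].
#'
#' @param fit a [NetworkFit-class] with at least one chain.
#' @return list of W x (N*(N-1)) matrices, one per chain (self-pairs dropped
#'   when the fit excluded self-loops).
#' @export
scoreTrajectories <- function(fit) {
    vars <- fit@variables
    N <- length(vars)
    tasks <- seq_len(N)
    lapply(fit@chains, function(chain) {
        W <- length(chain[[1L]]@pi)
        ind <- matrix(0, W, N * N)
        for (j in tasks) {
            smp <- chain[[j]]
            cidx <- match(smp@candidates, vars)
            for (w in seq_len(W)) {
                src <- cidx[smp@pi[[w]]]
                ind[w, (j - 1L) * N + src] <- 1
            }
        }
        colnames(ind) <- as.vector(outer(vars, vars, paste, sep = "->"))
        # column e of block j is edge vars[e] -> vars[j]
        keep <- if (fit@allowSelfLoops) rep(TRUE, N * N) else
            as.vector(outer(seq_len(N), seq_len(N), "!="))
        traj <- apply(ind[, keep, drop = FALSE], 2L, cumsum) /
            seq_len(W)
        traj
    })
}

#' Mean inferred coupled fraction of a fit
#'
#' The average of the sampled coupling indicators over all covariates present
#' in the posterior snapshots — the model's estimate of the fraction of
#' coupled edges.
#'
#' @param fit a [NetworkFit-class].
#' @return scalar in [0, 1] (NA if no covariate was ever sampled).
#' @export
inferredCoupledFraction <- function(fit) {
    es <- fit@scores
    tot <- es@coupledTally + es@uncoupledTally
    if (sum(tot) == 0) return(NA_real_)
    sum(es@coupledTally) / sum(tot)
}

#' Paired AUC-difference experiment on synthetic RAF data
#'
#' For each (K, replicate) cell: generate one synthetic RAF dataset, run every
#' requested variant with the changepoints fixed at the truth, compute each
#' fit's precision-recall AUC against the true 20-edge network, and summarize
#' the paired AUC differences of the first variant (the reference, typically
#' the edge-wise coupled model) against every other, with 0.95 paired-t
#' confidence intervals.
#'
#' @param scenario benchmark scenario.
#' @param K integer vector of coupled-coefficient counts.
#' @param replicates datasets per K.
#' @param variants list of [VariantSpec-class]; the first is the reference.
#' @param config a [ChainConfig-class] (its `fixedTau` is overridden by the
#'   true changepoints; its seed seeds the whole experiment).
#' @param hyper an [EwcHyper-class].
#' @param m,snr generation parameters.
#' @return list with `results` (one row per dataset and variant: scenario, K,
#'   replicate, variant, auc, coupledFraction) and `differences` (per
#'   competitor: mean paired difference, 0.95 CI, n).
#' @export
aucDifferenceExperiment <- function(scenario = "T1T3",
                                    K = c(seq(0L, 27L, 3L), 31L),
                                    replicates = 5L,
                                    variants = list(variantSpec("EWC"),
                                                    variantSpec("M1")),
                                    config = chainConfig(nIter = 5000L,
                                                         burnIn = 2500L,
                                                         thin = 10L),
                                    hyper = ewcHyperparams(), m = 5L,
                                    snr = 3) {
    vnames <- vapply(variants, function(v) v@name, "")
    plan <- studyGridPlan(replicates, scenarios = scenario, K = K,
                          masterSeed = config@seed)
    rows <- list()
    for (i in seq_len(nrow(plan))) {
        ds <- simulateRafData(K = plan$K[i], scenario = plan$scenario[i],
                              m = m, snr = snr, seed = plan$seed[i])
        for (v in seq_along(variants)) {
            cfg <- config
            # seed by variant identity, so identical specs rerun identically
            cfg@seed <- plan$seed[i] + 100000L *
                (.variantCode(vnames[v]) + 10L * variants[[v]]@trafo)
            cfg@fixedTau <- if (vnames[v] == "M1") NULL else ds$tau
            fit <- inferNetwork(ds$data, cfg, hyper, variants[[v]])
            auc <- precisionRecallAuc(fit, ds$truth)$auc
            rows[[length(rows) + 1L]] <- data.frame(
                scenario = plan$scenario[i], K = plan$K[i],
                replicate = plan$replicate[i], variant = vnames[v],
                slot = v, auc = auc,
                coupledFraction = inferredCoupledFraction(fit),
                stringsAsFactors = FALSE)
        }
    }
    results <- do.call(rbind, rows)
    ref <- results[results$slot == 1L, ]
    diffs <- lapply(seq_along(variants)[-1L], function(v) {
        cmp <- results[results$slot == v, ]
        d <- ref$auc - cmp$auc
        ci <- if (length(d) > 1L && stats::sd(d) > 0)
            stats::t.test(d, conf.level = 0.95)$conf.int else c(NA_real_, NA_real_)
        data.frame(competitor = vnames[v], meanDiff = mean(d), lo = ci[1L],
                   hi = ci[2L], n = length(d), stringsAsFactors = FALSE)
    })
    list(results = results, differences = do.call(rbind, diffs))
}
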