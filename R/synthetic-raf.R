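## Synthetic benchmark data: piece-wise linear autoregressive dynamics on the
## RAF protein signalling network (11 nodes, 20 directed edges; consensus
## topology of Sachs et al. 2005, bundled as inst/extdata/raf_edges.tsv).
## Trajectories have H = 4 coefficient segments of m transitions each; each
## regression coefficient is one of four temporal types, and observational
## noise is added at a fixed signal-to-noise ratio.

#' A directed network structure
#'
#' @param edges two-column data.frame or matrix of directed edges
#'   (from, to), or NULL for the bundled RAF pathway.
#' @param nodes character vector of node names; defaults to the nodes
#'   appearing in `edges`.
#' @return list with `nodes` (character) and `parents` (named list of parent
#'   node sets, one per node).
#' @examples
#' raf <- rafNetwork()
#' length(raf$nodes)                            # 11
#' sum(lengths(raf$parents))                    # 20 edges
#' sum(lengths(raf$parents) + 1L)               # 31 regression coefficients
#' @export
networkStructure <- function(edges, nodes = NULL) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(ncol(edges) >= 2L)
    names(edges)[1:2] <- c("from", "to")
    if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
    parents <- lapply(setNames(nodes, nodes),
                      function(v) edges$from[edges$to == v])
    list(nodes = nodes, parents = parents)
}

#' @describeIn networkStructure the bundled RAF pathway (11 nodes, 20 edges).
#' @export
rafNetwork <- function() {
    path <- system.file("extdata", "raf_edges.tsv", package = "ewcnet",
                        mustWork = TRUE)
    edges <- utils::read.delim(path, stringsAsFactors = FALSE)
    nodes <- c("PKC", "PKA", "Raf", "Mek", "Erk", "Akt", "P38", "Jnk",
               "Plcg", "PIP2", "PIP3")
    networkStructure(edges, nodes = nodes)
}

#' Total regression coefficient positions of a structure
#'
#' One intercept plus one coefficient per parent, summed over nodes.
#' @param structure a network structure (see [networkStructure()]).
#' @return integer count.
#' @export
coefficientCount <- function(structure) {
    sum(lengths(structure$parents) + 1L)
}

#' Draw segment-specific regression coefficients with temporal types
#'
#' For every node and each of the `nSegments` segments, a coefficient vector
#' (intercept plus one entry per parent) is drawn elementwise from N(0, 1)
#' and normalized to unit Euclidean norm. `K` coefficient positions chosen
#' uniformly at random (intercepts included) are then made type T1
#' ("coupled": the segment-1 value is copied to all segments); every other
#' position gets the scenario's second type:
#' \describe{
#'   \item{T2 "similar"}{all segments forced to the sign of segment 1.}
#'   \item{T3 "independent"}{left unchanged.}
#'   \item{T4 "dissimilar"}{the sign alternates from segment to segment.}
#' }
#'
#' @param structure network structure.
#' @param K number of coupled (T1) positions, `0 <= K <=`
#'   [coefficientCount()].
#' @param scenario one of "T1T2", "T1T3", "T1T4".
#' @param nSegments number of segments (4 for the benchmark protocol).
#' @return list with `beta` (per node: segments x (|parents|+1) matrix) and
#'   `type` (per node: character vector of position types).
#' @export
drawCoefficients <- function(structure, K,
                             scenario = c("T1T3", "T1T2", "T1T4"),
                             nSegments = 4L) {
    scenario <- match.arg(scenario)
    nodes <- structure$nodes
    sizes <- lengths(structure$parents)[nodes] + 1L
    total <- sum(sizes)
    if (K < 0 || K > total)
        stop("K must lie between 0 and ", total)
    beta <- lapply(sizes, function(p) {
        b <- matrix(rnorm(nSegments * p), nrow = nSegments)
        b / sqrt(rowSums(b^2))  # unit norm per segment
    })
    coupledPos <- sample.int(total, K)
    other <- c(T1T2 = "T2", T1T3 = "T3", T1T4 = "T4")[[scenario]]
    offset <- c(0L, cumsum(sizes))
    type <- vector("list", length(nodes)); names(type) <- nodes
    for (i in seq_along(nodes)) {
        p <- sizes[[i]]
        tp <- rep(other, p)
        tp[(offset[i] + seq_len(p)) %in% coupledPos] <- "T1"
        b <- beta[[i]]
        for (j in seq_len(p)) {
            if (tp[j] == "T1") {
                b[, j] <- b[1L, j]
            } else if (tp[j] == "T2") {
                b[, j] <- sign(b[1L, j]) * abs(b[, j])
            } else if (tp[j] == "T4") {
                for (h in seq_len(nSegments)[-1L])
                    b[h, j] <- sign(-b[h - 1L, j]) * abs(b[h, j])
            }
        }
        beta[[i]] <- b
        type[[i]] <- tp
    }
    list(beta = beta, type = type, scenario = scenario, K = as.integer(K))
}

#' Segment index of a transition
#'
#' `F(t) = 1 + floor((t - 1) / m)`: the coefficient segment governing the
#' transition from time point `t` to `t + 1` when segments hold `m`
#' transitions each.
#'
#' @param t transition index (1-based).
#' @param m transitions per segment.
#' @return integer segment index.
#' @export
segmentIndex <- function(t, m) 1L + (as.integer(t) - 1L) %/% as.integer(m)

#' Simulate piece-wise linear autoregressive trajectories
#'
#' `z_{i,t+1} = beta_{i,F(t),0} + sum_j beta_{i,F(t),j} z_{j,t} + e_{i,t}`
#' for `t = 1..nSegments*m`, with initial values and process noise drawn
#' i.i.d. N(0, processSd^2).
#'
#' @param structure network structure.
#' @param coefficients result of [drawCoefficients()].
#' @param m transitions per segment.
#' @param processSd standard deviation of initial values and process noise.
#' @return a [NetworkTimeSeries-class] with `nSegments * m + 1` time points.
#' @export
simulateTimeSeries <- function(structure, coefficients, m = 5L,
                               processSd = 0.05) {
    nodes <- structure$nodes
    N <- length(nodes)
    nSeg <- nrow(coefficients$beta[[1L]])
    Ttot <- nSeg * m
    z <- matrix(0, N, Ttot + 1L, dimnames = list(nodes, NULL))
    z[, 1L] <- rnorm(N, 0, processSd)
    parentIdx <- lapply(structure$parents[nodes], function(p) match(p, nodes))
    for (t in seq_len(Ttot)) {
        h <- segmentIndex(t, m)
        for (i in seq_len(N)) {
            b <- coefficients$beta[[i]][h, ]
            pa <- parentIdx[[i]]
            z[i, t + 1L] <- b[1L] +
                (if (length(pa)) sum(b[-1L] * z[pa, t]) else 0) +
                rnorm(1, 0, processSd)
        }
    }
    networkTimeSeries(z)
}

#' Add observational noise at a fixed signal-to-noise ratio
#'
#' For each variable the standard deviation `s_i` of its trajectory is
#' computed (unbiased, n-1 denominator) and independent `N(0, (s_i/snr)^2)`
#' noise is added to every value. Constant (zero-variance) variables are
#' passed through unchanged with a warning.
#'
#' @param dataset a [NetworkTimeSeries-class].
#' @param snr signal-to-noise ratio (> 0); the benchmark protocol uses 3.
#' @return a noisy [NetworkTimeSeries-class].
#' @export
addObservationNoise <- function(dataset, snr = 3) {
    if (snr <= 0) stop("snr must be positive")
    z <- tsValues(dataset)
    s <- apply(z, 1L, sd)
    if (any(s == 0))
        warning("zero-variance variables left noise-free: ",
                paste(rownames(z)[s == 0], collapse = ", "))
    noise <- matrix(rnorm(length(z), 0, rep(s / snr, ncol(z))),
                    nrow(z), ncol(z))
    networkTimeSeries(z + noise)
}

#' Generate one synthetic RAF benchmark dataset
#'
#' Runs the full protocol: draw typed coefficients, simulate the trajectories,
#' add observational noise. The true changepoints on the transition axis are
#' `m, 2m, ..., (nSegments-1) m`.
#'
#' @inheritParams drawCoefficients
#' @param m transitions per segment (benchmark default 5).
#' @param snr signal-to-noise ratio (benchmark default 3).
#' @param processSd process / initial-value standard deviation.
#' @param seed optional integer seed.
#' @param structure network structure (default: bundled RAF pathway).
#' @return list with `data` ([NetworkTimeSeries-class]), `truth` (the
#'   structure), `coefficients`, `tau` (true changepoints), `seed`.
#' @export
simulateRafData <- function(K, scenario = c("T1T3", "T1T2", "T1T4"),
                            m = 5L, snr = 3, processSd = 0.05, seed = NULL,
                            structure = rafNetwork(), nSegments = 4L) {
    scenario <- match.arg(scenario)
    if (!is.null(seed)) set.seed(seed)
    coef <- drawCoefficients(structure, K, scenario, nSegments)
    clean <- simulateTimeSeries(structure, coef, m, processSd)
    noisy <- addObservationNoise(clean, snr)
    list(data = noisy, clean = clean, truth = structure, coefficients = coef,
         tau = as.integer(m) * seq_len(nSegments - 1L),
         m = as.integer(m), snr = snr, scenario = scenario,
         K = as.integer(K), seed = seed)
}

#' Enumerate the benchmark study grid
#'
#' The full protocol crosses 3 scenarios with 11 coupled-coefficient counts
#' `K in {0, 3, ..., 27, 31}` and `replicates` datasets per cell
#' (3 x 11 x 100 = 3300 at full scale). `studyGridPlan()` returns the plan
#' with one reproducible seed per dataset; [generateStudyGrid()] generates
#' the datasets.
#'
#' @param replicates datasets per (scenario, K) cell.
#' @param scenarios scenario subset.
#' @param K coupled-coefficient counts.
#' @param masterSeed seed from which per-dataset seeds are derived.
#' @return data.frame with columns scenario, K, replicate, seed.
#' @export
studyGridPlan <- function(replicates = 100L,
                          scenarios = c("T1T2", "T1T3", "T1T4"),
                          K = c(seq(0L, 27L, by = 3L), 31L),
                          masterSeed = 1L) {
    plan <- expand.grid(replicate = seq_len(replicates), K = as.integer(K),
                        scenario = scenarios, stringsAsFactors = FALSE)
    plan <- plan[, c("scenario", "K", "replicate")]
    plan$seed <- as.integer(masterSeed) + seq_len(nrow(plan)) - 1L
    plan
}

#' @describeIn studyGridPlan generate the datasets of a plan.
#' @param plan a plan from [studyGridPlan()].
#' @param m,snr,processSd protocol parameters.
#' @return list of datasets as returned by [simulateRafData()].
#' @export
generateStudyGrid <- function(plan, m = 5L, snr = 3, processSd = 0.05) {
    lapply(seq_len(nrow(plan)), function(i)
        simulateRafData(K = plan$K[i], scenario = plan$scenario[i], m = m,
                        snr = snr, processSd = processSd, seed = plan$seed[i]))
}
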