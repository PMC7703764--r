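#' @import methods
#' @importFrom stats rnorm rgamma runif sd dpois setNames
#' @importFrom utils combn head
#' @useDynLib ewcnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' NetworkTimeSeries: a multivariate time series over network nodes
#'
#' Container for an \eqn{N \times (T+1)} numeric matrix whose rows are network
#' variables (e.g. genes or proteins) and whose columns are equidistant time
#' points. This is the input object for dynamic network inference: every
#' transition from time point \eqn{t} to \eqn{t+1} contributes one data point
#' to each node's lagged regression.
#'
#' @slot values numeric matrix, variables in rows, time points in columns.
#'
#' @seealso [networkTimeSeries()], [readTimeSeries()], [buildRegressionTasks()]
#' @export
setClass("NetworkTimeSeries", representation(values = "matrix"))

setValidity("NetworkTimeSeries", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (any(!is.finite(v))) return("values must be finite")
    if (nrow(v) < 2L) return("need at least 2 network variables (rows)")
    if (ncol(v) < 2L) return("need at least 2 time points (columns)")
    if (is.null(rownames(v))) return("variables must be named (rownames)")
    if (anyDuplicated(rownames(v))) return("variable names must be unique")
    TRUE
})

#' Hyperparameters of the edge-wise coupled NH-DBN
#'
#' Fixed hyperparameters of the hierarchical model: inverse-Gamma shape/rate
#' pairs for the noise variance \eqn{\sigma^2}, the signal-to-noise parameter
#' \eqn{\lambda_u} (uncoupled coefficients) and the coupling strength
#' \eqn{\lambda_c} (coupled coefficients); the Bernoulli prior probability on
#' each coupling indicator \eqn{\delta_i}; the (truncated) Poisson mean of the
#' prior on the number of segments; and the fan-in bound on covariate sets.
#'
#' @seealso [ewcHyperparams()]
#' @export
setClass("EwcHyper", representation(
    aSigma = "numeric", bSigma = "numeric",
    aU = "numeric", bU = "numeric",
    aC = "numeric", bC = "numeric",
    pCouple = "numeric", poissonMean = "numeric",
    faninMax = "integer"))

setValidity("EwcHyper", function(object) {
    pos <- c(aSigma = object@aSigma, bSigma = object@bSigma, aU = object@aU,
             bU = object@bU, aC = object@aC, bC = object@bC,
             poissonMean = object@poissonMean)
    if (any(!is.finite(pos)) || any(pos <= 0))
        return("all shape/rate parameters and the Poisson mean must be strictly positive")
    if (!is.finite(object@pCouple) || object@pCouple < 0 || object@pCouple > 1)
        return("pCouple must lie in [0, 1]")
    if (object@faninMax < 1L) return("faninMax must be a positive integer")
    TRUE
})

#' MCMC chain configuration
#'
#' Settings of one per-node RJMCMC run: iteration counts, thinning, the seed,
#' and optional constraints (known changepoints, a frozen covariate set, the
#' minimum segment length enforced by the changepoint moves).
#'
#' @slot nIter total iterations.
#' @slot burnIn iterations discarded before sampling.
#' @slot thin sampling stride; one snapshot per `thin` post-burn-in iterations.
#' @slot seed integer RNG seed.
#' @slot fixedTau integer changepoint positions, or NULL to infer them.
#' @slot fixedPi integer candidate-covariate indices, or NULL to infer the set.
#' @slot minSegLen minimum number of time points per segment.
#' @slot randomSweep logical; randomly permute the delta sweep order.
#'
#' @seealso [chainConfig()], [runChain()]
#' @export
setClass("ChainConfig", representation(
    nIter = "integer", burnIn = "integer", thin = "integer", seed = "integer",
    fixedTau = "integerOrNULL", fixedPi = "integerOrNULL",
    minSegLen = "integer", randomSweep = "logical"))

setValidity("ChainConfig", function(object) {
    if (object@nIter < 1L) return("nIter must be positive")
    if (object@burnIn < 0L || object@burnIn >= object@nIter)
        return("burnIn must satisfy 0 <= burnIn < nIter")
    if (object@thin < 1L) return("thin must be >= 1")
    if (object@minSegLen < 1L) return("minSegLen must be >= 1")
    if (!is.null(object@fixedTau)) {
        tau <- object@fixedTau
        if (length(tau) && (is.unsorted(tau, strictly = TRUE)))
            return("fixedTau must be strictly increasing")
    }
    TRUE
})

#' Model variant specification
#'
#' Selects one member of the NH-DBN family sharing the same machinery:
#' \describe{
#'   \item{EWC}{edge-wise coupled model: one binary indicator per design
#'     column decides coupled vs. uncoupled.}
#'   \item{M1}{homogeneous DBN: a single segment, no changepoints.}
#'   \item{M2}{fully uncoupled NH-DBN: all indicators pinned to 0.}
#'   \item{M3}{fully coupled NH-DBN: all indicators pinned to 1.}
#'   \item{M5}{switch model: one global indicator, all-0 or all-1.}
#'   \item{M6}{segment-wise coupled model: one indicator per segment h > 1.}
#' }
#' `trafo = TRUE` augments each design matrix with quadratic and pairwise
#' interaction terms of the selected covariates.
#'
#' @seealso [variantSpec()]
#' @export
setClass("VariantSpec", representation(name = "character", trafo = "logical"))

setValidity("VariantSpec", function(object) {
    if (!object@name %in% c("EWC", "M1", "M2", "M3", "M5", "M6"))
        return("variant name must be one of EWC, M1, M2, M3, M5, M6")
    TRUE
})

#' Posterior sample of one per-node chain
#'
#' Thinned snapshots `(pi, tau, delta, lambdaU, lambdaC)` of one RJMCMC run for
#' a single response variable, together with the per-snapshot log marginal
#' likelihood and move acceptance rates.
#'
#' @slot pi list of integer vectors: sampled covariate sets (candidate indices).
#' @slot tau list of integer vectors: sampled changepoint sets.
#' @slot delta list of numeric vectors: coupling indicators, intercept first,
#'   then one entry per covariate in `pi` (same order).
#' @slot segDelta list of numeric vectors: per-segment indicators (M6 only;
#'   empty vectors otherwise).
#' @slot lambdaU,lambdaC numeric: sampled variance parameters per snapshot.
#' @slot logML numeric: log marginal likelihood of each snapshot's state.
#' @slot acceptance named numeric: acceptance rates per move type.
#' @slot response character: response variable name.
#' @slot candidates character: candidate covariate names (index space of `pi`).
#' @slot T integer: number of modelled transitions.
#' @slot variant character: variant name.
#'
#' @export
setClass("ChainSample", representation(
    pi = "list", tau = "list", delta = "list", segDelta = "list",
    lambdaU = "numeric", lambdaC = "numeric", logML = "numeric",
    acceptance = "numeric", response = "character", candidates = "character",
    T = "integer", variant = "character"))

setValidity("ChainSample", function(object) {
    W <- length(object@pi)
    if (length(object@tau) != W || length(object@delta) != W ||
        length(object@lambdaU) != W || length(object@lambdaC) != W ||
        length(object@logML) != W)
        return("snapshot slots must have equal length")
    TRUE
})

#' Marginal edge posterior scores with coupling-state tallies
#'
#' An \eqn{N \times N} matrix of marginal edge posterior probabilities
#' (fraction of posterior graph samples containing each directed edge), plus,
#' per edge, tallies of how often the coupling indicator of the corresponding
#' covariate was 1 (coupled) vs. 0 (uncoupled) among the snapshots containing
#' the edge.
#'
#' @slot scores numeric matrix; entry (i, j) scores the edge i -> j.
#' @slot coupledTally,uncoupledTally numeric matrices of indicator counts.
#' @slot nSnapshots integer: snapshots per node (pooled over chains).
#'
#' @seealso [edgeScores()], [labelEdges()]
#' @export
setClass("EdgeScores", representation(
    scores = "matrix", coupledTally = "matrix", uncoupledTally = "matrix",
    nSnapshots = "integer"))

setValidity("EdgeScores", function(object) {
    s <- object@scores
    if (nrow(s) != ncol(s)) return("score matrix must be square")
    if (any(s < 0) || any(s > 1)) return("scores must lie in [0, 1]")
    if (!identical(dim(s), dim(object@coupledTally)) ||
        !identical(dim(s), dim(object@uncoupledTally)))
        return("tally matrices must match the score matrix dimension")
    TRUE
})

#' Fitted network posterior
#'
#' The result of [inferNetwork()]: per-node, per-chain posterior samples, the
#' merged edge scores, and the settings used.
#'
#' @slot chains list (one element per chain) of lists of [ChainSample-class]
#'   objects, one per response variable.
#' @slot scores [EdgeScores-class] merged over nodes and chains.
#' @slot variables character: node names.
#' @slot variant character: variant name.
#' @slot allowSelfLoops logical.
#'
#' @export
setClass("NetworkFit", representation(
    chains = "list", scores = "EdgeScores", variables = "character",
    variant = "character", allowSelfLoops = "logical"))

## ---- show methods -----------------------------------------------------------

setMethod("show", "NetworkTimeSeries", function(object) {
    v <- object@values
    cat(sprintf("NetworkTimeSeries: %d variables x %d time points\n",
                nrow(v), ncol(v)))
    cat("variables:", paste(head(rownames(v), 8L), collapse = ", "),
        if (nrow(v) > 8L) "..." else "", "\n")
})

setMethod("show", "EwcHyper", function(object) {
    cat("EwcHyper:",
        sprintf("sigma^-2 ~ GAM(%g, %g);", object@aSigma, object@bSigma),
        sprintf("lambda_u^-1 ~ GAM(%g, %g);", object@aU, object@bU),
        sprintf("lambda_c^-1 ~ GAM(%g, %g);", object@aC, object@bC), "\n",
        sprintf(" delta_i ~ BER(%g); H ~ Poi(%g) truncated to H >= 1; fan-in <= %d\n",
                object@pCouple, object@poissonMean, object@faninMax))
})

setMethod("show", "ChainConfig", function(object) {
    cat(sprintf("ChainConfig: %d iterations, %d burn-in, thin %d (W = %d), seed %d\n",
                object@nIter, object@burnIn, object@thin,
                snapshotCount(object), object@seed))
    if (!is.null(object@fixedTau))
        cat(" fixed changepoints:", paste(object@fixedTau, collapse = ", "), "\n")
    if (!is.null(object@fixedPi))
        cat(" fixed covariate set:", paste(object@fixedPi, collapse = ", "), "\n")
})

setMethod("show", "VariantSpec", function(object) {
    cat(sprintf("VariantSpec: %s%s\n", object@name,
                if (object@trafo) " + quadratic/interaction design terms" else ""))
})

setMethod("show", "ChainSample", function(object) {
    cat(sprintf("ChainSample (%s) for response '%s': %d snapshots, T = %d\n",
                object@variant, object@response, length(object@pi), object@T))
    cat(" acceptance:", paste(sprintf("%s %.2f", names(object@acceptance),
                                      object@acceptance), collapse = ", "), "\n")
})

setMethod("show", "EdgeScores", function(object) {
    cat(sprintf("EdgeScores: %d x %d, %d snapshots per node\n",
                nrow(object@scores), ncol(object@scores), object@nSnapshots))
})

setMethod("show", "NetworkFit", function(object) {
    cat(sprintf("NetworkFit (%s): %d variables, %d chain(s)\n",
                object@variant, length(object@variables), length(object@chains)))
})
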