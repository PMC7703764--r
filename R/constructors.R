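#' Construct a NetworkTimeSeries
#'
#' @param x numeric matrix or data.frame (variables in rows, time points in
#'   columns), or a `SummarizedExperiment` whose first assay holds the series.
#' @param variableNames optional character vector of row names; required when
#'   `x` carries none.
#'
#' @return A [NetworkTimeSeries-class] object.
#' @examples
#' m <- matrix(rnorm(20), nrow = 4,
#'             dimnames = list(paste0("G", 1:4), NULL))
#' networkTimeSeries(m)
#' @export
networkTimeSeries <- function(x, variableNames = NULL) {
    if (methods::is(x, "SummarizedExperiment")) {
        if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
            stop("the SummarizedExperiment package is required for this input type")
        x <- SummarizedExperiment::assay(x)
    }
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.null(variableNames)) rownames(x) <- variableNames
    if (is.null(rownames(x))) rownames(x) <- paste0("V", seq_len(nrow(x)))
    storage.mode(x) <- "double"
    methods::new("NetworkTimeSeries", values = x)
}

#' @describeIn networkTimeSeries the underlying values matrix.
#' @param object a `NetworkTimeSeries`.
#' @export
tsValues <- function(object) object@values

#' @describeIn networkTimeSeries variable (node) names.
#' @export
variableNames <- function(object) rownames(object@values)

#' @describeIn networkTimeSeries number of variables / time points.
#' @export
nVariables <- function(object) nrow(object@values)

#' @describeIn networkTimeSeries number of time points (columns).
#' @export
nTimePoints <- function(object) ncol(object@values)

#' Hyperparameters of the model
#'
#' Defaults follow the standard weakly-informative choices for this model
#' family: near-flat inverse-Gamma priors on the noise variance
#' (`aSigma = bSigma = 0.005`), moderately informative priors on the variance
#' parameters (`aU = aC = 2`, `bU = bC = 0.2`, prior mean 0.2), an even-odds
#' Bernoulli prior on each coupling indicator, a Poisson(1) prior (truncated
#' to H >= 1) on the number of segments, and a fan-in bound of 3 parents.
#'
#' @param aSigma,bSigma inverse-Gamma shape/rate for the noise variance.
#' @param aU,bU shape/rate for the uncoupled signal-to-noise parameter.
#' @param aC,bC shape/rate for the coupling strength parameter.
#' @param pCouple Bernoulli prior probability that an indicator equals 1.
#' @param poissonMean mean of the truncated Poisson prior on segment count.
#' @param faninMax maximum covariate-set size.
#'
#' @return An [EwcHyper-class] object.
#' @examples
#' ewcHyperparams()
#' @export
ewcHyperparams <- function(aSigma = 0.005, bSigma = 0.005,
                           aU = 2, bU = 0.2, aC = 2, bC = 0.2,
                           pCouple = 0.5, poissonMean = 1, faninMax = 3L) {
    methods::new("EwcHyper", aSigma = aSigma, bSigma = bSigma,
                 aU = aU, bU = bU, aC = aC, bC = bC, pCouple = pCouple,
                 poissonMean = poissonMean, faninMax = as.integer(faninMax))
}

#' MCMC configuration
#'
#' Defaults (100000 iterations, 50000 burn-in, thinning 100) give
#' `W = 500` posterior snapshots per chain.
#'
#' @param nIter,burnIn,thin iteration schedule.
#' @param seed integer RNG seed.
#' @param fixedTau integer vector of known changepoint positions (on the
#'   transition index 1..T), or NULL to sample the segmentation.
#' @param fixedPi integer vector of candidate indices to freeze the covariate
#'   set at, or NULL to sample it.
#' @param minSegLen minimum segment length enforced by changepoint proposals.
#' @param randomSweep permute the coupling-indicator sweep order each
#'   iteration instead of sweeping 0..k in order.
#'
#' @return A [ChainConfig-class] object.
#' @examples
#' snapshotCount(chainConfig())  # 500
#' @export
chainConfig <- function(nIter = 100000L, burnIn = 50000L, thin = 100L,
                        seed = 1L, fixedTau = NULL, fixedPi = NULL,
                        minSegLen = 2L, randomSweep = FALSE) {
    methods::new("ChainConfig",
                 nIter = as.integer(nIter), burnIn = as.integer(burnIn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 fixedTau = if (is.null(fixedTau)) NULL else as.integer(fixedTau),
                 fixedPi = if (is.null(fixedPi)) NULL else as.integer(fixedPi),
                 minSegLen = as.integer(minSegLen),
                 randomSweep = isTRUE(randomSweep))
}

#' Number of thinned posterior snapshots implied by a configuration
#'
#' @param config a [ChainConfig-class].
#' @return integer `(nIter - burnIn) %/% thin`.
#' @export
snapshotCount <- function(config) {
    as.integer((config@nIter - config@burnIn) %/% config@thin)
}

#' Model variant specification
#'
#' @param name one of "EWC", "M1", "M2", "M3", "M5", "M6".
#' @param trafo augment designs with quadratic and interaction terms.
#' @return A [VariantSpec-class] object.
#' @examples
#' variantSpec("M2")
#' @export
variantSpec <- function(name = c("EWC", "M1", "M2", "M3", "M5", "M6"),
                        trafo = FALSE) {
    name <- match.arg(name)
    methods::new("VariantSpec", name = name, trafo = isTRUE(trafo))
}

## internal: variant -> integer code used by the compiled sampler
.variantCode <- function(name) {
    switch(name, EWC = 0L, M1 = 1L, M2 = 2L, M3 = 3L, M5 = 5L, M6 = 6L,
           stop("unknown variant name: ", name))
}
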