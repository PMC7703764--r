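## Plain-text I/O: TSV data matrices, TSV score/edge/curve tables, JSON
## ground-truth files and run manifests.

#' Read a multivariate time series from delimited text
#'
#' Expects a rectangular numeric table with variables in rows and time points
#' in columns (or transposed, with `orientation = "timeRows"`), an optional
#' header row of time labels and a first column of variable names. Time
#' points are assumed equidistant; this is not checked.
#'
#' @param path file path.
#' @param delimiter field separator (default tab).
#' @param orientation "variableRows" (default) or "timeRows".
#' @param header whether the first row holds time labels.
#' @return a [NetworkTimeSeries-class].
#' @export
readTimeSeries <- function(path, delimiter = "\t",
                           orientation = c("variableRows", "timeRows"),
                           header = TRUE) {
    orientation <- match.arg(orientation)
    raw <- utils::read.table(path, sep = delimiter, header = header,
                             row.names = 1L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(raw)
    bad <- which(!vapply(as.vector(m), function(x)
        is.numeric(x) || !is.na(suppressWarnings(as.numeric(x))), TRUE))
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(m))
        stop("non-numeric value at row ", rownames(m)[rc[1L]] %||% rc[1L],
             ", column ", colnames(m)[rc[2L]] %||% rc[2L], " of ", path)
    }
    storage.mode(m) <- "double"
    if (orientation == "timeRows") m <- t(m)
    colnames(m) <- NULL  # time labels carry no information (equidistant)
    if (nrow(m) < 2L) stop("need at least 2 variables")
    if (ncol(m) < 5L) stop("need at least 5 time points")
    networkTimeSeries(m)
}

#' @describeIn readTimeSeries write a series as delimited text (variables in
#'   rows, header of time indices).
#' @param dataset a [NetworkTimeSeries-class].
#' @export
writeTimeSeries <- function(dataset, path, delimiter = "\t") {
    m <- tsValues(dataset)
    colnames(m) <- seq_len(ncol(m))
    utils::write.table(data.frame(variable = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = delimiter, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write the edge-score matrix of a fit as TSV
#'
#' @param fit a [NetworkFit-class] or [EdgeScores-class].
#' @param path output path.
#' @export
writeEdgeScores <- function(fit, path) {
    s <- edgeScores(fit)
    utils::write.table(data.frame(variable = rownames(s), s,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write the ground truth of a synthetic dataset as JSON
#'
#' Records the structure, the true changepoints, the coefficient types and
#' the per-edge coupling truth (type T1 positions are the coupled ones),
#' fully seed-stamped.
#'
#' @param sim result of [simulateRafData()].
#' @param path output path.
#' @export
writeGroundTruth <- function(sim, path) {
    truth <- list(
        nodes = sim$truth$nodes,
        parents = sim$truth$parents,
        tau = sim$tau,
        m = sim$m, snr = sim$snr, scenario = sim$scenario, K = sim$K,
        seed = sim$seed,
        coefficientTypes = sim$coefficients$type)
    jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}

#' Write a run manifest
#'
#' A JSON snapshot of everything needed to reproduce a run bit for bit with
#' the same build: configuration, hyperparameters, seeds, package version,
#' acceptance rates and wall time.
#'
#' @param path output path.
#' @param config a [ChainConfig-class].
#' @param hyper an [EwcHyper-class].
#' @param variant a [VariantSpec-class].
#' @param fit optional [NetworkFit-class] for acceptance rates.
#' @param wallTime elapsed seconds.
#' @param extra named list of additional fields.
#' @export
writeManifest <- function(path, config, hyper, variant = variantSpec("EWC"),
                          fit = NULL, wallTime = NA_real_, extra = list()) {
    man <- c(list(
        package = "ewcnet",
        version = as.character(utils::packageVersion("ewcnet")),
        variant = variant@name, trafo = variant@trafo,
        nIter = config@nIter, burnIn = config@burnIn, thin = config@thin,
        seed = config@seed, fixedTau = config@fixedTau,
        fixedPi = config@fixedPi, minSegLen = config@minSegLen,
        hyper = list(aSigma = hyper@aSigma, bSigma = hyper@bSigma,
                     aU = hyper@aU, bU = hyper@bU, aC = hyper@aC,
                     bC = hyper@bC, pCouple = hyper@pCouple,
                     poissonMean = hyper@poissonMean,
                     faninMax = hyper@faninMax),
        wallTimeSec = wallTime), extra)
    if (!is.null(fit))
        man$acceptance <- lapply(fit@chains, function(ch)
            lapply(ch, function(s) as.list(s@acceptance)))
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}
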