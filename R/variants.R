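## Model variants: the homogeneous (M1), fully uncoupled (M2), fully coupled
## (M3), switch (M5) and segment-wise coupled (M6) models are configuration-
## level restrictions of the edge-wise coupled model; the design
## transformation adds quadratic and interaction terms.

#' Apply a variant's constraints to a sampler state
#'
#' Pins the state components that the chosen variant fixes: M1 empties the
#' changepoint set (one segment), M2 pins all coupling indicators to 0, M3 to
#' 1, M5 ties all indicators to a single global value, and M6 replaces the
#' per-column indicators by one indicator per segment `h > 1` (segment 1 is
#' always uncoupled). The edge-wise model leaves the state untouched.
#'
#' @param state list with components `pi`, `tau`, `delta` (and, for M6,
#'   optionally `segDelta`, one 0/1 value per segment).
#' @param spec a [VariantSpec-class].
#' @return the constrained state list.
#' @export
applyVariantConstraints <- function(state, spec) {
    name <- spec@name
    P <- length(state$delta)
    if (name == "M1") {
        state$tau <- integer(0)
    } else if (name == "M2") {
        state$delta <- rep(0, P)
    } else if (name == "M3") {
        state$delta <- rep(1, P)
    } else if (name == "M5") {
        state$delta <- rep(round(mean(state$delta)), P)
    } else if (name == "M6") {
        H <- length(state$tau) + 1L
        if (is.null(state$segDelta)) state$segDelta <- rep(0, H)
        state$segDelta[1L] <- 0
        state$delta <- outer(state$segDelta, rep(1, P))
    }
    state
}

#' Per-segment indicator rows implied by a variant
#'
#' Expands a variant's coupling state to the indicator vector that applies to
#' segment `h`, the common currency of the model-core functions.
#'
#' @param spec a [VariantSpec-class].
#' @param delta edge-wise indicator vector (EWC/M5) or NULL.
#' @param segDelta per-segment indicators (M6) or NULL.
#' @param H segment count.
#' @param P design column count.
#' @return an `H x P` 0/1 matrix whose row `h` is the indicator vector for
#'   segment `h` (row 1 is conventionally all zero and never used).
#' @export
variantDeltaMatrix <- function(spec, delta = NULL, segDelta = NULL, H, P) {
    name <- spec@name
    row <- switch(name,
        EWC = , M5 = matrix(rep(delta, each = H), nrow = H),
        M1 = , M2 = matrix(0, H, P),
        M3 = matrix(1, H, P),
        M6 = outer(c(0, segDelta[-1L]), rep(1, P)))
    row[1L, ] <- 0
    row
}

#' Augment a design matrix with quadratic and interaction terms
#'
#' Given a design whose first column is the intercept followed by `k`
#' covariate columns, appends the `k` squared columns (by covariate index)
#' and the `choose(k, 2)` pairwise products (lexicographic order). The
#' column order is deterministic.
#'
#' @param X design matrix (intercept first).
#' @return the augmented design matrix.
#' @examples
#' X <- cbind(1, matrix(rnorm(12), ncol = 2))
#' ncol(augmentDesign(X))  # 1 + 2 + 2 + 1 = 6
#' @export
augmentDesign <- function(X) {
    X <- as.matrix(X)
    k <- ncol(X) - 1L
    if (k < 1L) return(X)
    covs <- X[, -1L, drop = FALSE]
    quad <- covs^2
    colnames(quad) <- if (!is.null(colnames(covs)))
        paste0(colnames(covs), "^2")
    inter <- NULL
    if (k >= 2L) {
        pairs <- combn(k, 2L)
        inter <- apply(pairs, 2L, function(ij) covs[, ij[1L]] * covs[, ij[2L]])
        inter <- matrix(inter, nrow = nrow(X))
        if (!is.null(colnames(covs)))
            colnames(inter) <- apply(pairs, 2L, function(ij)
                paste0(colnames(covs)[ij[1L]], ":", colnames(covs)[ij[2L]]))
    }
    cbind(X, quad, inter)
}

#' Number of design columns after augmentation
#'
#' @param k covariate count (excluding the intercept).
#' @param trafo logical; whether the transformation is applied.
#' @return integer column count `1 + k` or `1 + 2k + choose(k, 2)`.
#' @export
designColumns <- function(k, trafo = FALSE) {
    k <- as.integer(k)
    if (!trafo) 1L + k else 1L + 2L * k + choose(k, 2L)
}
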