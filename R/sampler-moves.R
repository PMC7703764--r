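## Priors and Metropolis-Hastings proposals on the changepoint set tau and
## the covariate set pi. These R functions define the move dialect; the
## compiled chain engine implements the identical logic.

#' Log prior of a changepoint layout
#'
#' The H-1 changepoints are distributed like the even-numbered order
#' statistics of `2(H-1)+1` points drawn uniformly on `S = {2, ..., T-1}`:
#' \deqn{p(\tau | H) = \frac{\prod_{h=0}^{H-1} (\tau_{h+1} - \tau_h - 1)}
#'   {\binom{T-2}{2(H-1)+1}}}
#' with `tau_0 = 1`, `tau_H = T`; the segment count has a Poisson prior
#' (mean `poissonMean`) truncated to `H >= 1`. Returns
#' `log p(tau | H) + log p(H)`. Layouts with adjacent changepoints (a gap
#' of one) have prior probability zero, i.e. log prior `-Inf`.
#'
#' @param tau integer changepoint positions in `{2, ..., T-1}`, possibly empty.
#' @param T number of modelled transitions (must be >= 4).
#' @param hyper an [EwcHyper-class] object.
#' @return scalar log prior.
#' @examples
#' changepointLogPrior(integer(0), T = 10)  # single segment
#' @export
changepointLogPrior <- function(tau, T, hyper = ewcHyperparams()) {
    if (T < 4) stop("need T >= 4")
    tau <- as.integer(tau)
    if (length(tau)) {
        if (is.unsorted(tau, strictly = TRUE))
            stop("changepoints must be strictly increasing")
        if (any(tau < 2L) || any(tau > T - 1L))
            stop("changepoints must lie in S = {2, ..., T-1}")
    }
    H <- length(tau) + 1L
    gaps <- diff(c(1L, tau, T)) - 1L
    lpTau <- if (any(gaps <= 0L)) -Inf else
        sum(log(gaps)) - lchoose(T - 2, 2 * (H - 1) + 1)
    lam <- hyper@poissonMean
    lpH <- dpois(H, lam, log = TRUE) - log(1 - dpois(0, lam))
    lpTau + lpH
}

## internal: positions where a new changepoint may be born, keeping every
## segment at least minSegLen long (gap >= minSegLen to both neighbours,
## including the virtual boundaries tau_0 = 1 and tau_H = T).
.birthPositions <- function(tau, T, minSegLen) {
    s <- seq(2L, T - 1L)
    bounds <- c(1L, as.integer(tau), T)
    ok <- vapply(s, function(p) all(abs(p - bounds) >= minSegLen), logical(1))
    s[ok & !(s %in% tau)]
}

#' Propose a changepoint move
#'
#' Birth draws a new changepoint uniformly from the admissible free positions
#' (those keeping all segments at least `minSegLen` long); death removes one
#' changepoint uniformly; reallocation moves one changepoint uniformly within
#' the window allowed by its neighbours. Inadmissible moves (death or
#' reallocation with a single segment, birth with no free position) return a
#' no-op. The log proposal ratio is the Hastings correction
#' `log q(reverse) - log q(forward)` for a move type drawn uniformly from
#' the three types.
#'
#' @param tau current changepoint set.
#' @param T number of transitions.
#' @param move one of "birth", "death", "reallocate".
#' @param minSegLen minimum segment length.
#' @return list with `tau` (proposed set), `logProposalRatio`, and `noop`.
#' @export
proposeChangepointMove <- function(tau, T,
                                   move = c("birth", "death", "reallocate"),
                                   minSegLen = 2L) {
    move <- match.arg(move)
    tau <- as.integer(tau)
    noop <- list(tau = tau, logProposalRatio = 0, noop = TRUE)
    if (move == "birth") {
        free <- .birthPositions(tau, T, minSegLen)
        if (!length(free)) return(noop)
        p <- if (length(free) == 1L) free else sample(free, 1L)
        newTau <- sort(c(tau, p))
        # reverse: delete that changepoint among |tau| + 1
        list(tau = newTau,
             logProposalRatio = log(length(free)) - log(length(newTau)),
             noop = FALSE)
    } else if (move == "death") {
        if (!length(tau)) return(noop)
        j <- if (length(tau) == 1L) 1L else sample(length(tau), 1L)
        newTau <- tau[-j]
        freeRev <- .birthPositions(newTau, T, minSegLen)
        list(tau = newTau,
             logProposalRatio = log(length(tau)) - log(length(freeRev)),
             noop = FALSE)
    } else {
        if (!length(tau)) return(noop)
        j <- if (length(tau) == 1L) 1L else sample(length(tau), 1L)
        left <- if (j == 1L) 1L else tau[j - 1L]
        right <- if (j == length(tau)) T else tau[j + 1L]
        win <- seq(max(2L, left + minSegLen), min(T - 1L, right - minSegLen))
        win <- setdiff(win, tau[j])
        if (!length(win)) return(noop)
        p <- if (length(win) == 1L) win else sample(win, 1L)
        newTau <- sort(c(tau[-j], p))
        # window size is neighbour-determined, identical from both states
        list(tau = newTau, logProposalRatio = 0, noop = FALSE)
    }
}

#' Propose a covariate-set move
#'
#' Addition draws a covariate uniformly from the candidates outside `pi`
#' (blocked at the fan-in bound); deletion removes one uniformly; exchange
#' swaps one member for one non-member, both uniform. Inadmissible moves are
#' no-ops. The covariate prior is uniform over all fan-in-admissible sets, so
#' only the Hastings correction is returned.
#'
#' @param pi current covariate set (integer indices into the candidate list).
#' @param nCandidates number of candidate covariates.
#' @param move one of "add", "delete", "exchange".
#' @param faninMax fan-in bound.
#' @return list with `pi`, `logProposalRatio`, `noop`.
#' @export
proposeCovariateMove <- function(pi, nCandidates,
                                 move = c("add", "delete", "exchange"),
                                 faninMax = 3L) {
    move <- match.arg(move)
    pi <- as.integer(pi)
    noop <- list(pi = pi, logProposalRatio = 0, noop = TRUE)
    free <- setdiff(seq_len(nCandidates), pi)
    if (move == "add") {
        if (length(pi) >= faninMax || !length(free)) return(noop)
        x <- if (length(free) == 1L) free else sample(free, 1L)
        list(pi = c(pi, x),
             logProposalRatio = log(length(free)) - log(length(pi) + 1L),
             noop = FALSE)
    } else if (move == "delete") {
        if (!length(pi)) return(noop)
        j <- if (length(pi) == 1L) 1L else sample(length(pi), 1L)
        list(pi = pi[-j],
             logProposalRatio = log(length(pi)) - log(length(free) + 1L),
             noop = FALSE)
    } else {
        if (!length(pi) || !length(free)) return(noop)
        j <- if (length(pi) == 1L) 1L else sample(length(pi), 1L)
        x <- if (length(free) == 1L) free else sample(free, 1L)
        newPi <- pi; newPi[j] <- x
        list(pi = newPi, logProposalRatio = 0, noop = FALSE)
    }
}

#' Metropolis-Hastings acceptance decision
#'
#' Standard log-space acceptance for a collapsed target: the log acceptance
#' probability is the difference in log marginal likelihood plus the
#' difference in log prior plus the log proposal ratio.
#'
#' @param currentLogTarget,proposedLogTarget log marginal likelihood plus log
#'   prior of the current and the proposed state.
#' @param logProposalRatio Hastings correction from the proposal.
#' @return logical: accept the proposal.
#' @export
mhAccept <- function(currentLogTarget, proposedLogTarget,
                     logProposalRatio = 0) {
    if (!is.finite(proposedLogTarget)) return(FALSE)
    logAlpha <- proposedLogTarget - currentLogTarget + logProposalRatio
    logAlpha >= 0 || log(runif(1)) < logAlpha
}
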