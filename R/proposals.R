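#' Metropolis-Hastings proposal kernels
#'
#' `multiplierProposal()` scales a positive parameter by
#' \eqn{m = \exp\{\lambda(u - 1/2)\}} with \eqn{\lambda = 2\ln d} and
#' \eqn{u \sim U(0,1)}; the log Hastings ratio is \eqn{\ln m}. Used for
#' rates. `slidingWindowProposal()` adds a \eqn{U(-w/2, w/2)} increment
#' (symmetric; Hastings ratio 0). Used for trends and the root state.
#'
#' @param value current parameter value (> 0 for the multiplier).
#' @param d multiplier tuning parameter (> 1); proposals lie in
#'   `[value/d, value*d]`.
#' @param w sliding-window width.
#' @return a list with `proposal` and `logHastings`.
#' @export
multiplierProposal <- function(value, d = 1.5) {
  stopifnot(value > 0, d > 1)
  lambda <- 2 * log(d)
  m <- exp(lambda * (stats::runif(1) - 0.5))
  list(proposal = value * m, logHastings = log(m))
}

#' @rdname multiplierProposal
#' @export
slidingWindowProposal <- function(value, w) {
  stopifnot(w > 0)
  list(proposal = value + stats::runif(1, -w / 2, w / 2), logHastings = 0)
}

#' Metropolis-Hastings acceptance decision
#'
#' Accepts with probability `min(1, exp(logPostNew - logPostOld +
#' logHastings))`.
#'
#' @param logPostOld,logPostNew log-posterior at the current and proposed
#'   values (`-Inf` allowed for the proposal).
#' @param logHastings log Hastings ratio of the proposal.
#' @return `TRUE` to accept.
#' @export
mhAccept <- function(logPostOld, logPostNew, logHastings = 0) {
  a <- logPostNew - logPostOld + logHastings
  if (a >= 0) return(TRUE)
  log(stats::runif(1)) < a
}
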