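#' Priors and proposal constants for the shift model
#'
#' @param ratePriorRate rate of the exponential prior on every \eqn{\sigma^2}
#'   class. The chain driver defaults it to `1 / (var(tips) / treeHeight)`,
#'   a weakly-informative, scale-matched choice.
#' @param trendPriorSD standard deviation of the zero-mean normal prior on
#'   every trend class (default 10).
#' @param shiftPoissonRate rate of the Poisson prior on the number of shifts
#'   (default 1).
#' @param trendProposalSD standard deviation of the zero-mean normal from
#'   which a newborn trend-shift value is drawn (default 1; distinct from
#'   the prior SD).
#' @param deathPolicy `"stephens"` (default): the death rate of a shift is
#'   the likelihood ratio without/with the shift times the ratio of its
#'   birth-proposal density to its model-prior density, which preserves the
#'   Poisson prior as the stationary shift-count distribution when the data
#'   carry no signal. `"likelihood_only"`: the bare likelihood ratio.
#' @return an object of class `ftPriors`.
#' @export
priorConfig <- function(ratePriorRate = NULL, trendPriorSD = 10,
                        shiftPoissonRate = 1, trendProposalSD = 1,
                        deathPolicy = c("stephens", "likelihood_only")) {
  deathPolicy <- match.arg(deathPolicy)
  stopifnot(is.null(ratePriorRate) || ratePriorRate > 0,
            trendPriorSD > 0, shiftPoissonRate > 0, trendProposalSD > 0)
  structure(list(ratePriorRate = ratePriorRate, trendPriorSD = trendPriorSD,
                 shiftPoissonRate = shiftPoissonRate,
                 trendProposalSD = trendProposalSD, deathPolicy = deathPolicy),
            class = "ftPriors")
}

#' Eligible anchors for a new shift
#'
#' All non-root nodes (tips included) that do not already carry a shift of
#' the given kind; there are at most `n - 2` of them per kind, `n` being the
#' number of tips of a binary tree.
#'
#' @param tree a `timeTree`.
#' @param params a `bmParams`.
#' @param kind `"rate"` or `"trend"`.
#' @return integer vector of node indices.
#' @export
eligibleAnchors <- function(tree, params, kind = c("rate", "trend")) {
  kind <- match.arg(kind)
  taken <- if (kind == "rate") params$rateShifts$anchor else params$trendShifts$anchor
  setdiff(seq_len(nNodesTotal(tree))[-rootNode(tree)], taken)
}

#' Propose the birth of a shift
#'
#' Picks a kind (rate vs trend, probability 1/2 each when trends are
#' enabled), an anchor uniformly among eligible non-root nodes, and a value
#' from the birth proposal: exponential with mean equal to the current
#' background rate for rate shifts, `N(0, trendProposalSD)` for trend
#' shifts. Births in a birth-death MCMC are not filtered by an acceptance
#' step; useless shifts are instead removed quickly by the death process.
#'
#' @param tree a `timeTree`.
#' @param params current `bmParams`.
#' @param priors an `ftPriors`.
#' @param trendEnabled if `FALSE`, only rate shifts are proposed.
#' @return the augmented `bmParams` (unchanged if no anchor is eligible).
#' @export
proposeBirth <- function(tree, params, priors, trendEnabled = TRUE) {
  kind <- if (trendEnabled && stats::runif(1) < 0.5) "trend" else "rate"
  anchors <- eligibleAnchors(tree, params, kind)
  if (!length(anchors)) return(params)
  a <- anchors[sample.int(length(anchors), 1)]
  if (kind == "rate") {
    v <- stats::rexp(1, rate = 1 / params$rateBg)
    params$rateShifts <- rbind(params$rateShifts,
                               data.frame(anchor = a, value = v))
  } else {
    v <- stats::rnorm(1, 0, priors$trendProposalSD)
    params$trendShifts <- rbind(params$trendShifts,
                                data.frame(anchor = a, value = v))
  }
  params
}

removeShift <- function(params, kind, j) {
  if (kind == "rate") params$rateShifts <- params$rateShifts[-j, , drop = FALSE]
  else params$trendShifts <- params$trendShifts[-j, , drop = FALSE]
  params
}

#' Death rate of a shift
#'
#' The propensity with which the birth-death model search removes a shift:
#' the ratio of the augmented likelihood without the shift (its clade reset
#' to the parameter value at the anchor's parent; nested shifts kept) to the
#' likelihood with it, times a prior correction under the `"stephens"`
#' policy (see [priorConfig()]). Shifts that improve the fit get death rates
#' near zero; shifts that worsen it get large death rates and die quickly.
#'
#' @param tree a `timeTree`.
#' @param params current `bmParams`.
#' @param states per-node state vector (augmented likelihood).
#' @param kind `"rate"` or `"trend"`.
#' @param j row index of the shift in its table.
#' @param priors an `ftPriors`.
#' @param priorOnly if `TRUE` the likelihood term is dropped (model search
#'   under the prior alone).
#' @param cap upper bound on the log death rate (numerical guard).
#' @return the death rate, a non-negative finite number.
#' @export
deathRate <- function(tree, params, states, kind, j, priors,
                      priorOnly = FALSE, cap = 50) {
  sh <- if (kind == "rate") params$rateShifts else params$trendShifts
  stopifnot(j >= 1, j <= nrow(sh))
  logd <- 0
  if (!priorOnly) {
    without <- removeShift(params, kind, j)
    logd <- treeLogLik(tree, states, without) - treeLogLik(tree, states, params)
  }
  if (priors$deathPolicy == "stephens") {
    v <- sh$value[j]
    if (kind == "rate") {
      rr <- priors$ratePriorRate
      if (is.null(rr)) rr <- 1 / params$rateBg  # scale-matched default
      logq <- stats::dexp(v, rate = 1 / params$rateBg, log = TRUE)
      logg <- stats::dexp(v, rate = rr, log = TRUE)
    } else {
      logq <- stats::dnorm(v, 0, priors$trendProposalSD, log = TRUE)
      logg <- stats::dnorm(v, 0, priors$trendPriorSD, log = TRUE)
    }
    logd <- logd + logq - logg
  }
  exp(min(logd, cap))
}

#' One birth-death MCMC sweep over shift configurations
#'
#' Simulates the continuous-time birth-death process on model space for one
#' unit of virtual time: births arrive at rate 1 (a new shift with anchor
#' and value drawn as in [proposeBirth()]); each existing shift dies at its
#' [deathRate()]. Waiting times are exponential with the total event rate;
#' the sweep stops when the accumulated virtual time exceeds 1.
#'
#' @inheritParams deathRate
#' @param trendEnabled if `FALSE`, only rate shifts are proposed.
#' @param maxEvents abort guard: if more than this many events occur in one
#'   sweep, the sweep stops with a warning and the current configuration is
#'   kept.
#' @return the updated `bmParams`.
#' @export
bdmcmcStep <- function(tree, params, states, priors, trendEnabled = TRUE,
                       priorOnly = FALSE, maxEvents = 100) {
  if (is.list(states)) states <- states$values
  tAcc <- 0; nEvents <- 0
  repeat {
    kr <- nrow(params$rateShifts); kt <- nrow(params$trendShifts)
    dr <- if (kr) vapply(seq_len(kr), function(j)
      deathRate(tree, params, states, "rate", j, priors, priorOnly), 0) else numeric(0)
    dt <- if (kt) vapply(seq_len(kt), function(j)
      deathRate(tree, params, states, "trend", j, priors, priorOnly), 0) else numeric(0)
    R <- 1 + sum(dr) + sum(dt)
    tAcc <- tAcc + stats::rexp(1, R)
    if (tAcc > 1) break
    nEvents <- nEvents + 1
    if (nEvents > maxEvents) {
      warning("birth-death sweep exceeded ", maxEvents, " events; aborting sweep")
      break
    }
    u <- stats::runif(1) * R
    if (u < 1) {
      params <- proposeBirth(tree, params, priors, trendEnabled)
    } else {
      u <- u - 1
      cs <- cumsum(c(dr, dt))
      pick <- which(u < cs)[1]
      if (is.na(pick)) pick <- length(cs)
      if (pick <= kr) params <- removeShift(params, "rate", pick)
      else params <- removeShift(params, "trend", pick - kr)
    }
  }
  params
}
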