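#' Log-density of trait change along one branch
#'
#' Under Brownian motion with trend, the trait value at the end of a branch
#' of duration `t` is normal with mean `parentState + mu0 * t` and variance
#' `sigma2 * t`.
#'
#' @param parentState trait value at the start (rootward end) of the branch.
#' @param childState trait value at the end (tipward end).
#' @param t branch duration (Myr); must be > 0.
#' @param sigma2 rate of trait evolution; must be > 0.
#' @param mu0 trend (drift per Myr).
#' @return the log-density (scalar; vectorized over its arguments).
#' @export
branchLogDensity <- function(parentState, childState, t, sigma2, mu0 = 0) {
  if (any(t <= 0)) stop("branch length must be > 0")
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  stats::dnorm(childState, mean = parentState + mu0 * t,
               sd = sqrt(sigma2 * t), log = TRUE)
}

#' Augmented log-likelihood of a full set of node states
#'
#' The likelihood conditional on explicitly assigned internal-node states: a
#' sum over branches of [branchLogDensity()] with branch-resolved rate and
#' trend parameters. No root-state prior term is included. Zero-length
#' (sampled ancestor) branches contribute no density term.
#'
#' @param tree a `timeTree`.
#' @param states numeric vector of trait values, one per node (tips first),
#'   or the `values` element of a [bindTraits()] result with internal states
#'   filled in.
#' @param params a `bmParams`.
#' @return the log-likelihood (scalar).
#' @export
treeLogLik <- function(tree, states, params) {
  if (is.list(states)) states <- states$values
  m <- nNodesTotal(tree)
  stopifnot(length(states) == m)
  if (anyNA(states)) stop("all node states must be set")
  cls <- resolveClasses(tree, params)
  e <- tree$phy$edge
  len <- tree$phy$edge.length
  keep <- len > 0
  ch <- e[keep, 2]; pa <- e[keep, 1]; t <- len[keep]
  sum(stats::dnorm(states[ch],
                   mean = states[pa] + cls$trend[ch] * t,
                   sd = sqrt(cls$rate[ch] * t), log = TRUE))
}

#' Marginal log-likelihood of the observed tip values (oracle)
#'
#' Integrates the internal states out analytically for a single rate/trend
#' class: the tip values are jointly multivariate normal with mean
#' `rootState + mu0 * depth_i` (depth = root-to-tip path time) and covariance
#' `sigma2 * S`, `S` being the shared-path-time matrix. Used as an
#' independent check of the augmented-likelihood machinery; not part of the
#' sampler itself.
#'
#' @param tree a `timeTree`.
#' @param tipValues numeric vector of tip values in `tree$phy$tip.label`
#'   order (or named by tip label).
#' @param sigma2,mu0 single rate and trend for the whole tree.
#' @param rootState trait value at the root.
#' @return the multivariate-normal log-density of the tip values.
#' @export
marginalTipLogLik <- function(tree, tipValues, sigma2, mu0 = 0, rootState = 0) {
  stopifnot(sigma2 > 0)
  labs <- tree$phy$tip.label
  if (!is.null(names(tipValues))) tipValues <- tipValues[labs]
  n <- tree$N
  stopifnot(length(tipValues) == n)
  S <- ape::vcv.phylo(tree$phy)[labs, labs, drop = FALSE] * sigma2
  depth <- tree$height - tree$age[seq_len(n)]
  mu <- rootState + mu0 * depth
  dmvnormLog(tipValues, mu, S)
}

# log MVN density via Cholesky; errors on a (numerically) singular covariance
dmvnormLog <- function(x, mean, sigma) {
  L <- tryCatch(chol(sigma), error = function(e)
    stop("singular covariance matrix"))
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}
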