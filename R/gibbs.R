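#' Conditional posterior of one ancestral state
#'
#' Under Brownian motion with trend, the full conditional of an internal
#' node's state given its parent and children states is normal: the product
#' of the three branch densities (one from the parent, one per child) is
#' itself a normal density. With clade shifts, each of the three terms uses
#' its own branch's resolved rate and trend; the conjugacy is unaffected.
#'
#' Precision-weighted form: with parent value \eqn{x_p} at distance
#' \eqn{t_1}, child values \eqn{x'} and \eqn{x''} at distances \eqn{t_2},
#' \eqn{t_3},
#' \deqn{Var = \left[\frac{1}{\sigma^2_1 t_1} + \frac{1}{\sigma^2_2 t_2}
#'   + \frac{1}{\sigma^2_3 t_3}\right]^{-1},\quad
#'   Mean = Var\left[\frac{x_p + \mu_1 t_1}{\sigma^2_1 t_1}
#'   + \frac{x' - \mu_2 t_2}{\sigma^2_2 t_2}
#'   + \frac{x'' - \mu_3 t_3}{\sigma^2_3 t_3}\right].}
#' The ancestor term adds its trend displacement, the descendant terms
#' subtract theirs.
#'
#' Zero-length (sampled ancestor) branches drop out of the product; if every
#' neighbour drops, an error is raised.
#'
#' @param tree a `timeTree`.
#' @param node an internal, non-root node index.
#' @param states numeric per-node state vector (the node's own entry is
#'   ignored).
#' @param params a `bmParams`.
#' @return a list with `mean` and `var` of the conditional normal.
#' @export
conditionalPosterior <- function(tree, node, states, params) {
  if (is.list(states)) states <- states$values
  root <- rootNode(tree)
  if (node <= tree$N || node == root)
    stop("node must be internal and non-root")
  cls <- resolveClasses(tree, params)
  par <- parentOf(tree)
  blen <- branchLengthTo(tree)
  kids <- childrenOf(tree)[[node]]

  prec <- 0; wsum <- 0
  # ancestor term: mean contribution x_parent + mu * t
  t1 <- blen[node]
  if (t1 > 0) {
    v <- cls$rate[node] * t1
    prec <- prec + 1 / v
    wsum <- wsum + (states[par[node]] + cls$trend[node] * t1) / v
  }
  # descendant terms: mean contribution x_child - mu * t
  for (k in kids) {
    tk <- blen[k]
    if (tk > 0) {
      v <- cls$rate[k] * tk
      prec <- prec + 1 / v
      wsum <- wsum + (states[k] - cls$trend[k] * tk) / v
    }
  }
  if (prec <= 0) stop("all neighbouring branches are degenerate")
  list(mean = wsum / prec, var = 1 / prec)
}

#' One systematic-scan Gibbs sweep over ancestral states
#'
#' Replaces every unobserved internal non-root state by a draw from its
#' conditional posterior, visiting nodes in child-before-parent (post-)order
#' so that tip information propagates rootward within a single sweep. The
#' root state is left untouched (it is updated by Metropolis-Hastings in the
#' chain driver). Observed states (tips, sampled ancestors) are never
#' modified.
#'
#' @param tree a `timeTree`.
#' @param states a [bindTraits()]-style list (`values`, `observed`) or a
#'   plain numeric vector (then only tips are treated as observed).
#' @param params a `bmParams`.
#' @return the updated states, same shape as the input.
#' @export
gibbsSweep <- function(tree, states, params) {
  asList <- is.list(states)
  if (!asList) {
    obs <- c(rep(TRUE, tree$N), rep(FALSE, nNodesTotal(tree) - tree$N))
    states <- list(values = states, observed = obs)
  }
  root <- rootNode(tree)
  for (i in postorderNodes(tree)) {
    if (i <= tree$N || i == root || states$observed[i]) next
    cp <- conditionalPosterior(tree, i, states$values, params)
    states$values[i] <- stats::rnorm(1, cp$mean, sqrt(cp$var))
  }
  if (asList) states else states$values
}
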