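#' Brownian-motion parameters with clade shifts
#'
#' Bundles the background rate and trend, the root state, and any number of
#' clade shifts. A shift is anchored at a non-root node and applies to the
#' branch subtending that node and to all descendant branches, until
#' overridden by a nested anchor. Rate shifts and trend shifts are anchored
#' independently; a node may carry one, both, or neither.
#'
#' @param rateBg background rate of trait evolution, \eqn{\sigma^2} (trait
#'   units squared per Myr); must be > 0.
#' @param trendBg background trend \eqn{\mu_0} (trait units per Myr).
#' @param rootState trait value at the root.
#' @param rateShifts,trendShifts `NULL` or a data frame with columns `anchor`
#'   (node index, non-root) and `value`.
#' @return an object of class `bmParams`.
#' @examples
#' p <- bmParams(rateBg = 0.5, trendBg = 0.1, rootState = 2,
#'               rateShifts = data.frame(anchor = 6, value = 5))
#' @export
bmParams <- function(rateBg, trendBg = 0, rootState = 0,
                     rateShifts = NULL, trendShifts = NULL) {
  chk <- function(s) {
    if (is.null(s)) return(data.frame(anchor = integer(0), value = numeric(0)))
    stopifnot(all(c("anchor", "value") %in% names(s)))
    s <- data.frame(anchor = as.integer(s$anchor), value = as.numeric(s$value))
    if (anyDuplicated(s$anchor)) stop("duplicate shift anchors")
    s
  }
  rateShifts <- chk(rateShifts); trendShifts <- chk(trendShifts)
  if (!is.finite(rateBg) || rateBg <= 0) stop("rateBg must be > 0")
  if (any(rateShifts$value <= 0)) stop("rate shift values must be > 0")
  stopifnot(is.finite(trendBg), is.finite(rootState),
            all(is.finite(rateShifts$value)), all(is.finite(trendShifts$value)))
  structure(list(rateBg = rateBg, trendBg = trendBg, rootState = rootState,
                 rateShifts = rateShifts, trendShifts = trendShifts),
            class = "bmParams")
}

#' @export
print.bmParams <- function(x, ...) {
  cat(sprintf("bmParams: sigma2 = %.4g, mu0 = %.4g, root = %.4g; %d rate shift(s), %d trend shift(s)\n",
              x$rateBg, x$trendBg, x$rootState,
              nrow(x$rateShifts), nrow(x$trendShifts)))
  invisible(x)
}

#' Number of shifts in a parameter set
#' @param params a `bmParams`.
#' @return named integer vector `c(rate=, trend=)`.
#' @export
nShifts <- function(params)
  c(rate = nrow(params$rateShifts), trend = nrow(params$trendShifts))

resolveOneKind <- function(tree, anchors, values, background) {
  m <- nNodesTotal(tree)
  root <- rootNode(tree)
  if (length(anchors)) {
    if (any(anchors == root)) stop("shift anchors must be non-root nodes")
    if (any(anchors < 1L | anchors > m)) stop("shift anchor not in tree")
  }
  val <- rep(background, m)
  anc <- rep(0L, m)
  if (length(anchors)) {
    # preorder propagation: parent resolved before child
    ord <- rev(postorderNodes(tree))
    par <- parentOf(tree)
    amap <- rep(NA_real_, m); amap[anchors] <- values
    for (i in ord) {
      if (i == root) next
      if (!is.na(amap[i])) { val[i] <- amap[i]; anc[i] <- i }
      else { val[i] <- val[par[i]]; anc[i] <- anc[par[i]] }
    }
  }
  list(value = val, anchor = anc)
}

#' Resolve per-branch rate and trend classes
#'
#' Maps a shift configuration onto every branch of the tree: each branch
#' (identified by its child node) gets the rate and trend of its most recent
#' ancestral anchor, inclusive of the child node itself, or the background
#' values if none. Nested anchors override outer ones.
#'
#' @param tree a `timeTree`.
#' @param params a `bmParams`.
#' @return a list with numeric vectors `rate` and `trend` (per node; entries
#'   at the root are the background values) and integer vectors `rateAnchor`
#'   and `trendAnchor` (anchor node governing each branch, 0 = background).
#' @export
resolveClasses <- function(tree, params) {
  stopifnot(inherits(tree, "timeTree"), inherits(params, "bmParams"))
  r <- resolveOneKind(tree, params$rateShifts$anchor, params$rateShifts$value,
                      params$rateBg)
  tr <- resolveOneKind(tree, params$trendShifts$anchor, params$trendShifts$value,
                       params$trendBg)
  list(rate = r$value, trend = tr$value,
       rateAnchor = r$anchor, trendAnchor = tr$anchor)
}
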