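#' Accuracy metrics for simulation studies
#'
#' `mape()` is the mean absolute percentage error `mean(|est - true| /
#' |true|)`; `mae()` the mean absolute error; `rSquared()` the coefficient
#' of determination of the linear regression of estimates on truth, i.e.
#' the squared Pearson correlation. The regression form is deliberate: when
#' a misspecified model (e.g. a trend fixed to zero on trended data)
#' produces systematically but linearly biased state estimates, the
#' regression R-squared still measures how much of the true variation the
#' estimates track, whereas `1 - SS_res/SS_tot` collapses below zero under
#' any systematic offset.
#'
#' @param true numeric vector of true values.
#' @param est numeric vector of estimates (same length).
#' @return a single number.
#' @export
mape <- function(true, est) {
  stopifnot(length(true) == length(est), all(true != 0))
  mean(abs(est - true) / abs(true))
}

#' @rdname mape
#' @export
mae <- function(true, est) {
  stopifnot(length(true) == length(est))
  mean(abs(est - true))
}

#' @rdname mape
#' @export
rSquared <- function(true, est) {
  stopifnot(length(true) == length(est))
  stats::cor(true, est)^2
}

#' Shift-count recovery frequency
#'
#' The fraction of replicates whose posterior-mode total shift count equals
#' the true count. When the posterior mode is tied, the smaller count wins
#' (the same tie-break [shiftCountMode()] applies).
#'
#' @param trueCounts integer vector, one true total count per replicate.
#' @param modeCounts integer vector of posterior-mode counts (e.g. from
#'   [shiftCountMode()] per chain).
#' @return a frequency in `[0, 1]`.
#' @export
shiftRecovery <- function(trueCounts, modeCounts) {
  stopifnot(length(trueCounts) == length(modeCounts))
  mean(trueCounts == modeCounts)
}

#' Clade-averaged rates and trends
#'
#' For each named clade, averages the branch-resolved rate and trend over
#' the clade's branches and over the posterior samples of a chain. Clades
#' are given as tip-label sets; the MRCA is computed per tree so the same
#' definitions work across a posterior tree sample.
#'
#' @param chain an `ftChain`.
#' @param clades a named list of character vectors of tip labels.
#' @return a data frame with one row per clade: mean `sigma2` and `mu0`.
#' @export
cladeAverageParams <- function(chain, clades) {
  tree <- chain$tree
  keep <- postBurnin(chain)
  out <- lapply(names(clades), function(nm) {
    tips <- match(clades[[nm]], tree$phy$tip.label)
    if (anyNA(tips)) stop("unknown tip label in clade ", nm)
    node <- if (length(tips) == 1) tips else ape::getMRCA(tree$phy, tips)
    members <- setdiff(cladeNodes(tree, node), rootNode(tree))
    acc <- vapply(keep, function(s) {
      p <- paramsFromSample(chain, s)
      cls <- resolveClasses(tree, p)
      c(mean(cls$rate[members]), mean(cls$trend[members]))
    }, numeric(2))
    data.frame(clade = nm, sigma2 = mean(acc[1, ]), mu0 = mean(acc[2, ]))
  })
  do.call(rbind, out)
}

# rebuild a bmParams from one posterior sample
paramsFromSample <- function(chain, s) {
  sh <- chain$shifts[[s]]
  bmParams(rateBg = chain$trace$sigma2Bg[s], trendBg = chain$trace$mu0Bg[s],
           rootState = chain$trace$rootState[s],
           rateShifts = if (any(sh$kind == "rate"))
             sh[sh$kind == "rate", c("anchor", "value")] else NULL,
           trendShifts = if (any(sh$kind == "trend"))
             sh[sh$kind == "trend", c("anchor", "value")] else NULL)
}

#' Trait range through time
#'
#' The per-time-bin envelope (minimum and maximum) of reconstructed trait
#' values across lineages alive in that bin. States are interpolated
#' linearly along branches between the posterior-mean parent and child
#' values (the Brownian conditional expectation is linear in time); with
#' several replicate analyses the envelopes are averaged across replicates
#' per bin.
#'
#' @param chains an `ftChain` or list of them (replicate analyses).
#' @param binWidth bin width in Myr (default 1).
#' @return a data frame with columns `binStart`, `binEnd` (ages, older to
#'   younger), `min`, `max`.
#' @export
rangeThroughTime <- function(chains, binWidth = 1) {
  if (inherits(chains, "ftChain")) chains <- list(chains)
  envs <- lapply(chains, function(chain) {
    tree <- chain$tree
    st <- posteriorMeans(chain)$states
    par <- parentOf(tree); blen <- branchLengthTo(tree)
    age <- tree$age
    nb <- ceiling(tree$height / binWidth)
    lo <- rep(Inf, nb); hi <- rep(-Inf, nb)
    for (i in seq_len(nNodesTotal(tree))) {
      if (is.na(par[i]) || blen[i] <= 0) next
      aTop <- age[par[i]]; aBot <- age[i]
      vTop <- st[par[i]]; vBot <- st[i]
      b0 <- max(0L, floor(aBot / binWidth)) + 1L
      b1 <- min(nb, ceiling(aTop / binWidth))
      for (b in b0:b1) {
        if (b1 < b0) break
        a1 <- min(aTop, b * binWidth)
        a0 <- max(aBot, (b - 1) * binWidth)
        v1 <- vBot + (vTop - vBot) * (a1 - aBot) / (aTop - aBot)
        v0 <- vBot + (vTop - vBot) * (a0 - aBot) / (aTop - aBot)
        lo[b] <- min(lo[b], v0, v1); hi[b] <- max(hi[b], v0, v1)
      }
    }
    list(lo = lo, hi = hi, nb = as.integer(nb))
  })
  nb <- max(vapply(envs, `[[`, 0L, "nb"))
  pad <- function(x, fill) c(x, rep(fill, nb - length(x)))
  loM <- vapply(envs, function(e) pad(e$lo, NA_real_), numeric(nb))
  hiM <- vapply(envs, function(e) pad(e$hi, NA_real_), numeric(nb))
  loM[!is.finite(loM)] <- NA; hiM[!is.finite(hiM)] <- NA
  data.frame(binStart = (seq_len(nb) - 1) * binWidth,
             binEnd = seq_len(nb) * binWidth,
             min = rowMeans(matrix(loM, nb), na.rm = TRUE),
             max = rowMeans(matrix(hiM, nb), na.rm = TRUE))
}

#' Credible intervals of clade ancestral states
#'
#' Equal-tailed 95\% intervals of the sampled ancestral state at each
#' clade's most recent common ancestor, pooled over replicate chains (and
#' so over the posterior tree sample).
#'
#' @param chains an `ftChain` or list of them.
#' @param clades a named list of character vectors of tip labels.
#' @param level credible level (default 0.95).
#' @return a data frame with `clade`, `mean`, `lower`, `upper`.
#' @export
ancestralCredibleIntervals <- function(chains, clades, level = 0.95) {
  if (inherits(chains, "ftChain")) chains <- list(chains)
  a <- (1 - level) / 2
  out <- lapply(names(clades), function(nm) {
    draws <- unlist(lapply(chains, function(chain) {
      tree <- chain$tree
      tips <- match(clades[[nm]], tree$phy$tip.label)
      tips <- tips[!is.na(tips)]
      if (length(tips) < 1) return(numeric(0))
      node <- if (length(tips) == 1) tips else ape::getMRCA(chain$tree$phy, tips)
      chain$states[postBurnin(chain), node]
    }))
    data.frame(clade = nm, mean = mean(draws),
               lower = unname(stats::quantile(draws, a)),
               upper = unname(stats::quantile(draws, 1 - a)))
  })
  do.call(rbind, out)
}
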