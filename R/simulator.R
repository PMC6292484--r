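#' Simulate a birth-death tree retaining extinct lineages
#'
#' Forward simulation of a constant-rate birth-death process in continuous
#' time, conditioned on reaching `nExtant` living lineages: the process is
#' run from a single ancestor until the living-lineage count first hits the
#' target, and the "present" is set at a uniformly drawn time during that
#' visit (which avoids a zero-length terminal pair at the stopping event).
#' Lineages that went extinct before the present are retained as fossil
#' tips at their true extinction times.
#'
#' @param birth speciation rate (events per lineage per Myr); must exceed
#'   `death`.
#' @param death extinction rate (>= 0).
#' @param nExtant target number of living tips.
#' @param minFossils resimulate until at least this many extinct tips exist
#'   (default 0).
#' @param maxTries bound on resimulation attempts.
#' @return a `timeTree`; extant tips are labelled `s1, s2, ...` and fossil
#'   tips `f1, f2, ...`.
#' @export
simulateTree <- function(birth, death, nExtant, minFossils = 0,
                         maxTries = 1000) {
  stopifnot(birth > death, death >= 0, nExtant >= 2)
  for (try in seq_len(maxTries)) {
    sim <- simulateBDOnce(birth, death, nExtant)
    if (is.null(sim)) next
    if (sum(!sim$extant) < minFossils) next
    return(sim)
  }
  stop("failed to simulate a tree matching the conditions in ", maxTries,
       " attempts")
}

simulateBDOnce <- function(birth, death, nExtant) {
  # lineage records: parent, start time, end time, status
  par <- c(NA_integer_); start <- c(0); end <- c(NA_real_)
  status <- c("alive")  # alive | extinct | split
  kids <- list(integer(0))
  alive <- 1L
  t <- 0
  totRate <- birth + death
  repeat {
    nA <- length(alive)
    if (nA == 0L) return(NULL)
    dt <- stats::rexp(1, nA * totRate)
    if (nA == nExtant) {
      # present falls uniformly within the waiting time at the target count
      present <- t + stats::runif(1) * dt
      end[alive] <- present
      status[alive] <- "extant"
      break
    }
    t <- t + dt
    lin <- alive[sample.int(nA, 1)]
    if (stats::runif(1) < birth / totRate) {
      for (k in 1:2) {
        par <- c(par, lin); start <- c(start, t); end <- c(end, NA_real_)
        status <- c(status, "alive"); kids <- c(kids, list(integer(0)))
        kids[[lin]] <- c(kids[[lin]], length(par))
      }
      end[lin] <- t; status[lin] <- "split"
      alive <- c(setdiff(alive, lin), length(par) - 1L, length(par))
    } else {
      end[lin] <- t; status[lin] <- "extinct"
      alive <- setdiff(alive, lin)
    }
  }
  if (status[1] != "split") return(NULL)  # origin must have speciated
  # assemble Newick recursively from the origin's two children (crown at the
  # first split; the stem is dropped)
  nExt <- 0L; nFos <- 0L
  rec <- function(i) {
    len <- end[i] - start[i]
    if (status[i] == "split")
      return(paste0("(", rec(kids[[i]][1]), ",", rec(kids[[i]][2]), "):",
                    format(len, digits = 12)))
    lab <- if (status[i] == "extant") {
      nExt <<- nExt + 1L; paste0("s", nExt)
    } else {
      nFos <<- nFos + 1L; paste0("f", nFos)
    }
    paste0(lab, ":", format(len, digits = 12))
  }
  nwk <- paste0("(", rec(kids[[1]][1]), ",", rec(kids[[1]][2]), ");")
  timeTree(ape::read.tree(text = nwk))
}

#' Subsample tips of a simulated tree
#'
#' `subsampleFossils()` keeps `nFossils` uniformly chosen fossil tips and
#' prunes the remaining extinct tips; `subsampleExtant()` keeps a uniform
#' fraction of the extant tips. Pruning merges the branches of resulting
#' degree-2 nodes, so path lengths among retained tips are preserved.
#'
#' @param tree a `timeTree`.
#' @param nFossils number of fossil tips to retain.
#' @param fraction fraction of extant tips to retain (0, 1].
#' @return the pruned `timeTree`.
#' @export
subsampleFossils <- function(tree, nFossils) {
  fossils <- which(!tree$extant)
  if (length(fossils) < nFossils)
    stop("tree has only ", length(fossils), " fossil tips")
  drop <- fossils
  if (nFossils > 0)
    drop <- setdiff(fossils, fossils[sample.int(length(fossils), nFossils)])
  if (!length(drop)) return(tree)
  timeTree(ape::drop.tip(tree$phy, drop))
}

#' @rdname subsampleFossils
#' @export
subsampleExtant <- function(tree, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(tree)
  ext <- which(tree$extant)
  keepN <- ceiling(fraction * length(ext))
  drop <- setdiff(ext, ext[sample.int(length(ext), keepN)])
  if (!length(drop)) return(tree)
  timeTree(ape::drop.tip(tree$phy, drop))
}

#' Simulate trait evolution along a tree
#'
#' Evolves one continuous trait from the root tipward: each child state is
#' the parent state plus a normal increment with mean `mu0 * t` and variance
#' `sigma2 * t`, with `sigma2` and `mu0` resolved per branch from the shift
#' configuration.
#'
#' @param tree a `timeTree`.
#' @param params a `bmParams` (rates, trends, shifts, root state).
#' @return a list of class `simReplicate`: `tree`, `traits` (named tip
#'   values), `states` (true values at every node), `params`, and
#'   `shiftCount` (named vector, true number of shifts per kind).
#' @export
simulateTraits <- function(tree, params) {
  stopifnot(inherits(tree, "timeTree"), inherits(params, "bmParams"))
  cls <- resolveClasses(tree, params)
  m <- nNodesTotal(tree)
  par <- parentOf(tree); blen <- branchLengthTo(tree)
  st <- rep(NA_real_, m)
  st[rootNode(tree)] <- params$rootState
  for (i in rev(postorderNodes(tree))) {
    if (i == rootNode(tree)) next
    t <- blen[i]
    st[i] <- st[par[i]] +
      if (t > 0) stats::rnorm(1, cls$trend[i] * t, sqrt(cls$rate[i] * t)) else 0
  }
  structure(list(tree = tree,
                 traits = stats::setNames(st[seq_len(tree$N)], tree$phy$tip.label),
                 states = st, params = params, shiftCount = nShifts(params)),
            class = "simReplicate")
}

#' Simulation scenarios for the validation study
#'
#' Builds the grid of simulation settings used to validate the sampler:
#' \describe{
#'   \item{`"sc1"`}{constant-rate Brownian motion, no trend (`mu0 = 0`).}
#'   \item{`"sc2"`}{constant rate with a positive or negative trend.}
#'   \item{`"shift1r"`, `"shift2r"`}{one / two true rate shifts (x8 or /8)
#'     anchored at clades holding 20-45\% of the tips. The floor keeps the
#'     expected evidence for a rate decrease (which grows much more slowly
#'     per contrast than for an increase) clear of the anchor-prior
#'     penalty.}
#'   \item{`"shift1t"`}{one true trend shift (offset of one Brownian SD per
#'     Myr).}
#'   \item{`"platy"`}{the platyrrhine-sized setting: 200 extant taxa of
#'     which 44\% are sampled, 20 fossils, trended traits.}
#' }
#' Background parameters per replicate: `sigma2 ~ U(0.1, 1)`; for trended
#' scenarios `mu0 = +/- U(0.2, 1) * sqrt(sigma2)`; root state 0. Trees use
#' birth 0.2 and death 0.1 per lineage per Myr.
#'
#' @param nFossils number of fossil tips retained (default 20).
#' @param scenarios character vector of scenario ids to include.
#' @return a list of `simScenario` objects (fields: `id`, `nExtant`,
#'   `extantFraction`, `nFossils`, `trend`, `nRateShifts`, `nTrendShifts`).
#' @export
makeScenarioGrid <- function(nFossils = 20,
                             scenarios = c("sc1", "sc2", "shift1r",
                                           "shift2r", "shift1t")) {
  mk <- function(id, nExtant, frac, nf, trend, nr, nt)
    structure(list(id = id, nExtant = nExtant, extantFraction = frac,
                   nFossils = nf, trend = trend, nRateShifts = nr,
                   nTrendShifts = nt, birth = 0.2, death = 0.1),
              class = "simScenario")
  all <- list(
    sc1     = mk("sc1", 50, 1, nFossils, FALSE, 0, 0),
    sc2     = mk("sc2", 50, 1, nFossils, TRUE, 0, 0),
    shift1r = mk("shift1r", 50, 1, nFossils, FALSE, 1, 0),
    shift2r = mk("shift2r", 50, 1, nFossils, FALSE, 2, 0),
    shift1t = mk("shift1t", 50, 1, nFossils, FALSE, 0, 1),
    platy   = mk("platy", 200, 0.44, nFossils, TRUE, 0, 0))
  all[scenarios]
}

# pick disjoint shift anchors among internal nodes whose clades hold
# between 20% and 45% of the tips
pickShiftAnchors <- function(tree, k) {
  m <- nNodesTotal(tree)
  root <- rootNode(tree)
  cand <- setdiff(seq.int(tree$N + 1L, m), root)
  sizes <- vapply(cand, function(nd) sum(cladeNodes(tree, nd) <= tree$N), 0)
  cand <- cand[sizes >= max(4, 0.2 * tree$N) & sizes <= 0.45 * tree$N]
  anchors <- integer(0)
  cand <- cand[sample.int(length(cand))]
  for (a in cand) {
    if (length(anchors) == k) break
    clade <- cladeNodes(tree, a)
    if (!any(anchors %in% clade) &&
        !any(vapply(anchors, function(b) a %in% cladeNodes(tree, b), TRUE)))
      anchors <- c(anchors, a)
  }
  if (length(anchors) < k) return(NULL)
  anchors
}

#' Simulate one validation replicate
#'
#' Simulates a birth-death tree, applies the scenario's extant and fossil
#' subsampling, draws background parameters and (for shifted scenarios)
#' shift anchors and values, and evolves the trait.
#'
#' @param scenario a `simScenario` from [makeScenarioGrid()].
#' @param seed optional integer seed; every replicate is fully reproducible
#'   from it.
#' @return a `simReplicate` (see [simulateTraits()]).
#' @export
simulateReplicate <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    tree <- simulateTree(scenario$birth, scenario$death, scenario$nExtant,
                         minFossils = max(scenario$nFossils, 1))
    if (scenario$extantFraction < 1)
      tree <- subsampleExtant(tree, scenario$extantFraction)
    tree <- subsampleFossils(tree, scenario$nFossils)
    sigma2 <- stats::runif(1, 0.1, 1)
    mu0 <- if (scenario$trend)
      sample(c(-1, 1), 1) * stats::runif(1, 0.2, 1) * sqrt(sigma2) else 0
    rateShifts <- trendShifts <- NULL
    nr <- scenario$nRateShifts; nt <- scenario$nTrendShifts
    if (nr + nt > 0) {
      anchors <- pickShiftAnchors(tree, nr + nt)
      if (is.null(anchors)) next  # tree shape unsuitable; resimulate
      if (nr > 0)
        rateShifts <- data.frame(
          anchor = anchors[seq_len(nr)],
          value = sigma2 * sample(c(8, 1 / 8), nr, replace = TRUE))
      if (nt > 0)
        trendShifts <- data.frame(
          anchor = anchors[nr + seq_len(nt)],
          value = mu0 + sample(c(-1, 1), nt, replace = TRUE) * sqrt(sigma2))
    }
    params <- bmParams(rateBg = sigma2, trendBg = mu0, rootState = 0,
                       rateShifts = rateShifts, trendShifts = trendShifts)
    return(simulateTraits(tree, params))
  }
}
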