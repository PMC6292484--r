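#' Chain settings for the trait-evolution sampler
#'
#' @param iterations total number of MCMC iterations.
#' @param sampleEvery thinning interval (a sample is written every this many
#'   iterations).
#' @param burnin fraction of samples discarded by the posterior summaries
#'   (default 0.25).
#' @param seed optional integer seed; fixed seeds give bit-reproducible
#'   chains.
#' @param d multiplier-proposal tuning parameter for rates (default 1.5).
#' @param windowRoot sliding-window width for the root state; default
#'   `2 * sd(tip values)`, tuned so that acceptance rates stay within
#'   (0.1, 0.8) on realistically sized problems.
#' @param windowTrend sliding-window width for trend parameters; default
#'   `sd(tip values) / treeHeight` (trends have units of trait per Myr, so
#'   the window is scaled by the tree height).
#' @param trendEnabled `NA` (default) enables trend estimation only when the
#'   tree contains fossil tips; on ultrametric (extant-only) trees the trend
#'   is unidentifiable and is fixed to 0.
#' @param priorOnly if `TRUE` the likelihood is dropped and the chain
#'   samples the prior (used for validation).
#' @param maxEvents abort guard for one birth-death sweep (default 100).
#' @param engine `"cpp"` (default) or `"R"` (reference implementation, for
#'   small problems and cross-checks).
#' @return an object of class `ftSettings`.
#' @export
chainSettings <- function(iterations = 500000, sampleEvery = 500,
                          burnin = 0.25, seed = NULL, d = 1.5,
                          windowRoot = NULL, windowTrend = NULL,
                          trendEnabled = NA, priorOnly = FALSE,
                          maxEvents = 100, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(iterations >= sampleEvery, burnin >= 0, burnin < 1, d > 1)
  structure(list(iterations = as.integer(iterations),
                 sampleEvery = as.integer(sampleEvery), burnin = burnin,
                 seed = seed, d = d, windowRoot = windowRoot,
                 windowTrend = windowTrend, trendEnabled = trendEnabled,
                 priorOnly = priorOnly, maxEvents = as.integer(maxEvents),
                 engine = engine),
            class = "ftSettings")
}

initialStates <- function(tree, bound) {
  # internal states by child-averaging (a midpoint interpolation of the
  # observed values, propagated rootward)
  st <- bound$values
  ch <- childrenOf(tree)
  for (i in postorderNodes(tree)) {
    if (bound$observed[i] || i <= tree$N) next
    kv <- st[ch[[i]]]
    st[i] <- mean(kv[!is.na(kv)])
  }
  st
}

fillPriors <- function(priors, tree, tipValues) {
  if (is.null(priors$ratePriorRate)) {
    s2 <- stats::var(tipValues) / tree$height
    if (!is.finite(s2) || s2 <= 0) s2 <- 1
    priors$ratePriorRate <- 1 / s2
  }
  priors
}

#' Run the trait-evolution MCMC on one tree
#'
#' One iteration performs, in order: a birth-death sweep over the shift
#' configuration, a multiplier Metropolis-Hastings update of every rate
#' class, a sliding-window update of every trend class (when trends are
#' enabled), a sliding-window update of the root state (flat prior), and a
#' Gibbs sweep over all unobserved ancestral states.
#'
#' @param tree a `timeTree`.
#' @param traits named numeric vector of tip trait values.
#' @param priors an [priorConfig()] object.
#' @param settings a [chainSettings()] object.
#' @return an object of class `ftChain`: a list with `trace` (data frame:
#'   iteration, logLik, logPrior, kRate, kTrend, sigma2Bg, mu0Bg,
#'   rootState), `states` (samples x nodes matrix of sampled states),
#'   `shifts` (per-sample data frame of kind/anchor/value), `accept`
#'   (per-move acceptance rates), `tree`, `settings`, `priors`.
#' @export
runChain <- function(tree, traits, priors = priorConfig(),
                     settings = chainSettings()) {
  stopifnot(inherits(tree, "timeTree"))
  bound <- bindTraits(tree, traits)
  bound <- fixSampledAncestors(tree, bound)
  tipValues <- bound$values[seq_len(tree$N)]
  priors <- fillPriors(priors, tree, tipValues)

  trendEnabled <- settings$trendEnabled
  if (is.na(trendEnabled)) trendEnabled <- any(isFossilTip(tree))
  sdTip <- stats::sd(tipValues)
  if (!is.finite(sdTip) || sdTip <= 0) sdTip <- 1
  wRoot <- settings$windowRoot
  if (is.null(wRoot)) wRoot <- 2 * sdTip
  wTrend <- settings$windowTrend
  if (is.null(wTrend)) wTrend <- sdTip / tree$height

  sigma2Init <- stats::var(tipValues) / tree$height
  if (!is.finite(sigma2Init) || sigma2Init <= 0) sigma2Init <- 1

  if (!is.null(settings$seed)) set.seed(settings$seed)
  init <- initialStates(tree, bound)
  # guard: degenerate start (all equal tip values etc.) -> jitter
  tries <- 0
  while (!all(is.finite(init)) && tries < 10) {
    init[!is.finite(init)] <- stats::rnorm(sum(!is.finite(init)), mean(tipValues), sdTip)
    tries <- tries + 1
  }
  if (!all(is.finite(init))) stop("could not initialize ancestral states")

  m <- nNodesTotal(tree)
  par <- parentOf(tree); blen <- branchLengthTo(tree)
  ch <- childrenOf(tree)
  c1 <- vapply(ch, function(k) if (length(k) >= 1) k[1] else NA_integer_, 0L)
  c2 <- vapply(ch, function(k) if (length(k) >= 2) k[2] else NA_integer_, 0L)

  if (settings$engine == "cpp") {
    res <- chain_mcmc_cpp(
      tree$N, rootNode(tree), par, c1, c2, blen, postorderNodes(tree),
      bound$observed, init, sigma2Init, trendEnabled, settings$priorOnly,
      priors$deathPolicy == "stephens", priors$ratePriorRate,
      priors$trendPriorSD, priors$trendProposalSD, priors$shiftPoissonRate,
      settings$d, wRoot, wTrend,
      settings$iterations, settings$sampleEvery, settings$maxEvents)
    trace <- as.data.frame(res$trace)
    names(trace) <- c("iteration", "logLik", "logPrior", "kRate", "kTrend",
                      "sigma2Bg", "mu0Bg", "rootState")
    shifts <- lapply(res$shifts, function(sh) {
      sh <- matrix(sh, ncol = 3)
      data.frame(kind = ifelse(sh[, 1] == 0, "rate", "trend"),
                 anchor = as.integer(sh[, 2]), value = sh[, 3])
    })
    states <- res$states
    acc <- res$accept
    aborted <- res$abortedSweeps
  } else {
    res <- runChainR(tree, bound, init, sigma2Init, priors, settings,
                     trendEnabled, wRoot, wTrend)
    trace <- res$trace; shifts <- res$shifts; states <- res$states
    acc <- res$accept; aborted <- res$abortedSweeps
  }

  acceptRates <- c(rate = unname(acc["rateAcc"] / max(acc["rateProp"], 1)),
                   trend = unname(acc["trendAcc"] / max(acc["trendProp"], 1)),
                   root = unname(acc["rootAcc"] / max(acc["rootProp"], 1)))
  structure(list(trace = trace, states = states, shifts = shifts,
                 accept = acceptRates, acceptCounts = acc,
                 abortedSweeps = aborted, trendEnabled = trendEnabled,
                 tree = tree, settings = settings, priors = priors),
            class = "ftChain")
}

# sampled-ancestor preprocessing: a zero-length terminal branch fixes the
# parent node's state to the observed tip value
fixSampledAncestors <- function(tree, bound) {
  e <- tree$phy$edge; len <- tree$phy$edge.length
  for (i in seq_len(nrow(e))) {
    if (len[i] <= 0 && bound$observed[e[i, 2]] && !bound$observed[e[i, 1]]) {
      bound$values[e[i, 1]] <- bound$values[e[i, 2]]
      bound$observed[e[i, 1]] <- TRUE
    }
  }
  bound
}

# reference R implementation of the full iteration schedule (small problems)
runChainR <- function(tree, bound, init, sigma2Init, priors, settings,
                      trendEnabled, wRoot, wTrend) {
  params <- bmParams(rateBg = sigma2Init, trendBg = 0, rootState = init[rootNode(tree)])
  states <- list(values = init, observed = bound$observed)
  root <- rootNode(tree)
  nS <- settings$iterations %/% settings$sampleEvery
  trace <- matrix(NA_real_, nS, 8)
  stMat <- matrix(NA_real_, nS, length(init))
  shifts <- vector("list", nS)
  accP <- c(rateProp = 0, rateAcc = 0, trendProp = 0, trendAcc = 0,
            rootProp = 0, rootAcc = 0)
  ll <- function(p) if (settings$priorOnly) 0 else treeLogLik(tree, states$values, p)
  s <- 0; aborted <- 0
  for (iter in seq_len(settings$iterations)) {
    params <- withCallingHandlers(
      bdmcmcStep(tree, params, states, priors, trendEnabled,
                 settings$priorOnly, settings$maxEvents),
      warning = function(w) { aborted <<- aborted + 1; invokeRestart("muffleWarning") })
    # rate classes (background first, then each shift)
    for (j in 0:nrow(params$rateShifts)) {
      cur <- if (j == 0) params$rateBg else params$rateShifts$value[j]
      pr <- multiplierProposal(cur, settings$d)
      cand <- params
      if (j == 0) cand$rateBg <- pr$proposal else cand$rateShifts$value[j] <- pr$proposal
      dpost <- ll(cand) - ll(params) - priors$ratePriorRate * (pr$proposal - cur)
      accP["rateProp"] <- accP["rateProp"] + 1
      if (mhAccept(0, dpost, pr$logHastings)) {
        params <- cand; accP["rateAcc"] <- accP["rateAcc"] + 1
      }
    }
    if (trendEnabled) {
      for (j in 0:nrow(params$trendShifts)) {
        cur <- if (j == 0) params$trendBg else params$trendShifts$value[j]
        pr <- slidingWindowProposal(cur, wTrend)
        cand <- params
        if (j == 0) cand$trendBg <- pr$proposal else cand$trendShifts$value[j] <- pr$proposal
        dpost <- ll(cand) - ll(params) +
          stats::dnorm(pr$proposal, 0, priors$trendPriorSD, log = TRUE) -
          stats::dnorm(cur, 0, priors$trendPriorSD, log = TRUE)
        accP["trendProp"] <- accP["trendProp"] + 1
        if (mhAccept(0, dpost, 0)) {
          params <- cand; accP["trendAcc"] <- accP["trendAcc"] + 1
        }
      }
    }
    if (!states$observed[root]) {
      pr <- slidingWindowProposal(states$values[root], wRoot)
      old <- states$values[root]
      llOld <- ll(params)
      states$values[root] <- pr$proposal
      llNew <- ll(params)
      accP["rootProp"] <- accP["rootProp"] + 1
      if (mhAccept(llOld, llNew, 0)) accP["rootAcc"] <- accP["rootAcc"] + 1
      else states$values[root] <- old
    }
    states <- gibbsSweep(tree, states, params)
    if (iter %% settings$sampleEvery == 0) {
      s <- s + 1
      k <- nShifts(params)
      trace[s, ] <- c(iter, ll(params), NA, k["rate"], k["trend"],
                      params$rateBg, params$trendBg, states$values[root])
      stMat[s, ] <- states$values
      shifts[[s]] <- rbind(
        if (k["rate"]) data.frame(kind = "rate", anchor = params$rateShifts$anchor,
                                  value = params$rateShifts$value),
        if (k["trend"]) data.frame(kind = "trend", anchor = params$trendShifts$anchor,
                                   value = params$trendShifts$value),
        data.frame(kind = character(0), anchor = integer(0), value = numeric(0)))
    }
  }
  trace <- as.data.frame(trace)
  names(trace) <- c("iteration", "logLik", "logPrior", "kRate", "kTrend",
                    "sigma2Bg", "mu0Bg", "rootState")
  list(trace = trace, states = stMat, shifts = shifts, accept = accP,
       abortedSweeps = aborted)
}

#' @export
print.ftChain <- function(x, ...) {
  cat(sprintf("ftChain: %d samples (%d iterations), tree with %d tips\n",
              nrow(x$trace), x$settings$iterations, x$tree$N))
  cat(sprintf("  acceptance: rate %.2f, trend %.2f, root %.2f; trend %s\n",
              x$accept["rate"], x$accept["trend"], x$accept["root"],
              if (x$trendEnabled) "estimated" else "fixed to 0"))
  pm <- posteriorMeans(x)
  cat(sprintf("  posterior mean sigma2 = %.4g, mu0 = %.4g, root state = %.4g\n",
              pm$sigma2, pm$mu0, pm$rootState))
  cat(sprintf("  posterior mode shift count = %d\n", shiftCountMode(x)))
  invisible(x)
}

postBurnin <- function(chain) {
  n <- nrow(chain$trace)
  keep <- seq.int(floor(chain$settings$burnin * n) + 1, n)
  keep
}

#' Posterior summaries of a chain
#'
#' `posteriorMeans()` returns post-burn-in posterior means of the background
#' rate, background trend, root state and all node states.
#' `shiftCountMode()` returns the posterior-mode total number of shifts
#' (rate + trend), ties resolved toward the smaller count.
#'
#' @param chain an `ftChain`.
#' @return for `posteriorMeans()`, a list with `sigma2`, `mu0`, `rootState`
#'   and `states`; for `shiftCountMode()`, an integer.
#' @export
posteriorMeans <- function(chain) {
  keep <- postBurnin(chain)
  list(sigma2 = mean(chain$trace$sigma2Bg[keep]),
       mu0 = mean(chain$trace$mu0Bg[keep]),
       rootState = mean(chain$trace$rootState[keep]),
       states = colMeans(chain$states[keep, , drop = FALSE]))
}

#' @rdname posteriorMeans
#' @export
shiftCountMode <- function(chain) {
  keep <- postBurnin(chain)
  k <- chain$trace$kRate[keep] + chain$trace$kTrend[keep]
  tab <- table(k)
  best <- as.integer(names(tab)[tab == max(tab)])
  min(best)  # tie-break toward the smaller count
}

#' Run independent chains over a posterior tree sample
#'
#' @param trees a list of `timeTree` objects (e.g. from [readTimeTrees()]).
#' @param traits named numeric vector of tip trait values (tips absent from
#'   a given tree are ignored for that tree).
#' @param priors an [priorConfig()].
#' @param settings a [chainSettings()]; per-tree seeds are derived from
#'   `settings$seed`.
#' @return a list of `ftChain` objects (a failed tree yields `NULL`, with a
#'   warning).
#' @export
runReplicates <- function(trees, traits, priors = priorConfig(),
                          settings = chainSettings()) {
  stopifnot(length(trees) >= 1)
  baseSeed <- if (is.null(settings$seed)) 1L else as.integer(settings$seed)
  lapply(seq_along(trees), function(i) {
    s <- settings
    s$seed <- (baseSeed + 7919L * i) %% .Machine$integer.max
    tr <- trees[[i]]
    tv <- traits[intersect(names(traits), tr$phy$tip.label)]
    tryCatch(runChain(tr, tv, priors, s),
             error = function(e) {
               warning("replicate ", i, " failed: ", conditionMessage(e))
               NULL
             })
  })
}
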