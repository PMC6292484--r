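#' Run the simulation-validation harness for one scenario
#'
#' Simulates `nReplicates` data sets under a scenario, runs the sampler on
#' each, and summarizes parameter and ancestral-state recovery: MAPE of the
#' posterior-mean background rate, MAE of the posterior-mean background
#' trend, the per-replicate coefficient of determination of posterior-mean
#' internal states against the simulated truth, and the frequency with
#' which the posterior-mode shift count equals the true count.
#'
#' @param scenario a `simScenario` (see [makeScenarioGrid()]).
#' @param nReplicates number of independent replicates.
#' @param settings a [chainSettings()]; per-replicate seeds are derived
#'   from `seed`.
#' @param seed master seed for the simulation + analysis pipeline.
#' @param trendEnabled passed through to the sampler (default `NA`:
#'   enabled when fossils are present).
#' @param keepChains if `TRUE` the individual `ftChain` objects are
#'   returned too (memory permitting).
#' @return a list of class `accuracyReport`: per-replicate estimates and
#'   truths, plus `mapeSigma2`, `maeMu0`, `meanR2`, `shiftRecovery`.
#' @export
runValidation <- function(scenario, nReplicates = 15,
                          settings = chainSettings(iterations = 200000,
                                                   sampleEvery = 200),
                          seed = 1, trendEnabled = NA, keepChains = FALSE) {
  seed <- as.integer(seed)
  reps <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    simSeed <- (seed + 104729L * r) %% 2100000000L
    sim <- simulateReplicate(scenario, seed = simSeed)
    s <- settings
    s$seed <- (simSeed + 17L) %% 2100000000L
    s$trendEnabled <- trendEnabled
    chain <- runChain(sim$tree, sim$traits, settings = s)
    pm <- posteriorMeans(chain)
    internal <- seq.int(sim$tree$N + 1L, nNodesTotal(sim$tree))
    reps[[r]] <- list(
      trueSigma2 = sim$params$rateBg, estSigma2 = pm$sigma2,
      trueMu0 = sim$params$trendBg, estMu0 = pm$mu0,
      r2 = rSquared(sim$states[internal], pm$states[internal]),
      trueShifts = sum(sim$shiftCount), modeShifts = shiftCountMode(chain),
      accept = chain$accept,
      chain = if (keepChains) chain else NULL)
  }
  g <- function(f) vapply(reps, `[[`, 0, f)
  structure(list(
    scenario = scenario$id, nReplicates = nReplicates,
    settings = settings, replicates = reps,
    trueSigma2 = g("trueSigma2"), estSigma2 = g("estSigma2"),
    trueMu0 = g("trueMu0"), estMu0 = g("estMu0"), r2 = g("r2"),
    trueShifts = as.integer(g("trueShifts")),
    modeShifts = as.integer(g("modeShifts")),
    mapeSigma2 = mape(g("trueSigma2"), g("estSigma2")),
    maeMu0 = mae(g("trueMu0"), g("estMu0")),
    meanR2 = mean(g("r2")),
    shiftRecovery = shiftRecovery(g("trueShifts"), g("modeShifts"))),
    class = "accuracyReport")
}

#' @export
print.accuracyReport <- function(x, ...) {
  cat(sprintf("accuracyReport [%s], %d replicates:\n", x$scenario, x$nReplicates))
  cat(sprintf("  MAPE(sigma2) = %.3f   MAE(mu0) = %.3f\n", x$mapeSigma2, x$maeMu0))
  cat(sprintf("  mean R2(ancestral states) = %.3f\n", x$meanR2))
  cat(sprintf("  shift-count recovery = %.1f%%\n", 100 * x$shiftRecovery))
  invisible(x)
}
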