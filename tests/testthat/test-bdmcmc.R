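test_that("anchor bookkeeping matches the n-2 shift capacity", {
  tr <- fiveTipTree()  # binary, 5 tips: 9 nodes, 8 non-root anchors
  p <- bmParams(rateBg = 1)
  expect_length(eligibleAnchors(tr, p, "rate"), 8)
  expect_length(eligibleAnchors(tr, p, "trend"), 8)
  p2 <- bmParams(rateBg = 1, rateShifts = data.frame(anchor = 2, value = 3))
  expect_length(eligibleAnchors(tr, p2, "rate"), 7)
  expect_length(eligibleAnchors(tr, p2, "trend"), 8)
})

test_that("births draw anchors and values reproducibly and respect saturation", {
  tr <- fiveTipTree()
  pr <- priorConfig(ratePriorRate = 1)
  p <- bmParams(rateBg = 1)
  set.seed(41); b1 <- proposeBirth(tr, p, pr)
  set.seed(41); b2 <- proposeBirth(tr, p, pr)
  expect_identical(b1, b2)
  expect_equal(sum(nShifts(b1)), 1)
  # saturated configuration: a birth is a no-op
  full <- bmParams(rateBg = 1,
                   rateShifts = data.frame(anchor = setdiff(1:9, 6), value = rep(1, 8)),
                   trendShifts = data.frame(anchor = setdiff(1:9, 6), value = rep(0, 8)))
  set.seed(42)
  expect_identical(proposeBirth(tr, full, pr), full)
})

test_that("death rates follow the likelihood ratio with the stated corrections", {
  tr <- fiveTipTree()
  set.seed(43)
  st <- rnorm(9)
  prLik <- priorConfig(ratePriorRate = 1, deathPolicy = "likelihood_only")
  prSte <- priorConfig(ratePriorRate = 1, deathPolicy = "stephens")

  # a no-op shift (value equal to the background) has likelihood ratio 1
  noop <- bmParams(rateBg = 0.7, rateShifts = data.frame(anchor = 7, value = 0.7))
  expect_equal(deathRate(tr, noop, st, "rate", 1, prLik), 1)
  corr <- dexp(0.7, 1 / 0.7) / dexp(0.7, 1)
  expect_equal(deathRate(tr, noop, st, "rate", 1, prSte), corr)

  # with the clade's data generated under a strong shift, the shift's death
  # rate is tiny; an absurd shift dies almost surely
  set.seed(44)
  tr2 <- smallSimTree(seed = 44, nExtant = 15, nFossils = 4)
  a <- fossiltrait:::pickShiftAnchors(tr2, 1)
  truth <- bmParams(rateBg = 0.3, rateShifts = data.frame(anchor = a, value = 0.3 * 20))
  sim <- simulateTraits(tr2, truth)
  expect_lt(deathRate(tr2, truth, sim$states, "rate", 1, prLik), 1e-4)
  bad <- bmParams(rateBg = 0.3, rateShifts = data.frame(anchor = a, value = 0.3 / 50))
  expect_gt(deathRate(tr2, bad, sim$states, "rate", 1, prLik), 1e4)

  # removal rebinds the clade to its parent class, keeping nested shifts
  nested <- bmParams(rateBg = 1,
                     rateShifts = data.frame(anchor = c(7, 8), value = c(5, 2)))
  without <- fossiltrait:::removeShift(nested, "rate", 1)
  expect_equal(without$rateShifts$anchor, 8)
})

test_that("one birth-death sweep is reproducible and bounded", {
  tr <- fiveTipTree()
  tv <- c(A = 0.1, B = 0.5, C = -0.2, D = 1, E = 0.8)
  b <- bindTraits(tr, tv); st <- b$values; st[6:9] <- 0.3
  pr <- priorConfig(ratePriorRate = 1)
  p <- bmParams(rateBg = 0.5)
  set.seed(45); r1 <- bdmcmcStep(tr, p, st, pr)
  set.seed(45); r2 <- bdmcmcStep(tr, p, st, pr)
  expect_identical(r1, r2)
})

test_that("with the likelihood disabled the shift count follows its Poisson prior", {
  set.seed(46)
  tr <- smallSimTree(seed = 46, nExtant = 10, nFossils = 2)
  tv <- setNames(rnorm(tr$N), tr$phy$tip.label)
  ch <- runChain(tr, tv, priorConfig(ratePriorRate = 2),
                 chainSettings(iterations = 3e5, sampleEvery = 30, seed = 47,
                               priorOnly = TRUE, trendEnabled = TRUE,
                               windowTrend = 20, windowRoot = 1))
  k <- ch$trace$kRate + ch$trace$kTrend
  k <- k[-seq_len(1000)]
  obs <- table(factor(pmin(k, 4), levels = 0:4))
  expc <- dpois(0:4, 1); expc[5] <- 1 - sum(expc[1:4])
  chi <- suppressWarnings(chisq.test(obs, p = expc))
  # thinned but still autocorrelated draws: use an inflated critical value
  expect_gt(chi$p.value, 1e-4)
  expect_equal(mean(k), 1, tolerance = 0.1)
})

test_that("the sampled shift-count posterior matches an exact marginal oracle", {
  # small tree, one strong rate up-shift; compare the chain's P(k = 0,1,2)
  # (rate shifts only, trend fixed) against numerical integration of the
  # marginal likelihood over background rate, shift values and anchors
  set.seed(60)
  tree <- simulateTree(0.25, 0.1, 8, minFossils = 2)
  tree <- subsampleFossils(tree, 2)
  N <- tree$N; M <- N + tree$phy$Nnode
  sizes <- vapply((N + 2):M, function(nd) sum(cladeNodes(tree, nd) <= N), 0)
  a <- ((N + 2):M)[sizes >= 3 & sizes <= 6][1]
  pars <- bmParams(rateBg = 0.4, rateShifts = data.frame(anchor = a, value = 3.2))
  sim <- simulateTraits(tree, pars)
  y <- sim$traits
  geo <- marginalFlatRootSetup(tree)
  rr <- 1 / (var(y) / tree$height)
  root <- N + 1L
  anchors <- setdiff(1:M, root); A <- length(anchors)
  clades <- lapply(anchors, function(x) cladeNodes(tree, x))
  lgs <- seq(log(0.01), log(30), length.out = 45); ws <- diff(lgs)[1]
  ml0 <- logSumExp(vapply(lgs, function(ls) {
    s2 <- exp(ls)
    marginalFlatRoot(geo, y, rep(s2, M)) + dexp(s2, rr, log = TRUE) + ls
  }, 0)) + log(ws)
  ml1a <- vapply(seq_len(A), function(ai) {
    out <- outer(lgs, lgs, Vectorize(function(ls, lv) {
      s2 <- exp(ls); v <- exp(lv)
      rate <- rep(s2, M); rate[clades[[ai]]] <- v
      marginalFlatRoot(geo, y, rate) + dexp(s2, rr, log = TRUE) + ls +
        dexp(v, rr, log = TRUE) + lv
    }))
    logSumExp(as.vector(out)) + 2 * log(ws)
  }, 0)
  ml1 <- logSumExp(ml1a) - log(A)
  # coarse 3-D grid for k = 2, bias-corrected against its own k = 0 value
  lg2 <- seq(log(0.01), log(30), length.out = 12); w2 <- diff(lg2)[1]
  prs <- t(combn(seq_len(A), 2))
  ml2p <- apply(prs, 1, function(pq) {
    c1 <- clades[[pq[1]]]; c2 <- clades[[pq[2]]]
    innerFirst <- anchors[pq[1]] %in% c2  # anchor 1 nested inside clade 2
    vals <- numeric(length(lg2)^3); v <- 0L
    for (ls in lg2) for (l1 in lg2) for (l2 in lg2) {
      rate <- rep(exp(ls), M)
      if (innerFirst) { rate[c2] <- exp(l2); rate[c1] <- exp(l1) }
      else { rate[c1] <- exp(l1); rate[c2] <- exp(l2) }
      v <- v + 1L
      vals[v] <- marginalFlatRoot(geo, y, rate) +
        dexp(exp(ls), rr, log = TRUE) + ls +
        dexp(exp(l1), rr, log = TRUE) + l1 +
        dexp(exp(l2), rr, log = TRUE) + l2
    }
    logSumExp(vals) + 3 * log(w2)
  })
  ml0c <- logSumExp(vapply(lg2, function(ls) {
    s2 <- exp(ls)
    marginalFlatRoot(geo, y, rep(s2, M)) + dexp(s2, rr, log = TRUE) + ls
  }, 0)) + log(w2)
  ml2 <- logSumExp(ml2p) - log(A * (A - 1) / 2) + (ml0 - ml0c)
  lpost <- c(ml0, ml1, ml2) + dpois(0:2, 1, log = TRUE)
  oracle <- exp(lpost - logSumExp(lpost))

  ch <- runChain(tree, y,
                 settings = chainSettings(iterations = 4e5, sampleEvery = 100,
                                          seed = 5, trendEnabled = FALSE))
  k <- ch$trace$kRate[-seq_len(1000)]
  got <- as.numeric(table(factor(k, levels = 0:2))) / sum(k <= 2)
  expect_lt(max(abs(got - oracle)), 0.12)
  # and the posterior mode identifies the single true shift
  expect_equal(shiftCountMode(ch), 1)
})
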