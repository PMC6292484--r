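test_that("conditional posterior combines the three neighbouring normals", {
  # symmetric case: equal branch lengths, no trend -> precision-weighted mean
  tr <- fiveTipTree()
  # build a 4-tip tree where internal node 6 has parent root and two tips
  tq <- readTimeTree(text = "((A:1,B:1):1,C:2);")
  p <- bmParams(rateBg = 0.5)
  st <- c(1, 2, 0, 3, NA)  # A=1, B=2, C unused, root=3
  cp <- conditionalPosterior(tq, 5, st, p)
  expect_equal(cp$mean, 2)            # (1 + 2 + 3) / 3
  expect_equal(cp$var, 0.5 * 1 / 3)   # sigma2 * t / 3

  # trend signs: ancestor adds mu*t, descendants subtract it
  m <- 0.8
  pT <- bmParams(rateBg = 0.5, trendBg = m)
  st0 <- c(0, 0, 0, 0, NA)
  cpT <- conditionalPosterior(tq, 5, st0, pT)
  expect_equal(cpT$mean, -m * 1 / 3)

  # as the parent branch grows, the conditional tends to the two-descendant
  # combination
  tLong <- readTimeTree(text = "((A:1,B:1):1e9,C:2e9);")
  cpL <- conditionalPosterior(tLong, 5, st, p)
  expect_equal(cpL$mean, (1 + 2) / 2, tolerance = 1e-6)
  expect_equal(cpL$var, 0.5 / 2, tolerance = 1e-6)
})

test_that("with shifts each neighbouring branch uses its own parameters", {
  tq <- readTimeTree(text = "((A:1,B:2):1,C:2);")
  # rate shift on A's branch, trend shift on B's branch only
  p <- bmParams(rateBg = 1, trendBg = 0,
                rateShifts = data.frame(anchor = 1, value = 4),
                trendShifts = data.frame(anchor = 2, value = 0.6))
  st <- c(1.2, -0.4, 0, 0.9, NA)
  cp <- conditionalPosterior(tq, 5, st, p)
  prec <- 1 / (1 * 1) + 1 / (4 * 1) + 1 / (1 * 2)
  mean <- ((st[4] + 0 * 1) / 1 + (st[1] - 0 * 1) / 4 + (st[2] - 0.6 * 2) / 2) / prec
  expect_equal(cp$var, 1 / prec)
  expect_equal(cp$mean, mean)
})

test_that("conditional draws match the normalized three-density product", {
  # numeric-integration oracle: normalize the product on a grid, compare the
  # sampled distribution by a KS test
  tq <- readTimeTree(text = "((A:0.7,B:1.6):0.9,C:2.5);")
  p <- bmParams(rateBg = 0.8, trendBg = 0.35)
  st <- c(0.5, -1.2, 0, 1.1, NA)
  cp <- conditionalPosterior(tq, 5, st, p)
  grid <- seq(cp$mean - 8 * sqrt(cp$var), cp$mean + 8 * sqrt(cp$var),
              length.out = 8192)
  lp <- dnorm(grid, st[4] + 0.35 * 0.9, sqrt(0.8 * 0.9), log = TRUE) +
        dnorm(grid, st[1] - 0.35 * 0.7, sqrt(0.8 * 0.7), log = TRUE) +
        dnorm(grid, st[2] - 0.35 * 1.6, sqrt(0.8 * 1.6), log = TRUE)
  w <- exp(lp - max(lp)); cdf <- cumsum(w) / sum(w)
  oracleCdf <- approxfun(grid, cdf, yleft = 0, yright = 1)
  set.seed(99)
  draws <- rnorm(1e5, cp$mean, sqrt(cp$var))
  ks <- suppressWarnings(ks.test(draws, oracleCdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("gibbs sweeps leave observed states alone and are seed-reproducible", {
  tr <- fossilTree()
  tv <- c(A = 0.3, B = 1.2, C = -0.5)
  p <- bmParams(rateBg = 0.5)
  b <- bindTraits(tr, tv)
  b$values[4:5] <- c(0.2, 0.4)
  bAll <- b; bAll$observed[] <- TRUE
  expect_equal(gibbsSweep(tr, bAll, p), bAll)  # nothing to update
  set.seed(5); s1 <- gibbsSweep(tr, b, p)
  set.seed(5); s2 <- gibbsSweep(tr, b, p)
  expect_identical(s1, s2)
  expect_equal(s1$values[1:3], b$values[1:3])  # tips untouched
})

test_that("long-run Gibbs means match the marginal-MVN conditional means", {
  # condition on the tips and the root; the sampled internal states must
  # converge to the Gaussian conditional expectation
  tr <- readTimeTree(text = "((A:1,B:0.6):1,(C:1.5,D:2):0.5);")
  s2 <- 0.7; m0 <- 0.3; r0 <- 1
  p <- bmParams(rateBg = s2, trendBg = m0, rootState = r0)
  tv <- c(A = 1.2, B = 0.4, C = 2.2, D = 0.1)
  b <- bindTraits(tr, tv)
  root <- 5L
  b$values[root] <- r0; b$observed[root] <- TRUE
  st <- b; st$values[is.na(st$values)] <- mean(tv)
  set.seed(21)
  nS <- 12000; keep <- 1001:nS
  acc <- matrix(0, nS, 2)
  for (i in seq_len(nS)) { st <- gibbsSweep(tr, st, p); acc[i, ] <- st$values[6:7] }
  gm <- colMeans(acc[keep, ])
  # oracle: joint normal of all node states given the root, conditioned on tips
  depth <- tr$height - tr$age
  mr <- ape::mrca(tr$phy, full = TRUE)
  M <- 7
  S <- matrix(0, M, M)
  for (i in 1:M) for (j in 1:M) S[i, j] <- s2 * depth[mr[i, j]]
  mu <- r0 + m0 * depth
  iO <- 1:4; iU <- 6:7
  condMean <- mu[iU] + S[iU, iO] %*% solve(S[iO, iO], tv - mu[iO])
  condVar <- diag(S[iU, iU] - S[iU, iO] %*% solve(S[iO, iO], S[iO, iU]))
  # batch-means Monte Carlo SE
  bm <- apply(acc[keep, ], 2, function(x) {
    b <- colMeans(matrix(x[1:11000], nrow = 1100)); sd(b) / sqrt(length(b))
  })
  expect_true(all(abs(gm - condMean) < 3 * bm + 1e-3))
  # moments stable between early and late halves (stationarity)
  h1 <- colMeans(acc[1001:6000, ]); h2 <- colMeans(acc[7001:12000, ])
  expect_true(all(abs(h1 - h2) < 4 * bm + 4e-3))
  # sampled variances near the analytic conditional variances
  gv <- apply(acc[keep, ], 2, var)
  expect_true(all(abs(gv / condVar - 1) < 0.15))
})
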