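test_that("branch log-density matches the closed-form normal", {
  expect_equal(branchLogDensity(0, 0, 1, 1, 0), -0.5 * log(2 * pi))
  # the density is maximized at the trend-shifted mean
  xs <- seq(-2, 2, length.out = 101)
  dens <- branchLogDensity(0.3, 0.3 + 0.4 * 2 + xs, t = 2, sigma2 = 0.7, mu0 = 0.4)
  expect_equal(xs[which.max(dens)], 0)
  # a trend shifts the mean by mu0 * t
  expect_equal(branchLogDensity(0, 1, 1, 1, 1), branchLogDensity(0, 0, 1, 1, 0))
  expect_error(branchLogDensity(0, 0, 0, 1), "branch length")
  expect_error(branchLogDensity(0, 0, 1, -1), "sigma2")
})

test_that("shift classes resolve by nearest ancestral anchor", {
  tr <- fiveTipTree()
  root <- 6L
  par <- parentOf(tr)
  kids <- childrenOf(tr)[[root]]
  # empty config: all background
  p0 <- bmParams(rateBg = 1, trendBg = 0.5)
  cls <- resolveClasses(tr, p0)
  expect_true(all(cls$rate == 1) && all(cls$trend == 0.5))
  # one shift at a child of the root splits the tree in two classes
  p1 <- bmParams(rateBg = 1, rateShifts = data.frame(anchor = kids[1], value = 9))
  cls <- resolveClasses(tr, p1)
  inClade <- cladeNodes(tr, kids[1])
  expect_true(all(cls$rate[inClade] == 9))
  expect_true(all(cls$rate[setdiff(seq_along(cls$rate), inClade)] == 1))
  # nested shift overrides the outer one
  sub <- setdiff(inClade, c(kids[1], seq_len(tr$N)))[1]
  p2 <- bmParams(rateBg = 1,
                 rateShifts = data.frame(anchor = c(kids[1], sub), value = c(9, 4)))
  cls <- resolveClasses(tr, p2)
  expect_true(all(cls$rate[cladeNodes(tr, sub)] == 4))
  expect_true(all(cls$rate[setdiff(inClade, cladeNodes(tr, sub))] == 9))
  expect_error(resolveClasses(tr, bmParams(1, rateShifts = data.frame(anchor = root, value = 2))),
               "non-root")
})

test_that("augmented likelihood sums branch densities and is invariant as expected", {
  # 2-tip cherry with zero states: two standard-normal terms
  tr <- cherryTree()
  st <- c(0, 0, 0)
  p <- bmParams(rateBg = 1)
  expect_equal(treeLogLik(tr, st, p), 2 * dnorm(0, log = TRUE))

  # translation invariance when mu0 = 0
  tr5 <- fiveTipTree()
  set.seed(1)
  st5 <- rnorm(9)
  p5 <- bmParams(rateBg = 0.6)
  expect_equal(treeLogLik(tr5, st5, p5), treeLogLik(tr5, st5 + 3.7, p5))

  # doubling branch lengths while halving sigma2 and mu0 preserves every
  # branch's mean and variance
  set.seed(2)
  tr10 <- simulateTree(0.3, 0.1, 10, minFossils = 2)
  st10 <- rnorm(tr10$N + tr10$phy$Nnode)
  pA <- bmParams(rateBg = 0.8, trendBg = 0.3)
  phy2 <- tr10$phy; phy2$edge.length <- 2 * phy2$edge.length
  tr10b <- timeTree(phy2)
  pB <- bmParams(rateBg = 0.4, trendBg = 0.15)
  expect_equal(treeLogLik(tr10, st10, pA), treeLogLik(tr10b, st10, pB))

  expect_error(treeLogLik(tr5, c(st5[1:8], NA), p5), "states")
})

test_that("likelihood is additive over branches", {
  tr5 <- fiveTipTree()
  set.seed(3)
  st <- rnorm(9)
  p <- bmParams(rateBg = 0.5, trendBg = -0.2)
  cls <- resolveClasses(tr5, p)
  e <- tr5$phy$edge; len <- tr5$phy$edge.length
  manual <- sum(vapply(seq_len(nrow(e)), function(i)
    branchLogDensity(st[e[i, 1]], st[e[i, 2]], len[i],
                     cls$rate[e[i, 2]], cls$trend[e[i, 2]]), 0))
  expect_equal(treeLogLik(tr5, st, p), manual)
})

test_that("marginal tip likelihood equals brute-force MVN and integrates the augmented one", {
  # cherry: covariance sigma2 * [[2,1],[1,2]] around rootState + mu0*depth
  tr <- readTimeTree(text = "(A:1,B:1):1;")
  tv <- c(A = 0.4, B = -0.9)
  s2 <- 0.7; m0 <- 0.25; r0 <- 0.1
  S <- s2 * matrix(c(1, 0, 0, 1), 2)  # no shared path below the root
  mu <- r0 + m0 * 1
  manual <- -log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
    0.5 * drop(t(tv - mu) %*% solve(S) %*% (tv - mu))
  expect_equal(marginalTipLogLik(tr, tv, s2, m0, r0), manual)

  # 3-tip tree: marginal equals 1-D quadrature of the augmented likelihood
  tr3 <- threeTipTree()
  tv3 <- c(A = 0.2, B = 1.4, C = -0.6)
  s2 <- 0.5; m0 <- 0.3; r0 <- 0.4
  grid <- seq(-8, 8, length.out = 4001)
  h <- diff(grid)[1]
  p <- bmParams(rateBg = s2, trendBg = m0, rootState = r0)
  vals <- vapply(grid, function(x)
    treeLogLik(tr3, c(tv3, r0, x), p), 0)
  quad <- log(sum(exp(vals))) + log(h)
  expect_equal(marginalTipLogLik(tr3, tv3, s2, m0, r0), quad, tolerance = 1e-6)

  # numerically singular covariance rejected (duplicated tip positions)
  trz <- readTimeTree(text = "((A:0,B:0):1,C:2);")
  expect_error(marginalTipLogLik(trz, tv3, 1), "singular")
})

test_that("augmented likelihood is maximized where states equal their conditional means", {
  tr5 <- fiveTipTree()
  tv <- c(A = 0.1, B = 0.8, C = -0.4, D = 1.5, E = 0.3)
  p <- bmParams(rateBg = 0.6, trendBg = 0)
  b <- bindTraits(tr5, tv)
  idx <- which(!b$observed)
  f <- function(x) {
    st <- b$values; st[idx] <- x
    -treeLogLik(tr5, st, p)
  }
  opt <- optim(rep(0.5, length(idx)), f, method = "BFGS")
  st <- b$values; st[idx] <- opt$par
  # at the mode, every internal non-root node sits at its conditional mean
  for (nd in setdiff(idx, tr5$N + 1L)) {
    cp <- conditionalPosterior(tr5, nd, st, p)
    expect_equal(st[nd], cp$mean, tolerance = 1e-4)
  }
})
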