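# Small fixed trees used across tests
cherryTree <- function() readTimeTree(text = "(A:1,B:1);")
threeTipTree <- function() readTimeTree(text = "((A:1,B:1):1,C:2);")
fossilTree <- function() readTimeTree(text = "((A:1,B:0.4):1,C:2);")
fiveTipTree <- function()
  readTimeTree(text = "(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")

# a reproducible birth-death tree with fossils
smallSimTree <- function(seed = 42, nExtant = 12, nFossils = 3) {
  set.seed(seed)
  tr <- simulateTree(0.25, 0.1, nExtant, minFossils = nFossils)
  subsampleFossils(tr, nFossils)
}

internalNodes <- function(tree) seq.int(tree$N + 1L, tree$N + tree$phy$Nnode)

# Exact marginal log-likelihood of the tip values for an arbitrary per-node
# rate vector, integrating the root state over a flat prior and fixing the
# trend. Built from first principles (shared path-time covariance assembled
# branch by branch) as an oracle independent of treeLogLik. Precompute the
# geometry once with marginalFlatRootSetup() and evaluate cheaply per rate
# vector.
marginalFlatRootSetup <- function(tree) {
  N <- tree$N
  M <- N + tree$phy$Nnode
  par <- parentOf(tree); blen <- branchLengthTo(tree)
  P <- matrix(0, M, M)  # P[i, b] = 1 if branch b lies on the root->i path
  for (i in seq_len(M)) {
    j <- i
    while (!is.na(par[j])) { P[i, j] <- 1; j <- par[j] }
  }
  blen[is.na(blen)] <- 0
  mr <- ape::mrca(tree$phy, full = TRUE)[seq_len(N), seq_len(N)]
  list(N = N, M = M, P = P, blen = blen, mr = mr,
       depth = tree$height - tree$age)
}

marginalFlatRoot <- function(geo, y, rateByNode, mu0 = 0) {
  cum <- drop(geo$P %*% (rateByNode * geo$blen))
  S <- matrix(cum[geo$mr], geo$N)
  mu <- mu0 * geo$depth[seq_len(geo$N)]
  L <- chol(S)
  Si1 <- backsolve(L, backsolve(L, rep(1, geo$N), transpose = TRUE))
  a <- sum(Si1)
  rhat <- sum(Si1 * (y - mu)) / a
  z <- backsolve(L, y - mu - rhat, transpose = TRUE)
  -0.5 * (geo$N - 1) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z * z) +
    0.5 * log(2 * pi / a)
}

logSumExp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
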