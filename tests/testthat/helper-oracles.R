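# Independent oracles, deliberately implemented apart from the package code
# paths they check.

# Exact one-sided rank-sum p-value by exhaustive enumeration of all
# C(na+nb, na) assignments of the pooled ranks to sample a.
# p = P(W >= w_obs) for side "greater" (W = rank sum of a), the standard
# exact convention.
enumWilcoxP <- function(a, b, side = "greater") {
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  ranks <- rank(pooled)
  na <- length(a)
  wObs <- sum(ranks[seq_len(na)])
  splits <- utils::combn(length(pooled), na)
  wAll <- apply(splits, 2, function(ix) sum(ranks[ix]))
  switch(side,
         greater = mean(wAll >= wObs),
         less = mean(wAll <= wObs),
         two.sided = min(1, 2 * min(mean(wAll >= wObs),
                                    mean(wAll <= wObs))))
}

# Step-up BH executed literally: find the largest i with p_(i) <= i/m*alpha;
# q_(i) = min_{j >= i} m * p_(j) / j.
bhManual <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  crit <- seq_len(m) / m * alpha
  k <- suppressWarnings(max(which(ps <= crit)))
  reject <- rep(FALSE, m)
  if (is.finite(k)) reject[o[seq_len(k)]] <- TRUE
  q <- rev(cummin(rev(m * ps / seq_len(m))))
  q <- pmin(q, 1)
  qOut <- numeric(m)
  qOut[o] <- q
  list(q = qOut, reject = reject)
}

# R-side traversal of a fitted tree: independent of the C++ predictor.
predictTreeR <- function(rf, tree, xrow, overrideVar = NA, overrideVal = NA) {
  base <- rf$treeOffset[tree] + 1L # offsets are 0-based
  nd <- base
  repeat {
    v <- rf$nodeVar[nd]
    if (v < 0) return(rf$nodePred[nd])
    xv <- if (!is.na(overrideVar) && v == overrideVar - 1L) overrideVal
          else xrow[v + 1L]
    nd <- base + if (xv <= rf$nodeSplit[nd]) rf$nodeLeft[nd]
                 else rf$nodeRight[nd]
  }
}

# Brute-force permutation importance: re-predicts every OOB case of every
# tree before/after permutation (using the permutation sequences the fit
# recorded) and recomputes the MSE increases from scratch.
bruteImportance <- function(rf, x, y) {
  p <- ncol(x)
  nTrees <- rf$nTrees
  acc <- numeric(p)
  for (t in seq_len(nTrees)) {
    oob <- which(rf$inbag[, t] == 0)
    if (!length(oob)) next
    predBase <- vapply(oob, function(i) predictTreeR(rf, t, x[i, ]),
                       numeric(1))
    mseBase <- mean((predBase - y[oob])^2)
    perms <- rf$perms[[t]]
    for (v in seq_len(p)) {
      pv <- perms[[v]]
      if (!length(pv)) next # variable unused in this tree: exact zero
      predP <- vapply(seq_along(oob), function(j) {
        predictTreeR(rf, t, x[oob[j], ], overrideVar = v,
                     overrideVal = x[pv[j], v])
      }, numeric(1))
      acc[v] <- acc[v] + mean((predP - y[oob])^2) - mseBase
    }
  }
  acc / nTrees
}
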