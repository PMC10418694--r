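# Minimum-cost linear assignment via Jonker-Volgenant shortest augmenting
# paths (the algorithm behind scipy's linear_sum_assignment). Written here
# because no LAP solver ships with the pinned dependency set; O(n^3), exact.

# cost: square numeric matrix (finite; use a large sentinel for forbidden
# pairs). Returns integer vector a with a[i] = column assigned to row i.
solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 0L) return(integer(0))
  root <- n + 1L # virtual root column
  u <- numeric(n) # row potentials
  v <- numeric(n + 1) # column potentials (incl. root)
  p <- integer(n + 1) # p[j] = row matched to column j (0 = free)
  way <- integer(n + 1) # predecessor column on the alternating path
  for (i in seq_len(n)) {
    p[root] <- i
    j0 <- root
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      red <- cost[i0, seq_len(n)] - u[i0] - v[seq_len(n)]
      upd <- !used[seq_len(n)] & red < minv
      minv[upd] <- red[upd]
      way[seq_len(n)][upd] <- j0
      free_j <- which(!used[seq_len(n)])
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      usedCols <- which(used)
      u[p[usedCols]] <- u[p[usedCols]] + delta
      v[usedCols] <- v[usedCols] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == root) break
    }
    p[root] <- 0L
  }
  a <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) a[p[j]] <- j
  a
}
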