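# Minimum-cost linear assignment (Hungarian algorithm, potentials/shortest
# augmenting path formulation, O(n^3)). Peak lists are small (tens of peaks),
# so a plain R implementation is ample; correctness is cross-checked in the
# test suite against exhaustive enumeration of all pairings.
#
# `cost` must be square. Returns an integer vector a with a[i] = column
# assigned to row i.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(is.matrix(cost), ncol(cost) == n, all(is.finite(cost)))
  if (n == 0L) return(integer(0))
  virt <- n + 1L  # virtual column used to seed each augmenting search
  u <- numeric(n)
  v <- numeric(virt)
  assigned_row <- integer(virt)   # assigned_row[j]: row matched to column j
  way <- integer(virt)

  for (i in seq_len(n)) {
    assigned_row[virt] <- i
    j0 <- virt
    minv <- rep(Inf, n)
    used <- rep(FALSE, virt)
    repeat {
      used[j0] <- TRUE
      i0 <- assigned_row[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(virt)) {
        if (used[j]) {
          if (assigned_row[j] > 0L) u[assigned_row[j]] <- u[assigned_row[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (assigned_row[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      assigned_row[j0] <- assigned_row[j1]
      j0 <- j1
      if (j0 == virt) break
    }
  }

  out <- integer(n)
  for (j in seq_len(n)) out[assigned_row[j]] <- j
  out
}
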