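# Exact solver for the linear assignment problem, used to maximize the
# summed per-pair similarity over injective spiddo matchings (and, in the
# congruence module, one-to-one cluster matchings). Kuhn-Munkres with
# row/column potentials, O(n^3); profile sizes here are small (tens), so a
# pure-R implementation is ample.

# Minimize sum(cost[i, j[i]]) over permutations j of a square matrix.
# Returns integer vector j with j[i] = column assigned to row i.
lsap_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 1L) return(1L)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials, v[1] is the virtual column 0
  p <- integer(n + 1L)     # p[j+1] = row currently assigned to column j
  way <- integer(n)        # augmenting-path back-pointers (by column)
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- cols[!used[cols + 1L]]
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      k <- which.min(minv[free])
      j1 <- free[k]
      delta <- minv[j1]
      used_j <- c(0L, cols[used[cols + 1L]])  # column 0 is always on the path
      rows_on_path <- p[used_j + 1L]
      u[rows_on_path] <- u[rows_on_path] + delta
      v[used_j + 1L] <- v[used_j + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  assign[p[cols + 1L]] <- cols
  assign
}

# Maximize total score over injective matchings of size min(nA, nB).
# score: nA x nB matrix. Returns list(pairs = 2-col matrix (i, j) sorted by
# i, total = maximal summed score).
lsap_max_rect <- function(score) {
  na <- nrow(score)
  nb <- ncol(score)
  n <- max(na, nb)
  # pad to square with zero-scoring dummies; real-vs-real pairs keep their
  # score, so the optimum matches min(na, nb) real pairs whenever scores > 0,
  # and in general never benefits from leaving a beneficial pair unmatched
  big <- matrix(0, n, n)
  big[seq_len(na), seq_len(nb)] <- score
  j <- lsap_min(max(big) - big)
  i_real <- seq_len(na)
  pairs <- cbind(i = i_real, j = j[i_real])
  pairs <- pairs[pairs[, 2L] <= nb, , drop = FALSE]
  list(pairs = pairs, total = sum(score[pairs]))
}

# All permutations of 1..n as an (n!) x n integer matrix, rows in
# lexicographic order of the permutation vector.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  blocks <- lapply(seq_len(n), function(k) {
    shifted <- sub + (sub >= k)
    cbind(rep.int(k, nrow(sub)), shifted)
  })
  do.call(rbind, blocks)
}

# Exhaustively maximize total score over injective matchings of size
# min(na, nb), enumerating every subset and permutation. Oracle-grade:
# refuse when min(na, nb) > cap.
exhaustive_max_rect <- function(score, cap = 8L) {
  na <- nrow(score)
  nb <- ncol(score)
  flipped <- na > nb
  if (flipped) score <- t(score)
  k <- nrow(score)
  m <- ncol(score)
  if (k > cap) {
    stop(sprintf(paste0("exhaustive matching refused for min(n) = %d > %d; ",
                        "use mode = 'optimal' (exact assignment solver)"), k, cap),
         call. = FALSE)
  }
  perms <- all_permutations(k)
  nper <- nrow(perms)
  best <- -Inf
  best_pairs <- NULL
  subsets <- utils::combn(m, k)
  for (s in seq_len(ncol(subsets))) {
    cols <- subsets[, s]
    sub <- score[, cols, drop = FALSE]
    lin <- sweep((perms - 1L) * k, 2L, seq_len(k), `+`)
    totals <- rowSums(matrix(sub[as.vector(lin)], nrow = nper))
    w <- which.max(totals)
    if (totals[w] > best + 1e-15) {
      best <- totals[w]
      best_pairs <- cbind(i = seq_len(k), j = cols[perms[w, ]])
    }
  }
  if (flipped) best_pairs <- cbind(i = best_pairs[, 2L], j = best_pairs[, 1L])
  best_pairs <- best_pairs[order(best_pairs[, 1L]), , drop = FALSE]
  colnames(best_pairs) <- c("i", "j")
  list(pairs = best_pairs, total = best)
}
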