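#' PaSS computation settings
#'
#' @param w_theta Relative weight of the temperature axis versus the
#'   mobility axis (> 0). The theta coordinate is multiplied by `w_theta`
#'   before any norm is taken. The weight is the method's single tunable
#'   parameter; the default 1 treats both axes equally.
#' @param mode Matching strategy: `"optimal"` (exact linear-assignment
#'   solver, default), `"exhaustive"` (full enumeration, only for
#'   min(nA, nB) <= 8 — the test oracle), or `"monotone"` (best
#'   order-preserving matching by dynamic programming, for data where the
#'   serial order of spiddos is trusted).
#' @param min_overlap Minimum number of matched pairs required (>= 1).
#' @param size_penalty If `TRUE`, multiply PaSS by
#'   `min(nA, nB) / max(nA, nB)` so that profiles of very different sizes
#'   cannot score highly on their overlap alone. Off by default.
#' @return A list of class `pass_config`.
#' @export
pass_config <- function(w_theta = 1, mode = c("optimal", "monotone", "exhaustive"),
                        min_overlap = 1L, size_penalty = FALSE) {
  if (!is.numeric(w_theta) || length(w_theta) != 1L || !is.finite(w_theta) || w_theta <= 0) {
    stop("w_theta must be a single positive number", call. = FALSE)
  }
  mode <- match.arg(mode)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  structure(
    list(w_theta = w_theta, mode = mode, min_overlap = min_overlap,
         size_penalty = isTRUE(size_penalty)),
    class = "pass_config"
  )
}

#' Per-pair similarity between two spiddos
#'
#' The contribution of one matched spiddo pair to PaSS:
#' `1 - ||p - q||_w / (||p||_w + ||q||_w)`, where `||.||_w` is the
#' Euclidean norm with the theta component scaled by `w_theta`. The value
#' lies in (0, 1], equals 1 exactly when `p == q`, is symmetric, and is
#' invariant to rescaling both points by a common positive factor.
#'
#' @param p,q Length-2 numeric vectors `(mu, theta)` or n x 2 matrices
#'   (rowwise pairs).
#' @param w_theta Temperature-axis weight (> 0).
#' @return Numeric similarity value(s) in (0, 1].
#' @examples
#' pair_similarity(c(1, 1), c(1, 1))          # 1
#' pair_similarity(c(1, 0), c(0, 1))          # 1 - sqrt(2)/2
#' @export
pair_similarity <- function(p, q, w_theta = 1) {
  p <- rbind(p); q <- rbind(q)
  p[, 2L] <- p[, 2L] * w_theta
  q[, 2L] <- q[, 2L] * w_theta
  np <- sqrt(rowSums(p^2))
  nq <- sqrt(rowSums(q^2))
  if (any(np + nq <= 0)) {
    stop("degenerate spiddo pair: both points at the origin", call. = FALSE)
  }
  d <- sqrt(rowSums((p - q)^2))
  out <- 1 - d / (np + nq)
  if (length(out) == 1L) out <- as.numeric(out)
  out
}

# nA x nB matrix of per-pair similarities between two profiles
similarity_matrix <- function(a, b, w_theta = 1) {
  pa <- spiddo_matrix(a); pb <- spiddo_matrix(b)
  pa[, 2L] <- pa[, 2L] * w_theta
  pb[, 2L] <- pb[, 2L] * w_theta
  na_ <- sqrt(rowSums(pa^2))
  nb_ <- sqrt(rowSums(pb^2))
  # direct coordinate differences (not the polarization identity), so that
  # identical points give a distance of exactly zero and PaSS(a, a) == 1
  dx <- outer(pa[, 1L], pb[, 1L], `-`)
  dy <- outer(pa[, 2L], pb[, 2L], `-`)
  1 - sqrt(dx * dx + dy * dy) / outer(na_, nb_, `+`)
}

#' Optimal matching of spiddos between two genome profiles
#'
#' Finds the injective matching of size `min(nA, nB)` that maximizes the
#' summed [pair_similarity()] over matched pairs — the computational
#' realization of taking the maximum over all combinations of feature
#' points between the two organisms. Among equally optimal matchings the
#' lexicographically smallest pair list is returned, so the output is
#' deterministic.
#'
#' @param a,b [genome_profile()] objects (non-empty).
#' @param cfg A [pass_config()].
#' @return A list of class `gp_match` with elements `pairs` (two-column
#'   matrix of profile positions, sorted by the first column), `total`
#'   (maximal summed similarity), `pass_value` (`total / nrow(pairs)`,
#'   before any size penalty), `unmatched_a`, `unmatched_b` (positions
#'   left unpaired) and `mode`.
#' @export
match_spiddos <- function(a, b, cfg = pass_config()) {
  stopifnot(inherits(a, "gp_profile"), inherits(b, "gp_profile"))
  if (n_spiddos(a) == 0L || n_spiddos(b) == 0L) {
    stop("cannot match an empty profile", call. = FALSE)
  }
  s <- similarity_matrix(a, b, cfg$w_theta)
  k <- min(nrow(s), ncol(s))
  if (k < cfg$min_overlap) {
    stop(sprintf("only %d spiddo pairs available; min_overlap = %d", k, cfg$min_overlap),
         call. = FALSE)
  }
  res <- switch(cfg$mode,
    optimal    = lexmin_optimal_match(s),
    exhaustive = exhaustive_max_rect(s),
    monotone   = monotone_match(s)
  )
  pairs <- res$pairs
  structure(
    list(
      pairs = pairs,
      total = res$total,
      pass_value = res$total / nrow(pairs),
      unmatched_a = setdiff(seq_len(nrow(s)), pairs[, 1L]),
      unmatched_b = setdiff(seq_len(ncol(s)), pairs[, 2L]),
      mode = cfg$mode
    ),
    class = "gp_match"
  )
}

# Optimal assignment, refined so the returned pair list is the
# lexicographically smallest among all maximizers: pairs are fixed one at a
# time in (i, j) order, keeping only choices that preserve the optimum.
lexmin_optimal_match <- function(s, tol = 1e-9) {
  base <- lsap_max_rect(s)
  total <- base$total
  na <- nrow(s); nb <- ncol(s)
  k <- min(na, nb)
  forced <- matrix(0L, 0L, 2L)
  s_work <- s
  rows_free <- seq_len(na)
  cols_free <- seq_len(nb)
  fixed_total <- 0
  while (nrow(forced) < k && length(rows_free) > 0L && length(cols_free) > 0L) {
    i <- rows_free[[1L]]
    chosen <- NA_integer_
    for (j in sort(cols_free)) {
      sub <- s_work[setdiff(rows_free, i), setdiff(cols_free, j), drop = FALSE]
      rest <- if (min(dim(sub)) == 0L) 0 else lsap_max_rect(sub)$total
      if (fixed_total + s_work[i, j] + rest >= total - tol) {
        chosen <- j
        break
      }
    }
    if (is.na(chosen)) {
      # row i is unmatched in every optimal solution of this residual
      # problem (possible only when na > nb); skip it
      rows_free <- rows_free[-1L]
      next
    }
    forced <- rbind(forced, c(i, chosen))
    fixed_total <- fixed_total + s_work[i, chosen]
    rows_free <- rows_free[-1L]
    cols_free <- setdiff(cols_free, chosen)
  }
  colnames(forced) <- c("i", "j")
  list(pairs = forced, total = total)
}

# Best order-preserving matching of exactly min(na, nb) pairs:
# f[t, i, j] = best total matching t pairs within rows 1..i, cols 1..j.
monotone_match <- function(s) {
  na <- nrow(s); nb <- ncol(s)
  k <- min(na, nb)
  f <- array(-Inf, dim = c(k + 1L, na + 1L, nb + 1L))
  f[1L, , ] <- 0
  for (t in seq_len(k)) {
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        best <- max(f[t + 1L, i, j + 1L], f[t + 1L, i + 1L, j],
                    f[t, i, j] + s[i, j])
        f[t + 1L, i + 1L, j + 1L] <- best
      }
    }
  }
  total <- f[k + 1L, na + 1L, nb + 1L]
  # backtrack (preferring the matched move keeps pairs early/lexicographic)
  pairs <- matrix(0L, 0L, 2L)
  t <- k; i <- na; j <- nb
  while (t > 0L) {
    if (f[t + 1L, i + 1L, j + 1L] == f[t, i, j] + s[i, j]) {
      pairs <- rbind(c(i, j), pairs)
      t <- t - 1L; i <- i - 1L; j <- j - 1L
    } else if (i > 0L && f[t + 1L, i + 1L, j + 1L] == f[t + 1L, i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  colnames(pairs) <- c("i", "j")
  list(pairs = pairs, total = total)
}

#' Pattern similarity score (PaSS) between two genome profiles
#'
#' PaSS is the mean [pair_similarity()] over the optimally matched spiddo
#' pairs: the maximum attainable average superposition quality of the two
#' spiddos patterns. It lies in (0, 1], equals 1 exactly for identical
#' profiles, and is symmetric. With `cfg$size_penalty = TRUE` the mean is
#' additionally multiplied by `min(nA, nB) / max(nA, nB)`.
#'
#' @inheritParams match_spiddos
#' @return A single number in (0, 1].
#' @examples
#' a <- genome_profile("a", mu = c(0.5, 1.2), theta = c(0.9, 1.1))
#' pass_score(a, a)   # 1
#' @export
pass_score <- function(a, b, cfg = pass_config()) {
  s <- similarity_matrix(a, b, cfg$w_theta)
  k <- min(nrow(s), ncol(s))
  if (k < cfg$min_overlap) {
    stop(sprintf("only %d spiddo pairs available; min_overlap = %d", k, cfg$min_overlap),
         call. = FALSE)
  }
  total <- switch(cfg$mode,
    optimal    = lsap_max_rect(s)$total,
    exhaustive = exhaustive_max_rect(s)$total,
    monotone   = monotone_match(s)$total
  )
  p <- total / k
  if (cfg$size_penalty) p <- p * k / max(nrow(s), ncol(s))
  min(p, 1)  # guard against k-fold accumulation of double rounding
}

#' Genome distance between two profiles
#'
#' `d_G = 1 - PaSS`: the dissimilarity clustered to build genome-profiling
#' trees. Zero for identical profiles, symmetric, in `[0, 1)`. No triangle
#' inequality is claimed.
#'
#' @inheritParams match_spiddos
#' @return A single number in `[0, 1)`.
#' @export
genome_distance <- function(a, b, cfg = pass_config()) {
  1 - pass_score(a, b, cfg)
}

#' All-pairs genome distance matrix
#'
#' @param profiles A list of [genome_profile()] objects with unique labels.
#' @param cfg A [pass_config()].
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   profile labels, of class `matrix` (use [write_phylip_dist()] to
#'   export).
#' @export
genome_distance_matrix <- function(profiles, cfg = pass_config()) {
  stopifnot(length(profiles) >= 2L)
  labs <- vapply(profiles, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("duplicate profile labels", call. = FALSE)
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- genome_distance(profiles[[i]], profiles[[j]], cfg)
    }
  }
  d
}
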