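#' Lance-Williams weighing parameters for a linkage method
#'
#' The agglomerative methods used for genome-profiling trees are all
#' instances of one recurrence: after merging clusters `a` and `b` into
#' `c`, the distance from `c` to any other cluster `x` is
#' `d_cx = alpha_a * d_xa + alpha_b * d_xb + beta * d_ab +
#'  gamma * |d_xa - d_xb|`.
#'
#' * Ward: `alpha_a = (n_a+n_x)/(n_a+n_b+n_x)`,
#'   `alpha_b = (n_b+n_x)/(n_a+n_b+n_x)`, `beta = -n_x/(n_a+n_b+n_x)`,
#'   `gamma = 0`.
#' * Group average (UPGMA): `alpha_a = n_a/(n_a+n_b)`,
#'   `alpha_b = n_b/(n_a+n_b)`, `beta = gamma = 0`.
#' * Median: `alpha_a = alpha_b = 1/2`, `beta = -1/4`, `gamma = 0`.
#'
#' @param method One of `"ward"`, `"average"`, `"median"`.
#' @param n_a,n_b,n_x Cluster sizes (ignored for the median method).
#' @return A list with elements `alpha_a`, `alpha_b`, `beta`, `gamma`.
#' @export
linkage_params <- function(method = c("ward", "average", "median"),
                           n_a = 1L, n_b = 1L, n_x = 1L) {
  method <- match.arg(method)
  switch(method,
    ward = {
      s <- n_a + n_b + n_x
      list(alpha_a = (n_a + n_x) / s, alpha_b = (n_b + n_x) / s,
           beta = -n_x / s, gamma = 0)
    },
    average = list(alpha_a = n_a / (n_a + n_b), alpha_b = n_b / (n_a + n_b),
                   beta = 0, gamma = 0),
    median = list(alpha_a = 0.5, alpha_b = 0.5, beta = -0.25, gamma = 0)
  )
}

#' One step of the Lance-Williams distance update
#'
#' @param d_xa,d_xb Distances from cluster `x` to the merging clusters `a`
#'   and `b` (>= 0).
#' @param d_ab Distance between the merging clusters (>= 0).
#' @param params Weighing parameters, as from [linkage_params()].
#' @return The updated distance `d_cx` from the merged cluster to `x`.
#' @examples
#' lance_williams_update(2, 4, 3, linkage_params("ward"))     # 3
#' lance_williams_update(2, 4, 3, linkage_params("median"))   # 2.25
#' @export
lance_williams_update <- function(d_xa, d_xb, d_ab, params) {
  if (any(c(d_xa, d_xb, d_ab) < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  params$alpha_a * d_xa + params$alpha_b * d_xb + params$beta * d_ab +
    params$gamma * abs(d_xa - d_xb)
}

#' Agglomerative clustering of a genome-distance matrix
#'
#' Repeatedly merges the globally closest pair of clusters, updating all
#' distances with [lance_williams_update()], and records the pre-merge
#' distance of the merged pair as the node height. Ties on the minimum
#' distance are broken by merging the pair whose (smallest-member-label,
#' smallest-member-label) key is lexicographically least, so the output is
#' deterministic.
#'
#' The genome distances `d_G` are used as supplied — they are not squared
#' before Ward updates, since `d_G` is not claimed to be Euclidean. Set
#' `ward_squared = TRUE` to square the input first and take square roots
#' of the resulting heights (the behavior of implementations that assume
#' squared Euclidean input).
#'
#' @param d Labelled symmetric distance matrix (e.g. from
#'   [genome_distance_matrix()] or [read_phylip_dist()]).
#' @param method Linkage: `"ward"` (default), `"average"` or `"median"`.
#'   Ward and group-average trees have monotone non-decreasing merge
#'   heights; median linkage may produce height inversions, which are kept
#'   and flagged with a warning.
#' @param ward_squared Square distances before Ward updates (see above).
#' @return An object of class `hclust` (fields `merge`, `height`, `order`,
#'   `labels`, `method`), directly usable with [stats::cutree()],
#'   `plot()`, and convertible with [to_newick()] / [ape::as.phylo()].
#' @export
build_tree <- function(d, method = c("ward", "average", "median"),
                       ward_squared = FALSE) {
  method <- match.arg(method)
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 labels to cluster", call. = FALSE)
  labs <- rownames(d)
  work <- d
  if (ward_squared && method == "ward") work <- work^2

  active <- seq_len(n)              # column indices of live clusters
  id <- -seq_len(n)                 # hclust ids: negative leaf, positive merge
  size <- rep(1L, n)
  minlab <- labs                    # lexicographic tie-break key per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    sub <- work[active, active, drop = FALSE]
    off <- upper.tri(sub)
    dmin <- min(sub[off])
    cand <- which(sub == dmin & off, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1L, function(rc) {
        k <- sort(c(minlab[active[rc[1L]]], minlab[active[rc[2L]]]))
        paste(k, collapse = "\r")
      })
      cand <- cand[order(keys)[1L], , drop = FALSE]
    }
    ia <- active[cand[1L, 1L]]
    ib <- active[cand[1L, 2L]]

    merge[step, ] <- sort(c(id[ia], id[ib]))
    height[step] <- if (ward_squared && method == "ward") sqrt(dmin) else dmin

    rest <- setdiff(active, c(ia, ib))
    for (ix in rest) {
      pr <- linkage_params(method, n_a = size[ia], n_b = size[ib], n_x = size[ix])
      work[ia, ix] <- work[ix, ia] <-
        lance_williams_update(work[ix, ia], work[ix, ib], work[ia, ib], pr)
    }
    size[ia] <- size[ia] + size[ib]
    id[ia] <- step
    minlab[ia] <- min(minlab[ia], minlab[ib])
    active <- setdiff(active, ib)
  }
  if (method == "median" && any(diff(height) < -1e-12)) {
    warning("median linkage produced height inversions (kept as-is)", call. = FALSE)
  }

  structure(
    list(
      merge = merge, height = height, order = hclust_order(merge),
      labels = labs, method = method,
      call = match.call(), dist.method = "genome distance (1 - PaSS)"
    ),
    class = "hclust"
  )
}

# leaf ordering for plotting: left-to-right traversal of the merge table
hclust_order <- function(merge) {
  expand <- function(i) {
    if (i < 0L) return(-i)
    c(expand(merge[i, 1L]), expand(merge[i, 2L]))
  }
  expand(nrow(merge))
}
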