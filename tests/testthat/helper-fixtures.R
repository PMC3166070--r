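# Fixture builders and independent oracles shared across the suite.

random_profile <- function(label, n, lo = 0.2, hi = 1.8) {
  genome_profile(label, mu = runif(n, lo, hi), theta = runif(n, lo, hi))
}

random_dist_matrix <- function(n, labels = sprintf("sp%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d + t(d)
}

# independent oracle: maximum-total injective (partial) matching of subject
# rows to object columns by full recursion — each object column used at
# most once, subjects may stay unmatched
brute_force_assignment_max <- function(S) {
  ns <- nrow(S)
  no <- ncol(S)
  best <- 0
  rec <- function(i, used, tot) {
    if (i > ns) {
      best <<- max(best, tot)
      return(invisible(NULL))
    }
    rec(i + 1L, used, tot)
    for (j in seq_len(no)) {
      if (!used[j]) rec(i + 1L, replace(used, j, TRUE), tot + S[i, j])
    }
  }
  rec(1L, rep(FALSE, no), 0)
  best
}

# independent oracle for CMS: score matrix built from first principles on
# the two cluster lists, then brute-force matched
brute_force_cms <- function(subject, object, criterion) {
  if (length(subject) == 0L) return(0)
  if (length(object) == 0L) return(0)
  S <- matrix(0, length(subject), length(object))
  for (i in seq_along(subject)) {
    for (j in seq_along(object)) {
      a <- subject[[i]]$labels
      b <- object[[j]]$labels
      S[i, j] <- if (criterion == "exact") {
        as.numeric(setequal(a, b))
      } else {
        length(intersect(a, b)) / length(union(a, b))
      }
    }
  }
  brute_force_assignment_max(S)
}

# canonical form of a clustering for oracle comparison: the multiset of
# (sorted leaf set, height) pairs of the internal nodes
hclust_canonical <- function(hc, digits = 9) {
  sets <- vector("list", nrow(hc$merge))
  out <- character(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(x) {
      if (x < 0) hc$labels[-x] else sets[[x]]
    }))
    sets[[i]] <- sort(members)
    out[i] <- paste0(paste(sets[[i]], collapse = ","), "@",
                     signif(hc$height[i], digits))
  }
  sort(out)
}
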