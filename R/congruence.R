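#' Extract the cluster set of a dendrogram
#'
#' A tree's clusters are the leaf-label sets of its internal nodes,
#' excluding the root (whose cluster is the whole leaf set and carries no
#' grouping information). Multifurcating trees are handled, as
#' coarse-grained trees are routinely multifurcating.
#'
#' @param tree An `hclust` or `phylo` dendrogram with >= 2 leaves.
#' @param leaf_filter Optional character vector: restrict the tree to
#'   these leaves first (degree-2 nodes are pruned, heights to the
#'   remaining tips preserved).
#' @return An object of class `gp_clusterset`: a list of clusters, each
#'   `list(labels, height)`, sorted by size then lexicographically; the
#'   leaf universe is stored in `attr(, "leaves")`.
#' @export
clusters_of <- function(tree, leaf_filter = NULL) {
  phy <- as_gp_phylo(tree)
  if (!is.null(leaf_filter)) {
    shared <- intersect(phy$tip.label, leaf_filter)
    if (length(shared) < 2L) {
      stop("incomparable trees: fewer than 2 shared leaves", call. = FALSE)
    }
    if (length(shared) < length(phy$tip.label)) {
      phy <- ape::keep.tip(phy, shared)
    }
  }
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("tree must have >= 2 leaves", call. = FALSE)
  sets <- phylo_node_tipsets(phy)
  hts <- phylo_node_heights(phy)
  internal <- seq.int(ntip + 1L, ntip + phy$Nnode)
  root <- ntip + 1L
  internal <- setdiff(internal, root)
  cl <- lapply(internal, function(i) {
    list(labels = sort(sets[[i]]), height = hts[[i]])
  })
  # defensive de-duplication (identical leaf sets cannot arise from a tree
  # without unary nodes, but parsed Newick may contain them)
  keysets <- vapply(cl, function(x) paste(x$labels, collapse = "\r"), "")
  cl <- cl[!duplicated(keysets)]
  ord <- order(
    vapply(cl, function(x) length(x$labels), 0L),
    vapply(cl, function(x) paste(x$labels, collapse = "\r"), "")
  )
  structure(cl[ord], class = "gp_clusterset", leaves = sort(phy$tip.label))
}

#' @export
print.gp_clusterset <- function(x, ...) {
  cat(sprintf("<cluster set: %d clusters over %d leaves>\n",
              length(x), length(attr(x, "leaves"))))
  for (cl in x) {
    cat(sprintf("  h=%.4f  {%s}\n", cl$height, paste(cl$labels, collapse = ",")))
  }
  invisible(x)
}

#' Cluster matching score (CMS) between two cluster sets
#'
#' Each cluster of the subject tree is matched against the clusters of
#' the object tree; CMS is the summed match score, with every object
#' cluster usable at most once.
#'
#' * `criterion = "exact"`: a subject cluster scores 1 if an identical
#'   leaf set exists among the object clusters, else 0.
#' * `criterion = "jaccard"`: clusters are paired one-to-one so as to
#'   maximize the total Jaccard index (exact assignment solver).
#'
#' @param subject,object `gp_clusterset` objects (from [clusters_of()])
#'   over the same leaf universe, or trees (coerced via [clusters_of()]).
#' @param criterion `"exact"` (default) or `"jaccard"`.
#' @return A list with `cms` (total score) and `matches` (data.frame with
#'   columns `subject`, `object`, `score`; `object` is `NA` for unmatched
#'   subject clusters).
#' @export
cluster_matching_score <- function(subject, object, criterion = c("exact", "jaccard")) {
  criterion <- match.arg(criterion)
  if (!inherits(subject, "gp_clusterset")) subject <- clusters_of(subject)
  if (!inherits(object, "gp_clusterset")) object <- clusters_of(object)
  if (!identical(attr(subject, "leaves"), attr(object, "leaves"))) {
    stop("cluster sets have different leaf universes; restrict the trees first",
         call. = FALSE)
  }
  ns <- length(subject)
  no <- length(object)
  skey <- vapply(subject, function(x) paste(x$labels, collapse = "\r"), "")
  okey <- vapply(object, function(x) paste(x$labels, collapse = "\r"), "")
  fmt_cl <- function(x) paste(x$labels, collapse = ",")
  if (ns == 0L) {
    return(list(cms = 0,
                matches = data.frame(subject = character(), object = character(),
                                     score = numeric())))
  }
  if (criterion == "exact") {
    hit <- match(skey, okey)
    score <- as.numeric(!is.na(hit))
    matches <- data.frame(
      subject = vapply(subject, fmt_cl, ""),
      object = ifelse(is.na(hit), NA_character_,
                      vapply(object[replace(hit, is.na(hit), 1L)], fmt_cl, "")),
      score = score,
      stringsAsFactors = FALSE
    )
    matches$object[is.na(hit)] <- NA_character_
    return(list(cms = sum(score), matches = matches))
  }
  # jaccard: one-to-one assignment maximizing total Jaccard index
  if (no == 0L) {
    return(list(cms = 0,
                matches = data.frame(subject = vapply(subject, fmt_cl, ""),
                                     object = NA_character_, score = 0,
                                     stringsAsFactors = FALSE)))
  }
  J <- matrix(0, ns, no)
  for (i in seq_len(ns)) {
    for (j in seq_len(no)) {
      a <- subject[[i]]$labels; b <- object[[j]]$labels
      J[i, j] <- length(intersect(a, b)) / length(union(a, b))
    }
  }
  res <- lsap_max_rect(J)
  score <- numeric(ns)
  obj <- rep(NA_character_, ns)
  score[res$pairs[, 1L]] <- J[res$pairs]
  obj[res$pairs[, 1L]] <- vapply(object[res$pairs[, 2L]], fmt_cl, "")
  list(cms = res$total,
       matches = data.frame(subject = vapply(subject, fmt_cl, ""),
                            object = obj, score = score, stringsAsFactors = FALSE))
}

#' Congruence value Vc between two dendrograms
#'
#' `Vc = CMS / n_subject_clusters`, the fraction of the subject tree's
#' clusters recovered in the object tree (under the chosen matching
#' criterion), so `0 <= Vc <= 1` and any tree is perfectly congruent with
#' itself. The score is directional: the subject is the tree being
#' evaluated, the object the reference. The reverse direction and the
#' mean of both are reported alongside.
#'
#' Trees are first restricted to their shared leaf set. If the subject
#' has no non-root clusters the value is degenerate: 1 if the object has
#' none either (vacuous congruence), else 0; a message is emitted.
#'
#' @param subject_tree,object_tree `hclust` or `phylo` dendrograms with
#'   >= 2 shared leaves.
#' @param criterion `"exact"` (default) or `"jaccard"`; see
#'   [cluster_matching_score()].
#' @return An object of class `gp_congruence`: list with `vc`, `cms`,
#'   `n_subject_clusters`, `n_object_clusters`, `matches`, `criterion`,
#'   `coarse_grained`, `vc_reverse`, `vc_mean`.
#' @examples
#' t1 <- from_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' star <- from_newick("(A:2,B:2,C:2,D:2);")
#' congruence_value(t1, t1)$vc     # 1
#' congruence_value(t1, star)$vc   # 0
#' @export
congruence_value <- function(subject_tree, object_tree,
                             criterion = c("exact", "jaccard")) {
  criterion <- match.arg(criterion)
  s_phy <- as_gp_phylo(subject_tree)
  o_phy <- as_gp_phylo(object_tree)
  shared <- intersect(s_phy$tip.label, o_phy$tip.label)
  if (length(shared) < 2L) {
    stop("incomparable trees: fewer than 2 shared leaves", call. = FALSE)
  }
  subject <- clusters_of(s_phy, leaf_filter = shared)
  object <- clusters_of(o_phy, leaf_filter = shared)
  dir_vc <- function(su, ob) {
    if (length(su) == 0L) {
      vc <- if (length(ob) == 0L) 1 else 0
      message("degenerate congruence: subject tree has no non-root clusters; Vc = ", vc)
      return(list(vc = vc, cms = 0,
                  matches = data.frame(subject = character(), object = character(),
                                       score = numeric())))
    }
    m <- cluster_matching_score(su, ob, criterion)
    list(vc = m$cms / length(su), cms = m$cms, matches = m$matches)
  }
  fwd <- dir_vc(subject, object)
  rev <- dir_vc(object, subject)
  structure(
    list(
      vc = fwd$vc, cms = fwd$cms,
      n_subject_clusters = length(subject),
      n_object_clusters = length(object),
      matches = fwd$matches,
      criterion = criterion,
      coarse_grained = FALSE,
      vc_reverse = rev$vc,
      vc_mean = (fwd$vc + rev$vc) / 2
    ),
    class = "gp_congruence"
  )
}

#' @export
print.gp_congruence <- function(x, ...) {
  cat(sprintf("<congruence: Vc%s = %.4f (reverse %.4f, mean %.4f)>\n",
              if (x$coarse_grained) "'" else "", x$vc, x$vc_reverse, x$vc_mean))
  cat(sprintf("  CMS = %.4f over %d subject / %d object clusters (criterion: %s)\n",
              x$cms, x$n_subject_clusters, x$n_object_clusters, x$criterion))
  invisible(x)
}

#' Coarse-grain (bunch) a dendrogram
#'
#' Collapses fine structure before tree comparison: an internal node is
#' merged into its parent (children promoted, forming a polytomy)
#' whenever the relative height gap between them is below
#' `rel_threshold` — by default `(h_parent - h_child) / h_parent < 0.15`,
#' i.e. a compression of less than 15% height difference. The collapse is
#' iterated to a fixed point, so the operation is idempotent; the leaf
#' set is unchanged and the number of internal nodes never increases.
#' Height inversions (child above parent) always collapse.
#'
#' @param tree `hclust` or `phylo`.
#' @param rel_threshold Relative height-gap threshold in (0, 1); default
#'   0.15.
#' @param norm Denominator of the relative gap: `"parent"` (the parent
#'   node's height, default) or `"tree"` (the root height).
#' @return A `phylo` tree, possibly multifurcating. A tree whose root
#'   height is 0 collapses to a star, with a warning.
#' @export
coarse_grain <- function(tree, rel_threshold = 0.15, norm = c("parent", "tree")) {
  norm <- match.arg(norm)
  if (!is.numeric(rel_threshold) || rel_threshold <= 0 || rel_threshold >= 1) {
    stop("rel_threshold must lie in (0, 1)", call. = FALSE)
  }
  phy <- as_gp_phylo(tree)
  root_node <- phylo_to_nodes(phy)
  root_h <- root_node$height
  if (root_h <= 0) {
    warning("zero root height: coarse-graining collapses the tree to a star",
            call. = FALSE)
  }
  collapse <- function(nd) {
    if (is.null(nd$children)) return(nd)
    nd$children <- lapply(nd$children, collapse)
    repeat {
      promoted <- FALSE
      out <- list()
      for (ch in nd$children) {
        if (is.null(ch$children)) {
          out <- c(out, list(ch))
          next
        }
        denom <- if (norm == "parent") nd$height else root_h
        gap <- nd$height - ch$height
        absorb <- if (denom <= 0) TRUE else (gap / denom) < rel_threshold
        if (absorb) {
          out <- c(out, ch$children)
          promoted <- TRUE
        } else {
          out <- c(out, list(ch))
        }
      }
      nd$children <- out
      if (!promoted) break
    }
    nd
  }
  nodes_to_phylo(collapse(root_node))
}

#' Modified congruence value Vc' (coarse-grained comparison)
#'
#' `Vc'` is the congruence value obtained after coarse-graining the more
#' finely structured partner of the pair (the tree with more internal
#' nodes, after restriction to the shared leaves). When both trees have
#' the same number of internal nodes, both are coarse-grained.
#'
#' @inheritParams congruence_value
#' @param rel_threshold,norm Passed to [coarse_grain()].
#' @return A `gp_congruence` object with `coarse_grained = TRUE`.
#' @export
modified_congruence <- function(subject_tree, object_tree,
                                criterion = c("exact", "jaccard"),
                                rel_threshold = 0.15, norm = c("parent", "tree")) {
  criterion <- match.arg(criterion)
  norm <- match.arg(norm)
  s_phy <- as_gp_phylo(subject_tree)
  o_phy <- as_gp_phylo(object_tree)
  shared <- intersect(s_phy$tip.label, o_phy$tip.label)
  if (length(shared) < 2L) {
    stop("incomparable trees: fewer than 2 shared leaves", call. = FALSE)
  }
  if (length(shared) < length(s_phy$tip.label)) s_phy <- ape::keep.tip(s_phy, shared)
  if (length(shared) < length(o_phy$tip.label)) o_phy <- ape::keep.tip(o_phy, shared)
  if (s_phy$Nnode > o_phy$Nnode) {
    s_phy <- coarse_grain(s_phy, rel_threshold, norm)
  } else if (o_phy$Nnode > s_phy$Nnode) {
    o_phy <- coarse_grain(o_phy, rel_threshold, norm)
  } else {
    s_phy <- coarse_grain(s_phy, rel_threshold, norm)
    o_phy <- coarse_grain(o_phy, rel_threshold, norm)
  }
  res <- congruence_value(s_phy, o_phy, criterion)
  res$coarse_grained <- TRUE
  res
}
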