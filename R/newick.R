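# Dendrograms travel through the package in two forms: `hclust` objects
# (the native output of build_tree) and ape `phylo` trees (the exchange
# format, required for polytomies after coarse-graining). Node "height"
# always means the maximum path length from the node down to any of its
# descendant tips, so leaves sit at height 0 and, for an ultrametric
# clustering tree, an internal node's height is its merge distance.

#' Convert a dendrogram to a Newick string
#'
#' Branch lengths encode parent/child height differences, so a two-leaf
#' tree merged at height `h` becomes `(A:h,B:h);`.
#'
#' @param tree An `hclust` (from [build_tree()]) or ape `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string, terminated by `;`.
#' @seealso [from_newick()], [write_newick()]
#' @export
to_newick <- function(tree, digits = 10L) {
  phy <- as_gp_phylo(tree)
  ape::write.tree(phy, digits = digits)
}

#' Write one or more dendrograms to a Newick file (one tree per line)
#' @param tree A tree or list of trees (`hclust` or `phylo`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  trees <- if (inherits(tree, c("hclust", "phylo"))) list(tree) else tree
  writeLines(vapply(trees, to_newick, ""), path)
  invisible(path)
}

#' Parse a Newick tree
#'
#' Accepts standard Newick with branch lengths, named internal nodes and
#' polytomies (polytomies arise naturally from [coarse_grain()]).
#'
#' @param x A Newick string, or the path of a file whose first line holds
#'   one.
#' @return An ape `phylo` object.
#' @export
from_newick <- function(x) {
  phy <- tryCatch(
    if (grepl("(", x, fixed = TRUE)) {
      ape::read.tree(text = x)
    } else {
      ape::read.tree(file = x)
    },
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(phy)) stop("malformed Newick: ", substr(x, 1L, 60L), call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  phy
}

# hclust / phylo -> phylo
as_gp_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (!inherits(tree, "hclust")) stop("expected an hclust or phylo tree", call. = FALSE)
  # build Newick directly so branch lengths are exactly height differences
  # (leaves at height 0, internal nodes at their merge heights)
  merge <- tree$merge
  height <- tree$height
  labs <- tree$labels
  fmt <- function(x) sprintf("%.12g", x)
  node_str <- function(i) {
    h <- height[i]
    parts <- vapply(merge[i, ], function(child) {
      if (child < 0L) {
        paste0(labs[-child], ":", fmt(h))
      } else {
        paste0(node_str(child), ":", fmt(h - height[child]))
      }
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(node_str(nrow(merge)), ";"))
}

# heights of every node (tips then internal, ape numbering): max path
# length down to a descendant tip; tips are 0
phylo_node_heights <- function(phy) {
  phy <- stats::reorder(phy, "postorder")
  ntip <- length(phy$tip.label)
  h <- numeric(ntip + phy$Nnode)
  el <- phy$edge.length
  if (is.null(el)) el <- rep(1, nrow(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]
    ch <- phy$edge[e, 2L]
    h[par] <- max(h[par], h[ch] + el[e])
  }
  h
}

# tip labels below every node, as a list indexed by ape node number
phylo_node_tipsets <- function(phy) {
  phy <- stats::reorder(phy, "postorder")
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[[i]]
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]
    ch <- phy$edge[e, 2L]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

# recursive list form used by coarse_grain: leaf = list(label=), internal =
# list(height=, children=list(...))
phylo_to_nodes <- function(phy) {
  ntip <- length(phy$tip.label)
  h <- phylo_node_heights(phy)
  kids <- split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_along(h)))
  build <- function(i) {
    if (i <= ntip) return(list(label = phy$tip.label[[i]]))
    list(height = h[[i]], children = lapply(kids[[i]], build))
  }
  build(ntip + 1L)
}

nodes_to_phylo <- function(node) {
  fmt <- function(x) sprintf("%.12g", x)
  render <- function(nd, parent_height) {
    if (!is.null(nd$label)) {
      return(paste0(nd$label, ":", fmt(parent_height)))
    }
    inner <- vapply(nd$children, render, "", parent_height = nd$height)
    paste0("(", paste(inner, collapse = ","), ")", ":", fmt(parent_height - nd$height))
  }
  inner <- vapply(node$children, render, "", parent_height = node$height)
  ape::read.tree(text = paste0("(", paste(inner, collapse = ","), ");"))
}
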