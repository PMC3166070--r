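#' Simulation settings for synthetic genome profiles
#'
#' The simulator stands in for the wet-lab pipeline: it evolves a set of
#' spiddos along a known ultrametric species tree, so every downstream
#' stage (PaSS, clustering, congruence) can be exercised against a known
#' ground truth. Coordinate jitter emulates gel-to-gel experimental error
#' on the normalized scale; band loss/gain emulates fragments dropping
#' below detection or appearing, producing profiles of unequal size.
#'
#' @param n_leaves Number of species (tree tips), >= 2.
#' @param n_spiddos Points in the ancestral profile (default 12, a
#'   typical spiddos count per gel).
#' @param sigma Brownian jitter scale per unit branch length on the
#'   normalized (mu, theta) plane: along a branch of length `l` each
#'   coordinate receives independent Gaussian noise of sd
#'   `sigma * sqrt(l)`. Default 0.05.
#' @param p_loss,p_gain Per-branch probability that each existing point
#'   is lost / that a new point appears (per existing point), in
#'   `[0, 1)`. Defaults 0.05. A floor of 3 surviving points is enforced.
#' @param tree_model `"yule"` (pure-birth, default) or `"coalescent"`.
#' @param seed Master seed; all stochastic draws flow from named
#'   substreams derived from it, so tree shape and noise draws are
#'   independently reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 10L, n_spiddos = 12L, sigma = 0.05,
                       p_loss = 0.05, p_gain = 0.05,
                       tree_model = c("yule", "coalescent"), seed = 1L) {
  tree_model <- match.arg(tree_model)
  n_leaves <- as.integer(n_leaves)
  n_spiddos <- as.integer(n_spiddos)
  if (n_leaves < 2L) stop("n_leaves must be >= 2", call. = FALSE)
  if (n_spiddos < 1L) stop("n_spiddos must be >= 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (p_loss < 0 || p_loss >= 1 || p_gain < 0 || p_gain >= 1) {
    stop("p_loss and p_gain must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_leaves = n_leaves, n_spiddos = n_spiddos, sigma = sigma,
         p_loss = p_loss, p_gain = p_gain, tree_model = tree_model,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic substream seed < 2^31 derived from (master seed, name)
sub_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- as.double(seed %% 2147483647L)
  for (c in codes) h <- (h * 131 + c) %% 2147483629
  as.integer(h)
}

# run expr under a temporary RNG state seeded by (seed, name); restores
# the caller's RNG state afterwards
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, name))
  expr
}

#' Simulate a random ultrametric species tree
#'
#' Draws a rooted ultrametric tree with `cfg$n_leaves` tips labelled
#' `L1..Ln` under a Yule (pure-birth) or coalescent model, rescaled to
#' root height 1. Deterministic per seed.
#'
#' @param cfg A [sim_config()].
#' @return An ape `phylo` tree (ultrametric, root height 1).
#' @export
simulate_tree <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  phy <- with_substream(cfg$seed, paste0("tree:", cfg$tree_model), {
    if (cfg$tree_model == "yule") {
      ape::rphylo(cfg$n_leaves, birth = 1, death = 0)
    } else {
      ape::rcoal(cfg$n_leaves)
    }
  })
  root_h <- max(phylo_node_heights(phy))
  phy$edge.length <- phy$edge.length / root_h
  phy$tip.label <- paste0("L", seq_len(cfg$n_leaves))
  phy
}

#' Evolve synthetic genome profiles along a tree
#'
#' The ancestral profile is sampled uniformly on the square
#' `[0.3, 1.7]^2` of the normalized (mu, theta) plane (centred on the
#' reference point at (1, 1)). Along each branch of length `l`, every
#' point receives iid Gaussian jitter of sd `sigma * sqrt(l)` per
#' coordinate (Brownian motion on the normalized scale), is lost with
#' probability `p_loss` (at least 3 points always survive), and new
#' points appear with probability `p_gain` per existing point (uniform
#' position). Coordinates are clamped to be >= 0.05. One profile per
#' tip, labelled by tip label. Deterministic per seed.
#'
#' @param tree An ultrametric `phylo` tree with positive root height
#'   (e.g. from [simulate_tree()]). Non-ultrametric trees are accepted
#'   with a warning; branch lengths are used as-is.
#' @param cfg A [sim_config()].
#' @return A named list of [genome_profile()] objects, one per tip.
#' @export
simulate_profiles <- function(tree, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  phy <- as_gp_phylo(tree)
  if (!ape::is.ultrametric(phy, tol = 1e-6)) {
    warning("tree is not ultrametric; branch lengths used as-is", call. = FALSE)
  }
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])  # edge rows by parent

  ancestor <- with_substream(cfg$seed, "ancestor", {
    matrix(stats::runif(cfg$n_spiddos * 2L, 0.3, 1.7), ncol = 2L,
           dimnames = list(NULL, c("mu", "theta")))
  })

  profiles <- vector("list", ntip)
  evolve <- function(node, points) {
    if (node <= ntip) {
      profiles[[node]] <<- genome_profile(
        phy$tip.label[[node]], mu = points[, 1L], theta = points[, 2L]
      )
      return(invisible(NULL))
    }
    for (e in kids[[as.character(node)]]) {
      child <- phy$edge[e, 2L]
      len <- phy$edge.length[e]
      pts <- points
      if (cfg$sigma > 0 && len > 0) {
        pts <- with_substream(cfg$seed, sprintf("jitter:%d", child), {
          pts + matrix(stats::rnorm(length(pts), 0, cfg$sigma * sqrt(len)),
                       ncol = 2L)
        })
      }
      if (cfg$p_loss > 0) {
        keep <- with_substream(cfg$seed, sprintf("loss:%d", child), {
          stats::runif(nrow(pts)) >= cfg$p_loss
        })
        if (sum(keep) < 3L) {  # detection floor: a profile keeps >= 3 bands
          keep[seq_len(min(3L, nrow(pts)))] <- TRUE
        }
        pts <- pts[keep, , drop = FALSE]
      }
      if (cfg$p_gain > 0) {
        pts <- with_substream(cfg$seed, sprintf("gain:%d", child), {
          n_new <- stats::rbinom(1L, nrow(pts), cfg$p_gain)
          if (n_new > 0L) {
            rbind(pts, matrix(stats::runif(2L * n_new, 0.3, 1.7), ncol = 2L))
          } else pts
        })
      }
      pts[pts < 0.05] <- 0.05
      evolve(child, pts)
    }
  }
  evolve(root, ancestor)
  names(profiles) <- phy$tip.label
  profiles
}

#' Randomly swap leaf labels of a tree
#'
#' Performs `k` random pairwise tip-label swaps, leaving topology and
#' heights untouched — a controlled way to degrade the congruence between
#' a tree and its perturbed copy.
#'
#' @param tree `hclust` or `phylo`.
#' @param k_swaps Number of swaps (>= 0).
#' @param seed Seed for the swap positions.
#' @return A `phylo` tree.
#' @export
perturb_tree <- function(tree, k_swaps, seed = 1L) {
  if (k_swaps < 0) stop("k_swaps must be >= 0", call. = FALSE)
  phy <- as_gp_phylo(tree)
  if (k_swaps == 0L) return(phy)
  with_substream(seed, "swaps", {
    for (s in seq_len(k_swaps)) {
      ij <- sample.int(length(phy$tip.label), 2L)
      phy$tip.label[ij] <- phy$tip.label[rev(ij)]
    }
  })
  phy
}
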