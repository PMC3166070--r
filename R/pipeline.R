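#' Run the full genome-profiling classification pipeline
#'
#' Profiles -> all-pairs PaSS distance matrix -> agglomerative tree ->
#' (optionally) congruence against a reference dendrogram. Writes
#' `dist.phy` (PHYLIP square matrix), `tree.nwk`, `congruence.tsv`
#' (when a reference is given; Vc, Vc' and CMS in both subject/object
#' directions) and `manifest.json` (configuration, input checksums,
#' package version) into `out_dir`. Outputs are never silently
#' overwritten: an existing non-empty `out_dir` requires `force = TRUE`.
#'
#' @param profiles A named list of [genome_profile()] objects or the path
#'   of a spiddos TSV file.
#' @param reference Optional reference dendrogram (`phylo`/`hclust`) or
#'   the path of a Newick file; when absent the congruence stage is
#'   skipped with a notice.
#' @param out_dir Output directory (created if missing).
#' @param cfg [pass_config()] for the PaSS stage.
#' @param method Linkage method for [build_tree()].
#' @param criterion Matching criterion for the congruence stage.
#' @param rel_threshold Coarse-graining threshold for Vc'.
#' @param force Overwrite existing outputs.
#' @param quiet Suppress progress messages (logged to stderr).
#' @return Invisibly, a list with the distance matrix, the tree, the
#'   congruence results (or `NULL`) and the manifest.
#' @export
run_pipeline <- function(profiles, reference = NULL, out_dir,
                         cfg = pass_config(),
                         method = c("ward", "average", "median"),
                         criterion = c("exact", "jaccard"),
                         rel_threshold = 0.15, force = FALSE, quiet = FALSE) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  say <- function(...) if (!quiet) message("[gp] ", sprintf(...))

  input_path <- NULL
  if (is.character(profiles)) {
    input_path <- profiles
    if (!file.exists(input_path)) {
      stop("stage read: input file not found: ", input_path, call. = FALSE)
    }
    profiles <- read_spiddos(input_path)
  }
  if (length(profiles) < 2L) stop("stage read: need >= 2 profiles", call. = FALSE)

  ref_path <- NULL
  if (is.character(reference)) {
    ref_path <- reference
    if (!file.exists(ref_path)) {
      stop("stage reference: file not found: ", ref_path, call. = FALSE)
    }
    reference <- from_newick(ref_path)
  }

  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  } else if (!force && length(list.files(out_dir)) > 0L) {
    stop("output directory not empty (use force = TRUE): ", out_dir, call. = FALSE)
  }

  say("stage distance: %d profiles, mode %s, w_theta %g",
      length(profiles), cfg$mode, cfg$w_theta)
  d <- genome_distance_matrix(profiles, cfg)
  write_phylip_dist(d, file.path(out_dir, "dist.phy"), relaxed = TRUE)

  say("stage cluster: %s linkage", method)
  tree <- build_tree(d, method)
  write_newick(tree, file.path(out_dir, "tree.nwk"))

  congr <- NULL
  if (!is.null(reference)) {
    say("stage congruence: criterion %s, bunching threshold %g",
        criterion, rel_threshold)
    fwd <- congruence_value(tree, reference, criterion)
    bwd <- congruence_value(reference, tree, criterion)
    fwd_p <- modified_congruence(tree, reference, criterion, rel_threshold)
    bwd_p <- modified_congruence(reference, tree, criterion, rel_threshold)
    rep_df <- data.frame(
      direction = c("subject_gp", "object_gp"),
      vc = c(fwd$vc, bwd$vc),
      vc_prime = c(fwd_p$vc, bwd_p$vc),
      cms = c(fwd$cms, bwd$cms),
      n_subject_clusters = c(fwd$n_subject_clusters, bwd$n_subject_clusters),
      criterion = criterion
    )
    utils::write.table(rep_df, file.path(out_dir, "congruence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    congr <- list(forward = fwd, backward = bwd,
                  forward_prime = fwd_p, backward_prime = bwd_p)
  } else {
    say("stage congruence: skipped (no reference tree)")
  }

  manifest <- list(
    package = "genoprof",
    version = as.character(utils::packageVersion("genoprof")),
    config = list(
      w_theta = cfg$w_theta, mode = cfg$mode, min_overlap = cfg$min_overlap,
      size_penalty = cfg$size_penalty, method = method,
      criterion = criterion, rel_threshold = rel_threshold
    ),
    inputs = list(
      spiddos = if (is.null(input_path)) "(in-memory)" else input_path,
      reference = if (is.null(ref_path)) NULL else ref_path,
      n_profiles = length(profiles),
      labels = names(profiles)
    ),
    outputs = c("dist.phy", "tree.nwk", if (!is.null(congr)) "congruence.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: outputs in %s", out_dir)
  invisible(list(distances = d, tree = tree, congruence = congr,
                 manifest = manifest))
}
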