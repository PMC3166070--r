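#' Write a distance matrix in PHYLIP square format
#'
#' Strict dialect: labels are truncated/padded to 10 characters; relaxed
#' dialect: labels of any length followed by whitespace. One header line
#' with the number of taxa, then one row per taxon.
#'
#' @param d Symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @param relaxed If `TRUE`, write full labels separated from the numbers
#'   by a tab instead of the fixed 10-character field.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path, relaxed = FALSE) {
  validate_distance_matrix(d)
  labs <- rownames(d)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    row <- paste(sprintf("%.6f", d[i, ]), collapse = "  ")
    if (relaxed) {
      writeLines(paste0(labs[[i]], "\t", row), con)
    } else {
      writeLines(paste0(formatC(substr(labs[[i]], 1L, 10L), width = -10L), row), con)
    }
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Accepts both the strict 10-character-label dialect and the relaxed
#' whitespace-separated dialect (auto-detected: a tab after the label, or
#' a label shorter than 10 characters followed by spaces).
#'
#' @param path Path to a PHYLIP distance file.
#' @return A labelled symmetric numeric matrix.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[[1L]])))
  if (is.na(n) || n < 2L) stop("bad PHYLIP header: ", lines[[1L]], call. = FALSE)
  if (length(lines) < n + 1L) stop("PHYLIP file truncated", call. = FALSE)
  labs <- character(n)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    ln <- lines[[i + 1L]]
    if (grepl("\t", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      labs[[i]] <- parts[[1L]]
      nums <- strsplit(trimws(parts[[2L]]), "\\s+")[[1L]]
    } else {
      toks <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(toks) == n + 1L) {           # relaxed space-separated
        labs[[i]] <- toks[[1L]]
        nums <- toks[-1L]
      } else {                                 # strict fixed-width label
        labs[[i]] <- trimws(substr(ln, 1L, 10L))
        nums <- strsplit(trimws(substring(ln, 11L)), "\\s+")[[1L]]
      }
    }
    if (length(nums) != n) {
      stop(sprintf("row %d: expected %d distances, got %d", i, n, length(nums)),
           call. = FALSE)
    }
    d[i, ] <- as.numeric(nums)
  }
  dimnames(d) <- list(labs, labs)
  d <- (d + t(d)) / 2  # absorb rounding asymmetry from the fixed-digit format
  validate_distance_matrix(d)
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(d))) stop("distance matrix must be labelled", call. = FALSE)
  if (anyDuplicated(rownames(d))) stop("duplicate labels in distance matrix", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (any(d < 0)) stop("negative distances", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero", call. = FALSE)
  invisible(d)
}
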