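#' Read genome profiles from a spiddos TSV file
#'
#' The spiddos TSV dialect: UTF-8, tab-separated, header line
#' `label<TAB>index<TAB>mu<TAB>theta`, one row per spiddo, `#` comment
#' lines ignored. All rows sharing a `label` form one profile, in file
#' order. A file containing only the header yields an empty list.
#'
#' @param path Path to a spiddos TSV file.
#' @return A named list of [genome_profile()] objects, in order of first
#'   appearance.
#' @seealso [write_spiddos()], [read_raw_points()]
#' @export
read_spiddos <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty spiddos file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("label", "index", "mu", "theta"))) {
    stop(sprintf("line %d: expected header 'label\\tindex\\tmu\\ttheta'", lineno[[1L]]),
         call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L) {
      stop(sprintf("line %d: expected 4 tab-separated fields, got %d",
                   lineno[[i]], length(f)), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(num))) {
      stop(sprintf("line %d: non-numeric coordinate in '%s'", lineno[[i]], lines[[i]]),
           call. = FALSE)
    }
    list(label = f[[1L]], index = num[[1L]], mu = num[[2L]], theta = num[[3L]])
  })
  if (length(rows) == 0L) return(structure(list(), names = character()))
  labels <- vapply(rows, `[[`, "", "label")
  first_seen <- unique(labels)
  # a label's rows must be contiguous, otherwise the file interleaves profiles
  runs <- rle(labels)$values
  if (anyDuplicated(runs)) {
    stop(sprintf("duplicate label '%s': profile rows must be contiguous",
                 runs[duplicated(runs)][[1L]]), call. = FALSE)
  }
  profiles <- lapply(first_seen, function(lab) {
    rs <- rows[labels == lab]
    genome_profile(
      lab,
      mu = vapply(rs, `[[`, 0, "mu"),
      theta = vapply(rs, `[[`, 0, "theta"),
      index = vapply(rs, `[[`, 0, "index")
    )
  })
  names(profiles) <- first_seen
  profiles
}

#' Write genome profiles to a spiddos TSV file
#'
#' @param profiles A list of [genome_profile()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spiddos <- function(profiles, path) {
  stopifnot(all(vapply(profiles, inherits, TRUE, "gp_profile")))
  labs <- vapply(profiles, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("duplicate profile labels", call. = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("label\tindex\tmu\ttheta", con)
  for (p in profiles) {
    s <- p$spiddos
    writeLines(sprintf("%s\t%d\t%.10g\t%.10g", p$label, s$index, s$mu, s$theta), con)
  }
  invisible(path)
}

#' Read raw feature points and normalize them into genome profiles
#'
#' The raw variant of the spiddos TSV: header
#' `label<TAB>index<TAB>mobility<TAB>temperature`, plus one directive line
#' `@ref<TAB><mobility><TAB><temperature>` giving the internal reference
#' feature point for the whole file (exactly one reference per profile
#' set). All points are normalized with [normalize_point()].
#'
#' @param path Path to a raw feature-point TSV file.
#' @return A named list of normalized [genome_profile()] objects.
#' @export
read_raw_points <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  ref_ln <- grep("^@ref\t", lines)
  if (length(ref_ln) != 1L) {
    stop("raw feature-point file must contain exactly one '@ref' directive",
         call. = FALSE)
  }
  f <- strsplit(lines[[ref_ln]], "\t", fixed = TRUE)[[1L]]
  if (length(f) != 3L) {
    stop(sprintf("line %d: '@ref' directive needs mobility and temperature", ref_ln),
         call. = FALSE)
  }
  ref <- reference_point(as.numeric(f[[2L]]), as.numeric(f[[3L]]))

  body <- lines[-ref_ln]
  keep <- !grepl("^\\s*#", body) & nzchar(trimws(body))
  body <- body[keep]
  header <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("label", "index", "mobility", "temperature"))) {
    stop("expected header 'label\\tindex\\tmobility\\ttemperature'", call. = FALSE)
  }
  fields <- strsplit(body[-1L], "\t", fixed = TRUE)
  if (length(fields) == 0L) return(structure(list(), names = character()))
  labels <- vapply(fields, `[[`, "", 1L)
  runs <- rle(labels)$values
  if (anyDuplicated(runs)) {
    stop(sprintf("duplicate label '%s'", runs[duplicated(runs)][[1L]]), call. = FALSE)
  }
  profiles <- lapply(unique(labels), function(lab) {
    fs <- fields[labels == lab]
    normalize_profile(
      mobility = vapply(fs, function(x) as.numeric(x[[3L]]), 0),
      temperature = vapply(fs, function(x) as.numeric(x[[4L]]), 0),
      ref = ref, label = lab
    )
  })
  names(profiles) <- unique(labels)
  profiles
}
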