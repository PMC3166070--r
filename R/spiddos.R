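#' Normalize a raw gel feature point against the internal reference
#'
#' Genome profiling records, for every amplified DNA fragment on a
#' temperature gradient gel, the coordinate at which the double-stranded to
#' single-stranded transition begins: a (mobility, temperature) feature
#' point. Coordinates from different gels are only comparable after
#' normalization against the co-migrated internal reference fragment
#' (nominal melting temperature 60 degrees C). The normalized point is a
#' "spiddo" (species identification dot) with dimensionless coordinates
#' `mu = mobility / ref_mobility` and `theta = temperature / ref_temperature`.
#'
#' The componentwise ratio is the default normalization strategy; an
#' alternative map can be supplied through the `strategy` argument of
#' [normalize_profile()].
#'
#' @param mobility Raw gel migration coordinate(s), arbitrary gel units
#'   (must be > 0). Vectorized.
#' @param temperature Raw melting-onset temperature(s) in degrees C.
#'   Vectorized, recycled against `mobility`.
#' @param ref Reference feature point, as created by [reference_point()].
#' @return A two-column matrix with columns `mu` and `theta`.
#' @examples
#' ref <- reference_point(20, 60)
#' normalize_point(10, 30, ref)   # -> mu = 0.5, theta = 0.5
#' @seealso [normalize_profile()], [reference_point()]
#' @export
normalize_point <- function(mobility, temperature, ref) {
  stopifnot(inherits(ref, "gp_reference"))
  if (!all(is.finite(mobility)) || !all(is.finite(temperature))) {
    stop("feature-point coordinates must be finite", call. = FALSE)
  }
  if (any(mobility <= 0)) {
    stop("raw mobility must be > 0", call. = FALSE)
  }
  cbind(mu = mobility / ref$mobility, theta = temperature / ref$temperature)
}

#' Internal reference feature point
#'
#' The reference DNA fragment co-migrated in every gel run; its observed
#' feature-point coordinates anchor the normalization. Its nominal melting
#' temperature is 60 degrees C by construction of the reference fragment.
#'
#' @param mobility Observed reference mobility (gel units, > 0).
#' @param temperature Observed reference melting-onset temperature
#'   (degrees C, > 0).
#' @param nominal_melting_temp Nominal melting temperature of the reference
#'   fragment (degrees C); fixed at 60 for the standard reference.
#' @return An object of class `gp_reference`.
#' @export
reference_point <- function(mobility, temperature, nominal_melting_temp = 60) {
  if (!is.finite(mobility) || mobility <= 0) {
    stop("invalid reference: mobility must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("invalid reference: temperature must be finite and > 0", call. = FALSE)
  }
  structure(
    list(
      mobility = mobility, temperature = temperature,
      nominal_melting_temp = nominal_melting_temp
    ),
    class = "gp_reference"
  )
}

#' Construct a genome profile from normalized spiddos
#'
#' A genome profile is the ordered set of spiddos observed for one
#' species/sample. Serial indices follow input order (1..n); no sorting is
#' imposed because the matching step in [pass_score()] does not rely on
#' order by default.
#'
#' @param label Species/sample identifier (non-empty string).
#' @param mu,theta Numeric vectors of normalized coordinates (> 0).
#' @param index Optional serial indices; default `seq_along(mu)`. Must be
#'   strictly increasing positive integers.
#' @param meta Optional named list of free-form annotations.
#' @return An object of class `gp_profile` with fields `label`, `spiddos`
#'   (a data.frame with columns `index`, `mu`, `theta`) and `meta`.
#' @examples
#' p <- genome_profile("E.coli", mu = c(0.8, 1.1), theta = c(0.95, 1.02))
#' p
#' @export
genome_profile <- function(label, mu, theta, index = seq_along(mu), meta = list()) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("profile label must be a non-empty string", call. = FALSE)
  }
  if (length(mu) == 0L) {
    stop("empty profile: at least one spiddo is required", call. = FALSE)
  }
  if (length(theta) != length(mu) || length(index) != length(mu)) {
    stop("mu, theta and index must have equal length", call. = FALSE)
  }
  if (!all(is.finite(mu)) || !all(is.finite(theta)) || any(mu <= 0) || any(theta <= 0)) {
    stop("spiddo coordinates must be finite and > 0", call. = FALSE)
  }
  index <- as.integer(index)
  if (any(index < 1L) || any(diff(index) <= 0L)) {
    stop("spiddo indices must be strictly increasing integers >= 1", call. = FALSE)
  }
  structure(
    list(
      label = label,
      spiddos = data.frame(index = index, mu = as.numeric(mu), theta = as.numeric(theta)),
      meta = meta
    ),
    class = "gp_profile"
  )
}

#' @export
print.gp_profile <- function(x, ...) {
  cat(sprintf("<genome profile '%s': %d spiddos>\n", x$label, nrow(x$spiddos)))
  print(utils::head(x$spiddos, 8L), row.names = FALSE)
  if (nrow(x$spiddos) > 8L) cat(sprintf("  ... %d more\n", nrow(x$spiddos) - 8L))
  invisible(x)
}

#' Number of spiddos in a profile
#' @param x A `gp_profile`.
#' @return Integer count.
#' @export
n_spiddos <- function(x) {
  stopifnot(inherits(x, "gp_profile"))
  nrow(x$spiddos)
}

#' Normalize a table of raw feature points into a genome profile
#'
#' Vectorizes [normalize_point()] over all raw feature points of one
#' sample and assigns serial indices in input order.
#'
#' @param mobility,temperature Raw coordinates (equal-length vectors).
#' @param ref Reference point ([reference_point()]).
#' @param label Profile label.
#' @param strategy Normalization function `f(mobility, temperature, ref)`
#'   returning a two-column matrix; defaults to the componentwise ratio
#'   [normalize_point()].
#' @return A `gp_profile` with indices `1..n` in input order.
#' @export
normalize_profile <- function(mobility, temperature, ref, label,
                              strategy = normalize_point) {
  if (length(mobility) == 0L) {
    stop("empty profile: no raw feature points supplied", call. = FALSE)
  }
  norm <- strategy(mobility, temperature, ref)
  genome_profile(label, mu = norm[, 1L], theta = norm[, 2L])
}

# spiddo coordinate matrix (n x 2), used throughout the PaSS machinery
spiddo_matrix <- function(profile) {
  as.matrix(profile$spiddos[, c("mu", "theta")])
}
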