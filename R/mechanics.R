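#' Second moment of area of a circular cross-section
#'
#' `I = pi r^4 / 4`: the radius enters to the fourth power, so small radius
#' changes dominate the flexural stiffness `E I`.
#'
#' @param r Trabecular radius (um), `>= 0`.
#' @return Second moment of area (um^4).
#' @export
second_moment_area <- function(r) {
  if (any(r < 0, na.rm = TRUE)) abort("radius must be >= 0")
  pi * r^4 / 4
}

#' Critical Euler buckling force
#'
#' `F_E = n pi^2 E I / L^2`, the load at which an ideal column buckles.
#' The end-condition coefficient `n` is 4 for a beam with two fixed ends
#' (the appropriate condition for trabeculae clamped in nodes at both
#' ends); 1 corresponds to pinned-pinned.
#'
#' @param E Young's modulus (force/area; default 1 = dimensionless mode,
#'   since no calcite stereom modulus is assumed -- absolute forces are
#'   only meaningful when the user supplies `E`).
#' @param I Second moment of area (um^4).
#' @param L Beam length (um), `> 0`.
#' @param n_coeff End-condition coefficient, `> 0` (default 4).
#' @return Critical buckling force in units of `E` times um^2.
#' @export
euler_buckling_force <- function(E, I, L, n_coeff = 4) {
  if (any(L <= 0, na.rm = TRUE)) abort("beam length must be > 0")
  if (any(E <= 0, na.rm = TRUE)) abort("Young's modulus must be > 0")
  if (n_coeff <= 0) abort("`n_coeff` must be > 0")
  n_coeff * pi^2 * E * I / L^2
}

#' Per-segment buckling mechanics
#'
#' Augments a segment descriptor table with the second moment of area,
#' radius of gyration, slenderness ratio and critical Euler buckling force
#' of each trabecula, using the curved length as the beam length.
#' Zero-length segments are flagged and get `NA` forces.
#'
#' @param segments A [segment_table()] tibble.
#' @param E Young's modulus (default 1, dimensionless mode).
#' @param n_coeff End-condition coefficient (default 4, two fixed ends).
#' @return The input tibble with columns `I`, `F_E` and `skipped` added.
#' @export
per_segment_buckling <- function(segments, E = 1, n_coeff = 4) {
  stopifnot(is.data.frame(segments))
  if (nrow(segments) == 0) {
    return(dplyr::mutate(segments, I = numeric(0), F_E = numeric(0),
                         skipped = logical(0)))
  }
  dplyr::mutate(segments,
    I = second_moment_area(.data$mean_radius),
    skipped = .data$curved_length <= 0,
    F_E = ifelse(.data$skipped, NA_real_,
                 n_coeff * pi^2 * E * .data$I / .data$curved_length^2)
  )
}
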