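#' Measurement configuration
#'
#' Central collection of the tunable constants used across the measurement
#' pipeline. Every numerical tolerance or convention that a measurement
#' depends on lives here rather than being hard-coded at its point of use,
#' so a sensitivity analysis can vary them consistently.
#'
#' @param n_slices Number of coronal slices averaged for each muscle
#'   cross-sectional area (the mid-thigh slab). Default 10.
#' @param region_radius Geodesic radius in mm of the landmark-seeded submesh
#'   used to search for the tuberosity apex and the posterior plateau edge.
#'   Default 15 mm; large enough to cover the feature around its seed,
#'   small enough to exclude the malleolus and condyles.
#' @param index_scale Multiplier applied to d1 / tibial length for the
#'   tuberosity projection index. Default 100 (percent-like scale).
#' @param rounding_dp Decimal places used when serialising reports
#'   (half-away-from-zero). Internal values are never rounded.
#' @param unit_tol Permitted deviation of a stored direction from unit
#'   length.
#' @param cos_clamp How far \eqn{|\cos\theta|} may exceed 1 before a
#'   law-of-cosines input is rejected as an invalid triangle; smaller
#'   overshoots are clamped.
#' @param parallel_tol Angular tolerance in radians for treating two plane
#'   normals (or line directions) as parallel.
#' @param tie_tol Tie window in mm for extreme-point selection on a mesh.
#' @param dedup_tol Vertex deduplication distance in mm for mesh input.
#'
#' @return A list of class `morph_config`.
#' @export
morph_config <- function(n_slices = 10L,
                         region_radius = 15,
                         index_scale = 100,
                         rounding_dp = 1L,
                         unit_tol = 1e-9,
                         cos_clamp = 1e-9,
                         parallel_tol = 1e-6,
                         tie_tol = 1e-9,
                         dedup_tol = 1e-6) {
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1L)
    stop("`n_slices` must be a positive integer", call. = FALSE)
  if (region_radius <= 0) stop("`region_radius` must be > 0", call. = FALSE)
  if (index_scale <= 0) stop("`index_scale` must be > 0", call. = FALSE)
  structure(
    list(
      n_slices = n_slices,
      region_radius = region_radius,
      index_scale = index_scale,
      rounding_dp = as.integer(rounding_dp),
      unit_tol = unit_tol,
      cos_clamp = cos_clamp,
      parallel_tol = parallel_tol,
      tie_tol = tie_tol,
      dedup_tol = dedup_tol
    ),
    class = "morph_config"
  )
}
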