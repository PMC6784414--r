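# The six static measurement procedures: segment lengths, flexion angle,
# extensor moment arm, plateau/tuberosity plane metrics and pennation
# angles, all computed from landmarks and meshes in an explicit anatomical
# frame.

#' Femoral length
#'
#' Sagittal-plane distance between the greater trochanter and the
#' intercondylar notch.
#'
#' @param ls A `landmark_set`.
#' @param frame An `anatomical_frame`.
#' @return Length in mm.
#' @export
femoral_length <- function(ls, frame) {
  in_plane_distance(landmark(ls, "greater_trochanter"),
                    landmark(ls, "intercondylar_notch"),
                    frame$lateral)
}

#' Tibial length
#'
#' Coronal-plane distance between the tibial plateau reference point and
#' the lateral malleolus.
#'
#' @inheritParams femoral_length
#' @return Length in mm.
#' @export
tibial_length <- function(ls, frame) {
  in_plane_distance(landmark(ls, "tibial_plateau_ref"),
                    landmark(ls, "lateral_malleolus"),
                    frame$anterior)
}

#' Knee flexion angle
#'
#' The included angle at the knee between the femoral and tibial midshaft
#' directions, measured in the sagittal plane via the law of cosines on the
#' triangle (femur midshaft, knee centre, tibia midshaft) after projecting
#' all three points onto the sagittal plane. Full extension is 180 degrees
#' by this convention.
#'
#' @inheritParams femoral_length
#' @param config A [morph_config()].
#' @return Angle in degrees.
#' @export
flexion_angle <- function(ls, frame, config = morph_config()) {
  sagittal <- plane3(frame$origin, frame$lateral)
  f <- project_point_to_plane(landmark(ls, "femur_midshaft_proximal"), sagittal)
  k <- project_point_to_plane(landmark(ls, "knee_center"), sagittal)
  t <- project_point_to_plane(landmark(ls, "tibia_midshaft_distal"), sagittal)
  a <- vnorm(f - k)
  b <- vnorm(t - k)
  if (a < 1e-9 || b < 1e-9)
    stop("degenerate-angle error: projected midshaft points coincide with the knee",
         call. = FALSE)
  angle_from_sides(a, b, vnorm(f - t), cos_clamp = config$cos_clamp)
}

#' Transepicondylar axis
#'
#' The flexion-extension axis of the femoral condyles: the line through the
#' medial collateral-ligament sulcus directed toward the lateral sulcus.
#'
#' @param ls A `landmark_set`.
#' @return A `line3`.
#' @export
transepicondylar_axis <- function(ls) {
  m <- landmark(ls, "medial_sulcus")
  l <- landmark(ls, "lateral_sulcus")
  if (vnorm(l - m) == 0)
    stop("degenerate-axis error: sulcus landmarks coincide", call. = FALSE)
  line3(m, l - m)
}

#' Extensor mechanism line of action
#'
#' Fits a least-squares plane to the extensor path points (quadriceps
#' tendon to tibial tuberosity) and returns the line through their centroid
#' along the principal in-plane direction, oriented proximal-positive. The
#' fitted plane's normal is oriented along the frame's anterior axis.
#'
#' @inheritParams femoral_length
#' @return A `line3`; the fitted plane is attached as attribute `"plane"`.
#' @export
extensor_line_of_action <- function(ls, frame) {
  pts <- landmark_matrix(ls, "extensor_path")
  if (nrow(pts) < 3L)
    stop("degenerate-fit error: need >= 3 extensor path points", call. = FALSE)
  pl <- fit_plane_least_squares(pts, orient = frame$anterior)
  dir <- attr(pl, "principal")
  if (sum(dir * frame$proximal) < 0) dir <- -dir
  loa <- line3(pl$point, dir)
  attr(loa, "plane") <- pl
  loa
}

#' Extensor moment arm
#'
#' The perpendicular distance between the extensor-mechanism line of action
#' and the transepicondylar axis — the common-perpendicular (skew-line)
#' distance, implemented literally.
#'
#' @param axis Transepicondylar axis (`line3`).
#' @param line_of_action Extensor line of action (`line3`).
#' @return Distance in mm.
#' @export
moment_arm <- function(axis, line_of_action) {
  skew_line_distance(axis, line_of_action)
}

#' Torque-effective moment arm (diagnostic)
#'
#' The mechanically exact lever arm \eqn{|((p - a) \times \hat f) \cdot
#' \hat a|} of a force along the line of action about the axis, provided as
#' a secondary diagnostic alongside the primary common-perpendicular
#' distance. The two coincide when the lines are orthogonal in projection;
#' they differ when the line of action is oblique to the axis.
#'
#' @inheritParams moment_arm
#' @return Lever arm in mm.
#' @export
moment_arm_torque <- function(axis, line_of_action) {
  r <- line_of_action$point - axis$point
  abs(sum(cross3(r, line_of_action$direction) * axis$direction))
}

# Landmark-seeded geodesic submesh: vertices within `radius` of the vertex
# nearest to `seed_point`, distance measured along mesh edges; faces with
# at least one retained vertex are kept so the region always carries faces.
#' Extract a landmark-seeded mesh region
#'
#' @param mesh A `trimesh`.
#' @param seed_point Seed point in mm; the search starts from the nearest
#'   mesh vertex.
#' @param radius Geodesic radius in mm.
#' @return A `trimesh` restricted to the region.
#' @export
mesh_region <- function(mesh, seed_point, radius = morph_config()$region_radius) {
  stopifnot(inherits(mesh, "trimesh"))
  seed_point <- vec3(seed_point, "seed point")
  v <- mesh$vertices
  start <- which.min(colSums((t(v) - seed_point)^2))
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  w <- sqrt(rowSums((v[e[, 1L], , drop = FALSE] - v[e[, 2L], , drop = FALSE])^2))
  g <- igraph::make_graph(as.vector(t(e)), n = nrow(v), directed = FALSE)
  d <- as.vector(igraph::distances(g, v = start, weights = w))
  keep <- which(d <= radius)
  if (!length(keep))
    stop("region error: no mesh vertices within the region radius", call. = FALSE)
  fkeep <- f[rowSums(matrix(f %in% keep, ncol = 3L)) > 0L, , drop = FALSE]
  if (!nrow(fkeep))
    stop("region error: region contains no faces", call. = FALSE)
  used <- sort(unique(as.vector(fkeep)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  trimesh(v[used, , drop = FALSE],
          matrix(remap[fkeep], ncol = 3L))
}

#' Tibial plateau / tibial tuberosity plane metrics
#'
#' Realises the three-parallel-planes construction on the tibial model: a
#' plane with the frame's anterior normal through the most anterior point
#' of the tuberosity region (P1), through the anterior-cortex reference
#' landmark (P2) and through the posteriormost point of the plateau region
#' (P3). `d1` is the P1-P2 separation (tuberosity projection), `d2` the
#' P2-P3 separation (plateau depth); the TP:TT ratio is `d2/d1` and the
#' tuberosity projection index is `index_scale * d1 / tl`.
#'
#' The tuberosity and plateau regions are landmark-seeded geodesic
#' submeshes (seeds `tt_anterior_region` and `tibial_plateau_ref`) so that
#' the extreme-point searches cannot wander onto the malleolus or shaft.
#'
#' @param tibia Tibial surface as a `trimesh`.
#' @param ls A `landmark_set`.
#' @param frame An `anatomical_frame`.
#' @param tl Tibial length in mm (> 0), used to normalise the index.
#' @param config A [morph_config()]; supplies `region_radius` and
#'   `index_scale`.
#' @return A list of class `tp_tt_result` with fields `d1`, `d2`,
#'   `tp_tt_ratio`, `tt_projection_index`, and the three planes.
#' @export
tp_tt_metrics <- function(tibia, ls, frame, tl, config = morph_config()) {
  stopifnot(inherits(tibia, "trimesh"), tl > 0)
  ant <- frame$anterior
  tt_sub <- mesh_region(tibia, landmark(ls, "tt_anterior_region"),
                        config$region_radius)
  tp_sub <- mesh_region(tibia, landmark(ls, "tibial_plateau_ref"),
                        config$region_radius)
  p1 <- plane3(extreme_point_along(tt_sub, ant, config$tie_tol), ant)
  p2 <- plane3(landmark(ls, "anterior_cortex_ref"), ant)
  p3 <- plane3(extreme_point_along(tp_sub, -ant, config$tie_tol), ant)
  d1 <- parallel_plane_separation(p1, p2, config$parallel_tol)
  d2 <- parallel_plane_separation(p2, p3, config$parallel_tol)
  if (d1 <= config$tie_tol)
    stop("degenerate-tuberosity error: tuberosity apex lies on the anterior cortex plane",
         call. = FALSE)
  structure(list(d1 = d1, d2 = d2,
                 tp_tt_ratio = d2 / d1,
                 tt_projection_index = config$index_scale * d1 / tl,
                 planes = list(p1 = p1, p2 = p2, p3 = p3)),
            class = "tp_tt_result")
}

#' Muscle pennation angle
#'
#' Angle between an aponeurosis axis and a fascicle line, constructed the
#' way it is measured on an axial view: unit segments are laid along each
#' direction from the lines' closest-approach midpoint, the triangle is
#' closed, and the law of cosines applied. The acute angle is reported
#' (pennation is conventionally <= 90 degrees). Parallel lines return 0.
#'
#' @param aponeurosis,fascicle `line3` objects.
#' @param config A [morph_config()].
#' @return Angle in degrees, in \[0, 90\].
#' @export
pennation_angle <- function(aponeurosis, fascicle, config = morph_config()) {
  stopifnot(inherits(aponeurosis, "line3"), inherits(fascicle, "line3"))
  cp <- closest_points_between_lines(aponeurosis, fascicle,
                                     config$parallel_tol)
  x <- cp$midpoint
  a <- x + aponeurosis$direction
  b <- x + fascicle$direction
  cc <- vnorm(a - b)
  if (cc < 1e-12) return(0)
  theta <- angle_from_sides(1, 1, cc, cos_clamp = config$cos_clamp)
  if (theta > 90) theta <- 180 - theta
  theta
}

#' One limb's static profile
#'
#' Bundles the ten profile metrics with their units. Values are stored at
#' full precision; reporting rounding happens only at serialisation.
#'
#' @param tl,fl Tibial and femoral length (mm).
#' @param flexion_angle Knee flexion angle (deg).
#' @param qca Total quadriceps cross-sectional area (cm^2).
#' @param qca_fl Quadriceps volume proxy (cm^2 m).
#' @param moment_arm Extensor moment arm (mm).
#' @param tt_projection_index Tuberosity projection index (percent-scale).
#' @param tp_tt_ratio Plateau-to-tuberosity ratio.
#' @param pennation_vl,pennation_rf Pennation angles (deg).
#' @param extras Optional named list of diagnostics (raw d1/d2, the
#'   torque-effective moment arm, per-muscle areas, ...).
#' @return An object of class `limb_metrics`.
#' @export
limb_metrics <- function(tl, fl, flexion_angle, qca, qca_fl, moment_arm,
                         tt_projection_index, tp_tt_ratio,
                         pennation_vl, pennation_rf, extras = list()) {
  vals <- list(tl = tl, fl = fl, flexion_angle = flexion_angle, qca = qca,
               qca_fl = qca_fl, moment_arm = moment_arm,
               tt_projection_index = tt_projection_index,
               tp_tt_ratio = tp_tt_ratio, pennation_vl = pennation_vl,
               pennation_rf = pennation_rf)
  bad <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1L))]
  if (length(bad))
    stop("incomplete-profile error: missing or non-finite fields: ",
         paste(bad, collapse = ", "), call. = FALSE)
  lengths <- c("tl", "fl", "qca", "qca_fl", "moment_arm",
               "tt_projection_index", "tp_tt_ratio")
  neg <- lengths[unlist(vals[lengths]) <= 0]
  if (length(neg))
    stop("limb_metrics fields must be positive: ",
         paste(neg, collapse = ", "), call. = FALSE)
  angles <- c("flexion_angle", "pennation_vl", "pennation_rf")
  av <- unlist(vals[angles])
  if (any(av <= 0 | av > 180))
    stop("limb_metrics angles must lie in (0, 180]", call. = FALSE)
  structure(c(vals, list(extras = extras)), class = "limb_metrics")
}

#' Metric column order used in reports
#' @return Character vector of the ten metric field names.
#' @export
metric_names <- function() {
  c("tl", "fl", "flexion_angle", "qca", "qca_fl", "moment_arm",
    "tt_projection_index", "tp_tt_ratio", "pennation_vl", "pennation_rf")
}

#' @export
as.data.frame.limb_metrics <- function(x, ...) {
  as.data.frame(x[metric_names()], ...)
}

#' @export
print.limb_metrics <- function(x, ...) {
  cat("Static limb profile:\n")
  df <- as.data.frame(x)
  print(round(df, 3))
  invisible(x)
}

pennation_line <- function(ls, prefix) {
  a <- landmark(ls, paste0(prefix, "_1"))
  b <- landmark(ls, paste0(prefix, "_2"))
  line3(a, b - a)
}

#' Measure a full static limb profile
#'
#' Runs every measurement procedure over one limb's landmarks, tibial mesh
#' and muscle label mask and assembles the ten-metric profile. Missing
#' inputs for a metric produce an incomplete-profile error naming the
#' affected fields.
#'
#' @param ls A `landmark_set`.
#' @param tibia Tibial surface (`trimesh`).
#' @param mask A `voxel_mask` of muscle labels.
#' @param femur,extensor Optional surfaces, accepted for completeness of
#'   the input contract; all profile metrics derive from landmarks, the
#'   tibial mesh and the mask.
#' @param config A [morph_config()].
#' @return A `limb_metrics`; diagnostics (raw plane separations, the
#'   torque-effective moment arm, per-muscle mean areas, the frame) are in
#'   `$extras`.
#' @export
measure_limb <- function(ls, tibia, mask, femur = NULL, extensor = NULL,
                         config = morph_config()) {
  frame <- build_frame(ls)
  fl <- femoral_length(ls, frame)
  tl <- tibial_length(ls, frame)
  flex <- flexion_angle(ls, frame, config)
  axis <- transepicondylar_axis(ls)
  loa <- extensor_line_of_action(ls, frame)
  ma <- moment_arm(axis, loa)
  tptt <- tp_tt_metrics(tibia, ls, frame, tl, config)

  missing_pen <- character(0)
  for (pre in c("vl_aponeurosis", "vl_fascicle", "rf_aponeurosis", "rf_fascicle"))
    for (s in c("_1", "_2"))
      if (!paste0(pre, s) %in% rownames(ls$points))
        missing_pen <- c(missing_pen, paste0(pre, s))
  if (length(missing_pen))
    stop("incomplete-profile error: pennation_vl, pennation_rf (missing landmarks: ",
         paste(missing_pen, collapse = ", "), ")", call. = FALSE)
  pen_vl <- pennation_angle(pennation_line(ls, "vl_aponeurosis"),
                            pennation_line(ls, "vl_fascicle"), config)
  pen_rf <- pennation_angle(pennation_line(ls, "rf_aponeurosis"),
                            pennation_line(ls, "rf_fascicle"), config)

  slab <- midfemur_slab(frame, ls, mask, config$n_slices)
  csa <- vapply(c("RF", "VL", "VI", "VM"), function(m)
    mean_csa(slice_areas(mask, m, slab)), numeric(1L))
  qca <- total_qca(csa[["RF"]], csa[["VL"]], csa[["VI"]], csa[["VM"]])
  qfl <- qca_fl(qca, fl)

  limb_metrics(
    tl = tl, fl = fl, flexion_angle = flex, qca = qca, qca_fl = qfl,
    moment_arm = ma, tt_projection_index = tptt$tt_projection_index,
    tp_tt_ratio = tptt$tp_tt_ratio,
    pennation_vl = pen_vl, pennation_rf = pen_rf,
    extras = list(d1 = tptt$d1, d2 = tptt$d2,
                  moment_arm_torque = moment_arm_torque(axis, loa),
                  muscle_csa = csa, slab = slab, frame = frame,
                  axis = axis, line_of_action = loa)
  )
}
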