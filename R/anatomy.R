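# Anatomical landmark bookkeeping and the landmark-derived coordinate frame
# that realises the sagittal / coronal / axial planes for in-plane
# measurements.

#' Landmark names required for a full static profile
#' @return Character vector of required landmark names.
#' @export
required_landmarks <- function() {
  c("greater_trochanter", "lesser_trochanter", "intercondylar_notch",
    "medial_sulcus", "lateral_sulcus", "femur_midshaft_proximal",
    "knee_center", "tibia_midshaft_distal", "tibial_plateau_ref",
    "lateral_malleolus", "tt_anterior_region", "anterior_cortex_ref")
}

#' Named anatomical landmark set
#'
#' Holds named points in a common 3D frame (mm). The required single-point
#' landmarks are listed by [required_landmarks()]; in addition at least
#' three `extensor_path_*` points spanning the quadriceps-tendon-to-
#' tuberosity path are required. Optional per-muscle aponeurosis/fascicle
#' point pairs (`vl_aponeurosis_1`, `vl_aponeurosis_2`, `vl_fascicle_1`,
#' ... and the `rf_` equivalents) enable pennation measurement. Unknown
#' names are preserved and ignored.
#'
#' @param points Named list of numeric(3) points, or a matrix with three
#'   columns and row names.
#' @param side `"left"` or `"right"`.
#' @param validate If `TRUE` (default), missing required names raise one
#'   error listing all of them.
#' @return An object of class `landmark_set` with fields `points`
#'   (n x 3 matrix with row names) and `side`.
#' @export
landmark_set <- function(points, side = c("right", "left"), validate = TRUE) {
  side <- match.arg(side)
  if (is.list(points)) {
    nms <- names(points)
    points <- do.call(rbind, lapply(points, function(p) vec3(p)))
    rownames(points) <- nms
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || is.null(rownames(points)))
    stop("landmarks must be named 3D points", call. = FALSE)
  if (any(!is.finite(points)))
    stop("all landmark coordinates must be finite", call. = FALSE)
  ls <- structure(list(points = points, side = side), class = "landmark_set")
  if (validate) validate_landmarks(ls)
  ls
}

validate_landmarks <- function(ls) {
  nms <- rownames(ls$points)
  missing <- setdiff(required_landmarks(), nms)
  if (sum(startsWith(nms, "extensor_path")) < 3L)
    missing <- c(missing, "extensor_path_* (>= 3 points)")
  if (length(missing))
    stop("named-landmark error: missing landmarks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (vnorm(landmark(ls, "medial_sulcus") - landmark(ls, "lateral_sulcus")) == 0)
    stop("medial_sulcus and lateral_sulcus must differ", call. = FALSE)
  invisible(ls)
}

#' Fetch one landmark by name
#' @param ls A `landmark_set`.
#' @param name Landmark name.
#' @return The point as numeric(3).
#' @export
landmark <- function(ls, name) {
  stopifnot(inherits(ls, "landmark_set"))
  if (!name %in% rownames(ls$points))
    stop("named-landmark error: missing landmark: ", name, call. = FALSE)
  ls$points[name, ]
}

#' Fetch all landmarks whose name matches a prefix
#' @param ls A `landmark_set`.
#' @param prefix Name prefix, e.g. `"extensor_path"`.
#' @return Matrix of matching points (possibly 0 rows).
#' @export
landmark_matrix <- function(ls, prefix) {
  stopifnot(inherits(ls, "landmark_set"))
  sel <- startsWith(rownames(ls$points), prefix)
  ls$points[sel, , drop = FALSE]
}

#' Landmark-derived anatomical frame
#'
#' Builds the right-handed orthonormal (anterior, proximal, lateral) triad
#' that realises the anatomical planes: the sagittal plane has normal
#' `lateral`, the coronal plane has normal `anterior` and the axial plane
#' has normal `proximal`.
#'
#' The proximal axis runs from the knee centre to the proximal femoral
#' midshaft; the lateral axis is the inter-sulcus direction orthogonalised
#' against it (sign-flipped for left limbs so that one canonical code path
#' serves both sides); anterior completes the triad as proximal x lateral.
#'
#' @param ls A `landmark_set`.
#' @param side Limb side; defaults to the side recorded in `ls`.
#' @return An object of class `anatomical_frame` with fields `origin`,
#'   `anterior`, `proximal`, `lateral`.
#' @export
build_frame <- function(ls, side = ls$side) {
  stopifnot(inherits(ls, "landmark_set"))
  side <- match.arg(side, c("right", "left"))
  origin <- landmark(ls, "knee_center")
  proximal <- unitize(landmark(ls, "femur_midshaft_proximal") - origin,
                      "proximal axis")
  lat_raw <- landmark(ls, "lateral_sulcus") - landmark(ls, "medial_sulcus")
  if (side == "left") lat_raw <- -lat_raw
  lat_perp <- lat_raw - sum(lat_raw * proximal) * proximal
  if (vnorm(lat_perp) < 1e-9 * max(vnorm(lat_raw), 1))
    stop("degenerate-frame error: sulci are collinear with the proximal axis",
         call. = FALSE)
  lateral <- unitize(lat_perp, "lateral axis")
  anterior <- cross3(proximal, lateral)
  structure(list(origin = origin, anterior = anterior,
                 proximal = proximal, lateral = lateral),
            class = "anatomical_frame")
}

#' In-plane distance between two points
#'
#' Length of the projection of `b - a` onto the plane with the given
#' normal: \eqn{\sqrt{|b-a|^2 - ((b-a)\cdot \hat n)^2}}. This realises the
#' study's "measured on the sagittal/coronal plane" distances.
#'
#' @param a,b Points (numeric(3), mm).
#' @param plane_normal Non-zero plane normal.
#' @return Distance in mm.
#' @export
in_plane_distance <- function(a, b, plane_normal) {
  n <- unitize(vec3(plane_normal, "plane normal"), "plane normal")
  d <- vec3(b) - vec3(a)
  v <- sum(d * d) - sum(d * n)^2
  sqrt(max(v, 0))
}

#' Read a landmark set from JSON
#'
#' Expected layout: `{"units": "mm", "side": "left|right",
#' "landmarks": {"name": [x, y, z], ...}}`. Validation lists every missing
#' required name in a single error.
#'
#' @param path JSON file path.
#' @param validate Passed to [landmark_set()].
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path, validate = TRUE) {
  if (!file.exists(path))
    stop("landmark file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(doc$units) && !identical(doc$units, "mm"))
    stop("landmark file must declare units \"mm\": ", path, call. = FALSE)
  side <- if (is.null(doc$side)) "right" else doc$side
  pts <- doc$landmarks
  if (is.null(pts) || !length(pts))
    stop("landmark file has no \"landmarks\" map: ", path, call. = FALSE)
  landmark_set(as.list(pts), side = side, validate = validate)
}

#' Write a landmark set to JSON
#' @param ls A `landmark_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(ls, path) {
  stopifnot(inherits(ls, "landmark_set"))
  pts <- lapply(seq_len(nrow(ls$points)), function(i) unname(ls$points[i, ]))
  names(pts) <- rownames(ls$points)
  jsonlite::write_json(list(units = "mm", side = ls$side, landmarks = pts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
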