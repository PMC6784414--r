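# Exact 3D primitives that every static measurement reduces to.
# Points are plain numeric(3) in millimetres; lines and planes are light
# S3 records carrying a point and a unit direction/normal.

vec3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop(sprintf("%s must be a finite numeric vector of length 3", what),
         call. = FALSE)
  p
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "direction") {
  n <- vnorm(v)
  if (n == 0 || !is.finite(n))
    stop(sprintf("degenerate %s: zero or non-finite length", what),
         call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Construct a 3D line
#'
#' @param point A point on the line (numeric(3), mm).
#' @param direction Direction vector; normalised internally and required to
#'   be non-zero.
#' @return An object of class `line3` with fields `point` and unit
#'   `direction`.
#' @export
line3 <- function(point, direction) {
  structure(list(point = vec3(point),
                 direction = unitize(vec3(direction, "direction"))),
            class = "line3")
}

#' Construct a 3D plane
#'
#' @param point A point on the plane (numeric(3), mm).
#' @param normal Normal vector; normalised internally and required to be
#'   non-zero.
#' @return An object of class `plane3` with fields `point` and unit
#'   `normal`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = vec3(point),
                 normal = unitize(vec3(normal, "normal"), "normal")),
            class = "plane3")
}

#' Construct a triangle surface mesh
#'
#' @param vertices Numeric matrix, one row per vertex, three columns (mm).
#' @param faces Integer matrix, one row per triangle, three 1-based vertex
#'   indices. Faces may not repeat a vertex; at least one face is required.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L || nrow(vertices) < 3L || any(!is.finite(vertices)))
    stop("vertices must be a finite n x 3 matrix with n >= 3", call. = FALSE)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L || nrow(faces) < 1L)
    stop("empty-geometry error: a mesh needs at least one triangular face",
         call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
            faces[, 1L] == faces[, 3L]))
    stop("a face may not repeat a vertex", call. = FALSE)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' Angle of a triangle from its three side lengths
#'
#' Law of cosines: returns the angle opposite side `c`, i.e.
#' \eqn{\arccos((a^2+b^2-c^2)/(2ab))}, in degrees. Degenerate (flat)
#' triangles are allowed; side lengths that violate the triangle inequality
#' beyond `cos_clamp` are rejected.
#'
#' @param a,b,c Side lengths (mm), all positive. The returned angle is at
#'   the vertex joining `a` and `b`.
#' @param cos_clamp Tolerance by which the cosine may overshoot \[-1, 1\]
#'   before the input is treated as an invalid triangle.
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_from_sides <- function(a, b, c, cos_clamp = morph_config()$cos_clamp) {
  if (!all(is.finite(c(a, b, c))) || a <= 0 || b <= 0 || c <= 0)
    stop("invalid-triangle error: side lengths must be positive", call. = FALSE)
  cv <- (a^2 + b^2 - c^2) / (2 * a * b)
  if (abs(cv) > 1 + cos_clamp)
    stop("invalid-triangle error: side lengths violate the triangle inequality",
         call. = FALSE)
  acos(max(-1, min(1, cv))) * 180 / pi
}

#' Angle between two directions
#'
#' Arc-cosine of the normalised dot product, in degrees.
#'
#' @param u,v Non-zero numeric(3) direction vectors.
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_between_directions <- function(u, v) {
  u <- unitize(vec3(u, "direction u"))
  v <- unitize(vec3(v, "direction v"))
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Perpendicular distance between two lines
#'
#' Length of the common perpendicular between two (generally skew) lines:
#' \eqn{|(p_2-p_1)\cdot(d_1\times d_2)| / |d_1\times d_2|}. Parallel lines
#' fall back to the point-to-line distance.
#'
#' @param l1,l2 `line3` objects.
#' @param parallel_tol Angular tolerance (radians) below which directions
#'   are treated as parallel.
#' @return Distance in mm, always >= 0.
#' @export
skew_line_distance <- function(l1, l2,
                               parallel_tol = morph_config()$parallel_tol) {
  stopifnot(inherits(l1, "line3"), inherits(l2, "line3"))
  n <- cross3(l1$direction, l2$direction)
  nn <- vnorm(n)
  dp <- l2$point - l1$point
  if (nn < parallel_tol) {
    # parallel: distance from l2's point to l1
    return(vnorm(dp - sum(dp * l1$direction) * l1$direction))
  }
  abs(sum(dp * n)) / nn
}

#' Perpendicular separation of two parallel planes
#'
#' @param p1,p2 `plane3` objects with parallel (or anti-parallel) normals.
#' @param parallel_tol Angular tolerance in radians; normals further apart
#'   raise a non-parallel-planes error.
#' @return Separation in mm, >= 0.
#' @export
parallel_plane_separation <- function(p1, p2,
                                      parallel_tol = morph_config()$parallel_tol) {
  stopifnot(inherits(p1, "plane3"), inherits(p2, "plane3"))
  s <- abs(sum(p1$normal * p2$normal))
  if (acos(max(-1, min(1, s))) > parallel_tol)
    stop("non-parallel-planes error: normals differ beyond tolerance",
         call. = FALSE)
  abs(sum((p2$point - p1$point) * p1$normal))
}

#' Extreme mesh vertex along a direction
#'
#' Returns the vertex with the largest projection onto the normalised
#' direction. Ties within `tie_tol` are broken deterministically in favour
#' of the lowest vertex index.
#'
#' @param mesh A `trimesh`.
#' @param direction Non-zero numeric(3) search direction.
#' @param tie_tol Tie window in mm.
#' @return The winning vertex as numeric(3), with the vertex index attached
#'   as attribute `"index"`.
#' @export
extreme_point_along <- function(mesh, direction,
                                tie_tol = morph_config()$tie_tol) {
  stopifnot(inherits(mesh, "trimesh"))
  d <- unitize(vec3(direction, "direction"))
  proj <- as.vector(mesh$vertices %*% d)
  idx <- which(proj >= max(proj) - tie_tol)[1L]
  structure(mesh$vertices[idx, ], index = idx)
}

#' Orthogonal projection of a point onto a plane
#'
#' @param p Point (numeric(3), mm).
#' @param plane A `plane3`.
#' @return The projected point (numeric(3)); it lies on the plane to within
#'   1e-9 mm.
#' @export
project_point_to_plane <- function(p, plane) {
  stopifnot(inherits(plane, "plane3"))
  p <- vec3(p)
  p - sum((p - plane$point) * plane$normal) * plane$normal
}

#' Least-squares plane fit
#'
#' Fits the plane through the centroid of `points` whose normal is the
#' direction of least variance (smallest principal component). When an
#' `orient` direction is supplied the normal's sign is fixed so that its
#' dot product with `orient` is >= 0 — used to make the extensor-mechanism
#' plane face the anterior axis of the active anatomical frame.
#'
#' @param points Numeric matrix (n x 3), n >= 3, not all collinear.
#' @param orient Optional direction used to fix the normal's sign.
#' @param collinear_tol Relative singular-value threshold below which the
#'   point set is rejected as collinear.
#' @return A `plane3`. The centred singular values are attached as
#'   attribute `"singular_values"` and the principal in-plane direction as
#'   `"principal"`.
#' @export
fit_plane_least_squares <- function(points, orient = NULL,
                                    collinear_tol = 1e-9) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 3L)
    stop("degenerate-fit error: need at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  sv <- svd(x)
  scale <- sv$d[1L]
  if (scale == 0 || sv$d[2L] / scale < collinear_tol)
    stop("degenerate-fit error: points are collinear", call. = FALSE)
  normal <- sv$v[, 3L]
  principal <- sv$v[, 1L]
  if (!is.null(orient) && sum(normal * vec3(orient, "orient")) < 0)
    normal <- -normal
  pl <- plane3(ctr, normal)
  attr(pl, "singular_values") <- sv$d
  attr(pl, "principal") <- principal
  pl
}

# Closest points between two lines; returns list(p1, p2, midpoint).
# For (near-)parallel lines the foot is taken from l1's anchor point.
closest_points_between_lines <- function(l1, l2,
                                         parallel_tol = morph_config()$parallel_tol) {
  d1 <- l1$direction
  d2 <- l2$direction
  r <- l2$point - l1$point
  b <- sum(d1 * d2)
  denom <- 1 - b * b
  if (denom < parallel_tol^2) {
    t1 <- 0
    t2 <- -sum(r * d2)
  } else {
    t1 <- (sum(r * d1) - b * sum(r * d2)) / denom
    t2 <- (b * sum(r * d1) - sum(r * d2)) / denom
  }
  p1 <- l1$point + t1 * d1
  p2 <- l2$point + t2 * d2
  list(p1 = p1, p2 = p2, midpoint = (p1 + p2) / 2)
}
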