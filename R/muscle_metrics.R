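# Slice-based muscle cross-sectional areas from labelled voxel volumes:
# the mid-thigh slab, per-slice areas, the quadriceps total (QCA) and the
# QCA x femoral length volume proxy.

#' Default muscle label codes
#' @return Named integer vector mapping muscle names to label codes.
#' @export
muscle_codes <- function() {
  c(RF = 1L, VL = 2L, VI = 3L, VM = 4L, SA = 5L)
}

#' Labelled voxel volume
#'
#' A 3D integer label grid with per-axis spacing and a rigid grid-to-world
#' transform. Grid axes are named by the anatomical direction they follow
#' when the limb is in its canonical pose (the mask is acquired rigidly
#' with the limb, so the names remain valid under any pose of the whole
#' limb).
#'
#' @param labels 3D integer array; 0 is background.
#' @param spacing Per-axis voxel size in mm (length 3, all > 0).
#' @param origin World position (mm) of the corner of voxel (1,1,1).
#' @param rotation 3x3 rotation whose columns are the world directions of
#'   the grid axes.
#' @param axes Character(3): anatomical direction of each grid axis; must
#'   contain "anterior" (the coronal-slab axis).
#' @param codes Named integer vector of permitted label codes.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(labels, spacing, origin = c(0, 0, 0),
                       rotation = diag(3),
                       axes = c("lateral", "anterior", "proximal"),
                       codes = muscle_codes()) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array", call. = FALSE)
  if (any(labels != round(labels)))
    stop("type error: mask labels must be integer-valued", call. = FALSE)
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes in mm", call. = FALSE)
  rotation <- as.matrix(rotation)
  if (any(abs(crossprod(rotation) - diag(3)) > 1e-6))
    stop("rotation must be orthonormal", call. = FALSE)
  axes <- as.character(axes)
  if (length(axes) != 3L || !"anterior" %in% axes)
    stop("axes must name the three grid directions and include \"anterior\"",
         call. = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, codes)
  if (length(unknown))
    stop("labels outside the declared code set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, spacing = spacing,
                 origin = vec3(origin, "origin"), rotation = rotation,
                 axes = axes, codes = codes),
            class = "voxel_mask")
}

# World point -> continuous voxel coordinates (1-based voxel i spans
# offset [(i-1)s, i*s) from the grid corner).
world_to_voxel <- function(mask, p) {
  u <- as.vector(crossprod(mask$rotation, vec3(p) - mask$origin))
  u / mask$spacing
}

#' Mid-femur coronal slab
#'
#' Selects the `n_slices` coronal slices (stacked along the grid's anterior
#' axis) centred on the slice containing the midpoint of the greater
#' trochanter and the knee centre — the mid-thigh level at which the
#' quadriceps bellies are sectioned. For even `n_slices` the extra slice is
#' taken on the increasing-index side (the deterministic tie rule).
#'
#' @param frame An `anatomical_frame` (accepted for interface symmetry; the
#'   slab is defined by the landmark midpoint and the mask geometry).
#' @param ls A `landmark_set`.
#' @param mask A `voxel_mask`.
#' @param n_slices Number of slices (>= 1).
#' @return Integer vector of slice indices along the anterior grid axis,
#'   with the slab axis attached as attribute `"axis"`.
#' @export
midfemur_slab <- function(frame, ls, mask, n_slices = morph_config()$n_slices) {
  stopifnot(inherits(mask, "voxel_mask"), n_slices >= 1L)
  mid <- (landmark(ls, "greater_trochanter") + landmark(ls, "knee_center")) / 2
  v <- world_to_voxel(mask, mid)
  dims <- dim(mask$labels)
  if (any(v < 0) || any(v > dims))
    stop("out-of-volume error: mid-femur point lies outside the mask extent",
         call. = FALSE)
  ax <- which(mask$axes == "anterior")[1L]
  i0 <- min(floor(v[ax]) + 1L, dims[ax])
  lo <- i0 - floor((n_slices - 1L) / 2)
  hi <- lo + n_slices - 1L
  if (lo < 1L || hi > dims[ax])
    stop("out-of-volume error: slab of ", n_slices,
         " slices around slice ", i0, " exceeds the mask extent", call. = FALSE)
  structure(seq.int(lo, hi), axis = ax)
}

#' Per-slice cross-sectional areas of one muscle
#'
#' Counts labelled voxels per slice and converts to cm^2 using the
#' in-plane voxel area (product of the two non-slab spacings; divided by
#' 100 for mm^2 to cm^2). A voxel contributes its full area when labelled
#' — manual-segmentation counting, with no partial-volume weighting.
#'
#' @param mask A `voxel_mask`.
#' @param label Muscle name (in `names(mask$codes)`) or integer code.
#' @param slices Slice index vector from [midfemur_slab()] (its `"axis"`
#'   attribute selects the slab axis; defaults to the anterior axis).
#' @return An object of class `muscle_slice_series`: list with `label`,
#'   `slices` and per-slice `areas_cm2`.
#' @export
slice_areas <- function(mask, label, slices) {
  stopifnot(inherits(mask, "voxel_mask"))
  code <- if (is.character(label)) {
    if (!label %in% names(mask$codes))
      stop("unknown muscle label: ", label, call. = FALSE)
    mask$codes[[label]]
  } else {
    if (!label %in% mask$codes)
      stop("unknown muscle code: ", label, call. = FALSE)
    as.integer(label)
  }
  ax <- attr(slices, "axis")
  if (is.null(ax)) ax <- which(mask$axes == "anterior")[1L]
  dims <- dim(mask$labels)
  slices <- as.integer(slices)
  if (any(slices < 1L) || any(slices > dims[ax]))
    stop("index error: slice indices out of range", call. = FALSE)
  if (is.unsorted(slices, strictly = TRUE))
    stop("slice indices must be strictly increasing", call. = FALSE)
  pix_mm2 <- prod(mask$spacing[-ax])
  counts <- vapply(slices, function(i) {
    sl <- switch(ax,
                 mask$labels[i, , , drop = FALSE],
                 mask$labels[, i, , drop = FALSE],
                 mask$labels[, , i, drop = FALSE])
    sum(sl == code)
  }, numeric(1L))
  structure(list(label = label, slices = slices,
                 areas_cm2 = counts * pix_mm2 / 100),
            class = "muscle_slice_series")
}

#' Mean cross-sectional area of a slice series
#' @param series A `muscle_slice_series`.
#' @return Mean area in cm^2.
#' @export
mean_csa <- function(series) {
  stopifnot(inherits(series, "muscle_slice_series"))
  if (!length(series$areas_cm2))
    stop("empty-series error: no slices to average", call. = FALSE)
  mean(series$areas_cm2)
}

#' Total quadriceps cross-sectional area
#'
#' Sum of the four quadriceps components (sartorius is segmentable but
#' excluded by definition).
#'
#' @param rf,vl,vi,vm Mean cross-sectional areas in cm^2, all >= 0.
#' @return QCA in cm^2.
#' @export
total_qca <- function(rf, vl, vi, vm) {
  v <- c(rf, vl, vi, vm)
  if (any(!is.finite(v)) || any(v < 0))
    stop("domain error: component areas must be >= 0", call. = FALSE)
  sum(v)
}

#' Quadriceps volume proxy
#'
#' QCA multiplied by femoral length, reported in cm^2 m (femoral length is
#' converted from mm to m).
#'
#' @param qca Quadriceps cross-sectional area (cm^2, >= 0).
#' @param fl Femoral length (mm, > 0).
#' @return Volume proxy in cm^2 m.
#' @export
qca_fl <- function(qca, fl) {
  if (!is.finite(qca) || qca < 0) stop("qca must be >= 0", call. = FALSE)
  if (!is.finite(fl) || fl <= 0) stop("fl must be > 0", call. = FALSE)
  qca * (fl / 1000)
}
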