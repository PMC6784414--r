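# NIfTI ingestion/serialisation of labelled muscle volumes via RNifti.
# The voxel grid's rigid pose is carried in the sform; a JSON sidecar
# declares the label code map and the anatomical direction of each grid
# axis.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".labels.json")
}

#' Write a labelled muscle mask as NIfTI + JSON sidecar
#'
#' The sform encodes spacing, rotation and origin (mapping 0-based voxel
#' indices at voxel centres to world mm); the sidecar stores the label
#' code map and grid axis names.
#'
#' @param mask A `voxel_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- RNifti::asNifti(mask$labels)
  m <- diag(4)
  m[1:3, 1:3] <- mask$rotation %*% diag(mask$spacing)
  m[1:3, 4] <- mask$origin + mask$rotation %*% (mask$spacing / 2)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(
    list(codes = as.list(mask$codes), axes = mask$axes),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a labelled muscle mask from NIfTI + JSON sidecar
#'
#' Requires integer-typed voxel data and the sidecar written by
#' [write_mask()] (or an equivalent hand-written one); a missing sidecar
#' is a configuration error because label codes cannot be guessed.
#'
#' @param path NIfTI path.
#' @return A `voxel_mask`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("config error: missing label sidecar ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$codes) || is.null(meta$axes))
    stop("config error: sidecar must declare codes and axes: ", sc,
         call. = FALSE)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  int_types <- c(2L, 4L, 8L, 256L, 512L, 768L, 1024L, 1280L)
  if (!hdr$datatype %in% int_types)
    stop("type error: mask voxel data must be integer-typed (datatype ",
         hdr$datatype, ")", call. = FALSE)
  m <- RNifti::xform(img)
  lin <- m[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  rotation <- lin %*% diag(1 / spacing)
  origin <- m[1:3, 4] - rotation %*% (spacing / 2)
  codes <- unlist(meta$codes)
  storage.mode(codes) <- "integer"
  voxel_mask(array(as.integer(img), dim = dim(img)),
             spacing = spacing, origin = as.vector(origin),
             rotation = rotation, axes = meta$axes, codes = codes)
}
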