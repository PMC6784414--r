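# Minimal STL reader/writer (ASCII and binary dialects). Units are
# millimetres throughout. Vertices are deduplicated on read within a
# configurable tolerance so that shared triangle corners become shared
# mesh vertices.

dedup_vertices <- function(tri_vertices, tol) {
  key <- apply(round(tri_vertices / tol) * tol, 1L,
               function(r) paste(sprintf("%.9g", r), collapse = "/"))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(vertices = tri_vertices[first, , drop = FALSE], index = idx)
}

#' Read an STL surface
#'
#' Accepts both ASCII and binary STL; the dialect is detected from the
#' file content (a leading "solid" token with facet records is treated as
#' ASCII, otherwise the 84-byte binary header convention applies, cross-
#' checked against the file size). Coordinates are taken as millimetres.
#'
#' @param path STL file path.
#' @param dedup_tol Vertex deduplication distance in mm.
#' @return A `trimesh`.
#' @export
read_stl <- function(path, dedup_tol = morph_config()$dedup_tol) {
  if (!file.exists(path)) stop("STL file not found: ", path, call. = FALSE)
  size <- file.info(path)$size
  if (size < 15)
    stop("STL parse error at byte 0: file too short (", size, " bytes)",
         call. = FALSE)
  head_raw <- readBin(path, "raw", n = min(size, 512))
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  if (is_ascii) read_stl_ascii(path, dedup_tol) else read_stl_binary(path, dedup_tol)
}

read_stl_ascii <- function(path, dedup_tol) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl))
    stop("STL parse error: ASCII file contains no vertex records: ", path,
         call. = FALSE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok[-1L]))
    if (length(v) != 3L || any(is.na(v)))
      stop("STL parse error: malformed vertex line", call. = FALSE)
    v
  })
  tv <- do.call(rbind, nums)
  if (nrow(tv) %% 3L != 0L)
    stop("STL parse error: truncated facet (vertex count not a multiple of 3)",
         call. = FALSE)
  build_mesh_from_soup(tv, dedup_tol)
}

read_stl_binary <- function(path, dedup_tol) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(n) || n < 1L)
    stop("STL parse error at byte 80: invalid triangle count", call. = FALSE)
  expected <- 84 + 50 * as.numeric(n)
  if (size < expected)
    stop("STL parse error at byte ", size, ": truncated binary STL (expected ",
         expected, " bytes for ", n, " triangles)", call. = FALSE)
  rec <- readBin(con, "raw", n = 50L * n)
  rec <- matrix(rec, nrow = 50L)
  float_block <- rec[1:48, , drop = FALSE]
  vals <- readBin(as.vector(float_block), "double", n = 12L * n, size = 4L,
                  endian = "little")
  m <- matrix(vals, nrow = 12L)          # per-triangle: normal + 3 vertices
  tv <- matrix(as.vector(m[4:12, , drop = FALSE]), ncol = 3L, byrow = TRUE)
  build_mesh_from_soup(tv, dedup_tol)
}

build_mesh_from_soup <- function(tri_vertices, dedup_tol) {
  dd <- dedup_vertices(tri_vertices, dedup_tol)
  faces <- matrix(dd$index, ncol = 3L, byrow = TRUE)
  ok <- faces[, 1L] != faces[, 2L] & faces[, 2L] != faces[, 3L] &
    faces[, 1L] != faces[, 3L]
  faces <- faces[ok, , drop = FALSE]
  if (!nrow(faces))
    stop("empty-geometry error: STL contains no non-degenerate faces",
         call. = FALSE)
  trimesh(dd$vertices, faces)
}

#' Write an STL surface
#'
#' @param mesh A `trimesh`.
#' @param path Output path.
#' @param ascii Write the ASCII dialect (default `FALSE` = binary).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "trimesh"))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (ascii) {
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L])
    lines <- c("solid stiflemorph",
               as.vector(rbind(
                 sprintf("  facet normal %s", fmt(n)),
                 "    outer loop",
                 sprintf("      vertex %s", fmt(a)),
                 sprintf("      vertex %s", fmt(b)),
                 sprintf("      vertex %s", fmt(c_)),
                 "    endloop",
                 "  endfacet")),
               "endsolid stiflemorph")
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw("stiflemorph binary STL"),
               raw(80L - nchar("stiflemorph binary STL"))), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    block <- t(cbind(n, a, b, c_))          # 12 floats per triangle
    floats <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
    fm <- matrix(floats, nrow = 48L)
    rec <- rbind(fm, matrix(as.raw(0L), nrow = 2L, ncol = ncol(fm)))
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}
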