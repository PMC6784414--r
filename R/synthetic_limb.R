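# Parametric generator of a stylised kangaroo-like hindlimb: primitive-based
# femur/tibia/extensor surfaces, labelled ellipsoidal muscle bellies, a full
# landmark set and the analytically implied value of every profile metric.
# The phantom replaces imaging specimens as the validation substrate: every
# landmark cluster is placed so that its measurement procedure recovers the
# requested true value exactly in the common anatomical frame.

#' Default muscle belly table for the synthetic limb
#'
#' Ellipsoid semi-axes in mm: `a` lateral, `b` anterior, `c` proximal;
#' `cx` is the lateral centre offset. Bellies are mutually disjoint so that
#' label painting order cannot alter any area. Sizes are chosen so the
#' default total quadriceps cross-sectional area lands near the published
#' median (~84 cm^2) for the default mid-thigh slab.
#'
#' @return Data frame with one row per muscle (RF, VL, VI, VM, SA).
#' @export
synthetic_muscles <- function() {
  data.frame(
    name = c("RF", "VL", "VI", "VM", "SA"),
    code = 1:5,
    cx = c(10, 30, -10, -30, -44),
    a = c(9, 10, 9, 8, 5),
    b = c(25, 25, 25, 25, 18),
    c = c(78, 90, 75, 80, 60)
  )
}

#' Synthetic limb specification
#'
#' Parameters of the phantom, each with the analytic metric it sets. The
#' defaults are tuned to the published four-limb medians (femoral length
#' 200.7 mm, tibial length 400.4 mm, flexion 74.1 deg, moment arm 28.9 mm,
#' TP:TT ratio 1.8, pennation 27.4/28.6 deg).
#'
#' @param fl,tl True femoral and tibial length (mm).
#' @param flexion True included knee angle (deg, in (0, 180)).
#' @param condyle_radius Femoral condyle sphere radius (mm).
#' @param sulcus_separation Distance between the collateral-ligament sulci
#'   (mm); sets the transepicondylar axis.
#' @param tt_projection True anterior projection of the tibial tuberosity
#'   beyond the anterior cortex (d1, mm).
#' @param plateau_depth True cortex-to-posterior-plateau depth (d2, mm);
#'   `plateau_depth / tt_projection` is the true TP:TT ratio.
#' @param extensor_offset True perpendicular distance from the extensor
#'   line of action to the transepicondylar axis (the moment arm, mm).
#' @param extensor_tilt Anterior tilt of the extensor strap relative to the
#'   femoral axis (deg).
#' @param strap_width Extensor strap width (mm).
#' @param malleolus_tilt Lateral tilt of the plateau-to-malleolus line
#'   within the coronal plane (deg).
#' @param pennation_vl,pennation_rf True pennation angles (deg, < 90).
#' @param muscles Muscle belly table as in [synthetic_muscles()].
#' @param spacing Mask voxel spacing (lateral, anterior, proximal) in mm.
#' @param landmark_sigma Isotropic Gaussian landmark noise SD (mm).
#' @param mesh_edge Target mesh edge length (mm).
#' @param side `"right"` or `"left"` (left limbs are generated mirrored).
#' @param pose `"random"` (seeded rigid motion), `"identity"`, or a list
#'   with `rotation` (3x3) and `translation` (numeric(3)).
#' @param seed Integer seed; every random element (pose, noise) flows from
#'   it.
#' @return A list of class `synthetic_limb_spec`.
#' @export
synthetic_limb_spec <- function(fl = 200.7, tl = 400.4, flexion = 74.1,
                                condyle_radius = 15, sulcus_separation = 60,
                                tt_projection = 20, plateau_depth = 36,
                                extensor_offset = 28.9, extensor_tilt = 8,
                                strap_width = 18, malleolus_tilt = 8,
                                pennation_vl = 27.4, pennation_rf = 28.6,
                                muscles = synthetic_muscles(),
                                spacing = c(1, 2.5, 1),
                                landmark_sigma = 0, mesh_edge = 1,
                                side = "right", pose = "identity",
                                seed = 1L) {
  spec <- list(fl = fl, tl = tl, flexion = flexion,
               condyle_radius = condyle_radius,
               sulcus_separation = sulcus_separation,
               tt_projection = tt_projection, plateau_depth = plateau_depth,
               extensor_offset = extensor_offset,
               extensor_tilt = extensor_tilt, strap_width = strap_width,
               malleolus_tilt = malleolus_tilt,
               pennation_vl = pennation_vl, pennation_rf = pennation_rf,
               muscles = muscles, spacing = as.numeric(spacing),
               landmark_sigma = landmark_sigma, mesh_edge = mesh_edge,
               side = match.arg(side, c("right", "left")), pose = pose,
               seed = as.integer(seed))
  validate_limb_spec(spec)
  structure(spec, class = "synthetic_limb_spec")
}

validate_limb_spec <- function(s) {
  pos <- c("fl", "tl", "condyle_radius", "sulcus_separation",
           "tt_projection", "plateau_depth", "extensor_offset",
           "strap_width", "mesh_edge")
  for (f in pos)
    if (!is.finite(s[[f]]) || s[[f]] <= 0)
      stop("spec-validation error: ", f, " must be > 0", call. = FALSE)
  for (f in c("flexion", "pennation_vl", "pennation_rf"))
    if (s[[f]] <= 0 || s[[f]] >= 180)
      stop("spec-validation error: ", f, " must lie in (0, 180)", call. = FALSE)
  if (s$pennation_vl >= 90 || s$pennation_rf >= 90)
    stop("spec-validation error: pennation angles must be acute", call. = FALSE)
  if (any(s$spacing <= 0))
    stop("spec-validation error: voxel spacing must be > 0", call. = FALSE)
  if (s$landmark_sigma < 0)
    stop("spec-validation error: landmark_sigma must be >= 0", call. = FALSE)
  geo <- strap_geometry(s)
  if (s$tt_projection >= geo$y_apex)
    stop("spec-validation error: tt_projection exceeds what the extensor ",
         "offset and tilt allow (tuberosity apex at y = ",
         signif(geo$y_apex, 4), " mm)", call. = FALSE)
  invisible(s)
}

# Sagittal geometry of the extensor strap: line at exact perpendicular
# distance `extensor_offset` from the transepicondylar (x) axis.
strap_geometry <- function(s) {
  psi <- s$extensor_tilt * pi / 180
  u <- c(0, sin(psi), cos(psi))          # along-strap, proximal-positive
  v <- c(0, cos(psi), -sin(psi))         # perpendicular offset direction
  d <- s$extensor_offset
  z_apex <- -(s$condyle_radius + 8)
  t_tt <- (z_apex + d * sin(psi)) / cos(psi)
  apex <- d * v + t_tt * u
  z_g <- -4 + sqrt(s$fl^2 - 64)          # greater trochanter height
  t_top <- (0.9 * z_g + d * sin(psi)) / cos(psi)
  list(u = u, v = v, d = d, z_apex = z_apex, t_tt = t_tt, t_top = t_top,
       apex = apex, y_apex = apex[2L], z_g = z_g)
}

# ---- mesh primitives -------------------------------------------------------

cylinder_mesh <- function(p0, p1, r0, r1, edge) {
  axis <- p1 - p0
  len <- vnorm(axis)
  w <- axis / len
  a <- if (abs(w[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3(w, a))
  e2 <- cross3(w, e1)
  na <- max(8L, ceiling(2 * pi * max(r0, r1) / edge))
  nl <- max(2L, ceiling(len / edge) + 1L)
  th <- seq(0, 2 * pi, length.out = na + 1L)[-(na + 1L)]
  tt <- seq(0, 1, length.out = nl)
  circ <- cbind(cos(th), sin(th))
  verts <- do.call(rbind, lapply(tt, function(s) {
    r <- r0 + (r1 - r0) * s
    ctr <- p0 + s * len * w
    sweep(r * (circ[, 1L] %o% e1 + circ[, 2L] %o% e2), 2L, ctr, `+`)
  }))
  idx <- function(ring, k) (ring - 1L) * na + ((k - 1L) %% na) + 1L
  f <- list()
  for (ring in seq_len(nl - 1L)) {
    k <- seq_len(na)
    f[[ring]] <- rbind(cbind(idx(ring, k), idx(ring, k + 1L), idx(ring + 1L, k)),
                       cbind(idx(ring + 1L, k), idx(ring, k + 1L),
                             idx(ring + 1L, k + 1L)))
  }
  faces <- do.call(rbind, f)
  # end caps (triangle fans around the axis points)
  nv <- nrow(verts)
  verts <- rbind(verts, p0, p1)
  k <- seq_len(na)
  faces <- rbind(faces,
                 cbind(nv + 1L, idx(1L, k + 1L), idx(1L, k)),
                 cbind(nv + 2L, idx(nl, k), idx(nl, k + 1L)))
  trimesh(verts, faces)
}

sphere_mesh <- function(center, r, edge) {
  nphi <- max(6L, ceiling(pi * r / edge))
  nth <- max(8L, ceiling(2 * pi * r / edge))
  phi <- seq(0, pi, length.out = nphi + 1L)[-c(1L, nphi + 1L)]
  th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  grid <- expand.grid(th = th, phi = phi)
  verts <- cbind(r * sin(grid$phi) * cos(grid$th),
                 r * sin(grid$phi) * sin(grid$th),
                 r * cos(grid$phi))
  verts <- sweep(verts, 2L, center, `+`)
  nb <- nphi - 1L                         # latitude bands of ring vertices
  idx <- function(band, k) (band - 1L) * nth + ((k - 1L) %% nth) + 1L
  f <- list()
  if (nb > 1L) for (band in seq_len(nb - 1L)) {
    k <- seq_len(nth)
    f[[band]] <- rbind(cbind(idx(band, k), idx(band, k + 1L), idx(band + 1L, k)),
                       cbind(idx(band + 1L, k), idx(band, k + 1L),
                             idx(band + 1L, k + 1L)))
  }
  faces <- do.call(rbind, f)
  nv <- nrow(verts)
  verts <- rbind(verts, center + c(0, 0, r), center - c(0, 0, r))
  k <- seq_len(nth)
  faces <- rbind(faces,
                 cbind(nv + 1L, idx(1L, k), idx(1L, k + 1L)),
                 cbind(nv + 2L, idx(nb, k + 1L), idx(nb, k)))
  trimesh(verts, faces)
}

box_mesh <- function(xlim, ylim, zlim) {
  v <- as.matrix(expand.grid(x = xlim, y = ylim, z = zlim))
  faces <- rbind(c(1, 3, 7), c(1, 7, 5), c(2, 6, 8), c(2, 8, 4),
                 c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),
                 c(1, 2, 4), c(1, 4, 3), c(5, 7, 8), c(5, 8, 6))
  trimesh(v, faces)
}

merge_meshes <- function(...) {
  parts <- list(...)
  off <- 0L
  verts <- list()
  faces <- list()
  for (i in seq_along(parts)) {
    verts[[i]] <- parts[[i]]$vertices
    faces[[i]] <- parts[[i]]$faces + off
    off <- off + nrow(parts[[i]]$vertices)
  }
  trimesh(do.call(rbind, verts), do.call(rbind, faces))
}

# ---- generator -------------------------------------------------------------

apply_rigid <- function(pts, R, t) sweep(pts %*% t(R), 2L, t, `+`)

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(qr_d)
  R <- R %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

#' Perturb a landmark set with isotropic Gaussian noise
#'
#' Emulates manual point-placement error: every coordinate of every
#' landmark is displaced by iid N(0, sigma^2). `sigma = 0` is the identity.
#'
#' @param ls A `landmark_set`.
#' @param sigma Noise SD in mm (>= 0).
#' @param seed Optional integer seed for reproducible displacements.
#' @return The perturbed `landmark_set`.
#' @export
perturb_landmarks <- function(ls, sigma, seed = NULL) {
  stopifnot(inherits(ls, "landmark_set"), sigma >= 0)
  if (sigma == 0) return(ls)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  ls$points <- ls$points +
    matrix(stats::rnorm(length(ls$points), sd = sigma), nrow = nrow(ls$points))
  ls
}

#' Generate a synthetic limb
#'
#' Builds the phantom implied by a [synthetic_limb_spec()]: femur (capsule
#' shaft plus condylar spheres), tibia (plateau slab, anterior tuberosity
#' wedge, tapered shaft), planar extensor strap, labelled ellipsoid muscle
#' mask, the full landmark set and the analytically implied ground-truth
#' profile. All randomness (pose, landmark noise) is driven by the spec
#' seed, so equal seeds give identical output.
#'
#' @param spec A `synthetic_limb_spec`.
#' @return A list of class `synthetic_limb` with elements `femur`, `tibia`,
#'   `extensor` (`trimesh`), `mask` (`voxel_mask`), `landmarks`
#'   (`landmark_set`), `truth` (`limb_metrics`), `spec` and `pose`.
#' @export
generate_limb <- function(spec) {
  stopifnot(inherits(spec, "synthetic_limb_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  geo <- strap_geometry(spec)
  z_g <- geo$z_g
  cr <- spec$condyle_radius
  s2 <- spec$sulcus_separation / 2
  theta <- spec$flexion * pi / 180
  lam <- spec$malleolus_tilt * pi / 180
  y_apex <- geo$y_apex
  y_c <- y_apex - spec$tt_projection
  y_post <- y_c - spec$plateau_depth
  z_top <- -(cr + 2)
  z_apex <- geo$z_apex

  # landmarks (canonical right-side frame: x lateral, y anterior, z proximal)
  pts <- list(
    knee_center = c(0, 0, 0),
    intercondylar_notch = c(0, -8, -4),
    greater_trochanter = c(0, 0, z_g),
    lesser_trochanter = c(0, -12, 0.75 * z_g),
    femur_midshaft_proximal = c(0, 0, z_g / 2),
    medial_sulcus = c(-s2, 0, 0),
    lateral_sulcus = c(s2, 0, 0),
    tibia_midshaft_distal = (spec$tl / 2) * c(0, sin(theta), cos(theta)),
    tibial_plateau_ref = c(0, y_post, z_top),
    lateral_malleolus = c(0, y_post, z_top) +
      spec$tl * c(sin(lam), 0, -cos(lam)),
    tt_anterior_region = c(0, y_apex, z_apex),
    anterior_cortex_ref = c(0, y_c, z_apex)
  )
  tvals <- seq(geo$t_tt, geo$t_top, length.out = 6L)
  w2 <- spec$strap_width / 2
  path <- do.call(rbind, lapply(tvals, function(t)
    rbind(c(-w2, 0, 0), c(0, 0, 0), c(w2, 0, 0)) +
      matrix(geo$d * geo$v + t * geo$u, 3L, 3L, byrow = TRUE)))
  rownames(path) <- sprintf("extensor_path_%02d", seq_len(nrow(path)))
  # pennation line endpoints in axial planes through the muscle bellies
  pen <- function(cx, z, alpha_deg, theta_deg, la, lf) {
    a <- alpha_deg * pi / 180
    f <- (alpha_deg + theta_deg) * pi / 180
    ctr <- c(cx, 0, z)
    rbind(ctr + la * c(cos(a), sin(a), 0), ctr - la * c(cos(a), sin(a), 0),
          ctr + lf * c(cos(f), sin(f), 0), ctr - lf * c(cos(f), sin(f), 0))
  }
  vl <- pen(30, 0.55 * z_g, 20, spec$pennation_vl, 15, 12)
  rf <- pen(10, 0.60 * z_g, -15, spec$pennation_rf, 15, 12)
  rownames(vl) <- c("vl_aponeurosis_1", "vl_aponeurosis_2",
                    "vl_fascicle_1", "vl_fascicle_2")
  rownames(rf) <- c("rf_aponeurosis_1", "rf_aponeurosis_2",
                    "rf_fascicle_1", "rf_fascicle_2")
  lmk <- rbind(do.call(rbind, pts), path, vl, rf)
  rownames(lmk)[seq_along(pts)] <- names(pts)

  # meshes
  femur <- merge_meshes(
    cylinder_mesh(c(0, 0, 10), c(0, 0, z_g), 12, 12, spec$mesh_edge),
    sphere_mesh(c(-(s2 - cr), 0, 0), cr, spec$mesh_edge),
    sphere_mesh(c(s2 - cr, 0, 0), cr, spec$mesh_edge))
  plateau <- box_mesh(c(-20, 20), c(y_post, y_c), c(z_top - 10, z_top))
  # explicit vertex at the posterior-top edge midpoint: the plateau seed
  # landmark sits exactly here, keeping the region search anchored to the
  # plateau rather than to whichever primitive happens to be nearest
  plateau <- trimesh(rbind(plateau$vertices, c(0, y_post, z_top)),
                     rbind(plateau$faces, c(9L, 5L, 1L), c(9L, 6L, 2L)))
  wedge <- trimesh(
    rbind(c(-9, y_c, z_apex - 6), c(9, y_c, z_apex - 6),
          c(9, y_c, z_apex + 6), c(-9, y_c, z_apex + 6),
          c(-9, y_apex, z_apex), c(9, y_apex, z_apex)),
    rbind(c(1, 2, 3), c(1, 3, 4), c(1, 2, 6), c(1, 6, 5),
          c(4, 3, 6), c(4, 6, 5), c(1, 4, 5), c(2, 3, 6)))
  shaft_dir <- c(sin(lam), 0, -cos(lam))
  shaft0 <- c(0, (y_post + y_c) / 2, z_top - 30)
  tibia <- merge_meshes(
    plateau, wedge,
    cylinder_mesh(shaft0, shaft0 + 0.9 * spec$tl * shaft_dir, 10, 7,
                  spec$mesh_edge))
  nstrap <- max(2L, ceiling((geo$t_top - geo$t_tt) / spec$mesh_edge))
  st <- seq(geo$t_tt, geo$t_top, length.out = nstrap)
  sv <- do.call(rbind, lapply(st, function(t)
    rbind(geo$d * geo$v + t * geo$u + c(-w2, 0, 0),
          geo$d * geo$v + t * geo$u + c(w2, 0, 0))))
  sf <- do.call(rbind, lapply(seq_len(nstrap - 1L), function(i) {
    b <- 2L * (i - 1L)
    rbind(c(b + 1L, b + 2L, b + 3L), c(b + 3L, b + 2L, b + 4L))
  }))
  extensor <- trimesh(sv, sf)

  # labelled muscle mask (canonical grid: x lateral, y anterior, z proximal)
  sp <- spec$spacing
  # the anterior corner is offset by half a slice so the mid-femur point
  # (y = 0) falls at a slice centre, never on a boundary
  x0 <- -52.5; y0 <- -32.5 - sp[2L] / 2; z0 <- -15
  nx <- ceiling(105 / sp[1L])
  ny <- ceiling((65 + sp[2L]) / sp[2L])
  nz <- ceiling((z_g + 30) / sp[3L])
  xs <- x0 + (seq_len(nx) - 0.5) * sp[1L]
  ys <- y0 + (seq_len(ny) - 0.5) * sp[2L]
  zs <- z0 + (seq_len(nz) - 0.5) * sp[3L]
  labels <- array(0L, dim = c(nx, ny, nz))
  zc <- z_g / 2
  mus <- spec$muscles
  for (i in seq_len(nrow(mus))) {
    m <- mus[i, ]
    ix <- which(abs(xs - m$cx) <= m$a)
    iy <- which(abs(ys) <= m$b)
    iz <- which(abs(zs - zc) <= m$c)
    if (!length(ix) || !length(iy) || !length(iz)) next
    ex <- ((xs[ix] - m$cx) / m$a)^2
    ey <- (ys[iy] / m$b)^2
    ez <- ((zs[iz] - zc) / m$c)^2
    inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
    sub <- labels[ix, iy, iz, drop = FALSE]
    sub[inside] <- m$code
    labels[ix, iy, iz] <- sub
  }

  # mirror for left limbs, then pose
  mirror <- if (spec$side == "left") diag(c(-1, 1, 1)) else diag(3)
  if (is.character(spec$pose)) {
    if (identical(spec$pose, "random")) {
      R <- random_rotation()
      tr <- stats::runif(3L, -100, 100)
    } else {
      R <- diag(3)
      tr <- c(0, 0, 0)
    }
  } else {
    R <- as.matrix(spec$pose$rotation)
    tr <- vec3(spec$pose$translation, "translation")
  }
  Rm <- R %*% mirror
  place_mesh <- function(m) trimesh(apply_rigid(m$vertices, Rm, tr), m$faces)
  femur <- place_mesh(femur)
  tibia <- place_mesh(tibia)
  extensor <- place_mesh(extensor)
  lmk <- apply_rigid(lmk, Rm, tr)
  mask <- voxel_mask(labels, spacing = sp,
                     origin = as.vector(Rm %*% c(x0, y0, z0) + tr),
                     rotation = Rm,
                     axes = c("lateral", "anterior", "proximal"))
  landmarks <- landmark_set(lmk, side = spec$side)
  if (spec$landmark_sigma > 0)
    landmarks <- perturb_landmarks(landmarks, spec$landmark_sigma)

  # analytic ground truth
  slab_i0 <- floor((0 - y0) / sp[2L]) + 1L
  n_sl <- morph_config()$n_slices
  lo <- slab_i0 - floor((n_sl - 1L) / 2)
  slab_y <- ys[seq.int(lo, lo + n_sl - 1L)]
  csa_true <- vapply(seq_len(nrow(mus)), function(i) {
    m <- mus[i, ]
    mean(pmax(0, 1 - (slab_y / m$b)^2)) * pi * m$a * m$c / 100
  }, numeric(1L))
  names(csa_true) <- mus$name
  qca_true <- sum(csa_true[c("RF", "VL", "VI", "VM")])
  truth <- limb_metrics(
    tl = spec$tl, fl = spec$fl, flexion_angle = spec$flexion,
    qca = qca_true, qca_fl = qca_true * spec$fl / 1000,
    moment_arm = spec$extensor_offset,
    tt_projection_index = morph_config()$index_scale * spec$tt_projection / spec$tl,
    tp_tt_ratio = spec$plateau_depth / spec$tt_projection,
    pennation_vl = spec$pennation_vl, pennation_rf = spec$pennation_rf,
    extras = list(
      d1 = spec$tt_projection, d2 = spec$plateau_depth,
      muscle_csa = csa_true,
      # frame axes in world coordinates; the lateral axis uses the pose
      # rotation only because build_frame canonicalises left limbs by
      # flipping the inter-sulcus direction (undoing the mirror)
      anterior = as.vector(R %*% c(0, 1, 0)),
      proximal = as.vector(R %*% c(0, 0, 1)),
      lateral = as.vector(R %*% c(1, 0, 0)),
      axis_point = as.vector(Rm %*% c(-s2, 0, 0) + tr),
      axis_direction = as.vector(Rm %*% c(1, 0, 0)),
      loa_direction = as.vector(Rm %*% geo$u)))

  structure(list(femur = femur, tibia = tibia, extensor = extensor,
                 mask = mask, landmarks = landmarks, truth = truth,
                 spec = spec, pose = list(rotation = R, translation = tr)),
            class = "synthetic_limb")
}

#' Draw a random limb specification
#'
#' Samples phantom parameters over ranges bracketing the published
#' four-limb spread (segment lengths, flexion, moment-arm offsets in
#' 20-40 mm, pennation, muscle belly length scale), with a random pose and
#' alternating side.
#'
#' @param seed Integer seed; also stored in the spec.
#' @param landmark_sigma Landmark noise SD passed through (mm).
#' @param mesh_edge Mesh resolution passed through (mm).
#' @return A `synthetic_limb_spec`.
#' @export
random_limb_spec <- function(seed, landmark_sigma = 0, mesh_edge = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  r <- function(lo, hi) stats::runif(1L, lo, hi)
  mus <- synthetic_muscles()
  mus$c <- mus$c * stats::runif(nrow(mus), 0.8, 1.2)
  tt <- r(8, 15)
  synthetic_limb_spec(
    fl = r(180, 220), tl = r(380, 430), flexion = r(65, 90),
    condyle_radius = r(13, 17), sulcus_separation = r(55, 70),
    tt_projection = tt, plateau_depth = r(1.3, 2.0) * tt,
    extensor_offset = r(20, 40), extensor_tilt = r(4, 8),
    pennation_vl = r(18, 46), pennation_rf = r(18, 46),
    muscles = mus, landmark_sigma = landmark_sigma, mesh_edge = mesh_edge,
    side = if (seed %% 2L == 0L) "left" else "right",
    pose = "random", seed = seed)
}

#' Write a synthetic limb to disk
#'
#' Serialises the phantom in the pipeline's exchange formats: three STL
#' surfaces, the NIfTI label mask with its JSON sidecar, the landmark JSON
#' and the ground-truth metrics as JSON.
#'
#' @param limb A `synthetic_limb`.
#' @param dir Output directory (created if needed).
#' @param ascii_stl Write ASCII STL instead of binary.
#' @return Invisibly, the named list of written paths.
#' @export
write_limb <- function(limb, dir, ascii_stl = FALSE) {
  stopifnot(inherits(limb, "synthetic_limb"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    femur = file.path(dir, "femur.stl"),
    tibia = file.path(dir, "tibia.stl"),
    extensor = file.path(dir, "extensor.stl"),
    mask = file.path(dir, "muscles.nii.gz"),
    landmarks = file.path(dir, "landmarks.json"),
    truth = file.path(dir, "truth.json"))
  write_stl(limb$femur, paths$femur, ascii = ascii_stl)
  write_stl(limb$tibia, paths$tibia, ascii = ascii_stl)
  write_stl(limb$extensor, paths$extensor, ascii = ascii_stl)
  write_mask(limb$mask, paths$mask)
  write_landmarks(limb$landmarks, paths$landmarks)
  jsonlite::write_json(limb$truth[metric_names()], paths$truth,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
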