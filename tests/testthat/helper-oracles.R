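# Independent oracles and small generators shared across the suite.
# Each oracle deliberately avoids the code path it checks.

# Brute-force minimum distance between two lines: dense parameter grid
# followed by local (Nelder-Mead) refinement of |P(s) - Q(t)|.
grid_line_distance <- function(l1, l2, half_range = 200, n_grid = 121) {
  s <- seq(-half_range, half_range, length.out = n_grid)
  P <- outer(s, l1$direction) + matrix(l1$point, n_grid, 3, byrow = TRUE)
  Q <- outer(s, l2$direction) + matrix(l2$point, n_grid, 3, byrow = TRUE)
  d2 <- outer(rowSums(P^2), rep(1, n_grid)) +
    outer(rep(1, n_grid), rowSums(Q^2)) - 2 * P %*% t(Q)
  best <- arrayInd(which.min(d2), dim(d2))
  obj <- function(st) {
    dd <- (l1$point + st[1] * l1$direction) - (l2$point + st[2] * l2$direction)
    sum(dd * dd)
  }
  fit <- stats::optim(c(s[best[1]], s[best[2]]), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  sqrt(fit$value)
}

# Sort-based reference for the profile statistics.
sort_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}
sort_range <- function(x) {
  x <- sort(x)
  x[length(x)] - x[1]
}

# Local vector helpers (kept independent of package internals).
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
unitize <- function(v) v / sqrt(sum(v^2))

# Random proper rotation (QR of a Gaussian matrix, sign-fixed).
rand_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

transform_mesh <- function(mesh, R, tr) {
  trimesh(sweep(mesh$vertices %*% t(R), 2, tr, `+`), mesh$faces)
}

transform_landmarks <- function(ls, R, tr) {
  ls$points <- sweep(ls$points %*% t(R), 2, tr, `+`)
  ls
}

# Uniformly scale a generated limb: meshes, landmarks and the mask's
# spatial calibration. Voxel counts do not change, so areas scale by s^2
# purely through the in-plane voxel area.
scale_limb <- function(limb, s) {
  limb$femur$vertices <- limb$femur$vertices * s
  limb$tibia$vertices <- limb$tibia$vertices * s
  limb$extensor$vertices <- limb$extensor$vertices * s
  limb$landmarks$points <- limb$landmarks$points * s
  limb$mask$spacing <- limb$mask$spacing * s
  limb$mask$origin <- limb$mask$origin * s
  limb
}

# Canonical hand-built landmark set: knee at the origin, femur along +z,
# sulci along x, tibia flexed anteriorly; values chosen so each measurement
# has a closed-form expectation.
canonical_landmarks <- function(flexion_deg = 90) {
  th <- flexion_deg * pi / 180
  pts <- list(
    knee_center = c(0, 0, 0),
    intercondylar_notch = c(0, 0, 0),
    greater_trochanter = c(0, 0, 196.1),
    lesser_trochanter = c(0, -10, 150),
    femur_midshaft_proximal = c(0, 0, 100),
    medial_sulcus = c(-30, 0, 0),
    lateral_sulcus = c(30, 0, 0),
    tibia_midshaft_distal = 150 * c(0, sin(th), cos(th)),
    tibial_plateau_ref = c(0, -30, -17),
    lateral_malleolus = c(0, -30, -17) + 395.5 * c(0, 0, -1),
    tt_anterior_region = c(0, 26, -23),
    anterior_cortex_ref = c(0, 6, -23),
    extensor_path_1 = c(-9, 28.9, -20),
    extensor_path_2 = c(0, 28.9, 30),
    extensor_path_3 = c(9, 28.9, 80),
    extensor_path_4 = c(0, 28.9, 130)
  )
  landmark_set(pts, side = "right")
}
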