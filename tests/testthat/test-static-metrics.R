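make_test_tibia <- function(with_wedge = TRUE) {
  plateau_v <- as.matrix(expand.grid(c(-20, 20), c(-54, 0), c(-27, -17)))
  plateau_f <- rbind(c(1, 3, 7), c(1, 7, 5), c(2, 6, 8), c(2, 8, 4),
                     c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),
                     c(1, 2, 4), c(1, 4, 3), c(5, 7, 8), c(5, 8, 6))
  v <- rbind(plateau_v, c(0, -54, -17))
  f <- rbind(plateau_f, c(9, 5, 1), c(9, 6, 2))
  if (with_wedge) {
    wv <- rbind(c(-9, 0, -29), c(9, 0, -29), c(9, 0, -17), c(-9, 0, -17),
                c(-9, 30, -23), c(9, 30, -23))
    wf <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 2, 6), c(1, 6, 5),
                c(4, 3, 6), c(4, 6, 5), c(1, 4, 5), c(2, 3, 6)) + nrow(v)
    v <- rbind(v, wv)
    f <- rbind(f, wf)
  }
  trimesh(v, f)
}

tp_tt_landmarks <- function(apex = c(0, 30, -23)) {
  ls <- canonical_landmarks()
  ls$points["tt_anterior_region", ] <- apex
  ls$points["anterior_cortex_ref", ] <- c(0, 0, -20)
  ls$points["tibial_plateau_ref", ] <- c(0, -54, -17)
  ls
}

test_that("segment lengths are in-plane distances between their landmarks", {
  ls <- canonical_landmarks()
  fr <- build_frame(ls)
  expect_equal(femoral_length(ls, fr), 196.1)
  expect_equal(tibial_length(ls, fr), 395.5)

  # a purely out-of-plane offset measures zero
  ls2 <- ls
  ls2$points["greater_trochanter", ] <-
    ls2$points["intercondylar_notch", ] + c(50, 0, 0)  # along sagittal normal
  expect_equal(femoral_length(ls2, build_frame(ls)), 0)
})

test_that("flexion angle follows the sagittal law-of-cosines construction", {
  ls <- canonical_landmarks(90)
  expect_equal(flexion_angle(ls, build_frame(ls)), 90)
  ls180 <- canonical_landmarks(180)
  expect_equal(flexion_angle(ls180, build_frame(ls180)), 180)

  # dot-product oracle after sagittal projection
  set.seed(17)
  for (i in 1:20) {
    th <- runif(1, 20, 170)
    ls <- canonical_landmarks(th)
    ls$points["femur_midshaft_proximal", ] <-
      ls$points["femur_midshaft_proximal", ] + c(runif(1, -30, 30), 0, 0)
    fr <- build_frame(canonical_landmarks(th))
    f <- ls$points["femur_midshaft_proximal", ]; f[1] <- 0
    t <- ls$points["tibia_midshaft_distal", ]; t[1] <- 0
    expect_equal(flexion_angle(ls, fr),
                 angle_between_directions(f, t), tolerance = 1e-9)
  }
})

test_that("transepicondylar axis joins the sulci and transforms rigidly", {
  ls <- canonical_landmarks()
  ax <- transepicondylar_axis(ls)
  expect_equal(ax$point, c(-30, 0, 0))
  expect_equal(ax$direction, c(1, 0, 0))

  set.seed(19)
  R <- rand_rotation(); tr <- rnorm(3) * 30
  axt <- transepicondylar_axis(transform_landmarks(ls, R, tr))
  expect_equal(axt$point, as.numeric(R %*% ax$point + tr), tolerance = 1e-9)
  expect_equal(axt$direction, as.numeric(R %*% ax$direction), tolerance = 1e-9)

  bad <- ls
  bad$points["lateral_sulcus", ] <- bad$points["medial_sulcus", ]
  expect_error(transepicondylar_axis(bad), "degenerate-axis")
})

test_that("extensor line of action lies in the fitted plane, proximal-positive", {
  ls <- canonical_landmarks()
  fr <- build_frame(ls)
  loa <- extensor_line_of_action(ls, fr)
  pl <- attr(loa, "plane")
  expect_lt(abs(sum(loa$direction * pl$normal)), 1e-9)
  expect_gt(sum(loa$direction * fr$proximal), 0)
  expect_gte(sum(pl$normal * fr$anterior), 0)

  # a straight two-column strap recovers the strap axis
  z <- seq(0, 100, length.out = 6)
  pts <- rbind(cbind(-5, 20, z), cbind(5, 20, z))
  ls2 <- ls
  keep <- !startsWith(rownames(ls2$points), "extensor_path")
  ls2$points <- ls2$points[keep, ]
  rownames(pts) <- sprintf("extensor_path_%02d", seq_len(nrow(pts)))
  ls2$points <- rbind(ls2$points, pts)
  loa2 <- extensor_line_of_action(ls2, fr)
  expect_equal(abs(loa2$direction), c(0, 0, 1), tolerance = 1e-12)
})

test_that("moment arm is the common perpendicular and is symmetric", {
  ax <- line3(c(0, 0, 0), c(1, 0, 0))
  loa <- line3(c(0, 0, 28.9), c(0, 1, 0))
  expect_equal(moment_arm(ax, loa), 28.9)
  expect_equal(moment_arm(loa, ax), 28.9)
  expect_equal(moment_arm(ax, line3(c(0, 0, 0), c(0, 1, 1))), 0)

  # full landmark-driven route on the canonical set: strap offset 28.9 in y
  ls <- canonical_landmarks()
  fr <- build_frame(ls)
  expect_equal(moment_arm(transepicondylar_axis(ls),
                          extensor_line_of_action(ls, fr)),
               28.9, tolerance = 1e-9)
})

test_that("three-plane tuberosity metrics reproduce a constructed tibia", {
  tibia <- make_test_tibia()
  ls <- tp_tt_landmarks()
  fr <- build_frame(ls)
  res <- tp_tt_metrics(tibia, ls, fr, tl = 400)
  expect_equal(res$d1, 30)
  expect_equal(res$d2, 54)
  expect_equal(res$tp_tt_ratio, 1.8)
  expect_equal(res$tt_projection_index, 7.5)

  # translating the tibial complex along the anterior axis changes nothing
  shift <- c(0, 12.5, 0)
  tib2 <- trimesh(sweep(tibia$vertices, 2, shift, `+`), tibia$faces)
  ls2 <- ls
  for (nm in c("tt_anterior_region", "anterior_cortex_ref", "tibial_plateau_ref"))
    ls2$points[nm, ] <- ls2$points[nm, ] + shift
  res2 <- tp_tt_metrics(tib2, ls2, fr, tl = 400)
  expect_equal(res2$d1, res$d1, tolerance = 1e-12)
  expect_equal(res2$d2, res$d2, tolerance = 1e-12)

  # apex on the cortex plane: degenerate tuberosity
  flat <- make_test_tibia(with_wedge = FALSE)
  lsf <- tp_tt_landmarks(apex = c(0, 0, -17))
  lsf$points["anterior_cortex_ref", ] <- c(0, 0, -20)
  expect_error(tp_tt_metrics(flat, lsf, fr, tl = 400), "degenerate-tuberosity")
})

test_that("pennation is the acute triangle angle between the two lines", {
  expect_equal(pennation_angle(line3(c(0, 0, 0), c(1, 0, 0)),
                               line3(c(0, 0, 0), c(0, 1, 0))), 90)
  expect_equal(pennation_angle(line3(c(0, 0, 0), c(1, 0, 0)),
                               line3(c(0, 5, 0), c(1, 0, 0))), 0)
  set.seed(23)
  for (i in 1:20) {
    l1 <- line3(rnorm(3) * 5, rnorm(3))
    l2 <- line3(rnorm(3) * 5, rnorm(3))
    ref <- angle_between_directions(l1$direction, l2$direction)
    if (ref > 90) ref <- 180 - ref
    expect_equal(pennation_angle(l1, l2), ref, tolerance = 1e-9)
  }
})

test_that("profile assembly validates completeness and ranges", {
  err <- expect_error(
    limb_metrics(tl = 400, fl = 200, flexion_angle = 74, qca = 80,
                 qca_fl = 16, moment_arm = 29, tt_projection_index = 5,
                 tp_tt_ratio = 1.8, pennation_vl = NA_real_,
                 pennation_rf = NULL),
    "incomplete-profile")
  expect_match(conditionMessage(err), "pennation_vl")
  expect_match(conditionMessage(err), "pennation_rf")
  expect_error(
    limb_metrics(tl = -1, fl = 200, flexion_angle = 74, qca = 80,
                 qca_fl = 16, moment_arm = 29, tt_projection_index = 5,
                 tp_tt_ratio = 1.8, pennation_vl = 27, pennation_rf = 28),
    "positive")

  # the pipeline names the pennation fields when their landmarks are absent
  limb <- generate_limb(synthetic_limb_spec(mesh_edge = 4))
  ls <- limb$landmarks
  ls$points <- ls$points[!startsWith(rownames(ls$points), "vl_"), ]
  err2 <- expect_error(measure_limb(ls, limb$tibia, limb$mask),
                       "incomplete-profile")
  expect_match(conditionMessage(err2), "pennation_vl")
})
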