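test_that("the generator is deterministic in its seed", {
  a <- generate_limb(synthetic_limb_spec(pose = "random", seed = 42L,
                                         mesh_edge = 4))
  b <- generate_limb(synthetic_limb_spec(pose = "random", seed = 42L,
                                         mesh_edge = 4))
  expect_identical(a$landmarks$points, b$landmarks$points)
  expect_identical(a$tibia$vertices, b$tibia$vertices)
  expect_identical(a$mask$labels, b$mask$labels)
  c <- generate_limb(synthetic_limb_spec(pose = "random", seed = 43L,
                                         mesh_edge = 4))
  expect_false(identical(a$landmarks$points, c$landmarks$points))
})

test_that("landmark perturbation is the identity at sigma 0 and calibrated at sigma 1", {
  ls <- canonical_landmarks()
  expect_identical(perturb_landmarks(ls, 0), ls)
  p1 <- perturb_landmarks(ls, 1, seed = 7)
  p2 <- perturb_landmarks(ls, 1, seed = 7)
  expect_identical(p1$points, p2$points)
  expect_false(identical(p1$points, ls$points))

  # Monte-Carlo: pooled per-coordinate displacement SD within 15% of 1 mm
  disp <- unlist(lapply(1:100, function(s)
    perturb_landmarks(ls, 1, seed = s)$points - ls$points))
  expect_lt(abs(stats::sd(disp) - 1), 0.15)
})

test_that("inconsistent phantom parameters are rejected", {
  expect_error(synthetic_limb_spec(fl = -5), "spec-validation")
  expect_error(synthetic_limb_spec(flexion = 200), "spec-validation")
  expect_error(synthetic_limb_spec(landmark_sigma = -1), "spec-validation")
  # a tuberosity projecting past what the extensor offset allows
  expect_error(synthetic_limb_spec(extensor_offset = 20, tt_projection = 30),
               "spec-validation")
})

test_that("the frame recovered from posed landmarks matches the generator axes", {
  for (s in 1:6) {
    limb <- generate_limb(random_limb_spec(s, mesh_edge = 6))
    fr <- build_frame(limb$landmarks)
    ex <- limb$truth$extras
    expect_lt(angle_between_directions(fr$anterior, ex$anterior), 0.5)
    expect_lt(angle_between_directions(fr$proximal, ex$proximal), 0.5)
    expect_lt(angle_between_directions(fr$lateral, ex$lateral), 0.5)
  }
})

test_that("ground truth is internally consistent and recovered end to end", {
  limb <- generate_limb(synthetic_limb_spec())
  tr <- limb$truth
  expect_equal(tr$qca_fl, tr$qca * tr$fl / 1000)
  expect_equal(tr$tp_tt_ratio, tr$extras$d2 / tr$extras$d1)

  m <- measure_limb(limb$landmarks, limb$tibia, limb$mask)
  for (f in metric_names())
    expect_lt(abs(m[[f]] - tr[[f]]) / tr[[f]], 0.02)
  # geometric metrics are exact, not merely within tolerance
  expect_equal(m$tl, tr$tl, tolerance = 1e-9)
  expect_equal(m$fl, tr$fl, tolerance = 1e-9)
  expect_equal(m$moment_arm, tr$moment_arm, tolerance = 1e-9)
  expect_equal(m$tp_tt_ratio, tr$tp_tt_ratio, tolerance = 1e-9)
})

test_that("recovery holds at two mesh resolutions", {
  for (edge in c(2.5, 5)) {
    limb <- generate_limb(synthetic_limb_spec(mesh_edge = edge,
                                              pose = "random", seed = 5L))
    m <- measure_limb(limb$landmarks, limb$tibia, limb$mask)
    for (f in metric_names())
      expect_lt(abs(m[[f]] - limb$truth[[f]]) / limb$truth[[f]], 0.02)
  }
})

test_that("left and right limbs of the same spec measure identically", {
  r <- generate_limb(synthetic_limb_spec(side = "right", mesh_edge = 4))
  l <- generate_limb(synthetic_limb_spec(side = "left", mesh_edge = 4))
  mr <- measure_limb(r$landmarks, r$tibia, r$mask)
  ml <- measure_limb(l$landmarks, l$tibia, l$mask)
  for (f in metric_names())
    expect_equal(ml[[f]], mr[[f]], tolerance = 1e-9)
})
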