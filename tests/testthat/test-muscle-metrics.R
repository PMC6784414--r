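test_that("mask construction enforces the declared contract", {
  arr <- array(0L, c(4, 4, 4))
  expect_error(voxel_mask(array(0.5, c(2, 2, 2)), spacing = c(1, 1, 1)),
               "integer")
  expect_error(voxel_mask(arr, spacing = c(1, -1, 1)), "positive")
  bad <- arr; bad[1, 1, 1] <- 9L
  expect_error(voxel_mask(bad, spacing = c(1, 1, 1)), "code set")
})

test_that("the mid-femur slab is centred with the documented even-n rule", {
  ls <- canonical_landmarks()
  fr <- build_frame(ls)
  # 100 slices of 2.5 mm along the anterior axis; the grid corner is placed
  # so the mid-femur point (y = 0) falls in the middle of slice 50
  arr <- array(0L, c(40, 100, 200))
  mask <- voxel_mask(arr, spacing = c(1, 2.5, 1), origin = c(-20, -123.75, -1))
  expect_equal(as.integer(midfemur_slab(fr, ls, mask, 10)), 46:55)
  expect_equal(as.integer(midfemur_slab(fr, ls, mask, 1)), 50L)
  expect_equal(as.integer(midfemur_slab(fr, ls, mask, 5)), 48:52)

  far <- voxel_mask(arr, spacing = c(1, 2.5, 1), origin = c(500, 500, 500))
  expect_error(midfemur_slab(fr, ls, far, 10), "out-of-volume")
})

test_that("slice areas count labelled voxels times the in-plane voxel area", {
  arr <- array(0L, c(10, 6, 10))
  arr[1:10, 2:4, 1:10] <- 1L  # RF: 100 voxels in each of slices 2..4
  mask <- voxel_mask(arr, spacing = c(0.5, 2.5, 0.5), origin = c(0, 0, 0))
  ser <- slice_areas(mask, "RF", structure(2:4, axis = 2L))
  expect_equal(ser$areas_cm2, rep(100 * 0.25 / 100, 3))  # 0.25 cm^2 each
  empty <- slice_areas(mask, "VL", structure(2:4, axis = 2L))
  expect_equal(empty$areas_cm2, c(0, 0, 0))
  expect_error(slice_areas(mask, "XX", 2:4), "unknown")
  expect_error(slice_areas(mask, "RF", structure(5:7, axis = 2L)),
               "index error")
})

test_that("a voxelised sphere section approximates the analytic disc", {
  r <- 20; h <- 0.5
  n <- ceiling(2 * r / h) + 4
  xs <- (seq_len(n) - 0.5) * h - (n * h / 2)
  zs <- xs
  ys <- (seq_len(21) - 11) * 2.5
  lab <- array(0L, c(n, 21, n))
  for (j in seq_along(ys)) {
    ry2 <- r^2 - ys[j]^2
    if (ry2 <= 0) next
    disc <- outer(xs^2, zs^2, `+`) <= ry2
    lab[, j, ][disc] <- 1L
  }
  mask <- voxel_mask(lab, spacing = c(h, 2.5, h), origin = c(0, 0, 0))
  mid <- slice_areas(mask, "RF", structure(11L, axis = 2L))
  analytic <- pi * r^2 / 100
  # within one voxel ring of the analytic disc
  ring <- 2 * pi * r * h / 100
  expect_lt(abs(mean_csa(mid) - analytic), ring)

  # halving the in-plane spacing moves the estimate by less than twice the
  # voxel perimeter term
  h2 <- h / 2
  n2 <- ceiling(2 * r / h2) + 4
  xs2 <- (seq_len(n2) - 0.5) * h2 - (n2 * h2 / 2)
  lab2 <- array(0L, c(n2, 1, n2))
  lab2[, 1, ][outer(xs2^2, xs2^2, `+`) <= r^2] <- 1L
  mask2 <- voxel_mask(lab2, spacing = c(h2, 2.5, h2), origin = c(0, 0, 0))
  a2 <- mean_csa(slice_areas(mask2, "RF", structure(1L, axis = 2L)))
  expect_lt(abs(a2 - mean_csa(mid)), 2 * ring)
})

test_that("mean, total and volume proxy compose as documented", {
  ser <- structure(list(label = "RF", slices = 1:3, areas_cm2 = c(1, 2, 3)),
                   class = "muscle_slice_series")
  expect_equal(mean_csa(ser), 2)
  ser1 <- structure(list(label = "RF", slices = 1L, areas_cm2 = 7.5),
                    class = "muscle_slice_series")
  expect_equal(mean_csa(ser1), 7.5)
  ser0 <- structure(list(label = "RF", slices = integer(0),
                         areas_cm2 = numeric(0)),
                    class = "muscle_slice_series")
  expect_error(mean_csa(ser0), "empty-series")

  expect_equal(total_qca(10, 20, 30, 17.1), 77.1)
  expect_equal(total_qca(0, 0, 0, 0), 0)
  expect_error(total_qca(-1, 0, 0, 0), "domain error")
  # permutation invariance
  set.seed(3)
  v <- runif(4, 0, 40)
  p <- sample(4)
  expect_equal(do.call(total_qca, as.list(v)), do.call(total_qca, as.list(v[p])))

  expect_equal(round_half_away(qca_fl(77.1, 196.1), 1), 15.1)
  expect_equal(round_half_away(qca_fl(101.7, 205.2), 1), 20.9)
  expect_equal(qca_fl(0, 123), 0)
  expect_error(qca_fl(10, 0), "fl")
})

test_that("ellipsoid belly areas match the analytic sections within 3%", {
  limb <- generate_limb(synthetic_limb_spec(mesh_edge = 4))
  slab <- midfemur_slab(build_frame(limb$landmarks), limb$landmarks,
                        limb$mask, 10)
  truth <- limb$truth$extras$muscle_csa
  for (m in c("RF", "VL", "VI", "VM")) {
    got <- mean_csa(slice_areas(limb$mask, m, slab))
    expect_lt(abs(got - truth[[m]]) / truth[[m]], 0.03)
  }
  # areas are invariant to relabelling of the other muscles
  mask2 <- limb$mask
  mask2$labels[mask2$labels == 4L] <- 5L  # VM -> SA
  got_rf <- mean_csa(slice_areas(mask2, "RF", slab))
  expect_equal(got_rf, mean_csa(slice_areas(limb$mask, "RF", slab)))
})
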