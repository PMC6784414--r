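test_that("law-of-cosines angle matches closed forms and a coordinate oracle", {
  expect_equal(angle_from_sides(1, 1, 1), 60)
  expect_equal(angle_from_sides(3, 4, 5), 90)
  expect_equal(angle_from_sides(1, 1, 2), 180)  # degenerate, allowed

  # coordinate-construction oracle: intersect circles of radius b and c
  # about the triangle's base, then measure the vertex angle directly
  coord_angle <- function(a, b, c) {
    x <- (a^2 + b^2 - c^2) / (2 * a)
    B <- c(x, sqrt(b^2 - x^2))
    A <- c(a, 0)
    acos(sum(A * B) / (a * b)) * 180 / pi
  }
  expect_equal(angle_from_sides(2, 3, 4), coord_angle(2, 3, 4), tolerance = 1e-12)

  expect_error(angle_from_sides(-1, 2, 2), "invalid-triangle")
  expect_error(angle_from_sides(1, 1, 3), "invalid-triangle")
})

test_that("direction angle agrees with the law of cosines on the spanned triangle", {
  expect_equal(angle_between_directions(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between_directions(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_error(angle_between_directions(c(0, 0, 0), c(1, 0, 0)), "degenerate")

  set.seed(11)
  for (i in 1:50) {
    u <- rnorm(3) * runif(1, 0.1, 20)
    v <- rnorm(3) * runif(1, 0.1, 20)
    lhs <- angle_between_directions(u, v)
    rhs <- angle_from_sides(sqrt(sum(u^2)), sqrt(sum(v^2)), sqrt(sum((u - v)^2)))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("skew-line distance handles skew, intersecting and parallel pairs", {
  lx <- line3(c(0, 0, 0), c(1, 0, 0))
  ly5 <- line3(c(0, 0, 5), c(0, 1, 0))
  expect_equal(skew_line_distance(lx, ly5), 5)
  expect_equal(skew_line_distance(lx, line3(c(0, 0, 0), c(0, 1, 1))), 0)
  expect_equal(skew_line_distance(lx, ly5), skew_line_distance(ly5, lx))

  # parallel: reduces to point-to-line distance
  lp <- line3(c(0, 3, 4), c(1, 0, 0))
  expect_equal(skew_line_distance(lx, lp), 5)
})

test_that("parallel plane separation measures the normal gap", {
  pz0 <- plane3(c(0, 0, 0), c(0, 0, 1))
  pz3 <- plane3(c(7, -2, 3), c(0, 0, 1))
  expect_equal(parallel_plane_separation(pz0, pz3), 3)
  expect_equal(parallel_plane_separation(pz0, pz0), 0)
  # anti-parallel normals carry no orientation information
  expect_equal(parallel_plane_separation(pz0, plane3(c(0, 0, 3), c(0, 0, -1))), 3)
  expect_error(parallel_plane_separation(pz0, plane3(c(0, 0, 0), c(0, 1, 0))),
               "non-parallel")
})

test_that("extreme point search is exact and tie-broken by lowest index", {
  cube <- trimesh(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                  rbind(c(1, 2, 3), c(2, 4, 3), c(5, 6, 7), c(6, 8, 7),
                        c(1, 5, 2), c(2, 5, 6), c(3, 4, 7), c(4, 8, 7)))
  p <- extreme_point_along(cube, c(1, 0, 0))
  expect_equal(p[[1]], 1)
  expect_equal(attr(p, "index"), 2L)  # first vertex with x = 1

  tri <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 matrix(c(1, 2, 3), 1))
  expect_equal(attr(extreme_point_along(tri, c(0, 0, 1)), "index"), 1L)

  set.seed(7)
  v <- matrix(rnorm(90), ncol = 3)
  mesh <- trimesh(v, cbind(1:28, 2:29, 3:30))
  d <- rand_unit()
  got <- extreme_point_along(mesh, d)
  scan <- v[which.max(v %*% d), ]  # exhaustive scan oracle
  expect_equal(as.numeric(got), scan)
})

test_that("point-to-plane projection lands on the plane at minimum distance", {
  pl <- plane3(c(0, 0, 0), c(0, 0, 1))
  expect_equal(project_point_to_plane(c(0.3, -2, 0), pl), c(0.3, -2, 0))
  expect_equal(project_point_to_plane(c(0, 0, 7), pl), c(0, 0, 0))

  set.seed(21)
  for (i in 1:10) {
    pl <- plane3(rnorm(3) * 10, rand_unit())
    p <- rnorm(3) * 20
    q <- project_point_to_plane(p, pl)
    expect_lt(abs(sum((q - pl$point) * pl$normal)), 1e-9)
    # sampled-minimisation oracle: no sampled plane point is closer
    e1 <- unitize(cross3(pl$normal, if (abs(pl$normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    e2 <- cross3(pl$normal, e1)
    grid <- as.matrix(expand.grid(seq(-50, 50, 2), seq(-50, 50, 2)))
    samples <- grid %*% rbind(e1, e2) + matrix(pl$point, nrow(grid), 3, byrow = TRUE)
    dmin <- sqrt(min(rowSums(sweep(samples, 2, p)^2)))
    expect_lte(sqrt(sum((q - p)^2)), dmin + 1e-9)
  }
})

test_that("least-squares plane fit recovers exact and noisy planes", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  pl <- fit_plane_least_squares(sq)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)

  three <- rbind(c(0, 0, 1), c(2, 0, 3), c(0, 5, -1))
  pl3 <- fit_plane_least_squares(three)
  for (i in 1:3)
    expect_lt(abs(sum((three[i, ] - pl3$point) * pl3$normal)), 1e-9)

  set.seed(31)
  n_true <- rand_unit()
  e1 <- unitize(cross3(n_true, c(0, 0, 1) + 0.3))
  e2 <- cross3(n_true, e1)
  pts <- matrix(runif(200, -30, 30), ncol = 2) %*% rbind(e1, e2) +
    matrix(rnorm(300, sd = 0.1), ncol = 3)
  plf <- fit_plane_least_squares(pts, orient = n_true)
  expect_lt(angle_between_directions(plf$normal, n_true), 1)

  expect_error(fit_plane_least_squares(rbind(c(0, 0, 0), c(1, 1, 1))),
               "degenerate-fit")
  line_pts <- outer(seq(0, 1, 0.25), c(1, 2, 3))
  expect_error(fit_plane_least_squares(line_pts), "degenerate-fit")
})

test_that("distance operators are rigid-invariant and scale-equivariant", {
  set.seed(41)
  for (i in 1:20) {
    l1 <- line3(rnorm(3) * 20, rnorm(3))
    l2 <- line3(rnorm(3) * 20, rnorm(3))
    p1 <- plane3(rnorm(3) * 20, n <- rand_unit())
    p2 <- plane3(rnorm(3) * 20, n)
    R <- rand_rotation(); tr <- rnorm(3) * 50
    tl <- function(l) line3(R %*% l$point + tr, R %*% l$direction)
    tp <- function(p) plane3(R %*% p$point + tr, R %*% p$normal)
    expect_equal(skew_line_distance(tl(l1), tl(l2)),
                 skew_line_distance(l1, l2), tolerance = 1e-6)
    expect_equal(parallel_plane_separation(tp(p1), tp(p2)),
                 parallel_plane_separation(p1, p2), tolerance = 1e-6)
    expect_equal(angle_between_directions(R %*% l1$direction, R %*% l2$direction),
                 angle_between_directions(l1$direction, l2$direction),
                 tolerance = 1e-6)
    for (s in c(0.5, 2, 10)) {
      sl <- function(l) line3(s * l$point, l$direction)
      expect_equal(skew_line_distance(sl(l1), sl(l2)),
                   s * skew_line_distance(l1, l2), tolerance = 1e-9)
    }
  }
})

test_that("mesh construction validates faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(trimesh(v, matrix(c(1, 2, 4), 1)), "out of range")
  expect_error(trimesh(v, matrix(c(1, 1, 2), 1)), "repeat")
  expect_error(trimesh(v, matrix(integer(0), ncol = 3)), "empty-geometry")
})
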