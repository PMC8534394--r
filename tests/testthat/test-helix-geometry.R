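test_that("fit_axis recovers the construction axis and radius", {
  h <- build_ideal_helix(18, ca_radius = 2.3)
  f <- fit_axis(ca_coords(h))
  expect_lt(acos(min(1, abs(sum(f$axis_dir * c(0, 0, 1))))) * 180 / pi, 1)
  expect_equal(f$local_radius, 2.3, tolerance = 0.1)

  # equivariance under a rigid rotation
  R <- rotation_about_z <- matrix(c(cos(0.7), -sin(0.7), 0,
                                    sin(0.7), cos(0.7), 0, 0, 0, 1), 3, byrow = TRUE)
  f2 <- fit_axis(ca_coords(h) %*% t(R))
  expect_lt(acos(min(1, abs(sum(f2$axis_dir * (R %*% c(0, 0, 1)))))) * 180 / pi, 1)

  expect_error(fit_axis(matrix(rnorm(12), 4, 3)), "at least 5")
  line_pts <- cbind(seq(0, 10, length.out = 8), 0, 0)
  expect_error(fit_axis(line_pts), "collinear")
})

test_that("fit_axis agrees with a direct SVD line fit on noisy helices", {
  set.seed(11)
  h <- build_ideal_helix(20)
  ca <- ca_coords(h) + matrix(rnorm(20 * 3, sd = 0.3), 20, 3)
  f <- fit_axis(ca)
  # oracle: principal component of the same 4-point window centroids
  centers <- t(vapply(1:17, function(i) colMeans(ca[i:(i + 3), ]), numeric(3)))
  pc <- prcomp(centers)$rotation[, 1]
  ang <- acos(min(1, abs(sum(f$axis_dir * pc)))) * 180 / pi
  expect_lt(ang, 1e-6)
  # and within 5 degrees of the generator axis
  expect_lt(acos(min(1, abs(f$axis_dir[3]))) * 180 / pi, 5)
})

test_that("analytic descriptor cases are reproduced", {
  mk <- function(point, dir, n = 18) {
    helix_segment_from_ca(ca_coords(build_ideal_helix(n, axis_point = point, axis_dir = dir)))
  }
  # parallel axes offset 10 A
  a <- mk(c(0, 0, 0), c(0, 0, 1)); b <- mk(c(10, 0, 0), c(0, 0, 1))
  d <- pair_descriptors(a, b)
  expect_equal(d$d, 10, tolerance = 1e-6)
  expect_equal(d$r, 10, tolerance = 1e-6)
  expect_equal(d$theta, 0)
  expect_equal(d$phi, 0, tolerance = 0.2)
  # perpendicular skew with interior closest points, gap 9.2
  a <- mk(c(0, 0, 0), c(0, 0, 1)); b <- mk(c(9.2, 0, 0), c(0, 1, 0))
  d <- pair_descriptors(a, b)
  expect_equal(d$d, 9.2, tolerance = 1e-6)
  expect_equal(d$r, 9.2, tolerance = 1e-6)
  expect_equal(d$phi, 90, tolerance = 1e-6)
})

test_that("swap symmetry: d, r, phi, S, P identical; theta preserved by convention", {
  bp <- build_helix_pair(7, 55)
  s <- bp$structure
  a <- helix_segment(s, "A", bp$helices$a[1], bp$helices$a[2])
  b <- helix_segment(s, "A", bp$helices$b[1], bp$helices$b[2])
  ab <- pair_descriptors(a, b); ba <- pair_descriptors(b, a)
  expect_equal(ab$d, ba$d, tolerance = 1e-9)
  expect_equal(ab$r, ba$r, tolerance = 1e-9)
  expect_equal(ab$phi, ba$phi, tolerance = 1e-9)
  expect_equal(ab$S, ba$S, tolerance = 1e-9)
  expect_equal(ab$P, ba$P, tolerance = 1e-9)
  # with this sign convention theta is symmetric under swap
  expect_equal(ab$theta, ba$theta, tolerance = 1e-9)
})

test_that("strip projection polygon matches closed forms", {
  # identical coincident rectangles: S = L*w, P = 2(L+w)
  h <- build_ideal_helix(18)
  a <- helix_segment_from_ca(ca_coords(h), radius = 5)
  d <- strip_projection_polygon(a, a)
  L <- a$axis_len
  expect_equal(d$S, L * 10, tolerance = 1e-6)
  expect_equal(d$P, 2 * (L + 10), tolerance = 1e-6)

  # long strips crossing at 66 degrees: S = w1 w2 / sin(66)
  bp <- build_helix_pair(0, 66, n_a = 26, n_b = 26)
  s <- bp$structure
  a <- helix_segment(s, "A", bp$helices$a[1], bp$helices$a[2])
  b <- helix_segment(s, "A", bp$helices$b[1], bp$helices$b[2])
  pol <- strip_projection_polygon(a, b)
  expect_equal(pol$S, 100 / sin(66 * pi / 180), tolerance = 0.01 * 109.5)

  expect_equal(strip_projection_polygon(a, b)$S > 0,
               strip_projection_polygon(a, b)$P > 0)
  a$radius <- 0
  expect_error(strip_projection_polygon(a, b), "zero projection radius")
})

test_that("polygon clipping area matches the Monte-Carlo oracle", {
  set.seed(21)
  for (k in 1:10) {
    ra <- make_rect(runif(2, -3, 3), runif(1, 0, 180), runif(1, 8, 25), runif(1, 4, 12))
    rb <- make_rect(runif(2, -3, 3), runif(1, 0, 180), runif(1, 8, 25), runif(1, 4, 12))
    poly <- helixptm:::polygon_dedup(helixptm:::convex_clip(ra, rb))
    S <- helixptm:::polygon_area(poly)
    S_mc <- mc_intersection_area(ra, rb, n = 4e5, seed = k)
    if (S_mc > 5) expect_equal(S, S_mc, tolerance = 0.02)
  }
})

test_that("rigid motion leaves all six descriptors unchanged", {
  bp <- build_helix_pair(9.2, 66, n_a = 18, n_b = 24)
  s <- bp$structure
  get_desc <- function(st) {
    a <- helix_segment(st, "A", bp$helices$a[1], bp$helices$a[2])
    b <- helix_segment(st, "A", bp$helices$b[1], bp$helices$b[2])
    pair_descriptors(a, b)
  }
  d0 <- get_desc(s)
  for (seed in 1:3) {
    d1 <- get_desc(transform_structure(s, seed))
    for (k in c("d", "r", "theta", "phi", "S", "P")) {
      expect_equal(d1[[k]], d0[[k]], tolerance = 1e-6)
    }
  }
})

test_that("d <= r always, with equality for interior crossings", {
  set.seed(5)
  ca_template <- ca_coords(build_ideal_helix(16))
  for (k in 1:200) {
    a <- helix_segment_from_ca(random_rigid(ca_template, seed = 2 * k))
    b <- helix_segment_from_ca(random_rigid(ca_template, seed = 2 * k + 1))
    d <- pair_descriptors(a, b)
    expect_lte(d$d, d$r + 1e-9)
    if (d$interior_crossing) expect_equal(d$d, d$r, tolerance = 1e-6)
  }
})
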