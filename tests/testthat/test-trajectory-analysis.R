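test_that("kabsch_rmsd is zero for congruent frames and symmetric", {
  set.seed(2)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(A, A), 0, tolerance = 1e-9)
  B <- random_rigid(A, seed = 3)
  expect_lt(kabsch_rmsd(A, B), 1e-6)
  C <- A + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(kabsch_rmsd(A, C), kabsch_rmsd(C, A), tolerance = 1e-9)
  expect_error(kabsch_rmsd(A, A[1:5, ]), "mismatched")
})

test_that("kabsch_rmsd matches a brute-force rotation-grid oracle", {
  set.seed(14)
  A <- matrix(rnorm(15, sd = 3), 5, 3)
  for (k in 1:3) {
    B <- A + matrix(rnorm(15, sd = 0.4), 5, 3)
    expect_equal(kabsch_rmsd(A, B), grid_min_rmsd(A, B), tolerance = 1e-4)
  }
  # one atom displaced by 1 A among N: RMSD <= sqrt(1/N) (refit can reduce it)
  N <- 20
  A <- matrix(rnorm(3 * N, sd = 4), N, 3)
  B <- A; B[1, ] <- B[1, ] + c(1, 0, 0)
  v <- kabsch_rmsd(A, B)
  expect_lte(v, sqrt(1 / N) + 1e-9)
  expect_gt(v, 0.8 * sqrt(1 / N))
})

test_that("descriptor series: frame 1 is the initial reference", {
  bp <- build_helix_pair(9.2, 66, n_a = 18, n_b = 24)
  tr <- perturb_trajectory(bp$structure, n_frames = 8, sigma = 0.2, seed = 4)
  ser <- descriptor_series(tr, "A", bp$helices$a, bp$helices$b)
  ini <- attr(ser, "initial")
  a <- helix_segment(tr, "A", bp$helices$a[1], bp$helices$a[2], model = 1)
  b <- helix_segment(tr, "A", bp$helices$b[1], bp$helices$b[2], model = 1)
  d0 <- pair_descriptors(a, b)
  for (k in c("d", "r", "theta", "phi", "S", "P")) {
    expect_equal(as.numeric(ini[[k]]), d0[[k]], tolerance = 1e-12)
    expect_equal(ser[[k]][1], d0[[k]], tolerance = 1e-12)
  }
  expect_gt(sd(ser$d), 0)
  expect_lt(abs(mean(ser$d) - ser$d[1]), 2 * sd(ser$d) + 0.2)
})

test_that("identical or rigidly moving trajectories give constant series", {
  bp <- build_helix_pair(8, 60, n_a = 18, n_b = 18)
  still <- perturb_trajectory(bp$structure, n_frames = 5, sigma = 0)
  ser <- descriptor_series(still, "A", bp$helices$a, bp$helices$b)
  expect_equal(sd(ser$d), 0, tolerance = 1e-12)
  moving <- perturb_trajectory(bp$structure, n_frames = 5, sigma = 0, drift = TRUE)
  ser2 <- descriptor_series(moving, "A", bp$helices$a, bp$helices$b)
  for (k in c("d", "r", "theta", "phi", "S", "P")) {
    expect_lt(max(abs(ser2[[k]] - ser2[[k]][1])), 1e-6)
  }
})

test_that("GROMOS clustering matches the brute-force greedy rule", {
  set.seed(8)
  for (k in 1:5) {
    # random synthetic RMSD-like symmetric matrix over 12 frames
    n <- 12
    P <- matrix(runif(n * 3, 0, 4), n, 3)
    M <- as.matrix(dist(P))
    got <- gromos_cluster(NULL, cutoff = 1.0, rmsd = M)
    expect_identical(got$clusters, gromos_brute(M, 1.0))
  }
  # on a real pseudo-trajectory too
  tr <- perturb_trajectory(build_ideal_helix(10), n_frames = 12, sigma = 0.6, seed = 12)
  M <- rmsd_matrix(tr)
  got <- gromos_cluster(tr, cutoff = 0.5)
  expect_identical(got$clusters, gromos_brute(M, 0.5))
})

test_that("clustering forms a partition with non-increasing sizes", {
  tr <- perturb_trajectory(build_ideal_helix(10), n_frames = 15, sigma = 0.7, seed = 5)
  for (cutoff in c(0.3, 0.6, 1.2)) {
    cl <- gromos_cluster(tr, cutoff = cutoff)
    all_frames <- sort(unlist(cl$clusters))
    expect_identical(all_frames, 1:15)
    sizes <- vapply(cl$clusters, length, integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
  # limits: huge cutoff -> one cluster; tiny cutoff -> singletons
  expect_length(gromos_cluster(tr, cutoff = 1e6)$clusters, 1)
  expect_length(gromos_cluster(tr, cutoff = 1e-9)$clusters, 15)
  # identical frames cluster together at any cutoff
  still <- perturb_trajectory(build_ideal_helix(10), n_frames = 6, sigma = 0)
  expect_length(gromos_cluster(still, cutoff = 0.01)$clusters, 1)
  expect_identical(largest_cluster(gromos_cluster(still, 0.01)), 1:6)
})

test_that("two constructed conformer groups separate at the right cutoff", {
  h <- build_ideal_helix(10)
  x0 <- model_xyz(h)
  xyz <- vector("list", 10)
  set.seed(77)
  for (k in 1:7) xyz[[k]] <- x0 + matrix(rnorm(length(x0), sd = 0.05), nrow(x0), 3)
  shifted <- x0; shifted[1:10, ] <- shifted[1:10, ] + 5  # distinct conformer
  for (k in 8:10) xyz[[k]] <- shifted + matrix(rnorm(length(x0), sd = 0.05), nrow(x0), 3)
  tr <- helixptm:::new_structure("two-state", h$atoms, xyz)
  cl <- gromos_cluster(tr, cutoff = 1.0)
  expect_equal(vapply(cl$clusters, length, integer(1)), c(7L, 3L))
})

test_that("stability summaries use sample sd and deviations from initial", {
  ser <- data.frame(frame = 1:3, d = c(9, 10, 11), r = c(9, 10, 11),
                    theta = 0, phi = 0, S = 1, P = 1)
  attr(ser, "initial") <- data.frame(d = 10, r = 10, theta = 0, phi = 0, S = 1, P = 1)
  class(ser) <- c("descriptor_series", "data.frame")
  sm <- stability_summary(ser)
  expect_equal(sm$mean[sm$descriptor == "d"], 10)
  expect_equal(sm$sd[sm$descriptor == "d"], 1)     # sample (n-1) convention
  expect_equal(sm$max_dev[sm$descriptor == "d"], 1)
  cmp <- stability_comparison(ser, ser)
  expect_setequal(unique(cmp$variant), c("stat", "nmd", "mod"))
  expect_equal(cmp$sd[cmp$variant == "stat"], rep(0, 6))
})

test_that("noise magnitude is recovered from a synthetic series", {
  # d between two rigid helices under iid coordinate noise: the axis fit
  # averages ~n centers, so sd(d) is well below sigma but positive
  bp <- build_helix_pair(9, 70, n_a = 18, n_b = 18)
  tr <- perturb_trajectory(bp$structure, n_frames = 60, sigma = 0.2, seed = 9)
  ser <- descriptor_series(tr, "A", bp$helices$a, bp$helices$b)
  expect_gt(sd(ser$d), 0.005)
  expect_lt(sd(ser$d), 0.2)
})
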