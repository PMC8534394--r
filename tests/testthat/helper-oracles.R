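# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# Monte-Carlo area of the intersection of two convex quadrilaterals.
# Points are sampled uniformly in the joint bounding box; membership is
# tested with per-edge cross products.
mc_intersection_area <- function(ra, rb, n = 1e6, seed = 1) {
  set.seed(seed)
  allv <- rbind(ra, rb)
  lo <- apply(allv, 2, min); hi <- apply(allv, 2, max)
  px <- runif(n, lo[1], hi[1]); py <- runif(n, lo[2], hi[2])
  inside_quad <- function(q) {
    m <- nrow(q)
    cr <- matrix(NA_real_, n, m)
    for (i in seq_len(m)) {
      a <- q[i, ]; b <- q[(i %% m) + 1, ]
      cr[, i] <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    }
    rowSums(cr >= 0) == m | rowSums(cr <= 0) == m
  }
  frac <- mean(inside_quad(ra) & inside_quad(rb))
  frac * prod(hi - lo)
}

# CCW rectangle from centre, direction angle (deg), length, width
make_rect <- function(center, angle_deg, len, wid) {
  th <- angle_deg * pi / 180
  d <- c(cos(th), sin(th)); p <- c(-d[2], d[1])
  q0 <- center - d * len / 2; q1 <- center + d * len / 2
  rbind(q0 - p * wid / 2, q1 - p * wid / 2, q1 + p * wid / 2, q0 + p * wid / 2)
}

# Brute-force re-statement of the greedy GROMOS rule on an RMSD matrix.
gromos_brute <- function(M, cutoff) {
  remaining <- seq_len(nrow(M))
  clusters <- list()
  while (length(remaining) > 0) {
    best <- NULL; best_n <- -1
    for (f in remaining) {
      nb <- remaining[M[f, remaining] <= cutoff]
      if (length(nb) > best_n) { best_n <- length(nb); best <- f }
    }
    members <- remaining[M[best, remaining] <= cutoff]
    clusters[[length(clusters) + 1]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  clusters
}

# Grid + refine search over rotations for the minimal RMSD superposition
# of two small centred point sets (oracle for kabsch_rmsd).
grid_min_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(sum((A %*% t(rotmat(ang)) - B)^2) / nrow(A))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); bv <- obj(best)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < bv) { bv <- v; best <- c(a1, a2, a3) }
  }
  o <- stats::optim(best, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 5000))
  o$value
}

# random rigid transform applied to an n x 3 coordinate matrix
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  cx <- cos(ang[1]); sx <- sin(ang[1]); cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
       matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
       matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  t_vec <- runif(3, -20, 20)
  sweep(xyz %*% t(R), 2, t_vec, "+")
}

# apply a rigid transform to every model of a structure
transform_structure <- function(s, seed) {
  s$xyz <- lapply(s$xyz, random_rigid, seed = seed)
  s
}

# quick accessor: CA coordinates of a structure model
ca_coords <- function(s, model = 1) {
  model_xyz(s, model)[s$atoms$name == "CA", , drop = FALSE]
}
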