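# Internal 3D vector / frame helpers shared by the geometry modules.
# All vectors are plain numeric length-3; coordinates in Angstrom,
# angles in degrees at the API surface, radians internally.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

clamp1 <- function(x) pmin(1, pmax(-1, x))

# angle at b between a-b and c-b, degrees
bond_angle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  deg(acos(clamp1(sum(u * v))))
}

# signed dihedral a-b-c-d, degrees, in (-180, 180]
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Rotation matrix: angle degrees about unit axis (Rodrigues)
rotation_about <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Minimal rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_about(p, 180))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

# NeRF atom placement: position D given A, B, C, bond |C-D|,
# angle B-C-D (deg) and dihedral A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle, dih) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  th <- rad(180 - angle)   # supplement: D extends away from B
  ph <- rad(dih)
  d_local <- bond * c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# distance between point p and the line through q with unit direction u
point_line_distance <- function(p, q, u) {
  w <- p - q
  vnorm(w - sum(w * u) * u)
}

# Minimum distance between two finite 3D segments p0-p1 and q0-q1.
# Standard clamped closest-approach computation; also returns the
# parameters (in [0,1]) of the closest points.
segment_segment_distance <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0; d2 <- q1 - q0; r <- p0 - q0
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a < 1e-14 && e < 1e-14) {
    return(list(dist = vnorm(r), s = 0, t = 0))
  }
  if (a < 1e-14) {
    s <- 0; t <- min(1, max(0, f / e))
  } else {
    c_ <- sum(d1 * r)
    if (e < 1e-14) {
      t <- 0; s <- min(1, max(0, -c_ / a))
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-12 * a * e) min(1, max(0, (b * f - c_ * e) / den)) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0; s <- min(1, max(0, -c_ / a))
      } else if (t > 1) {
        t <- 1; s <- min(1, max(0, (b - c_) / a))
      }
    }
  }
  cp <- p0 + s * d1; cq <- q0 + t * d2
  list(dist = vnorm(cp - cq), s = s, t = t)
}

# Sutherland-Hodgman clip of convex polygon subj (n x 2, CCW) against
# convex polygon clip (m x 2, CCW). Returns k x 2 matrix (possibly 0 rows).
convex_clip <- function(subj, clip) {
  out <- subj
  m <- nrow(clip)
  for (i in seq_len(m)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[(i %% m) + 1, ]
    edge <- b - a
    inside <- function(p) (edge[1] * (p[2] - a[2]) - edge[2] * (p[1] - a[1])) >= -1e-9
    nv <- nrow(out)
    res <- matrix(numeric(0), 0, 2)
    for (j in seq_len(nv)) {
      p <- out[j, ]; q <- out[(j %% nv) + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) res <- rbind(res, p)
      if (xor(pin, qin)) {
        # intersection of pq with the clip edge line
        den <- edge[1] * (q[2] - p[2]) - edge[2] * (q[1] - p[1])
        if (abs(den) > 1e-14) {
          t <- (edge[1] * (a[2] - p[2]) - edge[2] * (a[1] - p[1])) / den
          res <- rbind(res, p + t * (q - p))
        }
      }
    }
    out <- res
  }
  out
}

polygon_area <- function(v) {
  if (is.null(v) || nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(v) {
  if (is.null(v) || nrow(v) < 3) return(0)
  d <- v - v[c(2:nrow(v), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# Remove near-duplicate consecutive vertices (clipping artefacts)
polygon_dedup <- function(v, tol = 1e-7) {
  if (is.null(v) || nrow(v) < 2) return(v)
  keep <- rep(TRUE, nrow(v))
  for (i in seq_len(nrow(v))) {
    j <- if (i == 1) nrow(v) else i - 1
    if (i != j && sqrt(sum((v[i, ] - v[j, ])^2)) < tol) keep[i] <- FALSE
  }
  v[keep, , drop = FALSE]
}
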