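# ---------------------------------------------------------------------------
# Helix axis fitting and the six pairwise descriptors of a helix pair:
#   d     interplanar distance = distance between the infinite axis lines
#   r     minimum distance between the finite axis segments (r >= d)
#   theta signed torsion angle between the axes about their common
#         perpendicular, degrees in (-180, 180]
#   phi   unsigned planar angle between axis directions, degrees in [0, 90]
#   S, P  area and perimeter of the intersection polygon of the two
#         projected helix strips (finite rectangles of width 2*radius)
# ---------------------------------------------------------------------------

#' Fit a helix axis from ordered C-alpha coordinates
#'
#' Local helical centers are computed as centroids of four consecutive
#' C-alpha positions (a sliding window); the axis is the least-squares
#' (principal-component) line through those centers, oriented from the
#' N- to the C-terminus.
#'
#' @param ca numeric matrix (>= 5 rows) of ordered C-alpha coordinates
#' @return list with `axis_point` (centroid on the axis), `axis_dir`
#'   (unit vector, N->C), `axis_len` (span of center projections, Angstrom),
#'   `local_radius` (mean C-alpha distance to the axis), and the segment
#'   endpoints `end_start`/`end_stop`
#' @export
fit_axis <- function(ca) {
  ca <- as.matrix(ca)
  if (nrow(ca) < 5) stop("insufficient data: need at least 5 C-alpha points")
  n <- nrow(ca)
  centers <- t(vapply(seq_len(n - 3), function(i) colMeans(ca[i:(i + 3), , drop = FALSE]),
                      numeric(3)))
  c0 <- colMeans(centers)
  sv <- svd(sweep(centers, 2, c0))
  dir <- sv$v[, 1]
  if (sum(dir * (centers[nrow(centers), ] - centers[1, ])) < 0) dir <- -dir
  proj <- as.numeric(sweep(centers, 2, c0) %*% dir)
  radial <- sweep(ca, 2, c0)
  radial <- radial - (radial %*% dir) %*% t(dir)
  local_radius <- mean(sqrt(rowSums(radial^2)))
  if (local_radius < 1e-8) stop("degenerate fit: C-alpha points are collinear")
  list(axis_point = c0,
       axis_dir = as.numeric(dir),
       axis_len = max(proj) - min(proj),
       local_radius = local_radius,
       end_start = c0 + min(proj) * dir,
       end_stop = c0 + max(proj) * dir)
}

#' Construct a helix segment from a structure
#'
#' @param s a `ptm_structure`
#' @param chain chain identifier
#' @param start,end 0-based half-open residue-index range within the chain
#' @param model model number
#' @param radius projection cylinder radius in Angstrom (side-chain
#'   envelope; distinct from the fitted `local_radius`)
#' @return a `helix_segment` object
#' @export
helix_segment <- function(s, chain, start, end, model = 1, radius = 5.0) {
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (start < 0 || end > nrow(rt) || end - start < 5) {
    stop("invalid residue range for helix segment (need >= 5 residues)")
  }
  rows <- rt[(start + 1):end, , drop = FALSE]
  xyz <- model_xyz(s, model)
  ca_rows <- integer(0)
  for (k in seq_len(nrow(rows))) {
    idx <- seq.int(rows$first[k], rows$last[k])
    cai <- idx[s$atoms$name[idx] == "CA"]
    if (length(cai) != 1) stop("residue without a unique CA atom in helix range")
    ca_rows <- c(ca_rows, cai)
  }
  ca <- xyz[ca_rows, , drop = FALSE]
  ax <- fit_axis(ca)
  structure(c(list(chain = chain, start = start, end = end,
                   resno_start = rows$resno[1],
                   resno_end = rows$resno[nrow(rows)],
                   radius = radius, ca = ca), ax),
            class = "helix_segment")
}

#' Build a helix segment directly from C-alpha coordinates
#' @param ca matrix of ordered C-alpha coordinates (>= 5)
#' @param radius projection cylinder radius, Angstrom
#' @return a `helix_segment`
#' @export
helix_segment_from_ca <- function(ca, radius = 5.0) {
  ax <- fit_axis(ca)
  structure(c(list(chain = NA_character_, start = NA_integer_, end = NA_integer_,
                   resno_start = NA_integer_, resno_end = NA_integer_,
                   radius = radius, ca = as.matrix(ca)), ax),
            class = "helix_segment")
}

#' @export
print.helix_segment <- function(x, ...) {
  cat(sprintf("<helix_segment %s %s-%s: len %.1f A, radius %.1f A>\n",
              x$chain, x$resno_start, x$resno_end, x$axis_len, x$radius))
  invisible(x)
}

.PARALLEL_PHI_DEG <- 1  # below this planar angle the pair is treated as parallel

#' Pairwise descriptors of two helix segments
#'
#' Computes the interplanar distance `d` (between infinite axis lines),
#' the minimum distance `r` between the finite axis segments, the signed
#' torsion angle `theta` about the common perpendicular (right-handed,
#' looking along the perpendicular from helix `a` to helix `b`), the
#' unsigned planar angle `phi`, and the area/perimeter of the strip
#' projection polygon. `d == r` exactly when the mutual closest-approach
#' points are interior to both segments (the axes "intersect" in
#' projection); `d < r` otherwise.
#'
#' @param a,b `helix_segment` objects
#' @return object of class `helix_pair_descriptors`: list with d, r,
#'   theta, phi, S, P (Angstrom / degrees / Angstrom^2) and the polygon
#'   vertices
#' @export
pair_descriptors <- function(a, b) {
  stopifnot(inherits(a, "helix_segment"), inherits(b, "helix_segment"))
  if (a$axis_len <= 0 || b$axis_len <= 0) stop("degenerate zero-length axis")
  u1 <- a$axis_dir; u2 <- b$axis_dir
  p1 <- a$axis_point; p2 <- b$axis_point
  cr <- cross3(u1, u2)
  s <- vnorm(cr)
  phi <- deg(acos(clamp1(abs(sum(u1 * u2)))))
  seg <- segment_segment_distance(a$end_start, a$end_stop, b$end_start, b$end_stop)
  r <- seg$dist
  if (phi < .PARALLEL_PHI_DEG) {
    d <- point_line_distance(p2, p1, u1)
    theta <- 0
  } else {
    nhat <- cr / s
    d <- abs(sum((p2 - p1) * nhat))
    sgn <- sum((p2 - p1) * nhat)
    n_ab <- if (abs(sgn) > 1e-9) nhat * sign(sgn) else nhat
    theta <- deg(atan2(sum(cr * n_ab), sum(u1 * u2)))
  }
  if (d > r) d <- min(d, r)  # guard against numerical noise; d <= r by definition
  pol <- strip_projection_polygon(a, b)
  structure(list(d = d, r = r, theta = theta, phi = phi,
                 S = pol$S, P = pol$P, polygon = pol$polygon,
                 interior_crossing = seg$s > 1e-9 && seg$s < 1 - 1e-9 &&
                                     seg$t > 1e-9 && seg$t < 1 - 1e-9),
            class = "helix_pair_descriptors")
}

#' @export
print.helix_pair_descriptors <- function(x, ...) {
  cat(sprintf("d = %.2f A, r = %.2f A, theta = %.1f deg, phi = %.1f deg, S = %.1f A^2, P = %.1f A\n",
              x$d, x$r, x$theta, x$phi, x$S, x$P))
  invisible(x)
}

#' Intersection polygon of the projected helix strips
#'
#' Both helices are projected along their common perpendicular onto the
#' plane spanned by the two axis directions. Each helix projects to a
#' finite rectangle (length = fitted axis length, width = 2 * radius)
#' centred on its projected axis; the convex intersection polygon of the
#' two rectangles is obtained by successive half-plane clipping. For
#' near-parallel axes the projection is taken along the common normal of
#' the pair.
#'
#' @param a,b `helix_segment` objects
#' @return list with `S` (area, Angstrom^2), `P` (perimeter, Angstrom)
#'   and `polygon` (k x 2 matrix of vertices in the projection plane)
#' @export
strip_projection_polygon <- function(a, b) {
  if (a$radius <= 0 || b$radius <= 0) stop("zero projection radius")
  u1 <- a$axis_dir; u2 <- b$axis_dir
  cr <- cross3(u1, u2)
  phi <- deg(acos(clamp1(abs(sum(u1 * u2)))))
  if (phi >= .PARALLEL_PHI_DEG) {
    w <- cr / vnorm(cr)
  } else {
    off <- b$axis_point - a$axis_point
    off_perp <- off - sum(off * u1) * u1
    if (vnorm(off_perp) < 1e-9) {
      # coincident axis lines: any perpendicular works
      off_perp <- if (abs(u1[1]) < 0.9) cross3(u1, c(1, 0, 0)) else cross3(u1, c(0, 1, 0))
    }
    w <- unitv(off_perp)
  }
  e1 <- u1
  e2 <- cross3(w, e1)
  proj2 <- function(p) c(sum(p * e1), sum(p * e2))
  rect_of <- function(seg) {
    q0 <- proj2(seg$end_start); q1 <- proj2(seg$end_stop)
    dir2 <- q1 - q0
    L <- vnorm(dir2)
    if (L < 1e-9) stop("segment projects to a point")
    dir2 <- dir2 / L
    perp2 <- c(-dir2[2], dir2[1])
    rbind(q0 - seg$radius * perp2, q1 - seg$radius * perp2,
          q1 + seg$radius * perp2, q0 + seg$radius * perp2)
  }
  ensure_ccw <- function(v) {
    x <- v[, 1]; y <- v[, 2]
    a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    if (a2 < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
  }
  ra <- ensure_ccw(rect_of(a))
  rb <- ensure_ccw(rect_of(b))
  poly <- polygon_dedup(convex_clip(ra, rb))
  S <- polygon_area(poly)
  if (S < 1e-9) {
    return(list(S = 0, P = 0, polygon = matrix(numeric(0), 0, 2)))
  }
  list(S = S, P = polygon_perimeter(poly), polygon = poly)
}

#' Write a descriptor table as CSV
#'
#' @param rows data.frame of descriptor rows (see [enumerate_blocks()])
#' @param path output CSV path
#' @export
write_descriptor_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
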