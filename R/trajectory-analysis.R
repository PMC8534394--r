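# ---------------------------------------------------------------------------
# Multi-model (pseudo-trajectory) analysis: Kabsch superposition RMSD,
# per-frame descriptor series, GROMOS conformational clustering and
# stability summaries.
# ---------------------------------------------------------------------------

#' Optimal-superposition RMSD (Kabsch)
#'
#' Removes the centroids, finds the optimal proper rotation by SVD
#' (reflections corrected) and returns the root-mean-square deviation of
#' the superposed coordinate sets.
#'
#' @param frame_a,frame_b n x 3 coordinate matrices (same atom order)
#' @return RMSD in Angstrom
#' @export
kabsch_rmsd <- function(frame_a, frame_b) {
  A <- as.matrix(frame_a); B <- as.matrix(frame_b)
  if (!all(dim(A) == dim(B))) stop("mismatched selections")
  if (nrow(A) < 3) stop("need at least 3 atoms")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  sv <- svd(t(A) %*% B)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- A %*% t(R) - B
  sqrt(sum(diff^2) / nrow(A))
}

# atom-row selection for trajectory operations
.traj_selection <- function(s, selection = c("CA", "backbone", "all")) {
  selection <- match.arg(selection)
  switch(selection,
         CA = which(s$atoms$name == "CA"),
         backbone = which(s$atoms$name %in% c("N", "CA", "C")),
         all = which(s$atoms$element != "H"))
}

#' Pairwise RMSD matrix over trajectory frames
#' @param s multi-model `ptm_structure`
#' @param selection atom selection: `"CA"` (default), `"backbone"`, `"all"`
#' @return symmetric matrix of superposition RMSDs, Angstrom
#' @export
rmsd_matrix <- function(s, selection = "CA") {
  sel <- .traj_selection(s, selection)
  nf <- n_models(s)
  M <- matrix(0, nf, nf)
  coords <- lapply(seq_len(nf), function(m) model_xyz(s, m)[sel, , drop = FALSE])
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      M[i, j] <- M[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]])
    }
  }
  M
}

#' Per-frame helix-pair descriptor series
#'
#' Re-fits both helix axes and recomputes all six descriptors in every
#' model of a multi-model structure. Frame 1 is stored as the `initial`
#' (pre-experiment) reference.
#'
#' @param s multi-model `ptm_structure`
#' @param chain chain identifier
#' @param range_a,range_b 0-based half-open residue-index ranges
#'   (`c(start, end)`) of the two helices
#' @param radius projection cylinder radius, Angstrom
#' @return object of class `descriptor_series`: data.frame with columns
#'   frame, d, r, theta, phi, S, P; attribute `initial` holds frame 1
#' @export
descriptor_series <- function(s, chain, range_a, range_b, radius = 5.0) {
  nf <- n_models(s)
  rows <- vector("list", nf)
  for (m in seq_len(nf)) {
    a <- helix_segment(s, chain, range_a[1], range_a[2], model = m, radius = radius)
    b <- helix_segment(s, chain, range_b[1], range_b[2], model = m, radius = radius)
    ds <- pair_descriptors(a, b)
    rows[[m]] <- data.frame(frame = m, d = ds$d, r = ds$r, theta = ds$theta,
                            phi = ds$phi, S = ds$S, P = ds$P)
  }
  out <- do.call(rbind, rows)
  attr(out, "initial") <- out[1, c("d", "r", "theta", "phi", "S", "P")]
  class(out) <- c("descriptor_series", "data.frame")
  out
}

#' GROMOS conformational clustering
#'
#' Greedy RMSD-neighbour clustering: the frame with the most neighbours
#' within `cutoff` (self included) becomes a cluster centre; it is
#' removed with its neighbours and the procedure repeats on the
#' remaining frames. Ties are broken by the lowest frame index. Cluster
#' sizes are non-increasing by construction.
#'
#' @param s multi-model `ptm_structure` (or a precomputed RMSD matrix
#'   passed as `rmsd`)
#' @param cutoff RMSD cutoff, Angstrom
#' @param selection atom selection for the RMSD (default `"CA"`)
#' @param rmsd optional precomputed pairwise RMSD matrix
#' @return object of class `gromos_clusters`: list with `cutoff`,
#'   `clusters` (list of frame-index vectors, largest first),
#'   `representative` (centre frame of each cluster)
#' @export
gromos_cluster <- function(s, cutoff, selection = "CA", rmsd = NULL) {
  M <- if (is.null(rmsd)) rmsd_matrix(s, selection) else rmsd
  nf <- nrow(M)
  remaining <- seq_len(nf)
  clusters <- list()
  reps <- integer(0)
  while (length(remaining) > 0) {
    sub <- M[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff)
    centre_pos <- which.max(counts)           # which.max takes the first max: lowest index
    centre <- remaining[centre_pos]
    members <- remaining[sub[centre_pos, ] <= cutoff]
    clusters[[length(clusters) + 1]] <- sort(members)
    reps <- c(reps, centre)
    remaining <- setdiff(remaining, members)
  }
  structure(list(cutoff = cutoff, clusters = clusters, representative = reps),
            class = "gromos_clusters")
}

#' @export
print.gromos_clusters <- function(x, ...) {
  cat(sprintf("<gromos_clusters: cutoff %.2f A, %d cluster(s), sizes %s>\n",
              x$cutoff, length(x$clusters),
              paste(vapply(x$clusters, length, integer(1)), collapse = "/")))
  invisible(x)
}

#' Largest cluster of a clustering result
#' @param cl a `gromos_clusters`
#' @return integer vector of frame indices
#' @export
largest_cluster <- function(cl) cl$clusters[[1]]

#' Stability summary of a descriptor series
#'
#' Per-descriptor mean, sample (n-1) standard deviation and maximum
#' absolute deviation from the initial (frame-1) value. Small standard
#' deviations and means close to the initial value indicate a stable
#' motif.
#'
#' @param series a `descriptor_series`
#' @return data.frame with columns descriptor, initial, mean, sd, max_dev
#' @export
stability_summary <- function(series) {
  if (nrow(series) < 2) stop("need at least 2 frames")
  ini <- attr(series, "initial")
  descs <- c("d", "r", "theta", "phi", "S", "P")
  do.call(rbind, lapply(descs, function(k) {
    v <- series[[k]]
    data.frame(descriptor = k, initial = as.numeric(ini[[k]]),
               mean = mean(v), sd = stats::sd(v),
               max_dev = max(abs(v - as.numeric(ini[[k]]))),
               stringsAsFactors = FALSE)
  }))
}

#' Paired native-vs-modified stability comparison
#'
#' Combines the initial ("stat") values with the summaries of a native
#' ("nmd") and a modified ("mod") series, one row per descriptor and
#' variant, mirroring the usual stability-triplet presentation.
#'
#' @param series_native,series_modified `descriptor_series` objects
#' @return tidy data.frame with columns descriptor, variant, mean, sd
#' @export
stability_comparison <- function(series_native, series_modified) {
  sn <- stability_summary(series_native)
  sm <- stability_summary(series_modified)
  rbind(
    data.frame(descriptor = sn$descriptor, variant = "stat",
               mean = sn$initial, sd = 0, stringsAsFactors = FALSE),
    data.frame(descriptor = sn$descriptor, variant = "nmd",
               mean = sn$mean, sd = sn$sd, stringsAsFactors = FALSE),
    data.frame(descriptor = sm$descriptor, variant = "mod",
               mean = sm$mean, sd = sm$sd, stringsAsFactors = FALSE)
  )
}

#' Write a descriptor series as tidy CSV
#' @param series a `descriptor_series`
#' @param path output path
#' @param variant label column value (e.g. `"nmd"` or `"mod"`)
#' @export
write_series_csv <- function(series, path, variant = "nmd") {
  long <- do.call(rbind, lapply(c("d", "r", "theta", "phi", "S", "P"), function(k) {
    data.frame(frame = series$frame, descriptor = k, value = series[[k]],
               variant = variant, stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
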