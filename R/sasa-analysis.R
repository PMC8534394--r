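# ---------------------------------------------------------------------------
# Shrake-Rupley solvent-accessible surface area with a deterministic
# Fibonacci sphere point set, active-environment detection, and the
# VN/VM/UN/UM survey aggregation over sets of structures.
# ---------------------------------------------------------------------------

#' Deterministic Fibonacci sphere point set
#' @param n number of points
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Heavy-atom SASA with fixed Bondi radii: for every atom, the fraction
#' of `n_points` Fibonacci-sphere points at radius (r_vdw + probe) not
#' inside any neighbour's expanded sphere, times the expanded-sphere
#' area. Hydrogens (rebuilt amide H included) are excluded from both
#' the area and the occlusion.
#'
#' @param s a `ptm_structure`
#' @param model model number
#' @param probe probe radius, Angstrom (default 1.4, water)
#' @param n_points sphere sample count (default 960; error < 1%)
#' @return object of class `sasa_report`: list with `per_atom`
#'   (Angstrom^2, NA for hydrogens), `per_residue` (data.frame), `total`,
#'   `probe`, `n_points`
#' @export
sasa <- function(s, model = 1, probe = 1.4, n_points = 960) {
  xyz <- model_xyz(s, model)
  heavy <- which(s$atoms$element != "H")
  hx <- xyz[heavy, , drop = FALSE]
  hr <- s$atoms$vdw[heavy] + probe
  n <- length(heavy)
  pts <- fibonacci_sphere(n_points)
  per_atom_h <- numeric(n)
  # neighbour candidates via squared-distance threshold
  d2 <- as.matrix(stats::dist(hx))^2
  if (any(d2[upper.tri(d2)] < 1e-12)) {
    stop("overlapping identical atom positions; SASA undefined")
  }
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (hr[i] + hr)^2 & seq_len(n) != i)
    sp <- pts * hr[i]
    sp <- sweep(sp, 2, hx[i, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      nbx <- hx[nb, , drop = FALSE]
      # squared distances sphere-points x neighbours
      cross <- sp %*% t(nbx)
      d2pn <- outer(rowSums(sp^2), rowSums(nbx^2), "+") - 2 * cross
      inside <- d2pn < matrix(hr[nb]^2, n_points, length(nb), byrow = TRUE)
      acc <- sum(rowSums(inside) == 0)
    }
    per_atom_h[i] <- acc / n_points * 4 * pi * hr[i]^2
  }
  per_atom <- rep(NA_real_, nrow(xyz))
  per_atom[heavy] <- per_atom_h
  rt <- residue_table(s)
  res_area <- vapply(seq_len(nrow(rt)), function(k) {
    idx <- seq.int(rt$first[k], rt$last[k])
    sum(per_atom[idx], na.rm = TRUE)
  }, numeric(1))
  per_residue <- data.frame(chain = rt$chain, resno = rt$resno, ins = rt$ins,
                            resname = rt$resname, area = res_area,
                            stringsAsFactors = FALSE)
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 total = sum(per_atom_h), probe = probe, n_points = n_points),
            class = "sasa_report")
}

#' @export
print.sasa_report <- function(x, ...) {
  cat(sprintf("<sasa_report: %d residues, total %.1f A^2 (probe %.1f A, %d points)>\n",
              nrow(x$per_residue), x$total, x$probe, x$n_points))
  invisible(x)
}

#' Solvent-accessible area of one residue
#'
#' @param s a `ptm_structure`
#' @param chain chain identifier
#' @param residue_index 0-based residue index within the chain
#' @param report optional precomputed [sasa()] report for `s`
#' @param ... passed to [sasa()] when `report` is NULL
#' @return area in Angstrom^2 (side chain + backbone, heavy atoms only;
#'   moiety atoms of a modified residue are counted with the residue)
#' @export
residue_sasa <- function(s, chain, residue_index, report = NULL, ...) {
  if (is.null(report)) report <- sasa(s, ...)
  pr <- report$per_residue
  sub <- pr[pr$chain == chain, , drop = FALSE]
  if (residue_index < 0 || residue_index >= nrow(sub)) {
    stop("residue index out of range for chain ", chain)
  }
  sub$area[residue_index + 1L]
}

#' Active environment of a modification
#'
#' Residues (excluding the modified one) whose per-residue SASA changes
#' by more than `epsilon` between the native and modified structures.
#'
#' @param native,modified `ptm_structure`s identical except for the
#'   modification moiety
#' @param chain chain of the modified residue
#' @param residue_index 0-based index of the modified residue
#' @param epsilon membership threshold, Angstrom^2 (default 0.1)
#' @param report_native,report_modified optional precomputed [sasa()]
#'   reports
#' @param ... passed to [sasa()]
#' @return object of class `active_environment`: data.frame of members
#'   (chain, resno, resname, area_native, area_modified, delta) with
#'   attributes `ptm_chain`, `ptm_index`, `epsilon`
#' @export
active_environment <- function(native, modified, chain, residue_index,
                               epsilon = 0.1, report_native = NULL,
                               report_modified = NULL, ...) {
  rtn <- residue_table(native)
  rtm <- residue_table(modified)
  if (nrow(rtn) != nrow(rtm) ||
      !identical(rtn[c("chain", "resno", "ins")], rtm[c("chain", "resno", "ins")])) {
    stop("structures differ beyond the modification moiety")
  }
  extra <- rtm$n_atoms - rtn$n_atoms
  rows_target <- which(rtm$chain == chain)[residue_index + 1L]
  if (any(extra[-rows_target] != 0)) {
    stop("structures differ beyond the modification moiety")
  }
  if (is.null(report_native)) report_native <- sasa(native, ...)
  if (is.null(report_modified)) report_modified <- sasa(modified, ...)
  an <- report_native$per_residue$area
  am <- report_modified$per_residue$area
  delta <- am - an
  member <- abs(delta) > epsilon
  member[rows_target] <- FALSE
  out <- data.frame(chain = rtn$chain[member], resno = rtn$resno[member],
                    ins = rtn$ins[member], resname = rtn$resname[member],
                    area_native = an[member], area_modified = am[member],
                    delta = delta[member], stringsAsFactors = FALSE)
  attr(out, "ptm_chain") <- chain
  attr(out, "ptm_index") <- residue_index
  attr(out, "epsilon") <- epsilon
  class(out) <- c("active_environment", "data.frame")
  out
}

#' Survey a set of structures for a PTM peptide
#'
#' For every occurrence of the peptide in every structure: locate the
#' target residue, attach the modification, compute the SASA of the
#' target residue before (VN) and after (VM) modification, determine the
#' active environment and compute the total SASA of target plus
#' environment before (UN) and after (UM). Occurrences within one
#' structure are averaged first, then across structures.
#'
#' @param structures list of `ptm_structure`s
#' @param annotated_peptide annotated peptide string (see
#'   [parse_ptm_peptide()])
#' @param gene optional row label
#' @param epsilon active-environment threshold, Angstrom^2
#' @param ... passed to [sasa()]
#' @return one-row data.frame with columns gene, n_prot, VN, VM, UN, UM,
#'   loc, ptm_seq; attribute `per_structure` holds the per-structure
#'   values
#' @export
survey <- function(structures, annotated_peptide, gene = NA_character_,
                   epsilon = 0.1, ...) {
  spec <- parse_ptm_peptide(annotated_peptide)
  per_struct <- list()
  for (s in structures) {
    hits <- find_peptide(s, spec$peptide)
    if (nrow(hits) == 0) next
    vals <- matrix(NA_real_, nrow(hits), 4,
                   dimnames = list(NULL, c("VN", "VM", "UN", "UM")))
    for (h in seq_len(nrow(hits))) {
      ch <- hits$chain[h]
      idx <- hits$start[h] + spec$position - 1L
      mod <- apply_ptm(s, ch, idx, spec$ptm_type)
      rep_n <- sasa(s, ...)
      rep_m <- sasa(mod, ...)
      vn <- residue_sasa(s, ch, idx, report = rep_n)
      vm <- residue_sasa(mod, ch, idx, report = rep_m)
      ae <- active_environment(s, mod, ch, idx, epsilon = epsilon,
                               report_native = rep_n, report_modified = rep_m)
      vals[h, ] <- c(vn, vm, vn + sum(ae$area_native), vm + sum(ae$area_modified))
    }
    per_struct[[length(per_struct) + 1]] <- c(id = s$id, colMeans(vals))
  }
  if (length(per_struct) == 0) {
    stop("peptide not found in any structure: ", spec$peptide)
  }
  ps <- do.call(rbind, lapply(per_struct, function(x) {
    data.frame(id = x[["id"]], VN = as.numeric(x[["VN"]]), VM = as.numeric(x[["VM"]]),
               UN = as.numeric(x[["UN"]]), UM = as.numeric(x[["UM"]]),
               stringsAsFactors = FALSE)
  }))
  out <- data.frame(gene = gene, n_prot = nrow(ps),
                    VN = mean(ps$VN), VM = mean(ps$VM),
                    UN = mean(ps$UN), UM = mean(ps$UM),
                    loc = spec$loc, ptm_seq = spec$peptide,
                    stringsAsFactors = FALSE)
  attr(out, "per_structure") <- ps
  out
}

#' Write a survey table as CSV
#' @param rows data.frame of [survey()] rows (rbind-ed)
#' @param path output path
#' @export
write_survey_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
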