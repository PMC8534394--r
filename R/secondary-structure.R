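# ---------------------------------------------------------------------------
# Kabsch-Sander secondary-structure assignment.
#
# Backbone amide hydrogens are rebuilt geometrically, hydrogen bonds are
# scored with the Kabsch-Sander electrostatic model
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)   [kcal/mol]
# and a bond is accepted iff E < -0.5 kcal/mol (strict).  n-turns from
# i -> i+4 bonds give H, i -> i+3 give G, inter-strand bridges give E;
# priority H > E > G on conflict.  States assigned: H, G, E, C.
# ---------------------------------------------------------------------------

.HB_CUTOFF <- -0.5       # kcal/mol, strict <
.KS_CONST <- 0.084 * 332 # = 27.888 kcal*Angstrom/mol
.CHAIN_BREAK <- 2.5      # Angstrom, C(i-1)-N(i) beyond this splits the chain

#' Rebuild backbone amide hydrogens
#'
#' Adds one H atom on the backbone nitrogen of every residue that has a
#' bonded predecessor (C(i-1)-N(i) distance <= 2.5 Angstrom), placed at
#' N + 1.0 Angstrom along the reversed carbonyl direction of the
#' preceding residue (the standard DSSP construction). Prolines and
#' chain-initial residues get no H; skipped placements at chain breaks
#' are reported via `message()`.
#'
#' @param s a `ptm_structure` (hydrogens from the input were discarded
#'   at parse time)
#' @return a new `ptm_structure` with `H` atoms inserted (all models)
#' @export
place_amide_hydrogens <- function(s) {
  rt <- residue_table(s)
  nres <- nrow(rt)
  at <- s$atoms
  find_atom <- function(i, nm) {
    idx <- seq.int(rt$first[i], rt$last[i])
    idx[at$name[idx] == nm][1]
  }
  h_for <- rep(NA_integer_, nres)  # residue gets H after this atom row
  h_coords <- vector("list", n_models(s))
  for (m in seq_len(n_models(s))) h_coords[[m]] <- list()
  n_skipped <- 0
  for (i in 2:nres) {
    if (rt$chain[i] != rt$chain[i - 1]) next
    if (rt$resname[i] == "PRO") next
    ni <- find_atom(i, "N"); ci <- find_atom(i - 1, "C"); oi <- find_atom(i - 1, "O")
    if (is.na(ni) || is.na(ci) || is.na(oi)) next
    x1 <- model_xyz(s, 1)
    if (vnorm(x1[ni, ] - x1[ci, ]) > .CHAIN_BREAK) {
      n_skipped <- n_skipped + 1
      next
    }
    if (any(at$name[seq.int(rt$first[i], rt$last[i])] == "H")) next
    h_for[i] <- ni
    for (m in seq_len(n_models(s))) {
      xm <- model_xyz(s, m)
      h <- xm[ni, ] + unitv(xm[ci, ] - xm[oi, ]) * 1.0
      h_coords[[m]][[length(h_coords[[m]]) + 1]] <- h
    }
  }
  if (n_skipped > 0) {
    message(sprintf("amide H omitted at %d chain break(s)", n_skipped))
  }
  ins_after <- h_for[!is.na(h_for)]
  if (length(ins_after) == 0) return(s)
  ord <- order(c(seq_len(nrow(at)), ins_after + 0.5))
  newrow <- data.frame(name = "H", resname = at$resname[ins_after],
                       chain = at$chain[ins_after], resno = at$resno[ins_after],
                       ins = at$ins[ins_after], occ = 1, bfactor = 0,
                       element = "H", vdw = vdw_radius_of("H"),
                       stringsAsFactors = FALSE)
  atoms2 <- rbind(at, newrow)[ord, , drop = FALSE]
  rownames(atoms2) <- NULL
  xyz2 <- lapply(seq_len(n_models(s)), function(m) {
    hm <- do.call(rbind, h_coords[[m]])
    unname(rbind(model_xyz(s, m), hm)[ord, , drop = FALSE])
  })
  new_structure(s$id, atoms2, xyz2, s$title)
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' @param donor named list/matrix with coordinates `N` and `H`
#' @param acceptor named list with coordinates `C` and `O`
#' @return energy in kcal/mol, or `NA` when an atom is missing or any
#'   of the four distances is below 0.5 Angstrom (clash; treated as no
#'   bond). A bond is accepted iff the energy is strictly below -0.5.
#' @export
hbond_energy <- function(donor, acceptor) {
  if (is.null(donor$N) || is.null(donor$H) ||
      is.null(acceptor$C) || is.null(acceptor$O)) return(NA_real_)
  r_on <- vnorm(acceptor$O - donor$N)
  r_ch <- vnorm(acceptor$C - donor$H)
  r_oh <- vnorm(acceptor$O - donor$H)
  r_cn <- vnorm(acceptor$C - donor$N)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(NA_real_)
  .KS_CONST * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# internal: per-chain-fragment hydrogen-bond matrix and assignment
.assign_chain <- function(N, H, C, O, resno) {
  n <- nrow(N)
  ss <- rep("C", n)
  if (n < 5) return(ss)
  # bond[i, j]: CO of residue i accepts H-N of residue j  (DSSP Hbond(i, j))
  bond <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    if (any(is.na(H[j, ]))) next
    for (i in seq_len(n)) {
      if (abs(i - j) < 2) next
      if (any(is.na(O[i, ]))) next
      e <- hbond_energy(list(N = N[j, ], H = H[j, ]),
                        list(C = C[i, ], O = O[i, ]))
      if (!is.na(e) && e < .HB_CUTOFF) bond[i, j] <- TRUE
    }
  }
  turn <- function(k) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - k)) t[i] <- bond[i, i + k]
    t
  }
  t3 <- turn(3); t4 <- turn(4)
  # 3_10 helix first (lowest priority)
  for (i in 2:max(2, n - 3)) {
    if (t3[i - 1] && t3[i]) ss[i:(i + 2)] <- "G"
  }
  # strand bridges override G
  for (i in 2:(n - 1)) {
    for (j in seq_len(n - 1)) {
      if (j < i + 3) next
      if (j >= n) next
      para <- (i >= 2 && bond[i - 1, j] && bond[j, i + 1]) ||
              (bond[j - 1, i] && bond[i, j + 1])
      anti <- (bond[i, j] && bond[j, i]) ||
              (i >= 2 && bond[i - 1, j + 1] && bond[j - 1, i + 1])
      if (para || anti) ss[c(i, j)] <- "E"
    }
  }
  # alpha helix wins
  for (i in 2:max(2, n - 4)) {
    if (t4[i - 1] && t4[i]) ss[i:(i + 3)] <- "H"
  }
  ss
}

#' Assign secondary structure (Kabsch-Sander)
#'
#' @param s a `ptm_structure`; amide hydrogens are placed automatically
#'   if absent
#' @param model model number to analyse
#' @return object of class `ss_assignment`: data.frame with columns
#'   chain, resno, ins, resname, ss (one of H, G, E, C)
#' @export
assign_ss <- function(s, model = 1) {
  if (!any(s$atoms$name == "H")) s <- suppressMessages(place_amide_hydrogens(s))
  rt <- residue_table(s)
  xyz <- model_xyz(s, model)
  at <- s$atoms
  coord_of <- function(i, nm) {
    idx <- seq.int(rt$first[i], rt$last[i])
    hit <- idx[at$name[idx] == nm]
    if (length(hit) == 0) return(c(NA_real_, NA_real_, NA_real_))
    xyz[hit[1], ]
  }
  nres <- nrow(rt)
  ss <- rep("C", nres)
  for (ch in unique(rt$chain)) {
    rows <- which(rt$chain == ch)
    # split at chain breaks (C-N distance) into fragments
    frag_id <- integer(length(rows)); fid <- 1L; frag_id[1] <- 1L
    if (length(rows) > 1) {
      for (k in 2:length(rows)) {
        ci <- coord_of(rows[k - 1], "C"); ni <- coord_of(rows[k], "N")
        if (any(is.na(ci)) || any(is.na(ni)) || vnorm(ni - ci) > .CHAIN_BREAK) {
          fid <- fid + 1L
        }
        frag_id[k] <- fid
      }
    }
    for (f in unique(frag_id)) {
      sel <- rows[frag_id == f]
      if (length(sel) < 5) next
      getm <- function(nm) t(vapply(sel, coord_of, numeric(3), nm = nm))
      ss[sel] <- .assign_chain(getm("N"), getm("H"), getm("C"), getm("O"),
                               rt$resno[sel])
    }
  }
  out <- data.frame(chain = rt$chain, resno = rt$resno, ins = rt$ins,
                    resname = rt$resname, ss = ss, stringsAsFactors = FALSE)
  class(out) <- c("ss_assignment", "data.frame")
  out
}

#' Secondary-structure string of one chain
#' @param assignment an `ss_assignment`
#' @param chain chain identifier
#' @return single string of per-residue states
#' @export
ss_string <- function(assignment, chain) {
  paste(assignment$ss[assignment$chain == chain], collapse = "")
}

#' Extract helix segments from an assignment
#'
#' Maximal runs of H (optionally H or G) of at least `min_len` residues,
#' reported as 0-based half-open index ranges into each chain's residue
#' list together with the author residue numbers.
#'
#' @param assignment an `ss_assignment`
#' @param min_len minimum run length (default 5)
#' @param include_310 merge 3_10 (G) states into helix runs
#' @return data.frame with columns chain, start, end (0-based half-open),
#'   resno_start, resno_end, length
#' @export
helix_segments <- function(assignment, min_len = 5, include_310 = FALSE) {
  out <- list()
  for (ch in unique(assignment$chain)) {
    sub <- assignment[assignment$chain == ch, , drop = FALSE]
    is_h <- sub$ss == "H" | (include_310 & sub$ss == "G")
    r <- rle(is_h)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < min_len) next
      out[[length(out) + 1]] <- data.frame(
        chain = ch, start = starts[k] - 1L, end = stops[k],
        resno_start = sub$resno[starts[k]], resno_end = sub$resno[stops[k]],
        length = r$lengths[k], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chain = character(0), start = integer(0), end = integer(0),
                      resno_start = integer(0), resno_end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write a per-residue secondary-structure TSV
#' @param assignment an `ss_assignment`
#' @param path output path
#' @export
write_ss_tsv <- function(assignment, path) {
  utils::write.table(assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
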