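# ---------------------------------------------------------------------------
# Synthetic structure generators: every fixture used by the tests and the
# validation suite is built here in code (no downloads, no binary data).
# Backbone geometry uses canonical bond lengths/angles and NeRF placement;
# ideal helices use the alpha-helical dihedrals phi = -57, psi = -47.
# ---------------------------------------------------------------------------

.BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5
)

.ONE2THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# side-chain atoms beyond CB, placed by NeRF from (a, b, c) references.
# Each row: atom name, refs (names of previously placed atoms), bond,
# angle, dihedral ("chi1" resolved at build time).
.SIDECHAIN <- list(
  SER = list(list("OG",  c("N", "CA", "CB"), 1.417, 110.8, "chi1")),
  THR = list(list("OG1", c("N", "CA", "CB"), 1.433, 109.6, "chi1"),
             list("CG2", c("N", "CA", "CB"), 1.521, 110.5, "chi1+120")),
  LYS = list(list("CG", c("N", "CA", "CB"), 1.520, 114.0, "chi1"),
             list("CD", c("CA", "CB", "CG"), 1.520, 111.0, "180"),
             list("CE", c("CB", "CG", "CD"), 1.520, 111.0, "180"),
             list("NZ", c("CG", "CD", "CE"), 1.489, 112.0, "180")),
  TYR = list(list("CG",  c("N", "CA", "CB"), 1.512, 113.9, "chi1"),
             list("CD1", c("CA", "CB", "CG"), 1.389, 120.8, "90"),
             list("CD2", c("CA", "CB", "CG"), 1.389, 120.8, "-90"),
             list("CE1", c("CB", "CG", "CD1"), 1.382, 121.2, "180"),
             list("CE2", c("CB", "CG", "CD2"), 1.382, 121.2, "180"),
             list("CZ",  c("CG", "CD1", "CE1"), 1.378, 119.6, "0"),
             list("OH",  c("CD1", "CE1", "CZ"), 1.376, 119.9, "180"))
)

.sidechain_dihedral <- function(spec, chi1) {
  switch(spec,
         "chi1" = chi1,
         "chi1+120" = chi1 + 120,
         as.numeric(spec))
}

#' Build a peptide chain from backbone dihedrals
#'
#' Constructs an all-heavy-atom peptide (N, CA, C, O, CB and full side
#' chains for S, T, Y, K) with canonical bond lengths and angles by
#' sequential NeRF placement. Other residue types are built to CB
#' (glycine to CA).
#'
#' @param sequence one-letter sequence
#' @param phi,psi backbone dihedrals in degrees (scalar or per-residue)
#' @param omega peptide-bond dihedral (default 180, trans)
#' @param chi1 side-chain chi1 dihedral (default -60)
#' @param chain chain identifier
#' @param resno_start first author residue number
#' @param id structure identifier
#' @return a `ptm_structure` with one model
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, omega = 180,
                          chi1 = -60, chain = "A", resno_start = 1L,
                          id = "synthetic-peptide") {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 1) stop("empty sequence")
  if (!all(aa %in% names(.ONE2THREE))) stop("unknown residue in sequence")
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)

  res_atoms <- vector("list", n)
  # seed residue backbone
  Ncur <- c(0, 0, 0)
  CAcur <- c(.BB$n_ca, 0, 0)
  th <- rad(180 - .BB$ang_n_ca_c)
  Ccur <- CAcur + .BB$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Nn <- place_atom(Nprev, CAprev, Cprev, .BB$c_n, .BB$ang_ca_c_n, psi[i - 1])
      CAn <- place_atom(CAprev, Cprev, Nn, .BB$n_ca, .BB$ang_c_n_ca, omega[i - 1])
      Cn <- place_atom(Cprev, Nn, CAn, .BB$ca_c, .BB$ang_n_ca_c, phi[i])
      Ncur <- Nn; CAcur <- CAn; Ccur <- Cn
    }
    O <- place_atom(Ncur, CAcur, Ccur, .BB$c_o, .BB$ang_ca_c_o, psi[i] + 180)
    atoms <- list(N = Ncur, CA = CAcur, C = Ccur, O = O)
    if (aa[i] != "G") {
      atoms$CB <- place_atom(Ncur, Ccur, CAcur, .BB$ca_cb, .BB$ang_n_ca_cb, 122.6)
    }
    sc <- .SIDECHAIN[[.ONE2THREE[aa[i]]]]
    if (!is.null(sc)) {
      for (at in sc) {
        refs <- lapply(at[[2]], function(nm) atoms[[nm]])
        atoms[[at[[1]]]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                       at[[3]], at[[4]],
                                       .sidechain_dihedral(at[[5]], chi1))
      }
    }
    res_atoms[[i]] <- atoms
    Nprev <- Ncur; CAprev <- CAcur; Cprev <- Ccur
  }
  .assemble_structure(res_atoms, aa, chain, resno_start, id)
}

.assemble_structure <- function(res_atoms, aa, chain, resno_start, id) {
  n <- length(res_atoms)
  rows <- list(); xyz <- list()
  for (i in seq_len(n)) {
    atoms <- res_atoms[[i]]
    for (nm in names(atoms)) {
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, resname = .ONE2THREE[aa[i]], chain = chain,
        resno = resno_start + i - 1L, ins = " ", occ = 1, bfactor = 0,
        element = substr(nm, 1, 1), stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1]] <- atoms[[nm]]
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$vdw <- vdw_radius_of(atoms$element)
  rownames(atoms) <- NULL
  new_structure(id = id, atoms = atoms,
                xyz = list(do.call(rbind, xyz)))
}

# Cylindrical per-atom template of the canonical alpha-helix, memoised.
# For each backbone atom type: radius, phase offset and rise offset
# relative to the CA of the same residue, measured on a NeRF-built
# poly-alanine helix.
.helix_template_env <- new.env(parent = emptyenv())

.helix_template <- function() {
  if (!is.null(.helix_template_env$tmpl)) return(.helix_template_env$tmpl)
  ref <- build_peptide(strrep("A", 30), phi = -57, psi = -47)
  xyz <- model_xyz(ref)
  at <- ref$atoms
  ca_idx <- which(at$name == "CA")
  ax <- fit_axis(xyz[ca_idx, ])
  u <- ax$axis_dir
  e1 <- unitv(if (abs(u[1]) < 0.9) cross3(u, c(1, 0, 0)) else cross3(u, c(0, 1, 0)))
  e2 <- cross3(u, e1)
  cyl <- function(p) {
    w <- p - ax$axis_point
    z <- sum(w * u)
    x <- sum(w * e1); y <- sum(w * e2)
    c(rho = sqrt(x^2 + y^2), phi = atan2(y, x), z = z)
  }
  interior <- 4:27
  ca_cyl <- t(vapply(interior, function(i) cyl(xyz[ca_idx[i], ]), numeric(3)))
  dphi <- diff(ca_cyl[, "phi"])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  handed <- sign(mean(dphi))
  tmpl <- list(
    twist = deg(abs(mean(dphi))),
    rise = mean(diff(ca_cyl[, "z"])),
    ca_radius = mean(ca_cyl[, "rho"]),
    handed = handed,
    atoms = list()
  )
  for (nm in c("N", "CA", "C", "O", "CB")) {
    offs <- t(vapply(interior, function(i) {
      rowset <- which(at$name == nm & at$resno == i)
      stopifnot(length(rowset) == 1)
      a <- cyl(xyz[rowset, ])
      caa <- cyl(xyz[ca_idx[i], ])
      dph <- (a["phi"] - caa["phi"] + pi) %% (2 * pi) - pi
      c(a["rho"], dph, a["z"] - caa["z"])
    }, numeric(3)))
    tmpl$atoms[[nm]] <- c(rho = mean(offs[, 1]),
                          dphi = deg(mean(offs[, 2])) * handed,
                          dz = mean(offs[, 3]))
  }
  .helix_template_env$tmpl <- tmpl
  tmpl
}

#' Build an ideal alpha-helix at prescribed axis geometry
#'
#' Places backbone atoms on coaxial helical tracks derived from the
#' canonical alpha-helix (phi/psi = -57/-47), with the C-alpha track at
#' exactly the requested rise, twist and radius, then rigidly moves the
#' structure so that its *fitted* axis (see [fit_axis()]) coincides with
#' the requested line, centred at `axis_point`. Side chains for S, T, Y
#' and K are completed from the placed backbone.
#'
#' @param n_res number of residues (>= 5)
#' @param sequence one-letter sequence (default poly-alanine)
#' @param rise helical rise, Angstrom per residue
#' @param twist helical twist, degrees per residue
#' @param ca_radius C-alpha track radius, Angstrom
#' @param axis_point point on the axis (segment centre)
#' @param axis_dir axis direction (need not be unit length)
#' @param phase phase angle of the first residue, degrees
#' @param chain,resno_start,id labelling
#' @return a `ptm_structure` with one model
#' @export
build_ideal_helix <- function(n_res = 18, sequence = NULL, rise = 1.5,
                              twist = 100, ca_radius = 2.3,
                              axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                              phase = 0, chain = "A", resno_start = 1L,
                              id = "synthetic-helix") {
  if (n_res < 5) stop("need at least 5 residues for a helix")
  if (rise <= 0) stop("rise must be positive")
  if (is.null(sequence)) sequence <- strrep("A", n_res)
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n_res) stop("sequence length must equal n_res")
  tmpl <- .helix_template()
  res_atoms <- vector("list", n_res)
  pos_of <- function(rho, phi_deg, z) {
    ph <- rad(phi_deg)
    c(rho * cos(ph), rho * sin(ph) * tmpl$handed, z)
  }
  for (i in seq_len(n_res)) {
    j <- i - 1
    phi_ca <- phase + j * twist
    z_ca <- (j - (n_res - 1) / 2) * rise
    atoms <- list()
    for (nm in c("N", "CA", "C", "O", "CB")) {
      if (nm == "CB" && aa[i] == "G") next
      o <- tmpl$atoms[[nm]]
      atoms[[nm]] <- pos_of(o["rho"] - tmpl$ca_radius + ca_radius,
                            phi_ca + o["dphi"],
                            z_ca + o["dz"])
    }
    res_atoms[[i]] <- atoms
  }
  # complete side chains from the placed backbone
  for (i in seq_len(n_res)) {
    sc <- .SIDECHAIN[[.ONE2THREE[aa[i]]]]
    if (is.null(sc)) next
    atoms <- res_atoms[[i]]
    for (at in sc) {
      refs <- lapply(at[[2]], function(nm) atoms[[nm]])
      atoms[[at[[1]]]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                     at[[3]], at[[4]],
                                     .sidechain_dihedral(at[[5]], -60))
    }
    res_atoms[[i]] <- atoms
  }
  s <- .assemble_structure(res_atoms, aa, chain, resno_start, id)
  # correction transform: make the fitted axis coincide with the request
  xyz <- model_xyz(s)
  ca_rows <- which(s$atoms$name == "CA")
  f <- fit_axis(xyz[ca_rows, ])
  R <- rotation_between(f$axis_dir, unitv(axis_dir))
  s$xyz[[1]] <- sweep(sweep(xyz, 2, f$axis_point) %*% t(R), 2, axis_point, "+")
  s
}

#' Build a helix pair with known descriptors
#'
#' Places two ideal helices as a single chain so that the axis-line
#' distance is `target_d` and the planar angle is `target_phi`. With
#' `crossing = TRUE` the mutual closest approach is interior to both
#' segments (so d = r); otherwise helix B is slid along its own axis so
#' the closest approach falls at a segment end (r > d). The analytic
#' expectations are returned alongside the structure; for crossing
#' strips the intersection area is the closed-form strip value
#' S = (2 radius)^2 / sin(phi).
#'
#' @param target_d axis-line distance, Angstrom
#' @param target_phi planar angle, degrees (0 gives a parallel pair)
#' @param n_a,n_b residues per helix
#' @param crossing closest approach interior to both segments?
#' @param gap axial overhang (Angstrom) used for non-crossing placement
#' @param radius projection strip half-width (cylinder radius), Angstrom
#' @param rise helical rise, Angstrom
#' @return list with `structure` (one chain, two helices), `helices`
#'   (residue index ranges) and `expected` (analytic d, r, theta, phi, S)
#' @export
build_helix_pair <- function(target_d, target_phi, n_a = 18, n_b = 18,
                             crossing = TRUE, gap = 4, radius = 5.0,
                             rise = 1.5) {
  if (target_d < 0) stop("target_d must be >= 0")
  if (target_phi < 0 || target_phi > 90) stop("target_phi must be in [0, 90]")
  phi_r <- rad(target_phi)
  dir_b <- c(0, sin(phi_r), cos(phi_r))
  len_b <- (n_b - 4) * rise
  if (crossing || target_phi == 0) {
    b_center <- c(target_d, 0, 0)
    exp_r <- target_d
  } else {
    shift <- len_b / 2 + gap
    b_center <- c(target_d, 0, 0) + shift * dir_b
    exp_r <- sqrt(target_d^2 + (gap * sin(phi_r))^2)
  }
  ha <- build_ideal_helix(n_a, rise = rise, axis_point = c(0, 0, 0),
                          axis_dir = c(0, 0, 1), chain = "A",
                          resno_start = 1L, id = "pair")
  hb <- build_ideal_helix(n_b, rise = rise, axis_point = b_center,
                          axis_dir = dir_b, chain = "A",
                          resno_start = as.integer(n_a + 5L), id = "pair")
  s <- new_structure(id = "synthetic-helix-pair",
                     atoms = rbind(ha$atoms, hb$atoms),
                     xyz = list(rbind(model_xyz(ha), model_xyz(hb))))
  theta_exp <- if (target_phi == 0) 0 else if (target_d > 0) -target_phi else target_phi
  S_exp <- if (crossing && target_phi > 0) (2 * radius)^2 / sin(phi_r) else NA_real_
  list(structure = s,
       helices = list(a = c(0L, n_a), b = c(n_a, n_a + n_b)),
       radius = radius,
       expected = list(d = target_d, r = exp_r, phi = target_phi,
                       theta = theta_exp, S = S_exp))
}

#' Small toy proteins with known architecture
#'
#' Templates: `"single_helix"` (17 residues, lysine mid-helix),
#' `"hlh_contact"` (helix-loop-helix with the two helix axes 9 Angstrom
#' apart, crossing) and `"hlh_distant"` (same topology, axes 20 Angstrom
#' apart, beyond the 14-Angstrom contact threshold). The loop is placed
#' geometrically between the helix termini; the junctions are treated as
#' chain breaks by the secondary-structure machinery.
#'
#' @param template template identifier
#' @param sequence optional sequence override (length must match)
#' @return a `ptm_structure`
#' @export
toy_protein <- function(template = c("single_helix", "hlh_contact", "hlh_distant"),
                        sequence = NULL) {
  template <- match.arg(template)
  if (template == "single_helix") {
    if (is.null(sequence)) sequence <- "AAAAAAAAKAAAAAAAA"
    if (nchar(sequence) != 17) stop("single_helix template needs 17 residues")
    return(build_ideal_helix(17, sequence = sequence, id = "toy-single-helix"))
  }
  d <- if (template == "hlh_contact") 9 else 20
  n1 <- 14; n2 <- 14; nloop <- 4
  if (is.null(sequence)) sequence <- strrep("A", n1 + nloop + n2)
  if (nchar(sequence) != n1 + nloop + n2) stop("template needs 32 residues")
  aa <- strsplit(sequence, "")[[1]]
  phi_r <- rad(70)
  dir_b <- c(0, sin(phi_r), -cos(phi_r))  # runs back down past helix 1
  h1 <- build_ideal_helix(n1, sequence = paste(aa[1:n1], collapse = ""),
                          axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                          chain = "A", resno_start = 1L)
  h2 <- build_ideal_helix(n2, sequence = paste(aa[(n1 + nloop + 1):(n1 + nloop + n2)], collapse = ""),
                          axis_point = c(d, 0, 0), axis_dir = dir_b,
                          chain = "A", resno_start = as.integer(n1 + nloop + 1L))
  # loop: extended fragment placed between the two helix termini
  loop <- build_peptide(paste(aa[(n1 + 1):(n1 + nloop)], collapse = ""),
                        phi = -120, psi = 120, chain = "A",
                        resno_start = as.integer(n1 + 1L))
  x1 <- model_xyz(h1); x2 <- model_xyz(h2); xl <- model_xyz(loop)
  end1 <- x1[max(which(h1$atoms$name == "CA")), ]
  beg2 <- x2[min(which(h2$atoms$name == "CA")), ]
  lp_ca <- which(loop$atoms$name == "CA")
  lv <- xl[max(lp_ca), ] - xl[min(lp_ca), ]
  tv <- beg2 - end1
  R <- rotation_between(unitv(lv), unitv(tv))
  xl <- sweep(xl, 2, xl[min(lp_ca), ]) %*% t(R)
  xl <- sweep(xl, 2, end1 + tv / (nloop + 1), "+")
  s <- new_structure(id = paste0("toy-", template),
                     atoms = rbind(h1$atoms, loop$atoms, h2$atoms),
                     xyz = list(rbind(x1, xl, x2)))
  s
}

#' Synthetic helix-pair motif carrying a real peptide sequence
#'
#' Builds a single-chain, two-helix synthetic stand-in for a motif of
#' known geometry: helix A starts with the given peptide (placed at the
#' helix N-terminus so that helix-breaking prolines fall at the N-cap),
#' helix B is poly-alanine, and the two axes are placed at the requested
#' axis-line distance and crossing angle with an interior closest
#' approach. Useful for running the full motif/SASA pipeline at a
#' prescribed geometry when the originating crystal structure is not
#' available.
#'
#' @param peptide one-letter peptide placed at the start of helix A
#' @param d axis-line distance, Angstrom
#' @param phi crossing (planar) angle, degrees
#' @param n_a,n_b helix lengths in residues (n_a >= nchar(peptide))
#' @param resno_a,resno_b author numbers of the helix start residues
#' @return a `ptm_structure` (id prefixed `synthetic-`), chain A
#' @export
synthetic_motif_example <- function(peptide, d, phi, n_a = 18, n_b = 30,
                                    resno_a = 1L, resno_b = n_a + 30L) {
  if (nchar(peptide) > n_a) stop("peptide longer than helix A")
  seq_a <- paste0(peptide, strrep("A", n_a - nchar(peptide)))
  phi_r <- rad(phi)
  ha <- build_ideal_helix(n_a, sequence = seq_a, axis_point = c(0, 0, 0),
                          axis_dir = c(0, 0, 1), chain = "A",
                          resno_start = as.integer(resno_a))
  hb <- build_ideal_helix(n_b, axis_point = c(d, 0, 0),
                          axis_dir = c(0, sin(phi_r), cos(phi_r)), chain = "A",
                          resno_start = as.integer(resno_b))
  new_structure(id = "synthetic-motif-example",
                atoms = rbind(ha$atoms, hb$atoms),
                xyz = list(rbind(model_xyz(ha), model_xyz(hb))))
}

#' Gaussian-noise pseudo-trajectory
#'
#' Frame 1 is the input model; frames k > 1 add i.i.d. Gaussian noise of
#' standard deviation `sigma` to every coordinate. With `drift = TRUE`
#' an additional rigid translation of 0.5 Angstrom per frame along x is
#' applied (for rigid-invariance checks). Fully deterministic given
#' `seed`.
#'
#' @param s single-model `ptm_structure`
#' @param n_frames number of models in the output
#' @param sigma coordinate noise, Angstrom
#' @param seed RNG seed
#' @param drift add a rigid per-frame translation
#' @return multi-model `ptm_structure`
#' @export
perturb_trajectory <- function(s, n_frames, sigma, seed = 1L, drift = FALSE) {
  if (n_models(s) != 1) stop("input must be a single-model structure")
  if (sigma < 0) stop("sigma must be >= 0")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  x0 <- model_xyz(s)
  xyz <- vector("list", n_frames)
  xyz[[1]] <- x0
  for (k in seq_len(n_frames)[-1]) {
    xk <- x0 + matrix(stats::rnorm(length(x0), sd = sigma), nrow(x0), 3)
    if (drift) xk <- sweep(xk, 2, c(0.5 * (k - 1), 0, 0), "+")
    xyz[[k]] <- xk
  }
  new_structure(id = paste0(s$id, "-traj"), atoms = s$atoms, xyz = xyz,
                title = s$title)
}
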