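# ---------------------------------------------------------------------------
# PTM notation parsing and in-silico construction of modified side chains.
#
# Annotated peptides use hyphen-delimited tokens embedded in the
# one-letter sequence: "P(X)" phosphorylation, "AC(X)" acetylation,
# "GG(K)" the Gly-Gly ubiquitylation remnant; a leading token marks
# position 1, e.g. "VPHPLEH-AC(K)-IIIR" or "AC(K)-WQEEMELYR".
# Moieties are placed at idealised internal coordinates with the
# attachment torsion chosen by a deterministic 30-degree clash scan, so
# downstream solvent-accessibility numbers are reproducible.
# ---------------------------------------------------------------------------

.PTM_TYPES <- c("PHOSPHO_S", "PHOSPHO_T", "PHOSPHO_Y", "ACETYL_K",
                "GLYGLY_K", "NTERM_ACETYL")

.PTM_RESNAME <- c(PHOSPHO_S = "SEP", PHOSPHO_T = "TPO", PHOSPHO_Y = "PTR",
                  ACETYL_K = "ALY", GLYGLY_K = "KGG")

#' Heavy-atom count of a modification moiety
#' @param ptm_type one of the supported PTM type codes
#' @return integer atom count (phospho 4, acetyl 3, GlyGly 8)
#' @export
moiety_atom_count <- function(ptm_type) {
  switch(ptm_type,
         PHOSPHO_S = 4L, PHOSPHO_T = 4L, PHOSPHO_Y = 4L,
         ACETYL_K = 3L, NTERM_ACETYL = 3L, GLYGLY_K = 8L,
         stop("unknown PTM type: ", ptm_type))
}

#' Parse an annotated PTM peptide string
#'
#' @param annotated peptide in token notation, e.g. `"ILIVI-P(T)-DGK"`
#' @return object of class `ptm_spec`: list with `ptm_type`, `peptide`
#'   (unmodified one-letter sequence), `position` (1-based), `target_aa`
#'   and `loc` (position label such as `"T6"`)
#' @export
parse_ptm_peptide <- function(annotated) {
  parts <- strsplit(annotated, "-", fixed = TRUE)[[1]]
  tok_re <- "^(AC|P|GG)\\(([A-Z])\\)$"
  is_tok <- grepl(tok_re, parts)
  if (sum(is_tok) == 0) stop("no PTM token found in: ", annotated)
  if (sum(is_tok) > 1) stop("multiple PTM tokens are not supported: ", annotated)
  if (any(!is_tok & !grepl("^[A-Z]+$", parts))) {
    stop("malformed segment in annotated peptide: ", annotated)
  }
  k <- which(is_tok)
  tok_type <- sub(tok_re, "\\1", parts[k])
  target <- sub(tok_re, "\\2", parts[k])
  before <- paste(parts[seq_len(k - 1)], collapse = "")
  after <- if (k < length(parts)) paste(parts[(k + 1):length(parts)], collapse = "") else ""
  peptide <- paste0(before, target, after)
  position <- nchar(before) + 1L
  ptm_type <- switch(tok_type,
    P = {
      if (!target %in% c("S", "T", "Y")) {
        stop(sprintf("notation error: phosphorylation of '%s' is not supported", target))
      }
      paste0("PHOSPHO_", target)
    },
    AC = {
      if (target == "K") "ACETYL_K"
      else if (position == 1L) "NTERM_ACETYL"
      else stop(sprintf("notation error: acetylation of '%s' at position %d", target, position))
    },
    GG = {
      if (target != "K") stop("notation error: GlyGly remnant requires lysine")
      "GLYGLY_K"
    })
  structure(list(ptm_type = ptm_type, peptide = peptide,
                 position = position, target_aa = target,
                 loc = paste0(target, position)),
            class = "ptm_spec")
}

#' @export
print.ptm_spec <- function(x, ...) {
  cat(sprintf("<ptm_spec %s at %s of %s>\n", x$ptm_type, x$loc, x$peptide))
  invisible(x)
}

# moiety recipes: atom name, reference atom names (may include earlier
# moiety atoms), bond, angle, dihedral ("scan" resolved by clash search,
# "scan+x" offset from it)
.MOIETY <- list(
  PHOSPHO = list(anchor = c(S = "OG", T = "OG1", Y = "OH"),
                 frame = list(S = c("CA", "CB"), T = c("CA", "CB"), Y = c("CE1", "CZ")),
                 atoms = list(
                   list("P",   NULL, 1.60, 119.0, "scan"),
                   list("O1P", c("@f2", "@anchor", "P"), 1.50, 109.5, "60"),
                   list("O2P", c("@f2", "@anchor", "P"), 1.50, 109.5, "180"),
                   list("O3P", c("@f2", "@anchor", "P"), 1.50, 109.5, "-60"))),
  ACETYL = list(anchor = c(K = "NZ"), frame = list(K = c("CD", "CE")),
                atoms = list(
                  list("CX",  NULL, 1.33, 120.0, "scan"),
                  list("OX",  c("@f2", "@anchor", "CX"), 1.23, 121.0, "0"),
                  list("CME", c("@f2", "@anchor", "CX"), 1.50, 114.0, "180"))),
  NTERM_ACETYL = list(anchor = c(X = "N"), frame = list(X = c("C", "CA")),
                atoms = list(
                  list("CX",  NULL, 1.33, 120.0, "scan"),
                  list("OX",  c("@f2", "@anchor", "CX"), 1.23, 121.0, "0"),
                  list("CME", c("@f2", "@anchor", "CX"), 1.50, 114.0, "180"))),
  GLYGLY = list(anchor = c(K = "NZ"), frame = list(K = c("CD", "CE")),
                atoms = list(
                  list("C2G",  NULL, 1.33, 120.0, "scan"),
                  list("O2G",  c("@f2", "@anchor", "C2G"), 1.23, 121.0, "0"),
                  list("CA2G", c("@f2", "@anchor", "C2G"), 1.52, 116.0, "180"),
                  list("N2G",  c("@anchor", "C2G", "CA2G"), 1.45, 110.0, "180"),
                  list("C1G",  c("C2G", "CA2G", "N2G"), 1.33, 121.0, "180"),
                  list("O1G",  c("CA2G", "N2G", "C1G"), 1.23, 121.0, "0"),
                  list("CA1G", c("CA2G", "N2G", "C1G"), 1.52, 116.0, "180"),
                  list("N1G",  c("N2G", "C1G", "CA1G"), 1.45, 110.0, "180")))
)

.moiety_for <- function(ptm_type) {
  switch(ptm_type,
         PHOSPHO_S = , PHOSPHO_T = , PHOSPHO_Y = .MOIETY$PHOSPHO,
         ACETYL_K = .MOIETY$ACETYL,
         NTERM_ACETYL = .MOIETY$NTERM_ACETYL,
         GLYGLY_K = .MOIETY$GLYGLY,
         stop("unknown PTM type: ", ptm_type))
}

#' Attach a modification moiety to a residue
#'
#' Builds the moiety at idealised internal coordinates on the anchor
#' atom (hydroxyl O for phospho-S/T/Y, NZ for acetyl-K and GlyGly-K,
#' backbone N for N-terminal acetyl). The attachment torsion is scanned
#' in 30-degree steps and the rotation minimising the sum of
#' inverse-square distances to neighbouring heavy atoms is kept, making
#' the construction deterministic. Pre-existing atoms are never moved;
#' the residue is renamed (SEP/TPO/PTR/ALY/KGG) so the modification
#' survives a PDB round trip. Phosphate is built as PO3 (no protons)
#' and no moiety hydrogens are added.
#'
#' @param s a `ptm_structure`
#' @param chain chain identifier
#' @param residue_index 0-based residue index within the chain (as
#'   returned by [find_peptide()])
#' @param ptm_type one of `PHOSPHO_S`, `PHOSPHO_T`, `PHOSPHO_Y`,
#'   `ACETYL_K`, `GLYGLY_K`, `NTERM_ACETYL`
#' @return a new `ptm_structure` with the moiety atoms appended to the
#'   target residue (all models)
#' @export
apply_ptm <- function(s, chain, residue_index, ptm_type) {
  ptm_type <- match.arg(ptm_type, .PTM_TYPES)
  rt <- residue_table(s)
  rows <- residue_atom_rows(s, chain, residue_index)
  res_one <- .AA3TO1[s$atoms$resname[rows[1]]]
  expected_aa <- switch(ptm_type,
                        PHOSPHO_S = "S", PHOSPHO_T = "T", PHOSPHO_Y = "Y",
                        ACETYL_K = "K", GLYGLY_K = "K", NTERM_ACETYL = NA)
  if (!is.na(expected_aa) && (is.na(res_one) || res_one != expected_aa)) {
    stop(sprintf("residue %s:%d is %s; incompatible with %s",
                 chain, residue_index, s$atoms$resname[rows[1]], ptm_type))
  }
  rec <- .moiety_for(ptm_type)
  key <- if (ptm_type == "NTERM_ACETYL") "X" else expected_aa
  anchor_name <- unname(rec$anchor[key])
  frame_names <- rec$frame[[key]]
  names_here <- s$atoms$name[rows]
  need <- c(frame_names, anchor_name)
  if (!all(need %in% names_here)) {
    stop(sprintf("build error: residue %s:%d lacks anchor/frame atoms (%s)",
                 chain, residue_index, paste(setdiff(need, names_here), collapse = ",")))
  }
  row_of <- function(nm) rows[match(nm, names_here)]

  n_mod <- n_models(s)
  new_xyz_per_model <- vector("list", n_mod)
  scan_dih <- NA_real_
  for (m in seq_len(n_mod)) {
    xyz <- model_xyz(s, m)
    f1 <- xyz[row_of(frame_names[1]), ]
    f2 <- xyz[row_of(frame_names[2]), ]
    anc <- xyz[row_of(anchor_name), ]
    if (m == 1) {
      # choose attachment torsion by coarse clash scan on model 1
      first <- rec$atoms[[1]]
      env_rows <- setdiff(seq_len(nrow(xyz)), rows)
      env <- xyz[env_rows, , drop = FALSE]
      best <- NULL; best_score <- Inf
      for (dih in seq(0, 330, by = 30)) {
        # place the whole moiety at this torsion and score all atoms
        coords <- .place_moiety(rec, f1, f2, anc, dih)
        dmat <- as.matrix(stats::dist(rbind(coords, env)))[seq_len(nrow(coords)),
                                                           -seq_len(nrow(coords)), drop = FALSE]
        score <- sum(1 / pmax(dmat[dmat < 6], 0.5)^2)
        if (score < best_score) { best_score <- score; best <- dih }
      }
      scan_dih <- best
    }
    new_xyz_per_model[[m]] <- .place_moiety(rec, f1, f2, anc, scan_dih)
  }
  moiety_names <- vapply(rec$atoms, function(a) a[[1]], character(1))
  # name the phosphate / acetyl atoms conventionally
  out_names <- moiety_names
  out_names[out_names == "CX"] <- if (ptm_type == "NTERM_ACETYL") "CAY" else "CH"
  out_names[out_names == "OX"] <- if (ptm_type == "NTERM_ACETYL") "OAY" else "OH1"
  out_names[out_names == "CME"] <- "CH3"
  elements <- substr(moiety_names, 1, 1)

  # clash check against non-bonded heavy atoms (model 1)
  xyz1 <- model_xyz(s, 1)
  env_rows <- setdiff(seq_len(nrow(xyz1)), rows)
  if (length(env_rows)) {
    dmin <- min(as.matrix(stats::dist(rbind(new_xyz_per_model[[1]],
                                            xyz1[env_rows, , drop = FALSE])))[
      seq_len(nrow(new_xyz_per_model[[1]])),
      -seq_len(nrow(new_xyz_per_model[[1]]))])
    if (dmin < 1.5) {
      warning(sprintf("moiety heavy-atom clash after rotation search (min %.2f A)", dmin))
    }
  }

  at <- s$atoms
  insert_after <- rows[length(rows)]
  newrows <- data.frame(name = out_names,
                        resname = at$resname[rows[1]],
                        chain = at$chain[rows[1]], resno = at$resno[rows[1]],
                        ins = at$ins[rows[1]], occ = 1, bfactor = 0,
                        element = elements, vdw = vdw_radius_of(elements),
                        stringsAsFactors = FALSE)
  ord <- order(c(seq_len(nrow(at)), rep(insert_after + 0.5, nrow(newrows))))
  atoms2 <- rbind(at, newrows)[ord, , drop = FALSE]
  # rename the residue so the modification is visible in the PDB output
  new_resname <- .PTM_RESNAME[ptm_type]
  if (!is.na(new_resname)) {
    ridx <- which(atoms2$chain == at$chain[rows[1]] &
                  atoms2$resno == at$resno[rows[1]] &
                  atoms2$ins == at$ins[rows[1]])
    atoms2$resname[ridx] <- unname(new_resname)
  }
  rownames(atoms2) <- NULL
  xyz2 <- lapply(seq_len(n_mod), function(m) {
    unname(rbind(model_xyz(s, m), new_xyz_per_model[[m]])[ord, , drop = FALSE])
  })
  new_structure(s$id, atoms2, xyz2, s$title)
}

# place all moiety atoms for a given attachment torsion
.place_moiety <- function(rec, f1, f2, anc, dih) {
  placed <- list("@f1" = f1, "@f2" = f2, "@anchor" = anc)
  out <- matrix(NA_real_, length(rec$atoms), 3)
  for (k in seq_along(rec$atoms)) {
    a <- rec$atoms[[k]]
    if (is.null(a[[2]])) {
      refs <- list(f1, f2, anc)
      dh <- dih
    } else {
      refs <- lapply(a[[2]], function(nm) {
        if (startsWith(nm, "@")) placed[[nm]] else placed[[nm]]
      })
      dh <- as.numeric(a[[5]])
    }
    p <- place_atom(refs[[1]], refs[[2]], refs[[3]], a[[3]], a[[4]], dh)
    placed[[a[[1]]]] <- p
    out[k, ] <- p
  }
  out
}
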