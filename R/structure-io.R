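# ---------------------------------------------------------------------------
# Hierarchical coordinate model
#
# A `ptm_structure` holds one topology (flat atom table) shared by one or
# more coordinate sets ("models", one per MODEL record), the multi-model
# convention used for NMR ensembles and here for pseudo-trajectories.
# ---------------------------------------------------------------------------

# Bondi van der Waals radii (Angstrom); SE follows S-like packing.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, SE = 1.90)
.VDW_DEFAULT <- 1.80

.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  # modified residues keep their parent one-letter code
  SEP = "S", TPO = "T", PTR = "Y", ALY = "K", KGG = "K", MSE = "M"
)

vdw_radius_of <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

new_structure <- function(id, atoms, xyz, title = "") {
  stopifnot(is.data.frame(atoms), is.list(xyz), length(xyz) >= 1)
  for (m in xyz) stopifnot(is.matrix(m), ncol(m) == 3, nrow(m) == nrow(atoms))
  structure(list(id = id, title = title, atoms = atoms, xyz = xyz),
            class = "ptm_structure")
}

#' Number of models (frames) in a structure
#' @param s a `ptm_structure`
#' @return integer count of coordinate sets
#' @export
n_models <- function(s) length(s$xyz)

#' Coordinates of one model
#' @param s a `ptm_structure`
#' @param model model number (1-based)
#' @return numeric matrix, one row per atom, columns x/y/z in Angstrom
#' @export
model_xyz <- function(s, model = 1) {
  if (model < 1 || model > n_models(s)) stop("model index out of range")
  s$xyz[[model]]
}

#' @export
print.ptm_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<ptm_structure '%s': %d model(s), %d chain(s), %d residues, %d atoms>\n",
              x$id, n_models(x), length(unique(rt$chain)), nrow(rt), nrow(x$atoms)))
  invisible(x)
}

#' Residue-level view of a structure
#'
#' Groups the flat atom table into residues in order of first appearance.
#' The combination (chain, resno, ins) identifies a residue; `first`/`last`
#' are the atom-row bounds of the residue block.
#'
#' @param s a `ptm_structure`
#' @return data.frame with columns chain, resno, ins, resname, one
#'   (one-letter code, `X` for unknown), first, last, n_atoms
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  change <- c(TRUE, key[-1] != key[-length(key)])
  first <- which(change)
  last <- c(first[-1] - 1L, nrow(a))
  one <- .AA3TO1[a$resname[first]]
  one[is.na(one)] <- "X"
  data.frame(chain = a$chain[first], resno = a$resno[first],
             ins = a$ins[first], resname = a$resname[first],
             one = unname(one), first = first, last = last,
             n_atoms = last - first + 1L, stringsAsFactors = FALSE)
}

# atom-row indices of residue `idx` (0-based within chain)
residue_atom_rows <- function(s, chain, idx) {
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (idx < 0 || idx >= nrow(rt)) stop("residue index out of range for chain ", chain)
  r <- rt[idx + 1L, ]
  seq.int(r$first, r$last)
}

# named coordinates of selected atoms of a residue (model m)
residue_atom_coords <- function(s, rows, model = 1) {
  xyz <- model_xyz(s, model)
  out <- lapply(seq_along(rows), function(i) xyz[rows[i], ])
  names(out) <- s$atoms$name[rows]
  out
}

# ---------------------------------------------------------------------------
# PDB reading
# ---------------------------------------------------------------------------

.substr_trim <- function(x, a, b) trimws(substr(x, a, b))

.infer_element <- function(name_raw) {
  # name_raw is the 4-character atom-name field (cols 13-16).
  two <- toupper(gsub("[^A-Za-z]", "", substr(name_raw, 1, 2)))
  first_alpha <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1",
                             paste0(name_raw, "X")))
  el <- first_alpha
  # a name starting in column 13 signals a two-letter element (FE, SE, ...)
  wide <- substr(name_raw, 1, 1) != " " & two %in% c("FE", "ZN", "MG", "MN",
                                                     "SE", "CL", "BR", "NA",
                                                     "CU", "NI", "CO", "CD")
  el[wide] <- two[wide]
  el
}

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL records into a [ptm_structure]
#' (flat atom table + one coordinate matrix per model). Alternate
#' locations are collapsed to the highest-occupancy conformer (ties go
#' to altloc `A`); hydrogens are discarded (amide hydrogens are rebuilt
#' geometrically by [place_amide_hydrogens()]); waters and HETATM
#' ligands are dropped unless `keep_hetatm = TRUE`. Element symbols
#' missing from columns 77-78 are inferred from the atom name, and every
#' atom is assigned a fixed Bondi van der Waals radius.
#'
#' @param source path to a PDB file, or a character vector of PDB lines
#' @param id structure identifier (default: file base name)
#' @param keep_hetatm keep non-water HETATM records
#' @return a `ptm_structure`
#' @export
read_pdb <- function(source, id = NULL, keep_hetatm = FALSE) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(source))
  } else {
    lines <- if (length(source) == 1) strsplit(source, "\n", fixed = TRUE)[[1]] else source
    if (is.null(id)) id <- "structure"
  }
  rec <- substr(lines, 1, 6)
  title <- paste(.substr_trim(lines[rec == "TITLE "], 11, 80), collapse = " ")

  is_model <- rec == "MODEL "

  # model id per line
  model_no <- cumsum(is_model)
  if (!any(is_model)) model_no <- rep(1L, length(lines))
  model_no[model_no == 0L] <- 1L

  keep <- rec == "ATOM  " | rec == "HETATM"
  if (!any(keep)) stop("no ATOM records found: empty structure")
  al <- lines[keep]
  # pad short lines to full width so fixed-column extraction is safe
  al <- formatC(al, width = -80)
  ln_no <- which(keep)

  xs <- suppressWarnings(as.numeric(.substr_trim(al, 31, 38)))
  ys <- suppressWarnings(as.numeric(.substr_trim(al, 39, 46)))
  zs <- suppressWarnings(as.numeric(.substr_trim(al, 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad)) {
    stop(sprintf("malformed coordinate field at line %d: '%s'",
                 ln_no[bad[1]], trimws(lines[ln_no[bad[1]]])))
  }

  occ <- suppressWarnings(as.numeric(.substr_trim(al, 55, 60)))
  occ[is.na(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(.substr_trim(al, 61, 66)))
  bfac[is.na(bfac)] <- 0

  name_raw <- substr(al, 13, 16)
  el <- .substr_trim(al, 77, 78)
  miss <- el == ""
  el[miss] <- .infer_element(name_raw[miss])
  el <- toupper(el)

  df <- data.frame(
    record = substr(al, 1, 6),
    name = trimws(name_raw),
    altloc = substr(al, 17, 17),
    resname = .substr_trim(al, 18, 20),
    chain = substr(al, 22, 22),
    resno = suppressWarnings(as.integer(.substr_trim(al, 23, 26))),
    ins = substr(al, 27, 27),
    x = xs, y = ys, z = zs, occ = occ, bfactor = bfac,
    element = el, model = model_no[keep],
    stringsAsFactors = FALSE
  )

  # filters: hydrogens always; waters always; HETATM unless kept
  df <- df[df$element != "H" & df$element != "D", , drop = FALSE]
  df <- df[df$resname != "HOH" & df$resname != "DOD", , drop = FALSE]
  if (!keep_hetatm) {
    # modified residues (SEP/TPO/PTR/ALY/KGG/MSE) are part of the chain
    df <- df[df$record == "ATOM  " | df$resname %in% names(.AA3TO1), , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no ATOM records found: empty structure")

  models <- split(df, df$model)
  models <- lapply(models, .collapse_altloc)

  topo0 <- .topology_key(models[[1]])
  if (length(models) > 1) {
    for (k in 2:length(models)) {
      if (!identical(.topology_key(models[[k]]), topo0)) {
        stop("models differ in residue/atom topology; cannot be used as a trajectory")
      }
    }
  }

  a1 <- models[[1]]
  atoms <- data.frame(
    name = a1$name, resname = a1$resname, chain = a1$chain,
    resno = a1$resno, ins = a1$ins, occ = a1$occ, bfactor = a1$bfactor,
    element = a1$element, vdw = vdw_radius_of(a1$element),
    stringsAsFactors = FALSE
  )
  xyz <- lapply(models, function(m) unname(cbind(m$x, m$y, m$z)))
  names(xyz) <- NULL
  new_structure(id = id, atoms = atoms, xyz = xyz, title = title)
}

.topology_key <- function(m) {
  paste(m$chain, m$resno, m$ins, m$resname, m$name, sep = "|")
}

.collapse_altloc <- function(m) {
  if (all(m$altloc == " ")) return(m)
  key <- paste(m$chain, m$resno, m$ins, m$name, sep = "\r")
  keep <- rep(TRUE, nrow(m))
  for (k in unique(key[m$altloc != " "])) {
    rows <- which(key == k)
    if (length(rows) <= 1) next
    o <- m$occ[rows]
    best <- rows[o == max(o)]
    if (length(best) > 1) {
      pickA <- best[m$altloc[best] == "A"]
      best <- if (length(pickA)) pickA[1] else best[1]
    }
    keep[setdiff(rows, best)] <- FALSE
  }
  m[keep, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# PDB writing
# ---------------------------------------------------------------------------

#' Write a structure as PDB-format text
#'
#' Emits fixed-column ATOM records (MODEL/ENDMDL blocks when the
#' structure holds several models). Coordinates survive a read/write
#' round trip to the 3-decimal PDB precision.
#'
#' @param s a `ptm_structure`
#' @param target output path, or `NULL` to return the text invisibly
#' @return (invisibly) the character vector of PDB lines
#' @export
write_pdb <- function(s, target = NULL) {
  if (!inherits(s, "ptm_structure")) stop("not a ptm_structure")
  if (length(s$xyz) == 0) stop("structure has an empty model list")
  if (nrow(s$atoms) > 99999) stop("atom serial overflow: more than 99999 atoms")
  a <- s$atoms
  multi <- n_models(s) > 1
  out <- character(0)
  if (nzchar(s$title)) out <- c(out, sprintf("TITLE     %s", s$title))
  for (m in seq_len(n_models(s))) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    xyz <- s$xyz[[m]]
    nm <- ifelse(nchar(a$name) >= 4 | nchar(a$element) >= 2,
                 formatC(a$name, width = -4),
                 paste0(" ", formatC(a$name, width = -3)))
    rec <- ifelse(a$resname %in% names(.AA3TO1), "ATOM  ", "HETATM")
    rec[a$resname %in% c("SEP", "TPO", "PTR", "ALY", "KGG", "MSE")] <- "HETATM"
    lines <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(nrow(a)), nm, " ", a$resname, a$chain,
                     a$resno, a$ins, xyz[, 1], xyz[, 2], xyz[, 3],
                     a$occ, a$bfactor, a$element)
    out <- c(out, lines)
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(target)) writeLines(out, target)
  invisible(out)
}

# ---------------------------------------------------------------------------
# Sequence access and peptide search
# ---------------------------------------------------------------------------

#' One-letter sequence of a chain
#'
#' @param s a `ptm_structure`
#' @param chain_id single chain character
#' @param mse_as_met map selenomethionine (MSE) to `M` (default TRUE)
#' @return one-letter string; non-standard residues become `X`
#' @export
chain_sequence <- function(s, chain_id, mse_as_met = TRUE) {
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain_id, , drop = FALSE]
  if (nrow(rt) == 0) stop("no such chain: ", chain_id)
  one <- rt$one
  if (!mse_as_met) one[rt$resname == "MSE"] <- "X"
  paste(one, collapse = "")
}

#' Locate a peptide in all chains of a structure
#'
#' Finds every exact, gap-free occurrence of `peptide` in the one-letter
#' sequence of each chain.
#'
#' @param s a `ptm_structure`
#' @param peptide one-letter query, length >= 3
#' @return data.frame with columns chain, start, end (0-based half-open
#'   residue indices into the chain's residue list); zero rows if absent
#' @export
find_peptide <- function(s, peptide) {
  if (nchar(peptide) < 3) stop("peptide must be at least 3 residues")
  rt <- residue_table(s)
  hits <- list()
  for (ch in unique(rt$chain)) {
    seq1 <- chain_sequence(s, ch)
    m <- gregexpr(peptide, seq1, fixed = TRUE)[[1]]
    if (m[1] != -1) {
      for (p in as.integer(m)) {
        hits[[length(hits) + 1]] <- data.frame(
          chain = ch, start = p - 1L, end = p - 1L + nchar(peptide),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(chain = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}
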