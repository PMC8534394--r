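# ---------------------------------------------------------------------------
# Helix-pair motif blocks: enumeration under the d <= 14 Angstrom contact
# filter and alpha-alpha-corner vs L/V classification.
# ---------------------------------------------------------------------------

.CONTACT_MAX_D <- 14   # Angstrom: first and last helices "in contact"

#' Classify a helix-pair motif
#'
#' An alpha-alpha-corner has crossing axes (d = r within `tol`) and a
#' substantial projected intersection (S > `s_min`); an L- or
#' V-structure has non-intersecting axes (r - d > `tol`) with a zero or
#' near-zero intersection area (S <= `s_min`). Anything else is reported
#' as `UNCLASSIFIED`.
#'
#' @param desc a `helix_pair_descriptors`
#' @param tol tolerance for the d = r test, Angstrom (default 0.1)
#' @param s_min area threshold for "close to zero", Angstrom^2 (default 1)
#' @return one of `"ALPHA_ALPHA_CORNER"`, `"L_OR_V"`, `"UNCLASSIFIED"`
#' @export
classify_motif <- function(desc, tol = 0.1, s_min = 1) {
  if (!all(is.finite(c(desc$d, desc$r, desc$S)))) stop("non-finite descriptors")
  if (abs(desc$d - desc$r) <= tol && desc$S > s_min) return("ALPHA_ALPHA_CORNER")
  if (desc$r - desc$d > tol && desc$S <= s_min) return("L_OR_V")
  "UNCLASSIFIED"
}

#' Enumerate helix-pair motif blocks in a chain
#'
#' Every ordered helix pair (i < j) defines a candidate block whose
#' first and last helices are that pair; the block's `n_helix` counts
#' all helices lying fully inside the locus. Blocks are retained iff the
#' interplanar distance between the first and last helices satisfies
#' d <= 14 Angstrom (the contact filter); filtered pairs can be kept
#' with `keep_non_contact = TRUE` (labelled `NON_CONTACT`).
#'
#' @param s a `ptm_structure`
#' @param chain chain identifier
#' @param model model number
#' @param min_len minimum helix length passed to [helix_segments()]
#' @param radius projection cylinder radius, Angstrom
#' @param keep_non_contact also return pairs failing the contact filter
#' @param max_chain_len optional chain-length filter (residues); chains
#'   longer than this are skipped (`NULL` disables, the default)
#' @return list of `motif_block` objects (possibly empty); each holds
#'   `locus` (author numbers), `helices` (the segment table rows),
#'   `n_helix`, `descriptors` and `class_label`
#' @export
enumerate_blocks <- function(s, chain, model = 1, min_len = 5, radius = 5.0,
                             keep_non_contact = FALSE, max_chain_len = NULL) {
  rt <- residue_table(s)
  chain_len <- sum(rt$chain == chain)
  if (!is.null(max_chain_len) && chain_len > max_chain_len) return(list())
  asg <- assign_ss(s, model = model)
  segs <- helix_segments(asg, min_len = min_len)
  segs <- segs[segs$chain == chain, , drop = FALSE]
  if (nrow(segs) < 2) return(list())
  helix_objs <- lapply(seq_len(nrow(segs)), function(k) {
    helix_segment(s, chain, segs$start[k], segs$end[k], model = model,
                  radius = radius)
  })
  blocks <- list()
  for (i in seq_len(nrow(segs) - 1)) {
    for (j in (i + 1):nrow(segs)) {
      desc <- pair_descriptors(helix_objs[[i]], helix_objs[[j]])
      contact <- desc$d <= .CONTACT_MAX_D
      if (!contact && !keep_non_contact) next
      inside <- segs$start >= segs$start[i] & segs$end <= segs$end[j]
      blk <- structure(list(
        chain = chain,
        locus = c(segs$resno_start[i], segs$resno_end[j]),
        index_span = c(segs$start[i], segs$end[j]),
        helix_a = segs[i, , drop = FALSE],
        helix_b = segs[j, , drop = FALSE],
        helices = segs[inside, , drop = FALSE],
        n_helix = sum(inside),
        descriptors = desc,
        class_label = if (contact) classify_motif(desc) else "NON_CONTACT"
      ), class = "motif_block")
      blocks[[length(blocks) + 1]] <- blk
    }
  }
  blocks
}

#' @export
print.motif_block <- function(x, ...) {
  d <- x$descriptors
  cat(sprintf("<motif_block %s %d-%d: H_A (%d-%d) H_B (%d-%d), N_helix %d, d=%.1f r=%.1f S=%.1f, %s>\n",
              x$chain, x$locus[1], x$locus[2],
              x$helix_a$resno_start, x$helix_a$resno_end,
              x$helix_b$resno_start, x$helix_b$resno_end,
              x$n_helix, d$d, d$r, d$S, x$class_label))
  invisible(x)
}

#' Motif blocks overlapping a peptide
#'
#' Locates the peptide with [find_peptide()] and returns the blocks
#' from [enumerate_blocks()] whose residue-index span overlaps any
#' occurrence of the peptide.
#'
#' @param s a `ptm_structure`
#' @param peptide one-letter peptide query
#' @inheritParams enumerate_blocks
#' @return list of `motif_block`s; empty list with attribute
#'   `"not_found" = TRUE` when the peptide is absent
#' @export
motifs_for_peptide <- function(s, peptide, model = 1, min_len = 5,
                               radius = 5.0) {
  hits <- find_peptide(s, peptide)
  if (nrow(hits) == 0) {
    out <- list()
    attr(out, "not_found") <- TRUE
    return(out)
  }
  out <- list()
  for (ch in unique(hits$chain)) {
    blocks <- enumerate_blocks(s, ch, model = model, min_len = min_len,
                               radius = radius)
    hsub <- hits[hits$chain == ch, , drop = FALSE]
    for (blk in blocks) {
      ov <- any(pmax(blk$index_span[1], hsub$start) <
                pmin(blk$index_span[2], hsub$end))
      if (ov) out[[length(out) + 1]] <- blk
    }
  }
  out
}

#' Summarise motif blocks as a table
#'
#' One row per block: locus, helix ranges (author numbering), helix
#' count, the six descriptors and the class label.
#'
#' @param blocks list of `motif_block`s
#' @param gene,peptide optional label columns
#' @return data.frame
#' @export
motif_table <- function(blocks, gene = NA_character_, peptide = NA_character_) {
  if (length(blocks) == 0) {
    return(data.frame(gene = character(0), peptide = character(0),
                      chain = character(0), locus = character(0),
                      helix_a = character(0), helix_b = character(0),
                      n_helix = integer(0), d = numeric(0), r = numeric(0),
                      theta = numeric(0), phi = numeric(0), S = numeric(0),
                      P = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(blocks, function(b) {
    d <- b$descriptors
    data.frame(gene = gene, peptide = peptide, chain = b$chain,
               locus = sprintf("%d-%d", b$locus[1], b$locus[2]),
               helix_a = sprintf("%d-%d", b$helix_a$resno_start, b$helix_a$resno_end),
               helix_b = sprintf("%d-%d", b$helix_b$resno_start, b$helix_b$resno_end),
               n_helix = b$n_helix, d = d$d, r = d$r, theta = d$theta,
               phi = d$phi, S = d$S, P = d$P, class = b$class_label,
               stringsAsFactors = FALSE)
  }))
}

#' Write a motif table as TSV
#' @param tbl data.frame from [motif_table()]
#' @param path output path
#' @export
write_motif_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
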