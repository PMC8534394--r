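#!/usr/bin/env Rscript
# Builds the synthetic study structures used throughout the analysis and
# materialises them as PDB files under results/fixtures/:
#   - the two-helix alpha-alpha-corner stand-in at the reported geometry
#     (axis distance 9.2 A, crossing angle 66 deg) carrying the RPB11
#     peptide VPHPLEHKIIIR
#   - the dynein-peptide (IEDFWGPAKR) stand-in used for the SASA survey
#   - contacting / distant helix-loop-helix toys
#   - a 30-frame Gaussian pseudo-trajectory (sigma 0.2 A) of the corner

suppressMessages(library(helixptm))
out_dir <- "results/fixtures"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

corner <- synthetic_motif_example("VPHPLEHKIIIR", d = 9.2, phi = 66,
                                  n_a = 18, n_b = 30,
                                  resno_a = 40L, resno_b = 83L)
write_pdb(corner, file.path(out_dir, "synthetic_corner_rpb11_peptide.pdb"))

dyh <- synthetic_motif_example("IEDFWGPAKR", d = 9.2, phi = 66)
write_pdb(dyh, file.path(out_dir, "synthetic_corner_dynein_peptide.pdb"))

write_pdb(toy_protein("hlh_contact"), file.path(out_dir, "toy_hlh_contact.pdb"))
write_pdb(toy_protein("hlh_distant"), file.path(out_dir, "toy_hlh_distant.pdb"))

bp <- build_helix_pair(9.2, 66, n_a = 18, n_b = 30)
traj <- perturb_trajectory(bp$structure, n_frames = 30, sigma = 0.2, seed = 1)
write_pdb(traj, file.path(out_dir, "synthetic_corner_trajectory.pdb"))

cat("Fixtures written to", out_dir, "\n")
cat(sprintf("  corner stand-in: %d residues, %d atoms\n",
            nrow(residue_table(corner)), nrow(corner$atoms)))
cat(sprintf("  trajectory: %d frames of %d atoms\n",
            n_models(traj), nrow(traj$atoms)))
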