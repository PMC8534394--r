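#!/usr/bin/env Rscript
# Trajectory-level stability analysis of the corner motif:
#   - 30-frame Gaussian pseudo-trajectories (sigma 0.2 A) of the native
#     and acetylated stand-in
#   - per-frame descriptor series with the frame-1 ("stat") reference
#   - stability summaries (mean, sd, max deviation) and the
#     stat/nmd/mod comparison
#   - GROMOS clustering at the 1.3 A cutoff
# Writes results/series_{nmd,mod}.csv and results/stability.csv.

suppressMessages(library(helixptm))
dir.create("results", showWarnings = FALSE)

s <- synthetic_motif_example("VPHPLEHKIIIR", d = 9.2, phi = 66,
                             n_a = 18, n_b = 30)
hit <- find_peptide(s, "VPHPLEHKIIIR")
spec <- parse_ptm_peptide("VPHPLEH-AC(K)-IIIR")
mod <- apply_ptm(s, hit$chain[1], hit$start[1] + spec$position - 1L, spec$ptm_type)

ranges <- list(a = c(0L, 18L), b = c(18L, 48L))
tr_n <- perturb_trajectory(s, n_frames = 30, sigma = 0.2, seed = 11)
tr_m <- perturb_trajectory(mod, n_frames = 30, sigma = 0.2, seed = 12)

ser_n <- descriptor_series(tr_n, "A", ranges$a, ranges$b)
ser_m <- descriptor_series(tr_m, "A", ranges$a, ranges$b)
write_series_csv(ser_n, "results/series_nmd.csv", variant = "nmd")
write_series_csv(ser_m, "results/series_mod.csv", variant = "mod")

cmp <- stability_comparison(ser_n, ser_m)
utils::write.csv(cmp, "results/stability.csv", row.names = FALSE)
cat("Stability (stat / nmd / mod):\n")
print(cmp)

sn <- stability_summary(ser_n)
cat(sprintf("\nNative motif: d stays at %.2f +/- %.2f A (initial %.2f); the pair remains in contact throughout.\n",
            sn$mean[sn$descriptor == "d"], sn$sd[sn$descriptor == "d"],
            sn$initial[sn$descriptor == "d"]))

for (lab in c(native = "native", modified = "modified")) {
  tr <- if (lab == "native") tr_n else tr_m
  cl <- gromos_cluster(tr, cutoff = 1.3)
  cat(sprintf("GROMOS clustering (%s, cutoff 1.3 A): %d cluster(s), largest holds %d/%d frames (representative frame %d)\n",
              lab, length(cl$clusters), length(largest_cluster(cl)),
              n_models(tr), cl$representative[1]))
}
cat("Series and summaries written under results/\n")
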