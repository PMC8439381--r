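#!/usr/bin/env Rscript
# Single-trajectory MM-GB(SA) on the toy complex: component table,
# per-residue decomposition with hot-spot calls, and computational
# alanine scanning. The generator plants one strongly interacting
# receptor residue, which should dominate both the ledger and the scan.

suppressMessages(library(mdensemble))

out <- "results/analysis/energetics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tc <- toy_complex(n_frames = 15, seed = 501)
top <- tc$topology
allsel <- seq_len(n_atoms(top))

br <- binding_free_energy(tc$ensemble, top, allsel, tc$receptor_sel,
                          tc$ligand_sel, n_sphere_points = 240)
write_binding_result(br, file.path(out, "binding_components.tsv"))
cat("Component table (kcal/mol):\n")
print(within(br$summary, {mean <- round(mean, 3); sd <- round(sd, 3)
                          sem <- round(sem, 3)}), row.names = FALSE)

rl <- per_residue_decomposition(tc$ensemble, top, allsel, tc$receptor_sel,
                                tc$ligand_sel, n_sphere_points = 240)
write.table(rl, file.path(out, "residue_ledger.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nHot spots (total <= -0.5 kcal/mol): %s\n",
            paste(sprintf("%s:%s%d (%.2f)", rl$chain[rl$hot_spot],
                          rl$resname[rl$hot_spot], rl$resid[rl$hot_spot],
                          rl$total[rl$hot_spot]), collapse = ", ")))
cat(sprintf("Ledger sum vs dG_bind: %.2e kcal/mol difference\n",
            abs(sum(rl$total) -
                  br$summary$mean[br$summary$component == "G_total"])))

scan <- alanine_scan(tc$ensemble, top, allsel, tc$receptor_sel,
                     tc$ligand_sel, residues = 1:4, n_sphere_points = 240)
write.table(scan, file.path(out, "alanine_scan.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nAlanine scan (ddG = dG[WT] - dG[mutant], kcal/mol):\n")
print(within(scan, {dG_wt <- round(dG_wt, 3); dG_mut <- round(dG_mut, 3)
                    ddG <- round(ddG, 3)}), row.names = FALSE)
cat(sprintf("\nPlanted hot spot (resid %d) ranks first in both analyses: %s\n",
            tc$truth$hotspot_resid,
            rl$resid[which.min(rl$total[rl$chain == "R"])] ==
              tc$truth$hotspot_resid &&
              scan$resid[which.max(abs(scan$ddG))] == tc$truth$hotspot_resid))
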