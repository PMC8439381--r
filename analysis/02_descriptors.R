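#!/usr/bin/env Rscript
# Geometric descriptor battery on the fully engaged system (D): reads the
# files written by 01_build_systems.R back through the package's own I/O,
# then computes RMSD, Rg, RMSF, SASA, the hot-spot contact distance, a
# triangle-area series (the charge-clamp-style three-atom monitor), a
# contact shell around the ligand, and distribution summaries.

suppressMessages(library(mdensemble))

sysdir <- "results/analysis/systems"
out <- "results/analysis/descriptors"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

st <- read_structure(file.path(sysdir, "D_both.pdb"))
top <- read_parameters(st$topology, file.path(sysdir, "D_both.params"))
top <- guess_bonds(top, frame_coords(st$ensemble, 1))
ens <- read_trajectory(top, file.path(sysdir, "D_both.dcd"), "dcd")

rmsd <- rmsd_series(ens, top, reference = 1, fit_sel = "all")
write_time_series(rmsd, file.path(out, "rmsd.tsv"))
rg <- radius_of_gyration(ens, top, "all")
write_time_series(rg, file.path(out, "rg.tsv"))
sa <- sasa_series(ens, top, "all", n_sphere_points = 240)
write_time_series(sa, file.path(out, "sasa.tsv"))
rf <- rmsf(ens, top, "name CA")
write.table(rf, file.path(out, "rmsf.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

d_hot <- distance_series(ens, top, "name N1", "name OG and resid 2")
write_time_series(d_hot, file.path(out, "hotspot_distance.tsv"))
tri <- triangle_area_series(ens, top, "name CA and resid 1",
                            "name CA and resid 2", "name CA and resid 4")
write_time_series(tri, file.path(out, "triangle_area.tsv"))

ct <- contact_shell(frame_coords(ens, 1), top, "chain L",
                    shell_radius = 4.0, classify = TRUE)
write_contact_table(ct, file.path(out, "ligand_contacts.tsv"))

h <- histogram_summary(d_hot, n_bins = 30)

cat(sprintf("RMSD to frame 1:       %.3f +/- %.3f A\n",
            rmsd$summary["mean"], rmsd$summary["sd"]))
cat(sprintf("Radius of gyration:    %.3f +/- %.3f A\n",
            rg$summary["mean"], rg$summary["sd"]))
cat(sprintf("Total SASA:            %.1f +/- %.1f A^2\n",
            sa$summary["mean"], sa$summary["sd"]))
cat(sprintf("Mean CA RMSF:          %.3f A\n", mean(rf$rmsf)))
cat(sprintf("Hot-spot N1...OG:      %.2f A (mode bin centre %.2f A)\n",
            d_hot$summary["mean"], h$mids[h$mode_bin]))
cat(sprintf("Ligand 4.0 A shell:    %d residues (%s)\n", nrow(ct),
            paste(sprintf("%s%d:%s", ct$resname, ct$resid, ct$class),
                  collapse = ", ")))
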