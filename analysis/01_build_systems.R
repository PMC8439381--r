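#!/usr/bin/env Rscript
# Build the four synthetic study systems and write them in the on-disk
# formats the pipeline consumes (multi-model PDB, DCD, parameter table).
#
# The four systems are toy analogues of the four binding states of a
# receptor: an apo-like form (no planted interaction), two singly-bound
# forms with intermediate planted interaction strength, and the fully
# engaged form with the strong planted hot spot. Interaction strength is
# controlled through the planted hot-spot charge; everything else is
# identical, so downstream contrasts isolate that one difference.

suppressMessages(library(mdensemble))

out <- "results/analysis/systems"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

systems <- list(
  A_apo          = list(q = 0.0,  seed = 101),
  B_agonist      = list(q = -0.45, seed = 102),
  C_coactivator  = list(q = -0.45, seed = 103),
  D_both         = list(q = -0.8, seed = 104))

for (nm in names(systems)) {
  s <- systems[[nm]]
  tc <- toy_complex(n_frames = 20, seed = s$seed, hotspot_charge = s$q)
  write_structure(tc$topology, subset_frames(tc$ensemble, 1),
                  file.path(out, paste0(nm, ".pdb")))
  write_trajectory(tc$ensemble, file.path(out, paste0(nm, ".dcd")))
  write_parameters(tc$topology, file.path(out, paste0(nm, ".params")))
  cat(sprintf("%-14s hot-spot charge %+.2f e, %d frames, %d atoms\n",
              nm, s$q, n_frames(tc$ensemble), n_atoms(tc$topology)))
}
cat("wrote PDB/DCD/parameter files under", out, "\n")
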