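ion_top <- function(q = 1, gb_radius = 2.09, n = 1L) {
  atoms <- data.frame(serial = seq_len(n), name = "IP", element = "NA",
                      resname = "ION", resid = seq_len(n), chain = "A",
                      charge = rep(q, n), eps = 0.1, rmin_half = 1.8,
                      gb_radius = gb_radius, gb_screen = 0.8)
  topology(atoms)
}

test_that("Coulomb and Lennard-Jones closed forms", {
  t2 <- ion_top(n = 2L)
  t2$atoms$charge <- c(1, -1)
  fr <- rbind(c(0, 0, 0), c(3.320637, 0, 0))
  e <- mm_energy(fr, t2, "all")
  expect_equal(unname(e["E_ele"]), -100, tolerance = 1e-9)
  t2$atoms$charge <- c(0, 0)
  t2$atoms$eps <- 0.25; t2$atoms$rmin_half <- 1.6
  e2 <- mm_energy(rbind(c(0, 0, 0), c(3.2, 0, 0)), t2, "all")
  expect_equal(unname(e2["E_vdw"]), -0.25, tolerance = 1e-12)
})

test_that("nonbonded energies match a brute-force double loop with exclusions", {
  sys <- random_param_system(20, seed = 31)
  e <- mm_energy(sys$frame, sys$topology, "all")
  b <- brute_nonbonded(sys$frame, sys$topology)
  expect_equal(unname(e["E_ele"]), unname(b["E_ele"]), tolerance = 1e-9)
  expect_equal(unname(e["E_vdw"]), unname(b["E_vdw"]), tolerance = 1e-9)
  # pair symmetry / rigid invariance
  th <- 0.6
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fr2 <- sys$frame %*% R + matrix(c(3, 4, 5), 20, 3, byrow = TRUE)
  e2 <- mm_energy(fr2, sys$topology, "all")
  expect_equal(e2, e, tolerance = 1e-9)
  bad <- sys$topology
  bad$atoms$charge[3] <- NA
  expect_error(mm_energy(sys$frame, bad, "all"), "missing parameters")
})

test_that("Born ion and distant-ion limits of the GB energy", {
  ion <- ion_top()
  expect_equal(born_radii(matrix(0, 1, 3), ion), 2.0, tolerance = 1e-12)
  g1 <- gb_polar(matrix(0, 1, 3), ion)
  expect_equal(g1, -0.5 * 332.0637 * (1 - 1 / 80) / 2, tolerance = 1e-6)
  expect_equal(round(g1, 2), -81.98)
  # widely separated ions: Born sum plus the screened Coulomb cross term,
  # which itself vanishes as r grows
  t2 <- ion_top(n = 2L)
  for (r in c(500, 1e6)) {
    fr <- rbind(c(0, 0, 0), c(r, 0, 0))
    cross <- -332.0637 * (1 - 1 / 80) / r
    expect_equal(gb_polar(fr, t2), 2 * g1 + cross, tolerance = 0.01)
  }
  bad <- ion_top(gb_radius = 0.05)
  expect_error(born_radii(matrix(0, 1, 3), bad), "radii")
})

test_that("GB matches an independent OBC-II recomputation on a random system", {
  sys <- random_param_system(10, seed = 32, bonded_chain = FALSE)
  R_pkg <- born_radii(sys$frame, sys$topology, "all")
  oracle <- brute_gb(sys$frame, sys$topology)
  expect_equal(R_pkg, oracle$radii, tolerance = 1e-9)
  expect_equal(gb_polar(sys$frame, sys$topology, "all"), oracle$G_GB,
               tolerance = 1e-9)
  # |G_GB| shrinks monotonically as the solvent dielectric approaches
  # the solute's
  gs <- vapply(c(80, 20, 4, 2, 1.2), function(eo) {
    abs(gb_polar(sys$frame, sys$topology, "all", eps_out = eo))
  }, numeric(1))
  expect_true(all(diff(gs) < 0))
})

test_that("nonpolar solvation is gamma * SASA with its limits", {
  one <- topology(data.frame(serial = 1, name = "C", element = "C",
                             resname = "LIG", resid = 1, chain = "A",
                             vdw_radius = 1.7))
  g <- nonpolar_solvation(matrix(0, 1, 3), one, "all")
  expect_equal(g, 0.0072 * 4 * pi * 3.1^2, tolerance = 0.01 * g)
  expect_identical(nonpolar_solvation(matrix(0, 1, 3), one, "all",
                                      gamma = 0), 0)
  # a buried atom contributes nothing
  shell_n <- 26
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  atoms <- data.frame(serial = seq_len(nrow(dirs) + 1), name = "C",
                      element = "C", resname = "LIG",
                      resid = seq_len(nrow(dirs) + 1), chain = "A",
                      vdw_radius = 1.9)
  buried <- topology(atoms)
  fr <- rbind(c(0, 0, 0), dirs * 2.2)
  sa <- sasa(fr, buried, "all", n_sphere_points = 480)
  expect_equal(sa$per_atom[1], 0)
})

test_that("single-trajectory binding energy: identities and oracle", {
  tc <- toy_complex(n_frames = 6, seed = 3)
  top <- tc$topology
  allsel <- seq_len(n_atoms(top))
  br <- binding_free_energy(tc$ensemble, top, allsel, tc$receptor_sel,
                            tc$ligand_sel, n_sphere_points = 120)
  pf <- br$per_frame
  # internal terms cancel on every frame; gas/solv bookkeeping holds
  expect_true(all(pf$E_int == 0))
  expect_equal(pf$G_gas, pf$E_int + pf$E_ele + pf$E_vdw, tolerance = 1e-9)
  expect_equal(pf$G_solv, pf$G_GB + pf$G_np, tolerance = 1e-9)
  expect_equal(pf$G_total, pf$G_gas + pf$G_solv, tolerance = 1e-9)
  # per-frame recomputation from the exported species energies
  for (f in c(1L, 4L)) {
    fr <- frame_coords(tc$ensemble, f)
    g_of <- function(sel) {
      mm <- mm_energy(fr, top, sel)
      sum(mm) + gb_polar(fr, top, sel) +
        nonpolar_solvation(fr, top, sel, n_sphere_points = 120)
    }
    dg <- g_of(allsel) - g_of(tc$receptor_sel) - g_of(tc$ligand_sel)
    expect_equal(pf$G_total[f], dg, tolerance = 1e-9)
  }
  # SEM is SD over sqrt(n)
  expect_equal(br$summary$sem, br$summary$sd / sqrt(6), tolerance = 1e-12)
  # selection validation
  expect_error(binding_free_energy(tc$ensemble, top, allsel, allsel,
                                   tc$ligand_sel, n_sphere_points = 60),
               "overlap")
  expect_error(binding_free_energy(tc$ensemble, top, allsel,
                                   tc$receptor_sel[-1], tc$ligand_sel,
                                   n_sphere_points = 60),
               "cover")
})

test_that("non-interacting rigid partners bind with ~zero energy", {
  tc <- toy_complex(n_frames = 2, seed = 5, charge_scale = 0, vibration = 0)
  top <- tc$topology
  # push the ligand 80 A away: no vdW, no charges, no SASA change
  ens <- tc$ensemble
  ens$coords[, tc$ligand_sel, 1] <- ens$coords[, tc$ligand_sel, 1] + 80
  br <- binding_free_energy(ens, top, seq_len(n_atoms(top)), tc$receptor_sel,
                            tc$ligand_sel, n_sphere_points = 240)
  g <- br$summary$mean[br$summary$component == "G_total"]
  expect_lt(abs(g), 1e-3)
})

test_that("per-residue ledger conserves every component and flags hot spots", {
  tc <- toy_complex(n_frames = 4, seed = 3)
  top <- tc$topology
  allsel <- seq_len(n_atoms(top))
  rl <- per_residue_decomposition(tc$ensemble, top, allsel, tc$receptor_sel,
                                  tc$ligand_sel, n_sphere_points = 120)
  br <- binding_free_energy(tc$ensemble, top, allsel, tc$receptor_sel,
                            tc$ligand_sel, n_sphere_points = 120)
  sm <- function(cmp) br$summary$mean[br$summary$component == cmp]
  expect_equal(sum(rl$total), sm("G_total"), tolerance = 1e-6)
  expect_equal(sum(rl$vdw), sm("E_vdw"), tolerance = 1e-6)
  expect_equal(sum(rl$ele), sm("E_ele"), tolerance = 1e-6)
  expect_equal(sum(rl$gb), sm("G_GB"), tolerance = 1e-6)
  expect_equal(sum(rl$np), sm("G_np"), tolerance = 1e-6)
  expect_identical(rl$hot_spot, rl$total <= -0.5)
  # planted hot spot ranks first among receptor residues
  rec_rows <- rl[rl$chain == "R", ]
  expect_equal(rec_rows$resid[which.min(rec_rows$total)],
               tc$truth$hotspot_resid)
})

test_that("a charge-free, contact-free residue contributes nothing", {
  tc <- toy_complex(n_frames = 2, seed = 6, charge_scale = 0,
                    n_receptor_res = 6, vibration = 0)
  top <- tc$topology
  # move residue 6 far from everything (> any LJ or SASA reach)
  idx6 <- which(top$atoms$resid == 6 & top$atoms$chain == "R")
  ens <- tc$ensemble
  ens$coords[, idx6, 2] <- ens$coords[, idx6, 2] + 200
  rl <- per_residue_decomposition(ens, top, seq_len(n_atoms(top)),
                                  tc$receptor_sel, tc$ligand_sel,
                                  n_sphere_points = 60)
  r6 <- rl[rl$chain == "R" & rl$resid == 6, ]
  expect_lt(abs(r6$total), 1e-9)
})

test_that("alanine mutation follows template arithmetic and edge rules", {
  tc <- toy_complex(seed = 1)
  top <- tc$topology
  mut <- mutate_to_alanine(top, 2, chain = "R")
  # SER side chain beyond CB (OG) removed, one HB added: same atom count
  expect_equal(n_atoms(mut$topology), n_atoms(top))
  expect_true(is_parameterized(mut$topology))
  expect_false("OG" %in%
                 mut$topology$atoms$name[mut$topology$atoms$resid == 2 &
                                           mut$topology$atoms$chain == "R"])
  # a leucine-like residue loses net atoms
  atoms <- data.frame(
    serial = 1:6, name = c("N", "CA", "C", "CB", "CG", "CD1"),
    element = c("N", "C", "C", "C", "C", "C"), resname = "LEU",
    resid = 1L, chain = "A", charge = 0, eps = 0.1, rmin_half = 1.9,
    gb_radius = 1.7, gb_screen = 0.72)
  leu <- topology(atoms, bonds = cbind(1:5, 2:6))
  mleu <- mutate_to_alanine(leu, 1)
  expect_equal(n_atoms(mleu$topology), 6L - 2L + 1L)  # drop CG, CD1; add HB
  gly <- topology(transform(atoms[1:3, ], resname = "GLY"))
  expect_error(mutate_to_alanine(gly, 1), "unsupported")
  ala <- topology(transform(atoms[1:4, ], resname = "ALA"))
  expect_warning(m0 <- mutate_to_alanine(ala, 1), "identity")
  expect_equal(m0$charge_change, 0)
})

test_that("alanine scan: identity, sign, ranking, and manual-mutant oracle", {
  tc <- toy_complex(n_frames = 4, seed = 3)
  top <- tc$topology
  allsel <- seq_len(n_atoms(top))
  scan <- alanine_scan(tc$ensemble, top, allsel, tc$receptor_sel,
                       tc$ligand_sel, residues = 1:4,
                       n_sphere_points = 120)
  hs <- tc$truth$hotspot_resid
  expect_equal(scan$resid[which.max(abs(scan$ddG))], hs)
  # favourable wild-type contribution gives negative ddG
  expect_lt(scan$ddG[scan$resid == hs], 0)
  expect_true(scan$flagged[scan$resid == hs])
  expect_true(all(!scan$flagged[scan$resid != hs]))
  # oracle: rebuild the hot-spot mutant by hand and recompute both ends
  mut <- mutate_to_alanine(top, hs, chain = "R")
  mens <- mutant_ensemble(tc$ensemble, mut)
  old_to_new <- match(seq_len(n_atoms(top)), mut$map)
  rec_m <- sort(c(old_to_new[tc$receptor_sel][!is.na(old_to_new[tc$receptor_sel])],
                  mut$hb_after))
  lig_m <- old_to_new[tc$ligand_sel]
  br_wt <- binding_free_energy(tc$ensemble, top, allsel, tc$receptor_sel,
                               tc$ligand_sel, n_sphere_points = 120)
  br_mut <- binding_free_energy(mens, mut$topology, sort(c(rec_m, lig_m)),
                                rec_m, lig_m, n_sphere_points = 120)
  ddg_manual <- br_wt$summary$mean[br_wt$summary$component == "G_total"] -
    br_mut$summary$mean[br_mut$summary$component == "G_total"]
  expect_equal(scan$ddG[scan$resid == hs], ddg_manual, tolerance = 1e-9)
  # self-mutation is exactly zero
  tc0 <- toy_complex(seed = 2)
  ala_top <- tc0$topology
  ala_top$atoms$resname[ala_top$atoms$resid == 3 &
                          ala_top$atoms$chain == "R"] <- "ALA"
  scan0 <- alanine_scan(tc0$ensemble, ala_top, seq_len(n_atoms(ala_top)),
                        tc0$receptor_sel, tc0$ligand_sel, residues = 3,
                        n_sphere_points = 60)
  expect_equal(scan0$ddG, 0)
})
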