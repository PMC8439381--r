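#' @title Single-trajectory MM-GB(SA) energetics
#' @description Gas-phase molecular mechanics energies, OBC-II Generalized
#'   Born polar solvation, and surface-area nonpolar solvation, combined
#'   into single-trajectory binding free energies with per-residue
#'   decomposition and computational alanine scanning. Conventions:
#'   kcal/mol, Angstrom, electron charges; Coulomb constant 332.0637
#'   kcal A/(mol e^2); AMBER combining rules (Rij = Rmin/2_i + Rmin/2_j,
#'   eps_ij = sqrt(eps_i eps_j)); 1-4 pairs scaled by 1/1.2 (ele) and 1/2
#'   (vdW); no nonbonded cutoff (all pairs), the convention for end-state
#'   post-processing.
#' @name mdensemble-energetics
NULL

# symmetric pair scale matrices for atoms idx: 0 for 1-2/1-3, 1-4 scaled,
# else 1; diagonal 0
.pair_scales <- function(top, idx, scee = 1 / 1.2, scnb = 0.5) {
  n <- length(idx)
  S_ele <- matrix(1, n, n); S_vdw <- matrix(1, n, n)
  diag(S_ele) <- 0; diag(S_vdw) <- 0
  ex <- top$exclusions
  if (!is.null(ex)) {
    pos <- match(seq_len(n_atoms(top)), idx)  # global -> local
    put <- function(pairs, val_e, val_v) {
      if (!nrow(pairs)) return()
      i <- pos[pairs[, 1]]; j <- pos[pairs[, 2]]
      ok <- !is.na(i) & !is.na(j)
      if (any(ok)) {
        S_ele[cbind(i[ok], j[ok])] <<- val_e; S_ele[cbind(j[ok], i[ok])] <<- val_e
        S_vdw[cbind(i[ok], j[ok])] <<- val_v; S_vdw[cbind(j[ok], i[ok])] <<- val_v
      }
    }
    put(ex$ex12, 0, 0); put(ex$ex13, 0, 0); put(ex$ex14, scee, scnb)
  }
  list(ele = S_ele, vdw = S_vdw)
}

.dist_matrix <- function(x) {
  d <- as.matrix(stats::dist(x))
  d
}

#' Gas-phase molecular-mechanics energy of a selection
#'
#' `E_gas = E_int + E_ele + E_vdw` over the selected atoms:
#' internal (bond/angle/torsion) terms fully inside the selection,
#' Coulomb `k_e q_i q_j / (eps_in r_ij)` and 12-6 Lennard-Jones
#' `eps_ij[(R_ij/r)^12 - 2 (R_ij/r)^6]` over non-excluded pairs with
#' AMBER 1-4 scaling, no cutoff.
#'
#' @param frame coordinates (n_atoms x 3).
#' @param top parameterized `topology` (with exclusions built).
#' @param sel atom selection.
#' @param eps_in solute dielectric.
#' @return named numeric: `E_int`, `E_vdw`, `E_ele` (kcal/mol).
#' @export
mm_energy <- function(frame, top, sel = "all", eps_in = 1) {
  idx <- .as_indices(top, sel)
  a <- top$atoms
  if (anyNA(a$charge[idx]) || anyNA(a$eps[idx]) || anyNA(a$rmin_half[idx])) {
    bad <- idx[is.na(a$charge[idx]) | is.na(a$eps[idx]) | is.na(a$rmin_half[idx])]
    stop("missing parameters for atoms: ",
         paste(utils::head(.atom_label(top, bad), 10), collapse = ", "))
  }
  x <- frame[idx, , drop = FALSE]
  n <- length(idx)
  E_ele <- 0; E_vdw <- 0
  if (n > 1L) {
    d <- .dist_matrix(x)
    sc <- .pair_scales(top, idx)
    q <- a$charge[idx]
    qq <- outer(q, q)
    dd <- d; diag(dd) <- Inf
    E_ele <- KE_COULOMB / eps_in * sum(sc$ele * qq / dd) / 2
    rij <- outer(a$rmin_half[idx], a$rmin_half[idx], "+")
    eij <- sqrt(outer(a$eps[idx], a$eps[idx]))
    sr6 <- (rij / dd)^6
    E_vdw <- sum(sc$vdw * eij * (sr6^2 - 2 * sr6)) / 2
  }
  E_int <- .internal_energy(frame, top, idx)
  c(E_int = E_int, E_vdw = E_vdw, E_ele = E_ele)
}

# bond/angle/torsion energy for terms whose atoms all lie in idx
.internal_energy <- function(frame, top, idx) {
  inset <- rep(FALSE, n_atoms(top)); inset[idx] <- TRUE
  e <- 0
  bp <- top$bond_params
  if (!is.null(bp) && nrow(bp)) {
    keep <- inset[bp$i] & inset[bp$j]
    if (any(keep)) {
      r <- sqrt(rowSums((frame[bp$i[keep], , drop = FALSE] -
                           frame[bp$j[keep], , drop = FALSE])^2))
      e <- e + sum(bp$k_b[keep] * (r - bp$r0[keep])^2)
    }
  }
  ap <- top$angles
  if (!is.null(ap) && nrow(ap)) {
    keep <- inset[ap$i] & inset[ap$j] & inset[ap$k]
    for (r in which(keep)) {
      th <- .angle_deg(frame[ap$i[r], ], frame[ap$j[r], ], frame[ap$k[r], ])
      e <- e + ap$k_theta[r] * ((th - ap$theta0[r]) * pi / 180)^2
    }
  }
  tp <- top$torsions
  if (!is.null(tp) && nrow(tp)) {
    keep <- inset[tp$i] & inset[tp$j] & inset[tp$k] & inset[tp$l]
    for (r in which(keep)) {
      ph <- .torsion_deg(frame[tp$i[r], ], frame[tp$j[r], ],
                         frame[tp$k[r], ], frame[tp$l[r], ])
      e <- e + tp$pk[r] * (1 + cos((tp$per[r] * ph - tp$phase[r]) * pi / 180))
    }
  }
  e
}

#' Effective Born radii (OBC-II pairwise descreening)
#'
#' Hawkins-Cramer-Truhlar pairwise descreening integrals with the
#' Onufriev-Bashford-Case II rescaling (alpha = 1.0, beta = 0.8,
#' gamma = 4.85; intrinsic-radius offset 0.09 A). An isolated atom's
#' effective radius equals its offset intrinsic radius.
#'
#' @param frame coordinates (n_atoms x 3).
#' @param top parameterized `topology` (gb_radius, gb_screen).
#' @param sel atom selection (the species whose radii are computed; only
#'   these atoms descreen each other).
#' @param offset intrinsic-radius offset, A.
#' @return numeric vector of effective radii (A) in selection order.
#' @export
born_radii <- function(frame, top, sel = "all", offset = 0.09) {
  idx <- .as_indices(top, sel)
  rho <- top$atoms$gb_radius[idx]
  scr <- top$atoms$gb_screen[idx]
  if (anyNA(rho) || anyNA(scr)) stop("missing gb_radius/gb_screen parameters")
  if (any(rho <= offset)) stop("nonpositive offset GB radii")
  n <- length(idx)
  rhot <- rho - offset
  x <- frame[idx, , drop = FALSE]
  alpha <- 1.0; beta <- 0.8; gamma <- 4.85
  R <- numeric(n)
  d <- if (n > 1L) .dist_matrix(x) else matrix(0, 1, 1)
  for (i in seq_len(n)) {
    I <- 0
    if (n > 1L) for (j in seq_len(n)) {
      if (j == i) next
      r <- d[i, j]
      s <- scr[j] * rhot[j]
      U <- r + s
      if (rhot[i] >= U) next          # j entirely inside i's sphere
      L <- max(rhot[i], abs(r - s))
      term <- 0.5 * (1 / L - 1 / U +
                       0.25 * (r - s^2 / r) * (1 / U^2 - 1 / L^2) +
                       0.5 * log(L / U) / r)
      if (s >= r + rhot[i]) term <- term + (1 / rhot[i] - 1 / L)  # i engulfed
      I <- I + term
    }
    psi <- I * rhot[i]
    R[i] <- 1 / (1 / rhot[i] -
                   tanh(alpha * psi - beta * psi^2 + gamma * psi^3) / rho[i])
  }
  R
}

#' Generalized Born polar solvation energy
#'
#' `G_GB = -1/2 k_e (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))` and effective Born
#' radii from [born_radii()] (the double sum includes self terms i = j,
#' where f_GB = R_i).
#'
#' @inheritParams born_radii
#' @param eps_in,eps_out solute and solvent dielectric constants.
#' @return `G_GB` in kcal/mol.
#' @export
gb_polar <- function(frame, top, sel = "all", eps_in = 1, eps_out = 80,
                     offset = 0.09) {
  idx <- .as_indices(top, sel)
  q <- top$atoms$charge[idx]
  if (anyNA(q)) stop("missing charges")
  R <- born_radii(frame, top, idx, offset = offset)
  n <- length(idx)
  x <- frame[idx, , drop = FALSE]
  d2 <- if (n > 1L) .dist_matrix(x)^2 else matrix(0, 1, 1)
  RR <- outer(R, R)
  fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  pref <- -0.5 * KE_COULOMB * (1 / eps_in - 1 / eps_out)
  pref * sum(outer(q, q) / fgb)
}

#' Nonpolar solvation energy (gamma * SASA)
#'
#' @inheritParams sasa
#' @param gamma surface-tension coefficient, kcal/(mol A^2).
#' @return `G_np` in kcal/mol.
#' @export
nonpolar_solvation <- function(frame, top, sel = "all", gamma = 0.0072,
                               probe_radius = 1.4, n_sphere_points = 960L) {
  if (gamma == 0) return(0)
  gamma * sasa(frame, top, sel, probe_radius, n_sphere_points)$total
}

# all energy components of one species on one frame
.species_energy <- function(frame, top, idx, eps_in, eps_out, gamma,
                            probe_radius, n_sphere_points) {
  mm <- mm_energy(frame, top, idx, eps_in = eps_in)
  ggb <- gb_polar(frame, top, idx, eps_in = eps_in, eps_out = eps_out)
  gnp <- nonpolar_solvation(frame, top, idx, gamma = gamma,
                            probe_radius = probe_radius,
                            n_sphere_points = n_sphere_points)
  c(mm, G_GB = ggb, G_np = gnp,
    G_gas = unname(mm["E_int"] + mm["E_ele"] + mm["E_vdw"]),
    G_solv = ggb + gnp,
    G_total = unname(mm["E_int"] + mm["E_ele"] + mm["E_vdw"]) + ggb + gnp)
}

#' Single-trajectory MM-GB(SA) binding free energy
#'
#' `dG_bind = G_complex - (G_receptor + G_ligand)` with
#' `G = E_gas + G_solv` (the entropy term is set to zero, matching what
#' end-state tables conventionally report) evaluated for the three species
#' on the *same* complex coordinates of every frame (single-trajectory
#' scheme). Internal energies cancel exactly: `dE_int = 0` on every frame,
#' which is asserted. Component means are reported with SD and
#' `SEM = SD / sqrt(n_frames)`.
#'
#' Ternary systems are handled by bookkeeping: e.g. ligand = agonist with
#' receptor = protein + co-activator peptide, or ligand = co-activator with
#' receptor = protein + agonist.
#'
#' @param ens an `ensemble` (complex coordinates).
#' @param top parameterized `topology`.
#' @param complex_sel,receptor_sel,ligand_sel selections; receptor and
#'   ligand must be disjoint and their union must equal the complex.
#' @param eps_in,eps_out dielectric constants.
#' @param gamma,probe_radius,n_sphere_points nonpolar term settings.
#' @return object of class `binding_result`: `per_frame` (data.frame of
#'   delta components per frame), `summary` (component, mean, sd, sem),
#'   `species_means`, and the settings used.
#' @export
binding_free_energy <- function(ens, top, complex_sel, receptor_sel,
                                ligand_sel, eps_in = 1, eps_out = 80,
                                gamma = 0.0072, probe_radius = 1.4,
                                n_sphere_points = 960L) {
  com <- .as_indices(top, complex_sel, what = "complex_sel")
  rec <- .as_indices(top, receptor_sel, what = "receptor_sel")
  lig <- .as_indices(top, ligand_sel, what = "ligand_sel")
  if (length(intersect(rec, lig))) {
    stop("selection error: receptor and ligand selections overlap")
  }
  if (!setequal(union(rec, lig), com)) {
    stop("selection error: receptor + ligand must exactly cover the complex")
  }
  if (!is_parameterized(top)) stop("topology is not parameterized")
  nfr <- n_frames(ens)
  comp_names <- c("E_int", "E_vdw", "E_ele", "G_GB", "G_np", "G_gas",
                  "G_solv", "G_total")
  per_frame <- matrix(NA_real_, nfr, length(comp_names),
                      dimnames = list(NULL, comp_names))
  sp_mean <- matrix(0, 3, length(comp_names),
                    dimnames = list(c("complex", "receptor", "ligand"),
                                    comp_names))
  for (f in seq_len(nfr)) {
    fr <- frame_coords(ens, f)
    ec <- .species_energy(fr, top, com, eps_in, eps_out, gamma,
                          probe_radius, n_sphere_points)
    er <- .species_energy(fr, top, rec, eps_in, eps_out, gamma,
                          probe_radius, n_sphere_points)
    el <- .species_energy(fr, top, lig, eps_in, eps_out, gamma,
                          probe_radius, n_sphere_points)
    d <- ec - er - el
    if (abs(d["E_int"]) > 1e-6) {
      stop(sprintf("internal inconsistency: dE_int = %.3g on frame %d (must be 0 in single-trajectory mode)",
                   d["E_int"], f))
    }
    d["E_int"] <- 0
    per_frame[f, ] <- d[comp_names]
    sp_mean <- sp_mean + rbind(ec, er, el)[, comp_names] / nfr
  }
  sm <- data.frame(
    component = comp_names,
    mean = colMeans(per_frame),
    sd = apply(per_frame, 2, stats::sd),
    row.names = NULL)
  sm$sem <- sm$sd / sqrt(nfr)
  structure(list(per_frame = as.data.frame(per_frame), summary = sm,
                 species_means = sp_mean,
                 n_frames = nfr,
                 settings = list(eps_in = eps_in, eps_out = eps_out,
                                 gamma = gamma, probe_radius = probe_radius,
                                 n_sphere_points = n_sphere_points,
                                 entropy = "neglected (-TS = 0)"),
                 selections = list(complex = com, receptor = rec,
                                   ligand = lig)),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  g <- x$summary[x$summary$component == "G_total", ]
  cat(sprintf("<binding_result> dG_bind = %.3f +/- %.3f (SEM %.3f) kcal/mol over %d frames\n",
              g$mean, g$sd, g$sem, x$n_frames))
  invisible(x)
}

# per-residue energy vectors for one species on one frame: list of named
# numeric vectors (keyed "chain|resid") for vdw, ele, gb, np
.residue_energy <- function(frame, top, idx, eps_in, eps_out, gamma,
                            probe_radius, n_sphere_points) {
  a <- top$atoms
  rk <- paste(a$chain[idx], a$resid[idx], sep = "|")
  keys <- unique(rk)
  acc <- function() stats::setNames(numeric(length(keys)), keys)
  out <- list(vdw = acc(), ele = acc(), gb = acc(), np = acc())
  n <- length(idx)
  x <- frame[idx, , drop = FALSE]
  if (n > 1L) {
    d <- .dist_matrix(x); diag(d) <- Inf
    sc <- .pair_scales(top, idx)
    q <- a$charge[idx]
    ele_m <- KE_COULOMB / eps_in * sc$ele * outer(q, q) / d
    rij <- outer(a$rmin_half[idx], a$rmin_half[idx], "+")
    eij <- sqrt(outer(a$eps[idx], a$eps[idx]))
    sr6 <- (rij / d)^6
    vdw_m <- sc$vdw * eij * (sr6^2 - 2 * sr6)
    # pairwise halving: half of each pair term to each atom's residue
    half_to_res <- function(M) {
      per_atom <- rowSums(M) / 2
      v <- acc()
      agg <- tapply(per_atom, rk, sum)
      v[names(agg)] <- agg
      v
    }
    out$ele <- half_to_res(ele_m)
    out$vdw <- half_to_res(vdw_m)
  }
  # GB: pair matrix including self terms on the diagonal
  R <- born_radii(frame, top, idx)
  d2 <- if (n > 1L) .dist_matrix(x)^2 else matrix(0, 1, 1)
  RR <- outer(R, R)
  fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  q <- a$charge[idx]
  gb_m <- -0.5 * KE_COULOMB * (1 / eps_in - 1 / eps_out) * outer(q, q) / fgb
  # row sums of the ordered-pair matrix: each unordered pair is split
  # half-and-half between the two atoms' residues, self terms go whole
  per_atom_gb <- rowSums(gb_m)
  agg <- tapply(per_atom_gb, rk, sum)
  out$gb[names(agg)] <- agg
  if (gamma != 0) {
    sa <- sasa(frame, top, idx, probe_radius, n_sphere_points)
    agg <- tapply(gamma * sa$per_atom, rk, sum)
    out$np[names(agg)] <- agg
  }
  out
}

#' Per-residue decomposition of the binding free energy
#'
#' Pairwise energies are split half-and-half between the residues of the
#' two atoms; GB self terms and per-atom SASA go to the owning residue.
#' The per-residue delta is complex minus receptor minus ligand, so the
#' ledger's totals sum exactly to `dG_bind` (internal terms cancel).
#' Residues at or below `hotspot_cutoff` kcal/mol total are flagged as
#' hot spots ("-0.5 kcal/mol or above" read as magnitude >= 0.5,
#' favourable).
#'
#' @inheritParams binding_free_energy
#' @param hotspot_cutoff flag residues with total <= this value (kcal/mol).
#' @return data.frame of class `residue_ledger`: chain, resid, resname,
#'   vdw, ele, gb, np, total (frame-averaged kcal/mol), hot_spot.
#' @export
per_residue_decomposition <- function(ens, top, complex_sel, receptor_sel,
                                      ligand_sel, eps_in = 1, eps_out = 80,
                                      gamma = 0.0072, probe_radius = 1.4,
                                      n_sphere_points = 960L,
                                      hotspot_cutoff = -0.5) {
  com <- .as_indices(top, complex_sel, what = "complex_sel")
  rec <- .as_indices(top, receptor_sel, what = "receptor_sel")
  lig <- .as_indices(top, ligand_sel, what = "ligand_sel")
  if (length(intersect(rec, lig)) || !setequal(union(rec, lig), com)) {
    stop("selection error: receptor/ligand must partition the complex")
  }
  a <- top$atoms
  keys <- unique(paste(a$chain[com], a$resid[com], sep = "|"))
  nfr <- n_frames(ens)
  comp <- c("vdw", "ele", "gb", "np")
  tot <- matrix(0, length(keys), length(comp),
                dimnames = list(keys, comp))
  for (f in seq_len(nfr)) {
    fr <- frame_coords(ens, f)
    ec <- .residue_energy(fr, top, com, eps_in, eps_out, gamma,
                          probe_radius, n_sphere_points)
    er <- .residue_energy(fr, top, rec, eps_in, eps_out, gamma,
                          probe_radius, n_sphere_points)
    el <- .residue_energy(fr, top, lig, eps_in, eps_out, gamma,
                          probe_radius, n_sphere_points)
    for (cc in comp) {
      dv <- stats::setNames(numeric(length(keys)), keys)
      dv[names(ec[[cc]])] <- ec[[cc]]
      dv[names(er[[cc]])] <- dv[names(er[[cc]])] - er[[cc]]
      dv[names(el[[cc]])] <- dv[names(el[[cc]])] - el[[cc]]
      tot[, cc] <- tot[, cc] + dv / nfr
    }
  }
  parts <- do.call(rbind, strsplit(keys, "\\|"))
  first_atom <- match(keys, paste(a$chain, a$resid, sep = "|"))
  out <- data.frame(chain = parts[, 1], resid = as.integer(parts[, 2]),
                    resname = a$resname[first_atom],
                    vdw = tot[, "vdw"], ele = tot[, "ele"],
                    gb = tot[, "gb"], np = tot[, "np"],
                    total = rowSums(tot), row.names = NULL)
  out$hot_spot <- out$total <= hotspot_cutoff
  out <- out[order(out$total), ]
  rownames(out) <- NULL
  attr(out, "hotspot_cutoff") <- hotspot_cutoff
  class(out) <- c("residue_ledger", "data.frame")
  out
}

# alanine template: CB retyped as a methyl carbon absorbing two implicit
# hydrogens' charge, one explicit HB along the former CG direction
.ALA_TEMPLATE <- list(
  cb = list(charge = -0.1825 + 2 * 0.0603, eps = 0.1094, rmin_half = 1.9080,
            gb_radius = 1.70, gb_screen = 0.72),
  hb = list(charge = 0.0603, eps = 0.0157, rmin_half = 1.4870,
            gb_radius = 1.30, gb_screen = 0.85))

.BACKBONE_NAMES <- c("N", "H", "HN", "CA", "HA", "C", "O", "OXT", "H1",
                     "H2", "H3")

#' Mutate one residue to alanine
#'
#' Side-chain atoms beyond Cbeta are deleted; Cbeta is retyped as the
#' alanine methyl carbon (template charges absorb the implicit methyl
#' hydrogens, one explicit Hbeta is added 1.09 A along the former Cgamma
#' direction); the backbone is untouched. Glycine and proline are refused;
#' mutating alanine itself is an identity with a warning. The net-charge
#' change is reported as an attribute.
#'
#' @param top parameterized `topology`.
#' @param resid residue number to mutate.
#' @param chain chain id (default: wherever the residue is found).
#' @param template parameter template for the new CB/HB atoms.
#' @return list of class `ala_mutation`: `topology` (mutant), `map`
#'   (original indices of retained atoms, in mutant order; the added HB has
#'   map NA), `hb_after` (mutant index of the added HB or NA), `cg_index`
#'   (original index of the former CG used to place HB), `charge_change`.
#' @export
mutate_to_alanine <- function(top, resid, chain = NULL,
                              template = .ALA_TEMPLATE) {
  a <- top$atoms
  rows <- which(a$resid == resid &
                  (if (is.null(chain)) TRUE else a$chain == chain))
  if (!length(rows)) stop("residue ", resid, " not found")
  rn <- toupper(a$resname[rows[1]])
  if (!(rn %in% .STANDARD_AA)) stop("unsupported mutation: ", rn, " is not a standard amino acid")
  if (rn %in% c("GLY", "PRO")) stop("unsupported mutation: ", rn, " has no mutatable side chain")
  if (rn == "ALA") {
    warning("mutating ALA to ALA: identity")
    return(structure(list(topology = top, map = seq_len(n_atoms(top)),
                          hb_after = NA_integer_, cg_index = NA_integer_,
                          charge_change = 0),
                     class = "ala_mutation"))
  }
  cb <- rows[a$name[rows] == "CB"]
  if (!length(cb)) stop("unsupported mutation: residue has no CB atom")
  cg <- rows[grepl("^[CONS]G", a$name[rows])][1]
  keep_res <- rows[a$name[rows] %in% c(.BACKBONE_NAMES, "CB")]
  drop <- setdiff(rows, keep_res)
  keep <- setdiff(seq_len(n_atoms(top)), drop)
  old_charge <- sum(a$charge[rows], na.rm = TRUE)
  na <- a[keep, , drop = FALSE]
  cb_new <- which(keep == cb)
  na$resname[na$resid == resid & na$chain == a$chain[rows[1]]] <- "ALA"
  for (fld in c("charge", "eps", "rmin_half", "gb_radius", "gb_screen")) {
    na[[fld]][cb_new] <- template$cb[[fld]]
  }
  na$element[cb_new] <- "C"
  # add HB atom after CB
  hb_row <- na[cb_new, , drop = FALSE]
  hb_row$name <- "HB"; hb_row$element <- "H"
  hb_row$serial <- max(na$serial) + 1L
  for (fld in c("charge", "eps", "rmin_half", "gb_radius", "gb_screen")) {
    hb_row[[fld]] <- template$hb[[fld]]
  }
  hb_row$vdw_radius <- vdw_radius_bondi("H")
  na2 <- rbind(na[seq_len(cb_new), , drop = FALSE], hb_row,
               if (cb_new < nrow(na)) na[(cb_new + 1L):nrow(na), , drop = FALSE])
  map <- c(keep[seq_len(cb_new)], NA_integer_,
           if (cb_new < length(keep)) keep[(cb_new + 1L):length(keep)])
  hb_after <- cb_new + 1L
  # remap bonds
  new_of_old <- match(seq_len(n_atoms(top)), map)
  bonds <- top$bonds
  if (!is.null(bonds) && nrow(bonds)) {
    bi <- new_of_old[bonds[, 1]]; bj <- new_of_old[bonds[, 2]]
    ok <- !is.na(bi) & !is.na(bj)
    bonds <- cbind(bi[ok], bj[ok])
  } else {
    bonds <- matrix(integer(0), ncol = 2)
  }
  bonds <- rbind(bonds, c(cb_new, hb_after))
  mut <- topology(na2, bonds = bonds, numbering_offset = top$numbering_offset)
  # carry bonded parameter tables, dropping terms touching deleted atoms
  remap_tbl <- function(tbl, cols) {
    if (is.null(tbl) || !nrow(tbl)) return(tbl)
    for (cc in cols) tbl[[cc]] <- new_of_old[tbl[[cc]]]
    tbl[stats::complete.cases(tbl[, cols, drop = FALSE]), , drop = FALSE]
  }
  mut$bond_params <- remap_tbl(top$bond_params, c("i", "j"))
  mut$angles <- remap_tbl(top$angles, c("i", "j", "k"))
  mut$torsions <- remap_tbl(top$torsions, c("i", "j", "k", "l"))
  new_charge <- sum(mut$atoms$charge[mut$atoms$resid == resid &
                                       mut$atoms$chain == a$chain[rows[1]]])
  structure(list(topology = mut, map = map, hb_after = hb_after,
                 cg_index = if (length(cg) && !is.na(cg)) cg else NA_integer_,
                 charge_change = new_charge - old_charge),
            class = "ala_mutation")
}

#' Build mutant coordinates for an alanine mutation
#'
#' Retained atoms keep their coordinates; the added Hbeta is placed 1.09 A
#' from Cbeta along the former Cgamma direction in every frame.
#'
#' @param ens original `ensemble`.
#' @param mut an `ala_mutation`.
#' @return mutant `ensemble`.
#' @export
mutant_ensemble <- function(ens, mut) {
  map <- mut$map
  nfr <- n_frames(ens)
  coords <- array(NA_real_, dim = c(nfr, length(map), 3))
  kept <- !is.na(map)
  for (f in seq_len(nfr)) {
    fr <- frame_coords(ens, f)
    coords[f, kept, ] <- fr[map[kept], ]
    if (any(!kept)) {
      hb <- which(!kept)
      cb <- hb - 1L  # HB inserted right after CB
      if (!is.na(mut$cg_index)) {
        dir <- .unit(fr[mut$cg_index, ] - fr[map[cb], ])
      } else {
        dir <- c(1, 0, 0)
      }
      coords[f, hb, ] <- fr[map[cb], ] + 1.09 * dir
    }
  }
  ensemble(coords, frame_times = ens$frame_times,
           provenance = c(ens$provenance, list(mutation = "ALA")))
}

#' Computational alanine scanning
#'
#' For each residue: mutate to alanine, rebuild coordinates on the same
#' frames (no re-simulation), recompute the single-trajectory binding free
#' energy, and report `ddG = dG[wild type] - dG[mutant]`. Negative ddG
#' indicates a favourable wild-type contribution. Residues with
#' `|ddG| > flag_cutoff` are flagged.
#'
#' @inheritParams binding_free_energy
#' @param residues residue numbers to scan.
#' @param flag_cutoff reading cutoff for the flag column, kcal/mol.
#' @return data.frame: resid, resname, dG_wt, dG_mut, ddG, flagged.
#' @export
alanine_scan <- function(ens, top, complex_sel, receptor_sel, ligand_sel,
                         residues, eps_in = 1, eps_out = 80, gamma = 0.0072,
                         probe_radius = 1.4, n_sphere_points = 960L,
                         flag_cutoff = 1.0) {
  wt <- binding_free_energy(ens, top, complex_sel, receptor_sel, ligand_sel,
                            eps_in, eps_out, gamma, probe_radius,
                            n_sphere_points)
  dg_wt <- wt$summary$mean[wt$summary$component == "G_total"]
  rec <- wt$selections$receptor; lig <- wt$selections$ligand
  rows <- lapply(residues, function(rid) {
    res_rows <- which(top$atoms$resid == rid &
                        toupper(top$atoms$resname) %in% .STANDARD_AA)
    if (!length(res_rows)) stop("residue ", rid, " is not a standard amino acid")
    ch <- unique(top$atoms$chain[res_rows])
    if (length(ch) > 1L) stop("residue number ", rid, " is ambiguous across chains")
    rn <- toupper(top$atoms$resname[res_rows[1]])
    if (rn == "ALA") {
      return(data.frame(resid = rid, resname = rn, dG_wt = dg_wt,
                        dG_mut = dg_wt, ddG = 0, flagged = FALSE))
    }
    mut <- mutate_to_alanine(top, rid, chain = ch)
    mens <- mutant_ensemble(ens, mut)
    # remap selections: retained atoms keep membership; added HB follows CB
    old_to_new <- match(seq_len(n_atoms(top)), mut$map)
    map_sel <- function(sel_old) {
      s <- old_to_new[sel_old]
      s <- s[!is.na(s)]
      cb_old <- mut$map[mut$hb_after - 1L]
      if (cb_old %in% sel_old) s <- sort(c(s, mut$hb_after))
      s
    }
    rec_m <- map_sel(rec); lig_m <- map_sel(lig)
    br <- binding_free_energy(mens, mut$topology,
                              complex_sel = sort(c(rec_m, lig_m)),
                              receptor_sel = rec_m, ligand_sel = lig_m,
                              eps_in, eps_out, gamma, probe_radius,
                              n_sphere_points)
    dg_mut <- br$summary$mean[br$summary$component == "G_total"]
    ddg <- dg_wt - dg_mut
    data.frame(resid = rid, resname = rn, dG_wt = dg_wt, dG_mut = dg_mut,
               ddG = ddg, flagged = abs(ddg) > flag_cutoff)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a binding result as a TSV component table
#' @param br a `binding_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_binding_result <- function(br, path) {
  utils::write.table(br$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
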