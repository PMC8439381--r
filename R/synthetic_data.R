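#' @title Synthetic ensembles with known ground truth
#' @description Seeded, pure-function generators used to validate every
#'   analysis stage: Gaussian fluctuation ensembles with prescribed
#'   covariance, two-basin mixtures with prescribed populations, scripted
#'   donor-H-acceptor geometries with exact target occupancies, small
#'   parameterized complex/receptor/ligand systems with closed-form
#'   reference energies, and ideal helix/hairpin backbones. Each generator
#'   attaches a `manifest` attribute (its full spec) to the ensemble, and
#'   identical specs give bit-identical output.
#' @name mdensemble-synthetic
NULL

# run expr with a private RNG stream; global .Random.seed is untouched
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.manifest <- function(ens, spec) {
  attr(ens, "manifest") <- c(spec, list(generator_version = "0.1.0"))
  ens
}

#' Gaussian fluctuation ensemble about a reference
#'
#' Frames are the reference plus draws from a prescribed 3N-dimensional
#' Gaussian. The covariance may be a scalar (isotropic variance per
#' coordinate, A^2), a length-3N diagonal, a full 3N x 3N matrix, or a
#' low-rank form `list(vectors = 3N x k, values = k)` (plus an optional
#' `iso` floor added to every coordinate).
#'
#' @param reference n_atoms x 3 reference coordinates.
#' @param covariance covariance specification (A^2).
#' @param n_frames number of frames.
#' @param seed RNG seed; fully determines the output.
#' @param rigid_motion apply an additional random rigid rotation and
#'   translation to every frame (exercises fitting).
#' @return an `ensemble` (manifest attached).
#' @export
gaussian_ensemble <- function(reference, covariance, n_frames, seed,
                              rigid_motion = FALSE) {
  n3 <- 3L * nrow(reference)
  ref_flat <- as.numeric(t(reference))
  .with_seed(seed, {
    if (is.list(covariance)) {
      V <- covariance$vectors; lam <- covariance$values
      if (any(lam < 0)) stop("covariance not PSD: negative low-rank values")
      Z <- matrix(stats::rnorm(n_frames * length(lam)), n_frames)
      D <- Z %*% (t(V) * sqrt(lam))
      if (!is.null(covariance$iso) && covariance$iso > 0) {
        D <- D + sqrt(covariance$iso) * matrix(stats::rnorm(n_frames * n3), n_frames)
      }
    } else if (length(covariance) == 1L) {
      if (covariance < 0) stop("covariance not PSD")
      D <- sqrt(covariance) * matrix(stats::rnorm(n_frames * n3), n_frames)
    } else if (is.matrix(covariance)) {
      e <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
      if (min(e$values) < -1e-8 * max(abs(e$values))) {
        stop("covariance not PSD: negative eigenvalue")
      }
      lam <- pmax(e$values, 0)
      Z <- matrix(stats::rnorm(n_frames * n3), n_frames)
      D <- Z %*% (t(e$vectors) * sqrt(lam))
    } else {
      if (length(covariance) != n3) stop("diagonal covariance has wrong length")
      if (any(covariance < 0)) stop("covariance not PSD")
      D <- matrix(stats::rnorm(n_frames * n3), n_frames) *
        rep(sqrt(covariance), each = n_frames)
    }
    coords <- array(NA_real_, dim = c(n_frames, nrow(reference), 3))
    for (f in seq_len(n_frames)) {
      x <- matrix(ref_flat + D[f, ], ncol = 3, byrow = TRUE)
      if (rigid_motion) {
        R <- .random_rotation()
        x <- x %*% R + matrix(stats::runif(3, -5, 5), nrow(x), 3, byrow = TRUE)
      }
      coords[f, , ] <- x
    }
    .manifest(ensemble(coords),
              list(generator = "gaussian_ensemble", n_frames = n_frames,
                   seed = seed, rigid_motion = rigid_motion))
  })
}

.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
           2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
           2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Two-state conformational mixture
#'
#' Per-frame state drawn i.i.d. with probabilities (p1, 1 - p1); within
#' each state, isotropic Gaussian jitter of standard deviation `sigma` per
#' coordinate about that state's reference.
#'
#' @param ref1,ref2 n_atoms x 3 reference coordinates of the two states
#'   (same atom count).
#' @param p1 population of state 1.
#' @param sigma within-state standard deviation per coordinate, A.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return an `ensemble` with attribute `state_labels` (integer 1/2).
#' @export
two_state_ensemble <- function(ref1, ref2, p1, sigma, n_frames, seed) {
  stopifnot(nrow(ref1) == nrow(ref2), p1 >= 0, p1 <= 1)
  .with_seed(seed, {
    lab <- 1L + (stats::runif(n_frames) >= p1)
    coords <- array(NA_real_, dim = c(n_frames, nrow(ref1), 3))
    for (f in seq_len(n_frames)) {
      ref <- if (lab[f] == 1L) ref1 else ref2
      coords[f, , ] <- ref + matrix(stats::rnorm(length(ref), 0, sigma),
                                    nrow(ref), 3)
    }
    ens <- .manifest(ensemble(coords),
                     list(generator = "two_state_ensemble", p1 = p1,
                          sigma = sigma, n_frames = n_frames, seed = seed))
    attr(ens, "state_labels") <- lab
    ens
  })
}

#' Scripted donor-H-acceptor ensemble with exact target occupancy
#'
#' A three-atom system (donor oxygen with its hydrogen, and an acceptor
#' oxygen) placed inside the hydrogen-bond criteria (D-A 2.9 A, A-H-D
#' 180 deg) in exactly `round(occupancy * n_frames)` frames, and far
#' outside them (D-A 6 A) otherwise. Which frames form the bond is chosen
#' by the seed.
#'
#' @param occupancy target occupancy in [0, 1].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list: `topology`, `ensemble`, `bond_frames` (sorted indices).
#' @export
scripted_hbond_ensemble <- function(occupancy, n_frames, seed) {
  stopifnot(occupancy >= 0, occupancy <= 1)
  atoms <- data.frame(
    serial = 1:3, name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
    resname = c("DON", "DON", "ACC"), resid = c(1L, 1L, 2L),
    chain = "A", stringsAsFactors = FALSE)
  top <- topology(atoms, bonds = matrix(c(1L, 2L), ncol = 2))
  n_on <- round(occupancy * n_frames)
  .with_seed(seed, {
    on_frames <- sort(sample.int(n_frames, n_on))
    coords <- array(NA_real_, dim = c(n_frames, 3L, 3L))
    for (f in seq_len(n_frames)) {
      da <- if (f %in% on_frames) 2.9 else 6.0
      coords[f, , ] <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(da, 0, 0))
    }
    list(topology = top,
         ensemble = .manifest(ensemble(coords),
                              list(generator = "scripted_hbond_ensemble",
                                   occupancy = occupancy,
                                   n_frames = n_frames, seed = seed)),
         bond_frames = on_frames)
  })
}

#' Scripted water-bridge ensemble with exact target occupancy
#'
#' Partner A (acceptor oxygen), a water, and partner B (acceptor oxygen):
#' in bridge frames the water donates one hydrogen to each partner
#' (O-O 2.9 A, linear); otherwise the water is displaced 20 A away. The
#' bridge is present in exactly `round(occupancy * n_frames)` frames.
#'
#' @inheritParams scripted_hbond_ensemble
#' @return list: `topology`, `ensemble`, `bridge_frames`.
#' @export
scripted_water_bridge_ensemble <- function(occupancy, n_frames, seed) {
  stopifnot(occupancy >= 0, occupancy <= 1)
  atoms <- data.frame(
    serial = 1:5,
    name = c("OA", "OW", "HW1", "HW2", "OB"),
    element = c("O", "O", "H", "H", "O"),
    resname = c("PTA", "WAT", "WAT", "WAT", "PTB"),
    resid = c(1L, 2L, 2L, 2L, 3L),
    chain = c("A", "W", "W", "W", "B"), stringsAsFactors = FALSE)
  top <- topology(atoms, bonds = matrix(c(2L, 3L, 2L, 4L), ncol = 2,
                                        byrow = TRUE))
  # bridge geometry: water O at origin, partners on -x/+x at 2.9 A,
  # hydrogens on the O-O axes
  base <- rbind(c(-2.9, 0, 0), c(0, 0, 0), c(-0.96, 0, 0), c(0.96, 0, 0),
                c(2.9, 0, 0))
  n_on <- round(occupancy * n_frames)
  .with_seed(seed, {
    on_frames <- sort(sample.int(n_frames, n_on))
    coords <- array(NA_real_, dim = c(n_frames, 5L, 3L))
    for (f in seq_len(n_frames)) {
      x <- base
      if (!(f %in% on_frames)) x[2:4, 3] <- x[2:4, 3] + 20
      coords[f, , ] <- x
    }
    list(topology = top,
         ensemble = .manifest(ensemble(coords),
                              list(generator = "scripted_water_bridge_ensemble",
                                   occupancy = occupancy,
                                   n_frames = n_frames, seed = seed)),
         bridge_frames = on_frames)
  })
}

#' Parameterized toy receptor-ligand complex with a planted hot spot
#'
#' A small two-molecule system with complete force-field parameters and
#' closed-form reference energies. The receptor is a row of serine-like
#' residues (CA, CB, OG atoms); one residue (the planted hot spot) carries
#' a large negative charge on OG and sits nearest the ligand's positively
#' charged nitrogen, so it dominates the per-residue decomposition and the
#' alanine scan. Energy magnitudes are O(1-100) kcal/mol by construction.
#'
#' @param n_receptor_res number of receptor residues (>= 2).
#' @param hotspot_res resid of the planted hot spot (default 2).
#' @param hotspot_charge OG charge of the hot-spot residue, e.
#' @param ligand_charge charge on the ligand nitrogen, e.
#' @param vibration within-frame Gaussian jitter SD per coordinate, A.
#' @param charge_scale multiplier applied to every charge (0 gives a
#'   charge-free system with vanishing electrostatics and GB).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list: `topology` (parameterized), `ensemble`,
#'   `receptor_sel`/`ligand_sel` (index vectors), `truth` (reference-frame
#'   interaction energies computed by direct summation, and the planted
#'   hot-spot resid).
#' @export
toy_complex <- function(n_receptor_res = 4L, hotspot_res = 2L,
                        hotspot_charge = -0.8, ligand_charge = 0.8,
                        vibration = 0.03, charge_scale = 1,
                        n_frames = 25L, seed = 1L) {
  stopifnot(n_receptor_res >= 2L, hotspot_res >= 1L,
            hotspot_res <= n_receptor_res)
  rows <- list(); bonds <- list(); xyz <- list()
  serial <- 0L
  for (r in seq_len(n_receptor_res)) {
    base <- c(4.0 * (r - 1L), 0, 0)
    hot <- r == hotspot_res
    qog <- if (hot) hotspot_charge else -0.05
    rows[[r]] <- data.frame(
      serial = serial + 1:3, name = c("CA", "CB", "OG"),
      element = c("C", "C", "O"), resname = "SER", resid = r, chain = "R",
      is_het = FALSE,
      charge = c(0.02, 0.03, qog), eps = c(0.1094, 0.1094, 0.2104),
      rmin_half = c(1.908, 1.908, 1.721),
      gb_radius = c(1.7, 1.7, 1.5), gb_screen = c(0.72, 0.72, 0.85),
      stringsAsFactors = FALSE)
    bonds[[r]] <- rbind(serial + c(1L, 2L), serial + c(2L, 3L))
    # OG points toward the ligand plane (z > 0) for the hot spot only
    zog <- if (hot) 1.4 else -1.4
    xyz[[r]] <- rbind(base, base + c(0, 1.5, 0), base + c(0, 1.5, zog))
    serial <- serial + 3L
  }
  lig_base <- c(4.0 * (hotspot_res - 1L), 1.5, 4.4)  # N1 3 A above hot OG
  rows[[n_receptor_res + 1L]] <- data.frame(
    serial = serial + 1:3, name = c("C1", "C2", "N1"),
    element = c("C", "C", "N"), resname = "LIG", resid = 1L, chain = "L",
    is_het = TRUE,
    charge = c(0.05, 0.05, ligand_charge), eps = c(0.1094, 0.1094, 0.17),
    rmin_half = c(1.908, 1.908, 1.824),
    gb_radius = c(1.7, 1.7, 1.55), gb_screen = c(0.72, 0.72, 0.79),
    stringsAsFactors = FALSE)
  bonds[[n_receptor_res + 1L]] <- rbind(serial + c(1L, 2L), serial + c(2L, 3L))
  xyz[[n_receptor_res + 1L]] <- rbind(lig_base + c(-1.4, 0, 1.0),
                                      lig_base + c(0, 0, 1.4), lig_base)
  atoms <- do.call(rbind, rows)
  atoms$charge <- atoms$charge * charge_scale
  atoms$vdw_radius <- vdw_radius_bondi(atoms$element)
  top <- topology(atoms, bonds = do.call(rbind, bonds))
  ref <- do.call(rbind, xyz)
  rec_idx <- which(atoms$chain == "R")
  lig_idx <- which(atoms$chain == "L")
  # closed-form reference interaction energies by direct double loop
  # (intermolecular pairs only; no exclusions cross molecules)
  e_ele <- 0; e_vdw <- 0
  for (i in rec_idx) for (j in lig_idx) {
    r <- sqrt(sum((ref[i, ] - ref[j, ])^2))
    e_ele <- e_ele + KE_COULOMB * atoms$charge[i] * atoms$charge[j] / r
    rij <- atoms$rmin_half[i] + atoms$rmin_half[j]
    eij <- sqrt(atoms$eps[i] * atoms$eps[j])
    e_vdw <- e_vdw + eij * ((rij / r)^12 - 2 * (rij / r)^6)
  }
  ens <- gaussian_ensemble(ref, vibration^2, n_frames, seed)
  list(topology = top, ensemble = ens,
       receptor_sel = rec_idx, ligand_sel = lig_idx,
       truth = list(reference = ref,
                    dE_ele_gas = e_ele, dE_vdw = e_vdw,
                    hotspot_resid = hotspot_res))
}

# canonical backbone geometry (A, deg)
.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            a_ca_c_o = 120.8)

# build an N/CA/C/O backbone from phi/psi/omega sequences
.build_backbone <- function(phi, psi, omega = rep(180, length(phi))) {
  n_res <- length(phi)
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$b_n_ca, 0, 0)
  th <- .BB$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .BB$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    if (i < n_res) {
      N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], .BB$b_c_n,
                                .BB$a_ca_c_n, psi[i])
      CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], .BB$b_n_ca,
                                 .BB$a_c_n_ca, omega[i])
      C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], .BB$b_ca_c,
                                .BB$a_n_ca_c, phi[i + 1])
    }
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], .BB$b_c_o, .BB$a_ca_c_o,
                          psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

.backbone_topology <- function(n_res, chain = "A", resid_start = 1L,
                               resname = "ALA", serial_start = 0L) {
  rows <- lapply(seq_len(n_res), function(i) {
    data.frame(serial = serial_start + 4L * (i - 1L) + 1:4,
               name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"), resname = resname,
               resid = resid_start + i - 1L, chain = chain,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.backbone_coords <- function(bb) {
  n_res <- nrow(bb$N)
  x <- matrix(NA_real_, 4L * n_res, 3)
  for (i in seq_len(n_res)) {
    x[4L * (i - 1L) + 1:4, ] <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ],
                                      bb$O[i, ])
  }
  x
}

#' Ideal alpha-helix backbone
#'
#' N/CA/C/O backbone built at canonical helix dihedrals (phi = -57,
#' psi = -47, omega = 180) with standard bond geometry. Deterministic and
#' seed-free.
#'
#' @param n_res number of residues (>= 6).
#' @return list: `topology`, `ensemble` (single frame).
#' @export
ideal_helix <- function(n_res = 12L) {
  stopifnot(n_res >= 6L)
  bb <- .build_backbone(phi = rep(-57, n_res), psi = rep(-47, n_res))
  atoms <- .backbone_topology(n_res)
  list(topology = topology(atoms),
       ensemble = .manifest(ensemble(.backbone_coords(bb)),
                            list(generator = "ideal_helix", n_res = n_res)))
}

#' Ideal antiparallel beta-hairpin backbone
#'
#' One continuous chain: an extended strand (phi = -139, psi = 135),
#' a two-residue type II' beta-turn (phi/psi = 60/-120, -80/0), and the
#' returning strand, which places the two strands in proper antiparallel
#' hydrogen-bonding register. Deterministic and seed-free.
#'
#' @param n_res residues per strand (>= 4); total length 2 * n_res + 2.
#' @return list: `topology`, `ensemble` (single frame).
#' @export
ideal_sheet <- function(n_res = 5L) {
  stopifnot(n_res >= 4L)
  phi <- c(rep(-139, n_res), 60, -80, rep(-139, n_res))
  psi <- c(rep(135, n_res), -120, 0, rep(135, n_res))
  bb <- .build_backbone(phi, psi)
  top <- topology(.backbone_topology(2L * n_res + 2L))
  list(topology = top,
       ensemble = .manifest(ensemble(.backbone_coords(bb)),
                            list(generator = "ideal_sheet", n_res = n_res)))
}
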