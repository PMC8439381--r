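#' @title Core containers: topology and ensemble
#' @description Internal conventions: lengths in Angstrom, energies in
#'   kcal/mol, angles in degrees, times in ns, charges in electron units.
#'   Atom indices are 1-based throughout; residue numbers are stored as
#'   authored in the input (an optional `numbering_offset` is metadata used
#'   only when labelling output, never applied to storage).
#' @name mdensemble-containers
NULL

# Bondi van der Waals radii (A), element-keyed
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
            F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75,
            MG = 1.73, ZN = 1.39, FE = 1.50)

.MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
             P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
             NA. = 22.990, K = 39.098, MG = 24.305, ZN = 65.38, FE = 55.845)

# Coulomb constant, kcal*A/(mol*e^2), AMBER value
KE_COULOMB <- 332.0637
# Boltzmann constant, kcal/(mol*K)
KB_KCAL <- 0.0019872041

.WATER_RESNAMES <- c("HOH", "WAT", "TIP3")

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HIE", "HID", "HIP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Residues treated as polar when classifying contacts
.POLAR_AA <- c("SER", "THR", "ASN", "GLN", "HIS", "HIE", "HID", "HIP",
               "TYR", "CYS", "LYS", "ARG", "ASP", "GLU")

#' Look up Bondi van der Waals radii for element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param default radius used for unknown elements (A).
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius_bondi <- function(element, default = 1.5) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  r <- .BONDI[key]
  r[is.na(r)] <- default
  unname(r)
}

#' Atomic masses for element symbols
#'
#' @param element character vector of element symbols.
#' @param default mass for unknown elements (amu).
#' @return numeric vector of masses (amu).
#' @export
atomic_mass <- function(element, default = 12.0) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .MASSES[key]
  m[is.na(m)] <- default
  unname(m)
}

#' Infer element symbols from PDB atom names
#'
#' Uses the PDB v3 convention: for four-character names starting with a
#' digit or for names like "1HB1", hydrogen detection falls back to the
#' first alphabetic character; two-letter elements (CL, BR, FE, ZN, MG, NA)
#' are recognised when the name starts with them.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- character(length(nm))
  two_letter <- c("CL", "BR", "FE", "ZN", "MG")
  for (i in seq_along(nm)) {
    s <- nm[i]
    if (two[i] %in% two_letter && !grepl("^C[ABGDEZH1-9]", s)) {
      out[i] <- two[i]
    } else {
      first_alpha <- regmatches(s, regexpr("[A-Z]", s))
      out[i] <- if (length(first_alpha)) first_alpha else "C"
    }
  }
  out
}

#' Construct a topology
#'
#' A topology holds atom identities and, optionally, force-field parameters
#' and bonded terms. Parameter columns (`charge`, `eps`, `rmin_half`,
#' `gb_radius`, `gb_screen`) are either all present (parameterized topology)
#' or all `NA`.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`; optional `is_water`, `charge`, `eps`,
#'   `rmin_half`, `gb_radius`, `gb_screen`, `vdw_radius`, `is_het`.
#' @param bonds integer matrix (n x 2) of 1-based atom indices, or NULL.
#' @param angles data.frame (`i`,`j`,`k`,`k_theta`,`theta0`) or NULL;
#'   `theta0` in degrees, `k_theta` in kcal/mol/rad^2.
#' @param torsions data.frame (`i`,`j`,`k`,`l`,`pk`,`per`,`phase`) or NULL;
#'   `phase` in degrees.
#' @param numbering_offset integer; alternate-numbering metadata used only
#'   for labels (e.g. a rat/human offset of +7 prints "K300/307").
#' @param water_resnames residue names treated as water.
#' @return object of class `topology`.
#' @export
topology <- function(atoms, bonds = NULL, angles = NULL, torsions = NULL,
                     numbering_offset = 0L,
                     water_resnames = .WATER_RESNAMES) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "resname", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty topology: zero atoms")
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (any(!nzchar(atoms$element))) stop("empty element symbol")
  atoms$is_water <- toupper(atoms$resname) %in% toupper(water_resnames)
  if (is.null(atoms$is_het)) atoms$is_het <- FALSE
  for (col in c("charge", "eps", "rmin_half", "gb_radius", "gb_screen")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  par_cols <- c("charge", "eps", "rmin_half", "gb_radius", "gb_screen")
  has <- vapply(par_cols, function(cl) !all(is.na(atoms[[cl]])), logical(1))
  if (any(has) && !all(has)) {
    stop("partial parameterization: parameter columns must be all present or all absent")
  }
  if (is.null(atoms$vdw_radius) || all(is.na(atoms$vdw_radius))) {
    atoms$vdw_radius <- vdw_radius_bondi(atoms$element)
  }
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) && (min(bonds) < 1L || max(bonds) > nrow(atoms))) {
      stop("bond indices out of range")
    }
  }
  top <- structure(
    list(atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
         exclusions = NULL, numbering_offset = as.integer(numbering_offset)),
    class = "topology")
  if (!is.null(bonds) && nrow(bonds)) top$exclusions <- build_exclusions(top)
  top
}

#' Number of atoms in a topology or ensemble
#' @param x a `topology` or `ensemble`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "topology")) return(nrow(x$atoms))
  if (inherits(x, "ensemble")) return(dim(x$coords)[2])
  stop("n_atoms: unsupported class")
}

#' Is the topology fully parameterized?
#' @param top a `topology`.
#' @return logical.
#' @export
is_parameterized <- function(top) {
  !any(is.na(top$atoms$charge)) && !any(is.na(top$atoms$eps)) &&
    !any(is.na(top$atoms$rmin_half)) && !any(is.na(top$atoms$gb_radius)) &&
    !any(is.na(top$atoms$gb_screen))
}

#' Build 1-2/1-3 exclusion and 1-4 scaled pair sets from bonds
#'
#' @param top a `topology` with bonds.
#' @return list with integer pair matrices `ex12`, `ex13`, `ex14`
#'   (each row i < j; `ex14` excludes pairs already in 1-2/1-3, as in
#'   rings of size <= 4).
#' @export
build_exclusions <- function(top) {
  nb <- n_atoms(top)
  bonds <- top$bonds
  if (is.null(bonds) || nrow(bonds) == 0L) {
    empty <- matrix(integer(0), ncol = 2)
    return(list(ex12 = empty, ex13 = empty, ex14 = empty))
  }
  adj <- vector("list", nb)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  e12 <- unique(t(apply(bonds, 1, sort)))
  e13 <- list(); e14 <- list()
  for (j in seq_len(nb)) {
    nbrs <- adj[[j]]
    if (length(nbrs) >= 2) {
      cmb <- utils::combn(sort(nbrs), 2)
      e13[[length(e13) + 1L]] <- t(cmb)
    }
  }
  e13 <- if (length(e13)) unique(do.call(rbind, e13)) else matrix(integer(0), ncol = 2)
  # 1-4: endpoints of paths i-j-k-l
  for (r in seq_len(nrow(bonds))) {
    j <- bonds[r, 1]; k <- bonds[r, 2]
    for (i in setdiff(adj[[j]], k)) {
      for (l in setdiff(adj[[k]], c(j, i))) {
        e14[[length(e14) + 1L]] <- c(min(i, l), max(i, l))
      }
    }
  }
  e14 <- if (length(e14)) unique(do.call(rbind, e14)) else matrix(integer(0), ncol = 2)
  if (nrow(e14)) {
    seen <- c(pair_key(e12[, 1], e12[, 2]), pair_key(e13[, 1], e13[, 2]))
    e14 <- e14[!(pair_key(e14[, 1], e14[, 2]) %in% seen), , drop = FALSE]
  }
  storage.mode(e12) <- "integer"; storage.mode(e13) <- "integer"
  storage.mode(e14) <- "integer"
  list(ex12 = e12, ex13 = e13, ex14 = e14)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues, %s, %s\n",
              n_atoms(x),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              if (is.null(x$bonds)) "no bonds" else paste(nrow(x$bonds), "bonds"),
              if (is_parameterized(x)) "parameterized" else "unparameterized"))
  invisible(x)
}

#' Construct an ensemble of coordinate frames
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (A), or a single
#'   `n_atoms x 3` matrix (one frame).
#' @param frame_times optional numeric vector of frame times (ns).
#' @param provenance optional list (source file, stride, ...).
#' @return object of class `ensemble`.
#' @export
ensemble <- function(coords, frame_times = NULL, provenance = list()) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1]) {
    stop("frame_times length must equal number of frames")
  }
  structure(list(coords = coords, frame_times = frame_times,
                 provenance = provenance),
            class = "ensemble")
}

#' Number of frames in an ensemble
#' @param ens an `ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' Extract one frame as an n_atoms x 3 matrix
#' @param ens an `ensemble`.
#' @param i frame index (1-based).
#' @return numeric matrix `n_atoms x 3`.
#' @export
frame_coords <- function(ens, i) {
  stopifnot(i >= 1, i <= n_frames(ens))
  matrix(ens$coords[i, , ], ncol = 3)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames x %d atoms\n", n_frames(x), n_atoms(x)))
  invisible(x)
}

#' Subset an ensemble by frames
#' @param ens an `ensemble`.
#' @param frames integer frame indices to keep, in order.
#' @return new `ensemble`.
#' @export
subset_frames <- function(ens, frames) {
  ensemble(ens$coords[frames, , , drop = FALSE],
           frame_times = if (!is.null(ens$frame_times)) ens$frame_times[frames],
           provenance = ens$provenance)
}

#' Label a residue using the topology's alternate-numbering offset
#'
#' With offset 7, residue K300 prints as "K300/307". Storage is never
#' renumbered; this is a reporting aid only.
#'
#' @param top a `topology`.
#' @param resid author residue number(s).
#' @return character vector of labels.
#' @export
residue_label <- function(top, resid) {
  off <- top$numbering_offset
  if (off == 0L) as.character(resid) else sprintf("%d/%d", resid, resid + off)
}
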