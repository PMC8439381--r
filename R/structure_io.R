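#' Read a structure file (PDB v3)
#'
#' Parses a fixed-column PDB file into a `topology` plus an `ensemble` with
#' one frame per MODEL (a single frame if the file has no MODEL records).
#' HETATM records are kept and flagged (`is_het`). Alternate locations are
#' resolved to the highest-occupancy conformer, ties broken in favour of
#' altloc 'A'. File reading is delegated to bio3d; lines are validated
#' first so malformed ATOM records fail with their line number.
#'
#' @param path PDB file path.
#' @param water_resnames residue names treated as water.
#' @return list with elements `topology` and `ensemble`.
#' @export
read_structure <- function(path, water_resnames = .WATER_RESNAMES) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records in ", path)
  for (ln in which(is_atom)) {
    l <- lines[ln]
    if (nchar(l) < 54) {
      stop(sprintf("malformed ATOM line %d: shorter than coordinate fields", ln))
    }
    flds <- c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(flds)))) {
      stop(sprintf("malformed ATOM line %d: non-numeric coordinates", ln))
    }
    if (is.na(suppressWarnings(as.integer(substr(l, 23, 26))))) {
      stop(sprintf("malformed ATOM line %d: non-integer residue number", ln))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  nfr <- nrow(pdb$xyz)

  # resolve altlocs: per (chain, resid, insert, name) keep highest occupancy,
  # ties -> 'A' (then first)
  keep <- rep(TRUE, nrow(a))
  alt <- a$alt
  if (any(!is.na(alt))) {
    grp <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    occ <- ifelse(is.na(a$o), 1, a$o)
    for (g in unique(grp[!is.na(alt)])) {
      rows <- which(grp == g)
      if (length(rows) < 2L) next
      sc <- occ[rows] - 1e-9 * (ifelse(is.na(alt[rows]), "A", alt[rows]) != "A")
      keep[rows] <- FALSE
      keep[rows[which.max(sc)]] <- TRUE
    }
  }
  xyz_cols <- bio3d::atom2xyz(which(keep))
  coords <- array(NA_real_, dim = c(nfr, sum(keep), 3))
  for (f in seq_len(nfr)) {
    coords[f, , ] <- matrix(pdb$xyz[f, xyz_cols], ncol = 3, byrow = TRUE)
  }
  a <- a[keep, , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- guess_element(a$elety[bad])
  # bio3d loses the ATOM/HETATM distinction on multi-model files; take it
  # from the raw records (serials of first-model HETATM lines)
  het_serials <- suppressWarnings(
    as.integer(substr(lines[rec == "HETATM"], 7, 11)))
  atoms <- data.frame(
    serial = a$eleno, name = trimws(a$elety), element = toupper(trimws(elem)),
    resname = trimws(a$resid), resid = a$resno,
    chain = ifelse(is.na(a$chain), " ", a$chain),
    is_het = a$eleno %in% het_serials | a$type == "HETATM",
    stringsAsFactors = FALSE)
  top <- topology(atoms, water_resnames = water_resnames)
  ens <- ensemble(coords, provenance = list(source = path, format = "pdb"))
  list(topology = top, ensemble = ens)
}

#' Write a structure to a PDB file
#'
#' Multi-frame ensembles are written as MODEL/ENDMDL blocks. Coordinates are
#' stored at the PDB's 3-decimal precision; names, residue numbers and
#' chains round-trip exactly.
#'
#' @param top a `topology`.
#' @param ens an `ensemble` (or a single frame matrix).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(top, ens, path) {
  if (is.matrix(ens)) ens <- ensemble(ens)
  stopifnot(n_atoms(top) == n_atoms(ens))
  nfr <- n_frames(ens)
  a <- top$atoms
  # write each frame through bio3d (which keeps ATOM/HETATM records only
  # for single models) and assemble MODEL blocks ourselves
  one_model <- function(f) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    bio3d::write.pdb(file = tf, xyz = as.numeric(t(frame_coords(ens, f))),
                     type = ifelse(a$is_het, "HETATM", "ATOM"),
                     resno = a$resid, resid = a$resname, eleno = a$serial,
                     elety = a$name,
                     chain = ifelse(a$chain == " ", "", a$chain),
                     elesy = a$element)
    lines <- readLines(tf, warn = FALSE)
    lines[substr(lines, 1, 6) %in% c("ATOM  ", "HETATM", "TER   ", "TER")]
  }
  if (nfr == 1L) {
    writeLines(c(one_model(1L), "END"), path)
  } else {
    out <- unlist(lapply(seq_len(nfr), function(f) {
      c(sprintf("MODEL     %4d", f), one_model(f), "ENDMDL")
    }))
    writeLines(c(out, "END"), path)
  }
  invisible(path)
}

#' Read a trajectory (DCD or multi-model PDB)
#'
#' @param top a `topology`; the file's atom count must match.
#' @param path trajectory path.
#' @param format "dcd" or "pdb".
#' @param stride keep every `stride`-th frame starting from the first
#'   (frames 1, 1+stride, ...); deterministic subsampling.
#' @return an `ensemble` in file frame order.
#' @export
read_trajectory <- function(top, path, format = c("dcd", "pdb"), stride = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  if (format == "pdb") {
    ens <- read_structure(path)$ensemble
    if (n_atoms(ens) != n_atoms(top)) {
      stop(sprintf("topology mismatch: file has %d atoms, topology has %d",
                   n_atoms(ens), n_atoms(top)))
    }
  } else {
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) stop("DCD I/O error reading ", path,
                                             ": ", conditionMessage(e)))
    if (ncol(xyz) != 3L * n_atoms(top)) {
      stop(sprintf("topology mismatch: DCD has %d atoms, topology has %d",
                   ncol(xyz) %/% 3L, n_atoms(top)))
    }
    nfr <- nrow(xyz)
    coords <- array(NA_real_, dim = c(nfr, n_atoms(top), 3))
    for (f in seq_len(nfr)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    ens <- ensemble(coords, provenance = list(source = path, format = "dcd"))
  }
  if (stride > 1L) {
    ens <- subset_frames(ens, seq(1L, n_frames(ens), by = stride))
    ens$provenance$stride <- stride
  }
  ens
}

#' Write a trajectory in DCD format (CHARMM/NAMD 32-bit)
#'
#' @param ens an `ensemble`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(ens, path) {
  nfr <- n_frames(ens)
  nat <- n_atoms(ens)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4L)
    writer()
    writeBin(as.integer(nbytes), con, size = 4L)
  }
  # header: "CORD" + 20 control ints (frame count, start, save freq, ...,
  # CHARMM version flag in slot 20)
  icntrl <- integer(20)
  icntrl[1] <- nfr; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nfr
  icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4L)
  }, 84L)
  title <- formatC("written by mdensemble", width = 80, flag = "-")
  rec(function() {
    writeBin(1L, con, size = 4L)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84L)
  rec(function() writeBin(as.integer(nat), con, size = 4L), 4L)
  for (f in seq_len(nfr)) {
    fr <- frame_coords(ens, f)
    for (d in 1:3) {
      rec(function() writeBin(as.numeric(fr[, d]), con, size = 4L),
          4L * nat)
    }
  }
  invisible(path)
}

#' Read a force-field parameter table into a topology
#'
#' The table is whitespace-delimited text with a header. Two keying schemes
#' are accepted: by residue/atom name (`resname name charge eps rmin_half
#' gb_radius gb_screen vdw_radius`) or per-atom (`serial charge eps ...`).
#' Every atom must receive values; otherwise an incomplete-parameterization
#' error lists the uncovered atoms. Exclusion sets are (re)built from the
#' topology's bonds.
#'
#' @param top a `topology`.
#' @param path parameter table path.
#' @return a parameterized `topology`.
#' @export
read_parameters <- function(top, path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need_num <- c("charge", "eps", "rmin_half", "gb_radius", "gb_screen")
  miss <- setdiff(need_num, names(tab))
  if (length(miss)) stop("parameter table missing columns: ", paste(miss, collapse = ", "))
  a <- top$atoms
  if ("serial" %in% names(tab)) {
    m <- match(a$serial, tab$serial)
  } else if (all(c("resname", "name") %in% names(tab))) {
    m <- match(paste(toupper(a$resname), a$name),
               paste(toupper(tab$resname), tab$name))
  } else {
    stop("parameter table must be keyed by 'serial' or by 'resname'+'name'")
  }
  if (anyNA(m)) {
    bad <- which(is.na(m))
    stop("incomplete parameterization; no parameters for atoms: ",
         paste(sprintf("%s:%d:%s", a$resname[bad], a$resid[bad], a$name[bad])[
           seq_len(min(10L, length(bad)))], collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  }
  for (col in need_num) a[[col]] <- as.numeric(tab[[col]][m])
  if ("vdw_radius" %in% names(tab)) a$vdw_radius <- as.numeric(tab$vdw_radius[m])
  top$atoms <- a
  top$exclusions <- build_exclusions(top)
  top
}

#' Write a per-atom (serial-keyed) parameter table
#'
#' @param top a parameterized `topology`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_parameters <- function(top, path) {
  if (!is_parameterized(top)) stop("topology is not parameterized")
  a <- top$atoms
  utils::write.table(
    data.frame(serial = a$serial, resname = a$resname, name = a$name,
               charge = a$charge, eps = a$eps, rmin_half = a$rmin_half,
               gb_radius = a$gb_radius, gb_screen = a$gb_screen,
               vdw_radius = a$vdw_radius),
    path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Guess covalent bonds from interatomic distances
#'
#' Distance-based bond perception for inputs that carry no connectivity
#' (PDB files, synthetic systems): atoms i, j are bonded when
#' `d_ij <= scale * (r_cov_i + r_cov_j)`. Useful for identifying donor
#' hydrogens; not a substitute for a force-field bond list.
#'
#' @param top a `topology`.
#' @param frame coordinates (n_atoms x 3) used for perception.
#' @param scale tolerance multiplier on covalent radii sums.
#' @return the topology with `bonds` (and exclusions) populated.
#' @export
guess_bonds <- function(top, frame, scale = 1.2) {
  rcov <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
            F = 0.57, CL = 1.02, BR = 1.20, I = 1.39)
  r <- rcov[toupper(top$atoms$element)]
  r[is.na(r)] <- 0.9
  nb <- n_atoms(top)
  d <- as.matrix(stats::dist(frame))
  lim <- outer(r, r, "+") * scale
  hit <- which(d <= lim & upper.tri(d), arr.ind = TRUE)
  # never bond two hydrogens
  hh <- toupper(top$atoms$element[hit[, 1]]) == "H" &
        toupper(top$atoms$element[hit[, 2]]) == "H"
  hit <- hit[!hh, , drop = FALSE]
  top$bonds <- matrix(as.integer(hit), ncol = 2)
  top$exclusions <- build_exclusions(top)
  top
}
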