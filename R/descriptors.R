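#' Construct a time series of a per-frame descriptor
#'
#' @param values numeric per-frame values.
#' @param label descriptor name.
#' @param units unit string (e.g. "A", "deg", "A^2").
#' @param frame_index frame indices the values correspond to.
#' @return object of class `time_series` with a `summary` element
#'   (mean, sd, min, max) recomputable from the values.
#' @export
time_series <- function(values, label = "series", units = "",
                        frame_index = seq_along(values)) {
  stopifnot(length(values) == length(frame_index))
  structure(list(label = label, units = units,
                 frame_index = as.integer(frame_index),
                 values = as.numeric(values),
                 summary = c(mean = mean(values), sd = stats::sd(values),
                             min = min(values), max = max(values))),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s [%s], %d frames: mean %.4g, sd %.4g\n",
              x$label, x$units, length(x$values), x$summary["mean"],
              x$summary["sd"]))
  invisible(x)
}

#' Export a time series as tab-separated text
#' @param ts a `time_series`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_time_series <- function(ts, path) {
  df <- data.frame(frame = ts$frame_index, value = ts$values)
  names(df)[2] <- sprintf("%s_%s", gsub("\\s+", "_", ts$label),
                          if (nzchar(ts$units)) ts$units else "value")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-frame RMSD after superposition
#'
#' Each frame is superposed onto the reference over `fit_sel` (Kabsch);
#' the RMSD is then measured over `measure_sel`, which may differ from the
#' fit selection.
#'
#' @param ens an `ensemble`.
#' @param top the matching `topology`.
#' @param reference reference coordinates (n_atoms x 3) or a frame index
#'   into `ens`.
#' @param fit_sel selection used for the fit.
#' @param measure_sel selection the RMSD is reported over (default: fit).
#' @return a `time_series` in Angstrom.
#' @export
rmsd_series <- function(ens, top, reference = 1L, fit_sel = "backbone",
                        measure_sel = NULL) {
  fit_idx <- .as_indices(top, fit_sel, what = "fit_sel")
  meas_idx <- if (is.null(measure_sel)) fit_idx
              else .as_indices(top, measure_sel, what = "measure_sel")
  ref <- if (is.matrix(reference)) reference else frame_coords(ens, reference)
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    x <- frame_coords(ens, f)
    tr <- superpose(x, ref, fit_idx)
    moved <- apply_transform(x, tr)
    sqrt(mean(rowSums((moved[meas_idx, , drop = FALSE] -
                         ref[meas_idx, , drop = FALSE])^2)))
  }, numeric(1))
  time_series(vals, label = "RMSD", units = "A")
}

#' Root-mean-square fluctuation per atom
#'
#' Fluctuations are measured about the iteratively re-fitted average
#' structure (see [fit_to_mean()]), so global rotation/translation does not
#' inflate them: `RMSF_i = sqrt(<|x_i - <x_i>|^2>)`.
#'
#' @param ens an `ensemble`.
#' @param top the matching `topology`.
#' @param sel atom selection (default Calpha).
#' @param by_residue aggregate to per-residue values (mean over selected
#'   atoms of each residue).
#' @return data.frame with atom (or residue) identifiers and `rmsf` (A).
#' @export
rmsf <- function(ens, top, sel = "calpha", by_residue = FALSE) {
  if (n_frames(ens) < 2L) stop("undefined fluctuation: need >= 2 frames")
  idx <- .as_indices(top, sel)
  ft <- fit_to_mean(ens, top, sel)
  al <- ft$ensemble
  nfr <- n_frames(al)
  xs <- al$coords[, idx, , drop = FALSE]
  mu <- apply(xs, c(2, 3), mean)
  dev2 <- vapply(seq_along(idx), function(k) {
    mean(rowSums(sweep(matrix(xs[, k, ], ncol = 3), 2, mu[k, ])^2))
  }, numeric(1))
  out <- data.frame(index = idx,
                    name = top$atoms$name[idx],
                    resname = top$atoms$resname[idx],
                    resid = top$atoms$resid[idx],
                    chain = top$atoms$chain[idx],
                    rmsf = sqrt(dev2))
  if (by_residue) {
    agg <- stats::aggregate(rmsf ~ chain + resid + resname, data = out, FUN = mean)
    return(agg[order(agg$chain, agg$resid), ])
  }
  out
}

#' Radius of gyration per frame
#'
#' `Rg = sqrt(sum m_i |x_i - x_cm|^2 / sum m_i)`; with
#' `mass_weighted = FALSE` all masses are 1.
#'
#' @param ens an `ensemble`.
#' @param top the matching `topology`.
#' @param sel atom selection.
#' @param mass_weighted use atomic masses.
#' @return a `time_series` in Angstrom.
#' @export
radius_of_gyration <- function(ens, top, sel = "protein", mass_weighted = TRUE) {
  idx <- .as_indices(top, sel)
  m <- if (mass_weighted) atomic_mass(top$atoms$element[idx]) else rep(1, length(idx))
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    x <- frame_coords(ens, f)[idx, , drop = FALSE]
    cm <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, cm)^2)) / sum(m))
  }, numeric(1))
  time_series(vals, label = "Rg", units = "A")
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius `vdw_radius + probe_radius` is sampled with
#' a deterministic golden-spiral point set; points buried inside any other
#' selected atom's probe-expanded sphere are discarded.
#'
#' @param frame coordinates (n_atoms x 3).
#' @param top the matching `topology` (`vdw_radius` must be present for all
#'   selected atoms).
#' @param sel atom selection (default all atoms).
#' @param probe_radius water probe radius, A.
#' @param n_sphere_points sample points per atom.
#' @return list with `per_atom` (A^2, in selection order) and `total`.
#' @export
sasa <- function(frame, top, sel = "all", probe_radius = 1.4,
                 n_sphere_points = 960L) {
  idx <- .as_indices(top, sel)
  r <- top$atoms$vdw_radius[idx]
  if (anyNA(r)) stop("parameterization error: missing vdw_radius for selected atoms")
  x <- frame[idx, , drop = FALSE]
  re <- r + probe_radius
  pts <- .sphere_points(n_sphere_points)
  n <- length(idx)
  per_atom <- numeric(n)
  # neighbour lists via squared-distance threshold
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(x, 2, x[i, ])^2)
    nb <- which(d2 < (re[i] + re)^2 & seq_len(n) != i)
    sp <- sweep(pts * re[i], 2, x[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      d2j <- rowSums(sweep(sp[acc, , drop = FALSE], 2, x[j, ])^2)
      acc[acc] <- d2j >= re[j]^2
    }
    per_atom[i] <- 4 * pi * re[i]^2 * sum(acc) / n_sphere_points
  }
  list(per_atom = per_atom, total = sum(per_atom), indices = idx)
}

#' SASA per frame over an ensemble
#'
#' @inheritParams sasa
#' @param ens an `ensemble`.
#' @return a `time_series` of total SASA (A^2).
#' @export
sasa_series <- function(ens, top, sel = "all", probe_radius = 1.4,
                        n_sphere_points = 960L) {
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    sasa(frame_coords(ens, f), top, sel, probe_radius, n_sphere_points)$total
  }, numeric(1))
  time_series(vals, label = "SASA", units = "A^2")
}

.one_atom_index <- function(top, spec, what) {
  idx <- .as_indices(top, spec, what = what)
  if (length(idx) != 1L) stop(what, " must resolve to exactly one atom")
  idx
}

#' Interatomic distance per frame
#' @param ens an `ensemble`; @param top matching `topology`.
#' @param atom_a,atom_b single-atom selections (index or expression).
#' @return `time_series` (A).
#' @export
distance_series <- function(ens, top, atom_a, atom_b) {
  i <- .one_atom_index(top, atom_a, "atom_a")
  j <- .one_atom_index(top, atom_b, "atom_b")
  if (i == j) stop("geometry error: atoms must be distinct")
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    x <- frame_coords(ens, f); .vnorm(x[i, ] - x[j, ])
  }, numeric(1))
  time_series(vals, label = "distance", units = "A")
}

#' Angle a-b-c per frame (degrees, at b, in [0, 180])
#' @inheritParams distance_series
#' @param atom_c single-atom selection.
#' @return `time_series` (deg).
#' @export
angle_series <- function(ens, top, atom_a, atom_b, atom_c) {
  i <- .one_atom_index(top, atom_a, "atom_a")
  j <- .one_atom_index(top, atom_b, "atom_b")
  k <- .one_atom_index(top, atom_c, "atom_c")
  if (anyDuplicated(c(i, j, k))) stop("geometry error: atoms must be distinct")
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    x <- frame_coords(ens, f)
    if (.vnorm(x[i, ] - x[j, ]) < 1e-12 || .vnorm(x[k, ] - x[j, ]) < 1e-12) {
      stop("geometry error: coincident atoms in angle")
    }
    .angle_deg(x[i, ], x[j, ], x[k, ])
  }, numeric(1))
  time_series(vals, label = "angle", units = "deg")
}

#' Torsion a-b-c-d per frame (degrees, IUPAC sign, (-180, 180])
#' @inheritParams angle_series
#' @param atom_d single-atom selection.
#' @return `time_series` (deg).
#' @export
torsion_series <- function(ens, top, atom_a, atom_b, atom_c, atom_d) {
  ii <- c(.one_atom_index(top, atom_a, "atom_a"),
          .one_atom_index(top, atom_b, "atom_b"),
          .one_atom_index(top, atom_c, "atom_c"),
          .one_atom_index(top, atom_d, "atom_d"))
  if (anyDuplicated(ii)) stop("geometry error: atoms must be distinct")
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    x <- frame_coords(ens, f)
    .torsion_deg(x[ii[1], ], x[ii[2], ], x[ii[3], ], x[ii[4], ])
  }, numeric(1))
  time_series(vals, label = "torsion", units = "deg")
}

#' Triangle area spanned by three atoms per frame
#'
#' Area `= 0.5 |AB x AC|` (A^2); zero for collinear triples. Used e.g. to
#' monitor the charge-clamp triangle spanned by three Calpha atoms.
#'
#' @inheritParams angle_series
#' @return `time_series` (A^2).
#' @export
triangle_area_series <- function(ens, top, atom_a, atom_b, atom_c) {
  i <- .one_atom_index(top, atom_a, "atom_a")
  j <- .one_atom_index(top, atom_b, "atom_b")
  k <- .one_atom_index(top, atom_c, "atom_c")
  if (anyDuplicated(c(i, j, k))) stop("geometry error: atoms must be distinct")
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    x <- frame_coords(ens, f)
    0.5 * .vnorm(.cross(x[j, ] - x[i, ], x[k, ] - x[i, ]))
  }, numeric(1))
  time_series(vals, label = "triangle_area", units = "A^2")
}

#' Residues within a contact shell of a centre selection
#'
#' A residue enters the table when any of its heavy atoms lies within
#' `shell_radius` of any heavy atom of `center_sel` (heavy atoms only, for
#' crystal-structure comparability). With `classify = TRUE` each residue is
#' labelled `h-bond` if [find_hbonds()] reports a bond between the residue
#' and the centre selection, else `polar` if its residue type is in
#' `polar_set`, else `hydrophobic`.
#'
#' @param frame coordinates (n_atoms x 3).
#' @param top matching `topology`.
#' @param center_sel selection defining the centre (e.g. ligand atoms).
#' @param shell_radius shell radius, A.
#' @param classify add interaction-class labels (requires hydrogens/bonds
#'   for the h-bond check; falls back to polar/hydrophobic without them).
#' @param polar_set residue names treated as polar.
#' @return data.frame (chain, resid, resname, min_dist, class) of class
#'   `contact_table`, one row per residue, sorted by resid.
#' @export
contact_shell <- function(frame, top, center_sel, shell_radius = 4.0,
                          classify = TRUE, polar_set = .POLAR_AA) {
  cidx <- .as_indices(top, center_sel, what = "center_sel")
  heavy <- toupper(top$atoms$element) != "H"
  cidx <- cidx[heavy[cidx]]
  if (!length(cidx)) stop("center_sel has no heavy atoms")
  others <- setdiff(which(heavy), cidx)
  cx <- frame[cidx, , drop = FALSE]
  rows <- list()
  key <- paste(top$atoms$chain[others], top$atoms$resid[others])
  for (g in unique(key)) {
    aidx <- others[key == g]
    d <- sqrt(outer(rowSums(frame[aidx, , drop = FALSE]^2), rowSums(cx^2), "+") -
                2 * frame[aidx, , drop = FALSE] %*% t(cx))
    mind <- min(d)
    if (mind <= shell_radius) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = top$atoms$chain[aidx[1]], resid = top$atoms$resid[aidx[1]],
        resname = top$atoms$resname[aidx[1]], min_dist = mind,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(chain = character(0), resid = integer(0),
                      resname = character(0), min_dist = numeric(0),
                      class = character(0))
    attr(out, "shell_radius") <- shell_radius
    class(out) <- c("contact_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$class <- NA_character_
  if (classify) {
    hb_res <- character(0)
    has_h <- any(toupper(top$atoms$element) == "H")
    if (has_h && !is.null(top$bonds)) {
      ev <- tryCatch(
        find_hbonds(frame, top,
                    donor_sel = seq_len(n_atoms(top)),
                    acceptor_sel = seq_len(n_atoms(top))),
        error = function(e) NULL)
      if (!is.null(ev) && nrow(ev)) {
        involves_center <- (ev$donor %in% cidx) != (ev$acceptor %in% cidx)
        partner <- ifelse(ev$donor %in% cidx, ev$acceptor, ev$donor)
        hb_res <- unique(paste(top$atoms$chain[partner],
                               top$atoms$resid[partner])[involves_center])
      }
    }
    rk <- paste(out$chain, out$resid)
    out$class <- ifelse(rk %in% hb_res, "h-bond",
                 ifelse(toupper(out$resname) %in% toupper(polar_set),
                        "polar", "hydrophobic"))
  }
  out <- out[order(out$chain, out$resid), ]
  rownames(out) <- NULL
  attr(out, "shell_radius") <- shell_radius
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Write a contact table as BED-like 3-column text (chain, resid, class)
#' @param ct a `contact_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_contact_table <- function(ct, path) {
  utils::write.table(ct[, c("chain", "resid", "class")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalized histogram summary of a time series
#'
#' Equal-width bins spanning `[min, max]` of the data; counts normalized to
#' sum to one. A constant series yields a single occupied bin of mass 1.
#'
#' @param ts a `time_series` or numeric vector.
#' @param n_bins number of bins.
#' @return list: `breaks`, `mids`, `prob` (sums to 1), `mode_bin`.
#' @export
histogram_summary <- function(ts, n_bins = 100L) {
  v <- if (inherits(ts, "time_series")) ts$values else as.numeric(ts)
  if (!length(v)) stop("histogram_summary: empty series")
  rng <- range(v)
  if (diff(rng) == 0) {
    breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
    return(list(breaks = breaks, mids = rng[1], prob = 1, mode_bin = 1L))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins),
                  nbins = n_bins)
  prob <- cnt / sum(cnt)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       prob = prob, mode_bin = which.max(prob))
}
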