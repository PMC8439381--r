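#' Geometric hydrogen-bond detection in one frame
#'
#' A hydrogen bond is recorded when a donor heavy atom D (N/O/S carrying a
#' covalently bound hydrogen H) and an acceptor A (N/O/S) satisfy both
#' criteria: D-A distance <= `dist_cutoff` and the angle at the hydrogen,
#' A-H-D, >= `angle_cutoff`. The angle is evaluated at the hydrogen
#' (CPPTRAJ convention); this choice is recorded in the result's
#' `criteria` attribute so outputs are auditable.
#'
#' @param frame coordinates (n_atoms x 3).
#' @param top matching `topology`; bonds must be present so donor hydrogens
#'   can be identified (see [guess_bonds()] for inputs without
#'   connectivity).
#' @param donor_sel selection restricting donor heavy atoms.
#' @param acceptor_sel selection restricting acceptors.
#' @param dist_cutoff donor-acceptor distance cutoff, A.
#' @param angle_cutoff A-H-D angle cutoff, degrees.
#' @return data.frame (donor, hydrogen, acceptor, dist, angle), one row per
#'   event; atom columns hold 1-based indices.
#' @export
find_hbonds <- function(frame, top, donor_sel = "all", acceptor_sel = "all",
                        dist_cutoff = 3.5, angle_cutoff = 120) {
  if (is.null(top$bonds) || nrow(top$bonds) == 0L) {
    stop("missing hydrogens/bonds: topology has no bond list; run guess_bonds() first")
  }
  el <- toupper(top$atoms$element)
  if (!any(el == "H")) stop("missing hydrogens: no H atoms in topology")
  dsel <- .as_indices(top, donor_sel, what = "donor_sel")
  asel <- .as_indices(top, acceptor_sel, what = "acceptor_sel")
  dh <- .donor_hydrogens(top)
  dh <- dh[dh$donor %in% dsel, , drop = FALSE]
  acceptors <- asel[el[asel] %in% c("N", "O", "S")]
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), dist = numeric(0),
                      angle = numeric(0))
  attr(empty, "criteria") <- list(dist_cutoff = dist_cutoff,
                                  angle_cutoff = angle_cutoff,
                                  angle_at = "hydrogen (A-H-D)")
  if (!nrow(dh) || !length(acceptors)) return(empty)
  out <- empty
  for (r in seq_len(nrow(dh))) {
    d <- dh$donor[r]; h <- dh$hydrogen[r]
    acc <- acceptors[acceptors != d & acceptors != h]
    if (!length(acc)) next
    dv <- sweep(frame[acc, , drop = FALSE], 2, frame[d, ])
    dda <- sqrt(rowSums(dv^2))
    cand <- acc[dda <= dist_cutoff & dda > 1e-6]
    for (a in cand) {
      ang <- .angle_deg(frame[a, ], frame[h, ], frame[d, ])
      if (ang >= angle_cutoff) {
        out <- rbind(out, data.frame(donor = d, hydrogen = h, acceptor = a,
                                     dist = dda[match(a, acc)], angle = ang))
      }
    }
  }
  attr(out, "criteria") <- attr(empty, "criteria")
  out
}

# donor heavy atom / bound hydrogen pairs (N, O, S donors)
.donor_hydrogens <- function(top) {
  el <- toupper(top$atoms$element)
  b <- top$bonds
  i <- b[, 1]; j <- b[, 2]
  hd <- rbind(
    cbind(donor = i[el[i] %in% c("N", "O", "S") & el[j] == "H"],
          hydrogen = j[el[i] %in% c("N", "O", "S") & el[j] == "H"]),
    cbind(donor = j[el[j] %in% c("N", "O", "S") & el[i] == "H"],
          hydrogen = i[el[j] %in% c("N", "O", "S") & el[i] == "H"]))
  as.data.frame(hd)
}

.atom_label <- function(top, idx) {
  sprintf("%s:%s:%s", top$atoms$resname[idx],
          residue_label(top, top$atoms$resid[idx]), top$atoms$name[idx])
}

# shared occupancy tabulator: per-frame list of present pair keys ->
# occupancy table
.occupancy_table <- function(keys_by_frame, nfr, meta, criteria,
                             report_cutoff = 0) {
  all_keys <- unique(unlist(keys_by_frame))
  if (!length(all_keys)) {
    out <- cbind(meta[0, , drop = FALSE],
                 data.frame(occupancy = numeric(0), n_frames = integer(0)))
  } else {
    cnt <- vapply(all_keys, function(k) {
      sum(vapply(keys_by_frame, function(v) k %in% v, logical(1)))
    }, numeric(1))
    out <- cbind(meta[match(all_keys, meta$key), , drop = FALSE],
                 data.frame(occupancy = 100 * cnt / nfr, n_frames = nfr))
    out <- out[order(-out$occupancy), ]
    out <- out[out$occupancy > report_cutoff, , drop = FALSE]
  }
  out$key <- NULL
  rownames(out) <- NULL
  attr(out, "criteria") <- criteria
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' Occupancy is the percentage of frames in which a pair forms at least one
#' hydrogen bond. With `atom_level = TRUE` pairs are keyed by (donor heavy
#' atom, acceptor atom); otherwise events aggregate over all donor/acceptor
#' atom combinations of a residue pair.
#'
#' @inheritParams find_hbonds
#' @param ens an `ensemble`.
#' @param atom_level key pairs by atoms (TRUE) or residues (FALSE).
#' @param report_cutoff drop rows at or below this occupancy (%); 0 keeps
#'   every observed pair.
#' @return data.frame of class `occupancy_table`, sorted by occupancy.
#' @export
hbond_occupancy <- function(ens, top, donor_sel = "all", acceptor_sel = "all",
                            dist_cutoff = 3.5, angle_cutoff = 120,
                            atom_level = TRUE, report_cutoff = 0) {
  nfr <- n_frames(ens)
  if (nfr < 1L) stop("need >= 1 frame")
  meta_rows <- list(); keys_by_frame <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    ev <- find_hbonds(frame_coords(ens, f), top, donor_sel, acceptor_sel,
                      dist_cutoff, angle_cutoff)
    if (!nrow(ev)) { keys_by_frame[[f]] <- character(0); next }
    if (atom_level) {
      key <- paste(ev$donor, ev$acceptor)
      meta <- data.frame(
        key = key,
        donor = .atom_label(top, ev$donor),
        acceptor = .atom_label(top, ev$acceptor),
        stringsAsFactors = FALSE)
    } else {
      dres <- paste(top$atoms$chain[ev$donor], top$atoms$resid[ev$donor])
      ares <- paste(top$atoms$chain[ev$acceptor], top$atoms$resid[ev$acceptor])
      key <- paste(dres, "->", ares)
      meta <- data.frame(
        key = key,
        donor = sprintf("%s:%s", top$atoms$resname[ev$donor],
                        residue_label(top, top$atoms$resid[ev$donor])),
        acceptor = sprintf("%s:%s", top$atoms$resname[ev$acceptor],
                           residue_label(top, top$atoms$resid[ev$acceptor])),
        stringsAsFactors = FALSE)
    }
    keys_by_frame[[f]] <- unique(key)
    meta_rows[[length(meta_rows) + 1L]] <- meta
  }
  meta <- if (length(meta_rows)) unique(do.call(rbind, meta_rows))
          else data.frame(key = character(0), donor = character(0),
                          acceptor = character(0))
  .occupancy_table(keys_by_frame, nfr, meta,
                   list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff,
                        angle_at = "hydrogen (A-H-D)", atom_level = atom_level),
                   report_cutoff)
}

#' Water-bridge (wHB) occupancy
#'
#' A frame counts toward a bridge between selections A and B when at least
#' one water molecule is simultaneously hydrogen bonded (same geometric
#' criteria, either donor/acceptor direction) to A and to B. The identity
#' of the bridging water may change between frames.
#'
#' @inheritParams hbond_occupancy
#' @param sel_a,sel_b partner selections (e.g. a ligand atom set and a
#'   residue).
#' @param water_sel selection of water atoms.
#' @return `occupancy_table` with one row per bridged (A-residue,
#'   B-residue) pair.
#' @export
water_bridge_occupancy <- function(ens, top, sel_a, sel_b, water_sel = "water",
                                   dist_cutoff = 3.5, angle_cutoff = 120) {
  widx <- .as_indices(top, water_sel, what = "water_sel")
  aidx <- .as_indices(top, sel_a, what = "sel_a")
  bidx <- .as_indices(top, sel_b, what = "sel_b")
  nfr <- n_frames(ens)
  wat_key <- paste(top$atoms$chain, top$atoms$resid)
  keys_by_frame <- vector("list", nfr); meta_rows <- list()
  for (f in seq_len(nfr)) {
    fr <- frame_coords(ens, f)
    ev <- find_hbonds(fr, top, donor_sel = seq_len(n_atoms(top)),
                      acceptor_sel = seq_len(n_atoms(top)),
                      dist_cutoff, angle_cutoff)
    keys <- character(0)
    if (nrow(ev)) {
      dw <- ev$donor %in% widx; aw <- ev$acceptor %in% widx
      # bonds linking one water atom and one non-water partner
      to_a <- (dw & ev$acceptor %in% aidx) | (aw & ev$donor %in% aidx)
      to_b <- (dw & ev$acceptor %in% bidx) | (aw & ev$donor %in% bidx)
      wat_of <- ifelse(dw, wat_key[ev$donor], wat_key[ev$acceptor])
      part_of <- ifelse(dw, ev$acceptor, ev$donor)
      wa <- unique(wat_of[to_a]); wb <- unique(wat_of[to_b])
      bridging <- intersect(wa, wb)
      if (length(bridging)) {
        for (w in bridging) {
          pa <- unique(part_of[to_a & wat_of == w])
          pb <- unique(part_of[to_b & wat_of == w])
          for (i in pa) for (j in pb) {
            k <- paste(wat_key[i], "~", wat_key[j])
            keys <- c(keys, k)
            meta_rows[[length(meta_rows) + 1L]] <- data.frame(
              key = k,
              donor = sprintf("%s:%s", top$atoms$resname[i],
                              residue_label(top, top$atoms$resid[i])),
              acceptor = sprintf("%s:%s", top$atoms$resname[j],
                                 residue_label(top, top$atoms$resid[j])),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    keys_by_frame[[f]] <- unique(keys)
  }
  meta <- if (length(meta_rows)) unique(do.call(rbind, meta_rows))
          else data.frame(key = character(0), donor = character(0),
                          acceptor = character(0))
  .occupancy_table(keys_by_frame, nfr, meta,
                   list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff,
                        bridge = "water-mediated (wHB)"), 0)
}

# default charged-group atom names per residue type
.SB_CATION_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                         HIS = c("NE2", "ND1"), HIP = c("NE2", "ND1"))
.SB_ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Salt-bridge occupancy
#'
#' A salt bridge is present in a frame when the minimum distance between a
#' cationic-group nitrogen and an anionic-group oxygen is at most `cutoff`
#' (default 4.0 A, a common convention). Occupancy is tabulated per
#' residue pair.
#'
#' @inheritParams hbond_occupancy
#' @param cation_sel,anion_sel selections of charged-group heavy atoms;
#'   NULL selects the standard groups (Lys NZ; Arg NH1/NH2/NE;
#'   His NE2/ND1; Asp OD1/OD2; Glu OE1/OE2).
#' @param cutoff N-O distance cutoff, A.
#' @return `occupancy_table` per residue pair.
#' @export
salt_bridges <- function(ens, top, cation_sel = NULL, anion_sel = NULL,
                         cutoff = 4.0) {
  pick_group <- function(tbl) {
    hits <- integer(0)
    for (rn in names(tbl)) {
      hits <- c(hits, which(toupper(top$atoms$resname) == rn &
                              top$atoms$name %in% tbl[[rn]]))
    }
    sort(hits)
  }
  cat_idx <- if (is.null(cation_sel)) pick_group(.SB_CATION_ATOMS)
             else .as_indices(top, cation_sel, what = "cation_sel")
  an_idx <- if (is.null(anion_sel)) pick_group(.SB_ANION_ATOMS)
            else .as_indices(top, anion_sel, what = "anion_sel")
  if (!length(cat_idx) || !length(an_idx)) {
    stop("salt_bridges: no charged-group atoms found")
  }
  nfr <- n_frames(ens)
  rk <- paste(top$atoms$chain, top$atoms$resid)
  keys_by_frame <- vector("list", nfr); meta_rows <- list()
  for (f in seq_len(nfr)) {
    fr <- frame_coords(ens, f)
    d <- sqrt(outer(rowSums(fr[cat_idx, , drop = FALSE]^2),
                    rowSums(fr[an_idx, , drop = FALSE]^2), "+") -
                2 * fr[cat_idx, , drop = FALSE] %*% t(fr[an_idx, , drop = FALSE]))
    hit <- which(d <= cutoff, arr.ind = TRUE)
    keys <- character(0)
    if (nrow(hit)) {
      ci <- cat_idx[hit[, 1]]; ai <- an_idx[hit[, 2]]
      k <- paste(rk[ci], "+", rk[ai])
      keys <- unique(k)
      for (u in seq_along(k)) {
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          key = k[u],
          donor = sprintf("%s:%s", top$atoms$resname[ci[u]],
                          residue_label(top, top$atoms$resid[ci[u]])),
          acceptor = sprintf("%s:%s", top$atoms$resname[ai[u]],
                             residue_label(top, top$atoms$resid[ai[u]])),
          stringsAsFactors = FALSE)
      }
    }
    keys_by_frame[[f]] <- keys
  }
  meta <- if (length(meta_rows)) unique(do.call(rbind, meta_rows))
          else data.frame(key = character(0), donor = character(0),
                          acceptor = character(0))
  .occupancy_table(keys_by_frame, nfr, meta, list(cutoff = cutoff), 0)
}

#' Write an occupancy table as TSV
#' @param ot an `occupancy_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_occupancy_table <- function(ot, path) {
  utils::write.table(as.data.frame(ot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
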