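#' Define a pocket region from inclusion/exclusion spheres
#'
#' Inclusion spheres may be anchored on atoms (a single-atom selection,
#' re-resolved against each frame so the centre tracks the trajectory) or
#' fixed points. Overlapping inclusion spheres form a union (no double
#' counting); exclusion spheres carve grid points out wherever they reach.
#'
#' @param inclusion list of spheres, each `list(center = <selection or
#'   length-3 numeric>, radius = <A>)`.
#' @param exclusion like `inclusion`, possibly empty.
#' @param spacing grid spacing, A.
#' @param padding added to atom van der Waals radii when removing occluded
#'   grid points, A.
#' @param contiguity minimum connected-cluster size (grid points,
#'   6-connectivity); 0 disables pruning.
#' @return object of class `pocket_region`.
#' @export
build_region <- function(inclusion, exclusion = list(), spacing = 1.0,
                         padding = 1.09, contiguity = 0L) {
  if (!length(inclusion)) stop("pocket region needs at least one inclusion sphere")
  if (spacing <= 0) stop("grid spacing must be positive")
  chk <- function(sph, what) {
    if (is.null(sph$center) || is.null(sph$radius) || sph$radius <= 0) {
      stop("invalid ", what, " sphere: need center and positive radius")
    }
    sph
  }
  structure(list(inclusion = lapply(inclusion, chk, what = "inclusion"),
                 exclusion = lapply(exclusion, chk, what = "exclusion"),
                 spacing = spacing, padding = padding,
                 contiguity = as.integer(contiguity)),
            class = "pocket_region")
}

# resolve a sphere centre for a given frame
.sphere_center <- function(sph, frame, top) {
  ctr <- sph$center
  if (is.numeric(ctr) && length(ctr) == 3L && is.null(attr(ctr, "class"))) {
    return(as.numeric(ctr))
  }
  idx <- .as_indices(top, ctr, what = "sphere center")
  if (length(idx) != 1L) {
    stop("sphere center selection must resolve to exactly one atom (got ",
         length(idx), ")")
  }
  frame[idx, ]
}

#' Grid-based pocket volume per frame
#'
#' For each frame: a cubic grid at the region's spacing is laid over the
#' union of (frame-resolved) inclusion spheres; points inside any exclusion
#' sphere are removed; points within `vdw_radius + padding` of any
#' occluding heavy atom are removed; optionally clusters smaller than the
#' contiguity threshold (6-connectivity) are pruned. The volume is the
#' number of surviving points times spacing^3 exactly.
#'
#' By default ligand/het atoms can be excluded from the occluding set by
#' passing a protein-only `occluder_sel` (pocket volume then measures
#' cavity capacity on an equal footing between holo and apo frames).
#'
#' @param ens an `ensemble`.
#' @param top matching `topology`.
#' @param region a `pocket_region`.
#' @param occluder_sel selection of atoms that occlude the pocket (default
#'   `"protein and heavy"`); may be an empty selection only if the region
#'   is measured atom-free.
#' @return object of class `volume_series`: data.frame (frame, n_points,
#'   volume) with the region recorded as an attribute.
#' @export
pocket_volume_series <- function(ens, top, region,
                                 occluder_sel = "protein and heavy") {
  stopifnot(inherits(region, "pocket_region"))
  occ_idx <- .as_indices(top, occluder_sel, require_nonempty = FALSE,
                         what = "occluder_sel")
  heavy <- toupper(top$atoms$element) != "H"
  occ_idx <- occ_idx[heavy[occ_idx]]
  if (length(occ_idx)) {
    rads <- top$atoms$vdw_radius[occ_idx]
    if (anyNA(rads)) stop("missing vdw_radius for occluding atoms")
  }
  nfr <- n_frames(ens)
  out <- data.frame(frame = seq_len(nfr), n_points = NA_integer_,
                    volume = NA_real_)
  sp <- region$spacing
  for (f in seq_len(nfr)) {
    fr <- frame_coords(ens, f)
    inc <- lapply(region$inclusion, function(s) {
      list(c = .sphere_center(s, fr, top), r = s$radius)
    })
    exc <- lapply(region$exclusion, function(s) {
      list(c = .sphere_center(s, fr, top), r = s$radius)
    })
    lo <- apply(do.call(rbind, lapply(inc, function(s) s$c - s$r)), 2, min)
    hi <- apply(do.call(rbind, lapply(inc, function(s) s$c + s$r)), 2, max)
    gx <- seq(lo[1], hi[1], by = sp)
    gy <- seq(lo[2], hi[2], by = sp)
    gz <- seq(lo[3], hi[3], by = sp)
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    keep <- rep(FALSE, nrow(pts))
    for (s in inc) {
      keep <- keep | rowSums(sweep(pts, 2, s$c)^2) <= s$r^2
    }
    for (s in exc) {
      keep <- keep & rowSums(sweep(pts, 2, s$c)^2) > s$r^2
    }
    if (any(keep) && length(occ_idx)) {
      p <- pts[keep, , drop = FALSE]
      alive <- rep(TRUE, nrow(p))
      for (ai in seq_along(occ_idx)) {
        if (!any(alive)) break
        a <- fr[occ_idx[ai], ]
        lim2 <- (rads[ai] + region$padding)^2
        d2 <- rowSums(sweep(p[alive, , drop = FALSE], 2, a)^2)
        alive[alive] <- d2 > lim2
      }
      keep[keep] <- alive
    }
    if (region$contiguity > 0L && any(keep)) {
      keep_pts <- pts[keep, , drop = FALSE]
      lab <- .grid_clusters(keep_pts, sp)
      sizes <- table(lab)
      good <- as.integer(names(sizes)[sizes >= region$contiguity])
      keep[keep] <- lab %in% good
    }
    np <- sum(keep)
    if (np == 0L) warning(sprintf("frame %d: empty pocket grid, volume 0", f))
    out$n_points[f] <- np
    out$volume[f] <- np * sp^3
  }
  attr(out, "region") <- region
  class(out) <- c("volume_series", "data.frame")
  out
}

# connected-component labels for grid points (6-connectivity)
.grid_clusters <- function(pts, spacing) {
  n <- nrow(pts)
  key <- apply(round(sweep(pts, 2, apply(pts, 2, min)) / spacing), 1, paste,
               collapse = ",")
  lut <- stats::setNames(seq_len(n), key)
  ijk <- round(sweep(pts, 2, apply(pts, 2, min)) / spacing)
  lab <- rep(0L, n); cur <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      for (o in seq_len(6)) {
        nk <- paste(ijk[p, ] + offs[o, ], collapse = ",")
        q <- lut[nk]
        if (!is.na(q) && lab[q] == 0L) stack <- c(stack, q)
      }
    }
  }
  lab
}

#' Write a volume series as TSV
#' @param vs a `volume_series`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_volume_series <- function(vs, path) {
  utils::write.table(as.data.frame(vs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Dump surviving grid points of one frame as PDB pseudo-atoms
#'
#' Inspection aid: each retained grid point becomes a HETATM "GRD" record.
#'
#' @inheritParams pocket_volume_series
#' @param frame_index which frame to dump.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
dump_pocket_grid <- function(ens, top, region, frame_index, path,
                             occluder_sel = "protein and heavy") {
  one <- subset_frames(ens, frame_index)
  fr <- frame_coords(one, 1)
  # recompute with the same rules, retaining point coordinates
  occ_idx <- .as_indices(top, occluder_sel, require_nonempty = FALSE)
  occ_idx <- occ_idx[toupper(top$atoms$element[occ_idx]) != "H"]
  sp <- region$spacing
  inc <- lapply(region$inclusion, function(s) list(c = .sphere_center(s, fr, top), r = s$radius))
  exc <- lapply(region$exclusion, function(s) list(c = .sphere_center(s, fr, top), r = s$radius))
  lo <- apply(do.call(rbind, lapply(inc, function(s) s$c - s$r)), 2, min)
  hi <- apply(do.call(rbind, lapply(inc, function(s) s$c + s$r)), 2, max)
  pts <- as.matrix(expand.grid(x = seq(lo[1], hi[1], by = sp),
                               y = seq(lo[2], hi[2], by = sp),
                               z = seq(lo[3], hi[3], by = sp)))
  keep <- rep(FALSE, nrow(pts))
  for (s in inc) keep <- keep | rowSums(sweep(pts, 2, s$c)^2) <= s$r^2
  for (s in exc) keep <- keep & rowSums(sweep(pts, 2, s$c)^2) > s$r^2
  if (length(occ_idx)) {
    rads <- top$atoms$vdw_radius[occ_idx]
    p <- pts[keep, , drop = FALSE]
    alive <- rep(TRUE, nrow(p))
    for (ai in seq_along(occ_idx)) {
      if (!any(alive)) break
      d2 <- rowSums(sweep(p[alive, , drop = FALSE], 2, fr[occ_idx[ai], ])^2)
      alive[alive] <- d2 > (rads[ai] + region$padding)^2
    }
    keep[keep] <- alive
  }
  p <- pts[keep, , drop = FALSE]
  lines <- vapply(seq_len(nrow(p)), function(i) {
    sprintf("HETATM%5d  GRD GRD X%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i %% 100000L, i %% 10000L, p[i, 1], p[i, 2], p[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
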