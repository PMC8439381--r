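#' Iteratively fit an ensemble to its average structure
#'
#' Alternates between computing the mean over the fit selection and
#' superposing every frame onto that mean, until the mean moves by less
#' than `tol` (RMS over fit atoms). Removes global rotation/translation so
#' that fluctuations reflect internal motion only.
#'
#' @param ens an `ensemble`.
#' @param top matching `topology`.
#' @param sel fit selection (default backbone).
#' @param tol convergence tolerance on the mean, A.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   last iterate.
#' @return list: `ensemble` (aligned, all atoms transformed), `mean`
#'   (n_sel x 3 converged mean over the fit selection), `iterations`.
#' @export
fit_to_mean <- function(ens, top, sel = "backbone", tol = 1e-6, max_iter = 10L) {
  if (n_frames(ens) < 2L) stop("fit_to_mean: need >= 2 frames")
  idx <- .as_indices(top, sel)
  coords <- ens$coords
  nfr <- dim(coords)[1]
  # initialize from the raw mean: an already-aligned ensemble then
  # converges in a single iteration
  ref <- apply(coords[, idx, , drop = FALSE], c(2, 3), mean)
  iterations <- 0L
  repeat {
    for (f in seq_len(nfr)) {
      x <- matrix(coords[f, , ], ncol = 3)
      tr <- superpose(x[idx, , drop = FALSE], ref)
      coords[f, , ] <- apply_transform(x, tr)
    }
    mu <- apply(coords[, idx, , drop = FALSE], c(2, 3), mean)
    shift <- sqrt(mean(rowSums((mu - ref)^2)))
    iterations <- iterations + 1L
    ref <- mu
    if (shift < tol) break
    if (iterations >= max_iter) {
      warning(sprintf("fit_to_mean did not converge in %d iterations (shift %.2g A)",
                      max_iter, shift))
      break
    }
  }
  list(ensemble = ensemble(coords, frame_times = ens$frame_times,
                           provenance = c(ens$provenance, list(fitted = TRUE))),
       mean = ref, sel = idx, iterations = iterations)
}

#' Positional covariance matrix of an aligned ensemble
#'
#' `C_ij = <(x_i - <x_i>)(x_j - <x_j>)>` over the 3N Cartesian coordinates
#' of the selection, with the unweighted frame average (denominator n,
#' matching ensemble-average notation; at the frame counts used here the
#' difference from n-1 is negligible).
#'
#' @param aligned an aligned `ensemble` (see [fit_to_mean()]).
#' @param top matching `topology`.
#' @param sel atom selection.
#' @return 3N x 3N covariance matrix (A^2), attribute `mean` = 3N mean
#'   vector, attribute `sel` = atom indices.
#' @export
covariance_matrix <- function(aligned, top, sel = "backbone") {
  if (n_frames(aligned) < 2L) stop("covariance: need >= 2 frames")
  idx <- .as_indices(top, sel)
  X <- .flat_coords(aligned, idx)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(Xc)
  attr(C, "mean") <- mu
  attr(C, "sel") <- idx
  C
}

# frames x 3N coordinate matrix (x1,y1,z1,x2,...) for a selection
.flat_coords <- function(ens, idx) {
  nfr <- n_frames(ens)
  X <- matrix(NA_real_, nfr, 3L * length(idx))
  for (f in seq_len(nfr)) {
    X[f, ] <- as.numeric(t(matrix(ens$coords[f, idx, ], ncol = 3)))
  }
  X
}

#' Principal components of a positional covariance matrix
#'
#' Eigen-decomposition with eigenvalues in descending order, fractional and
#' cumulative variance, and a reproducible sign convention (each
#' eigenvector's largest-magnitude component is made positive).
#'
#' @param C symmetric covariance matrix from [covariance_matrix()].
#' @return object of class `ed_model`: `values` (A^2, descending),
#'   `vectors` (columns, orthonormal), `frac` (sums to 1), `cumfrac`,
#'   `mean`, `sel`.
#' @export
principal_components <- function(C) {
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) {
    stop("principal_components: input matrix is not symmetric")
  }
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  tot <- sum(vals)
  structure(list(values = vals, vectors = vecs,
                 frac = if (tot > 0) vals / tot else vals,
                 cumfrac = if (tot > 0) cumsum(vals) / tot else vals,
                 mean = attr(C, "mean"), sel = attr(C, "sel")),
            class = "ed_model")
}

#' @export
print.ed_model <- function(x, ...) {
  k <- min(5L, length(x$values))
  cat(sprintf("<ed_model> %d modes; top-%d variance fractions: %s\n",
              length(x$values), k,
              paste(sprintf("%.1f%%", 100 * x$frac[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

#' Fraction of total variance captured by the first k modes
#' @param model an `ed_model`.
#' @param k number of leading modes.
#' @return numeric fraction in [0, 1].
#' @export
top_k_fraction <- function(model, k = 10L) {
  model$cumfrac[min(k, length(model$cumfrac))]
}

#' Project an aligned ensemble onto a principal component
#'
#' `p_k(t) = v_k . (x(t) - <x>)`; the variance of `p_k` over frames equals
#' the k-th eigenvalue.
#'
#' @param aligned aligned `ensemble` (same selection the model was built
#'   from).
#' @param model an `ed_model`.
#' @param k mode index.
#' @return `time_series` of projections (A).
#' @export
project_mode <- function(aligned, model, k) {
  if (k < 1L || k > length(model$values)) stop("mode index k out of range")
  X <- .flat_coords(aligned, model$sel)
  p <- as.numeric(sweep(X, 2, model$mean) %*% model$vectors[, k])
  time_series(p, label = sprintf("PC%d", k), units = "A")
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' `DCCM_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` over per-residue
#' representative atoms (Calpha by default). Zero-variance atoms give NA
#' entries (flagged via attribute `undefined`).
#'
#' @param aligned aligned `ensemble`.
#' @param top matching `topology`.
#' @param sel per-residue representative atom selection.
#' @return square matrix in [-1, 1] with unit diagonal, dimnames = residue
#'   numbers.
#' @export
dccm_matrix <- function(aligned, top, sel = "calpha") {
  idx <- .as_indices(top, sel)
  n <- length(idx)
  nfr <- n_frames(aligned)
  xs <- aligned$coords[, idx, , drop = FALSE]
  mu <- apply(xs, c(2, 3), mean)
  D <- array(NA_real_, dim = dim(xs))
  for (f in seq_len(nfr)) D[f, , ] <- matrix(xs[f, , ], ncol = 3) - mu
  # inner products: sum over xyz of frame-averaged products
  ip <- matrix(0, n, n)
  for (d in 1:3) ip <- ip + crossprod(D[, , d]) / nfr
  v <- diag(ip)
  denom <- sqrt(outer(v, v))
  M <- ip / denom
  M[denom == 0] <- NA_real_
  dg <- diag(M); dg[v > 0] <- 1; diag(M) <- dg
  dimnames(M) <- list(top$atoms$resid[idx], top$atoms$resid[idx])
  attr(M, "undefined") <- which(v == 0)
  M
}

#' Free-energy landscape over two projection series
#'
#' Two-dimensional histogram of (p1, p2) converted to free energy via
#' `G = -kT ln(P / Pmax)`, `kT = 0.0019872041 * T` kcal/mol. The most
#' populated bin has G = 0 exactly; empty bins are NA (unassigned), never
#' a large constant.
#'
#' @param p1,p2 `time_series` (or numeric vectors) of equal length.
#' @param n_bins bins per axis.
#' @param temperature simulation temperature, K.
#' @param pad fractional range padding on each side.
#' @return object of class `fel_grid`: `x_breaks`, `y_breaks`, `x_mids`,
#'   `y_mids`, `P` (sums to 1), `G` (kcal/mol, NA where empty), `kT`,
#'   `temperature`.
#' @export
free_energy_landscape <- function(p1, p2, n_bins = 50L, temperature = 300,
                                  pad = 0.01) {
  v1 <- if (inherits(p1, "time_series")) p1$values else as.numeric(p1)
  v2 <- if (inherits(p2, "time_series")) p2$values else as.numeric(p2)
  if (length(v1) != length(v2)) stop("p1 and p2 must have equal length")
  kT <- KB_KCAL * temperature
  brk <- function(v) {
    r <- range(v); w <- diff(r)
    if (w == 0) w <- 1
    seq(r[1] - pad * w, r[2] + pad * w, length.out = n_bins + 1L)
  }
  xb <- brk(v1); yb <- brk(v2)
  ix <- pmin(findInterval(v1, xb, rightmost.closed = TRUE), n_bins)
  iy <- pmin(findInterval(v2, yb, rightmost.closed = TRUE), n_bins)
  cnt <- matrix(0, n_bins, n_bins)
  for (t in seq_along(ix)) cnt[ix[t], iy[t]] <- cnt[ix[t], iy[t]] + 1
  P <- cnt / sum(cnt)
  G <- matrix(NA_real_, n_bins, n_bins)
  occ <- P > 0
  G[occ] <- -kT * log(P[occ] / max(P))
  structure(list(x_breaks = xb, y_breaks = yb,
                 x_mids = (xb[-1] + xb[-length(xb)]) / 2,
                 y_mids = (yb[-1] + yb[-length(yb)]) / 2,
                 P = P, G = G, kT = kT, temperature = temperature,
                 frame_bins = cbind(ix, iy)),
            class = "fel_grid")
}

#' Locate free-energy minima and representative frames
#'
#' Candidate minima are occupied bins whose G is less than or equal to
#' that of all 8 neighbours (unoccupied neighbours do not veto) and whose
#' population is at least `min_count` frames (single-frame histogram noise
#' never defines a basin). Candidates are then merged into basins: working
#' upward in G, a candidate reachable from a deeper one through occupied
#' bins of G at most `candidate G + merge_barrier` belongs to the same
#' basin (sampling wiggles around one well do not split it; a real basin
#' separated by a barrier above `merge_barrier`, or by unvisited territory,
#' survives). The representative frame of a basin is the frame whose
#' (p1, p2) lies nearest the minimum-bin centre. Basins are ranked by G.
#'
#' @param grid a `fel_grid`.
#' @param p1,p2 the projection series the grid was built from.
#' @param min_count minimum frames in a bin for it to seed a basin;
#'   default 0.2% of the ensemble (at least 1).
#' @param merge_barrier G tolerance (kcal/mol) below which adjacent
#'   candidate minima are treated as one basin; default kT.
#' @return data.frame: `bin_x`, `bin_y`, `pc1`, `pc2`, `G`, `frame`.
#' @export
locate_minima <- function(grid, p1, p2, min_count = NULL,
                          merge_barrier = grid$kT) {
  v1 <- if (inherits(p1, "time_series")) p1$values else as.numeric(p1)
  v2 <- if (inherits(p2, "time_series")) p2$values else as.numeric(p2)
  if (is.null(min_count)) min_count <- max(1L, ceiling(0.002 * length(v1)))
  G <- grid$G
  counts <- grid$P * length(v1)
  nb <- nrow(G)
  cand <- list()
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (is.na(G[i, j]) || counts[i, j] < min_count) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nb || jj < 1 || jj > nb) next
      if (!is.na(G[ii, jj]) && G[ii, jj] < G[i, j]) ok <- FALSE
    }
    if (ok) cand[[length(cand) + 1L]] <- c(i, j, G[i, j])
  }
  if (!length(cand)) return(data.frame())
  m <- do.call(rbind, cand)
  m <- m[order(m[, 3]), , drop = FALSE]
  basin <- matrix(0L, nb, nb)  # 0 = unclaimed
  keep <- logical(nrow(m))
  n_basin <- 0L
  for (r in seq_len(nrow(m))) {
    i0 <- m[r, 1]; j0 <- m[r, 2]
    if (basin[i0, j0] != 0L) next  # already swallowed by a deeper basin
    lvl <- m[r, 3] + merge_barrier
    # flood fill over occupied bins with G <= lvl
    visited <- matrix(FALSE, nb, nb)
    stack <- list(c(i0, j0)); visited[i0, j0] <- TRUE
    hit_existing <- 0L
    cells <- list()
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      cells[[length(cells) + 1L]] <- p
      if (basin[p[1], p[2]] != 0L && hit_existing == 0L) {
        hit_existing <- basin[p[1], p[2]]
      }
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > nb || jj < 1 || jj > nb || visited[ii, jj]) next
        if (is.na(G[ii, jj]) || G[ii, jj] > lvl) next
        visited[ii, jj] <- TRUE
        stack[[length(stack) + 1L]] <- c(ii, jj)
      }
    }
    if (hit_existing != 0L) {
      for (p in cells) if (basin[p[1], p[2]] == 0L) basin[p[1], p[2]] <- hit_existing
    } else {
      n_basin <- n_basin + 1L
      keep[r] <- TRUE
      for (p in cells) if (basin[p[1], p[2]] == 0L) basin[p[1], p[2]] <- n_basin
    }
  }
  m <- m[keep, , drop = FALSE]
  out <- data.frame(bin_x = m[, 1], bin_y = m[, 2], G = m[, 3])
  out$pc1 <- grid$x_mids[out$bin_x]
  out$pc2 <- grid$y_mids[out$bin_y]
  out$frame <- vapply(seq_len(nrow(out)), function(r) {
    d2 <- (v1 - out$pc1[r])^2 + (v2 - out$pc2[r])^2
    which.min(d2)
  }, integer(1))
  out <- out[order(out$G), ]
  rownames(out) <- NULL
  out[, c("bin_x", "bin_y", "pc1", "pc2", "G", "frame")]
}

#' Export a principal-component mode in NMD (normal-mode) format
#'
#' Writes the mean coordinates and the per-atom displacement vector of mode
#' `k` in the ProDy-style NMD text format used for porcupine-style
#' visualization. The mode vector has unit Euclidean norm before scaling.
#'
#' @param model an `ed_model`.
#' @param top matching `topology`.
#' @param k mode index.
#' @param path output path.
#' @param scale multiplier written with the mode line (defaults to
#'   sqrt(eigenvalue), the RMS amplitude).
#' @return invisibly, `path`.
#' @export
export_porcupine <- function(model, top, k, path, scale = NULL) {
  if (k < 1L || k > length(model$values)) stop("mode index k out of range")
  if (model$values[k] <= 0) {
    stop("zero-variance mode: nothing to export for mode ", k)
  }
  if (is.null(scale)) scale <- sqrt(model$values[k])
  idx <- model$sel
  v <- model$vectors[, k]
  v <- v / sqrt(sum(v^2))
  lines <- c(
    "nmd",
    paste("names", paste(top$atoms$name[idx], collapse = " ")),
    paste("resids", paste(top$atoms$resid[idx], collapse = " ")),
    paste("coordinates", paste(sprintf("%.6f", model$mean), collapse = " ")),
    paste("mode", k, sprintf("%.6f", scale),
          paste(sprintf("%.6f", v), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read an NMD mode file written by [export_porcupine()]
#'
#' @param path NMD file path.
#' @return list: `coordinates` (3N), `mode` (k), `scale`, `vector` (3N,
#'   unit norm).
#' @export
read_nmd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_line <- function(prefix) {
    l <- lines[startsWith(lines, prefix)]
    if (!length(l)) stop("NMD parse error: missing '", prefix, "' line")
    strsplit(trimws(sub(prefix, "", l[1])), "\\s+")[[1]]
  }
  coords <- as.numeric(get_line("coordinates"))
  mode_f <- get_line("mode")
  list(coordinates = coords,
       mode = as.integer(mode_f[1]),
       scale = as.numeric(mode_f[2]),
       vector = as.numeric(mode_f[-(1:2)]))
}

#' Write a free-energy landscape grid as TSV
#' @param grid a `fel_grid`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fel_grid <- function(grid, path) {
  nb <- nrow(grid$P)
  df <- expand.grid(i = seq_len(nb), j = seq_len(nb))
  out <- data.frame(pc1_center = grid$x_mids[df$i],
                    pc2_center = grid$y_mids[df$j],
                    P = grid$P[cbind(df$i, df$j)],
                    G = grid$G[cbind(df$i, df$j)])
  out$G[is.na(out$G)] <- NA
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}
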