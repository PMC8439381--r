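# Low-level vector geometry shared across modules.

.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .vnorm(v)

# angle at b (degrees), for rows or single vectors
.angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# IUPAC-signed torsion a-b-c-d in (-180, 180]
.torsion_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference` over the fit atoms, via singular value
#' decomposition with reflection correction.
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param reference n x 3 coordinate matrix (same atom order).
#' @param fit_idx indices of atoms used for the fit (default: all rows).
#' @return list with `rotation` (3 x 3, det = +1), `translation` (length-3;
#'   the transform is `x %*% rotation + translation`), and `rmsd` (A) over
#'   the fit atoms at the optimum.
#' @export
superpose <- function(mobile, reference, fit_idx = NULL) {
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(mobile))
  if (length(fit_idx) < 3L) stop("degenerate fit: need >= 3 fit atoms")
  A <- mobile[fit_idx, , drop = FALSE]
  B <- reference[fit_idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check: rank of centred fit coordinates
  sv_a <- svd(A0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1)) stop("degenerate fit: fit atoms are collinear")
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)    # so that A0 %*% t(R') ... define for x %*% Rt
  Rt <- t(R)                   # x %*% Rt rotates mobile into reference frame
  moved <- A0 %*% Rt
  rmsd <- sqrt(mean(rowSums((moved - B0)^2)))
  list(rotation = Rt, translation = cb - ca %*% Rt, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param fit result of [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, as.numeric(fit$translation), "+")
}

# Place a point from internal coordinates: distance from c, angle at c with
# b, torsion about c-b relative to a (NeRF construction). Angles in degrees.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180; ph <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Deterministic near-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
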