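# Shared fixture builders (all generated in code; no data files).

# bare chain of n "CA" pseudo-atoms
ca_chain <- function(n, resname = "ALA") {
  topology(data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resname = resname, resid = seq_len(n), chain = "A",
                      stringsAsFactors = FALSE))
}

# donor(O)-H ... acceptor(O) triad with prescribed D-A distance and A-H-D
# angle (H on the D-A axis at 0.96 A, then acceptor swung off-axis)
hbond_triad <- function(da_dist, ahd_angle) {
  d <- c(0, 0, 0)
  h <- c(0.96, 0, 0)
  # place acceptor at distance da_dist from D such that angle at H is ahd
  # solve triangle D-H-A: |DH| = 0.96, angle at H known
  th <- ahd_angle * pi / 180
  # law of cosines for |HA| given |DA| and angle at H
  # |DA|^2 = |DH|^2 + |HA|^2 - 2 |DH||HA| cos(th)
  b <- 0.96
  ha <- b * cos(th) + sqrt(pmax(0, da_dist^2 - b^2 * sin(th)^2))
  a <- h + ha * c(cos(pi - th), sin(pi - th), 0)
  top <- topology(data.frame(
    serial = 1:3, name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
    resname = c("DON", "DON", "ACC"), resid = c(1L, 1L, 2L), chain = "A",
    stringsAsFactors = FALSE), bonds = matrix(c(1L, 2L), ncol = 2))
  list(topology = top, frame = rbind(d, h, a))
}

# random fully parameterized n-atom cluster with a chain of bonds (gives
# nonempty 1-2/1-3/1-4 sets), moderate charges
random_param_system <- function(n, seed, bonded_chain = TRUE) {
  set.seed(seed)
  atoms <- data.frame(
    serial = seq_len(n), name = paste0("X", seq_len(n)), element = "C",
    resname = "RES", resid = rep(seq_len(ceiling(n / 3)), each = 3)[seq_len(n)],
    chain = "A",
    charge = round(runif(n, -0.5, 0.5), 3),
    eps = round(runif(n, 0.05, 0.2), 4),
    rmin_half = round(runif(n, 1.5, 2.0), 4),
    gb_radius = round(runif(n, 1.3, 1.9), 4),
    gb_screen = round(runif(n, 0.7, 0.9), 4),
    stringsAsFactors = FALSE)
  bonds <- if (bonded_chain && n > 1) {
    cbind(seq_len(n - 1L), 2:n)
  } else NULL
  top <- topology(atoms, bonds = bonds)
  coords <- matrix(runif(3 * n, 0, max(6, n / 2)), n, 3)
  # avoid near-coincident atoms
  coords <- coords + 0.3 * matrix(seq_len(3 * n), n, 3)
  list(topology = top, frame = coords)
}

# independent brute-force nonbonded energies: plain double loop with
# explicit exclusion lookups (oracle for mm_energy)
brute_nonbonded <- function(frame, top, eps_in = 1) {
  a <- top$atoms
  n <- nrow(a)
  ex <- top$exclusions
  key <- function(p) paste(p[, 1], p[, 2])
  ex1213 <- c(key(ex$ex12), key(ex$ex13))
  ex14 <- key(ex$ex14)
  e_ele <- 0; e_vdw <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- paste(i, j)
    if (k %in% ex1213) next
    s_e <- if (k %in% ex14) 1 / 1.2 else 1
    s_v <- if (k %in% ex14) 0.5 else 1
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    e_ele <- e_ele + s_e * 332.0637 * a$charge[i] * a$charge[j] / (eps_in * r)
    rij <- a$rmin_half[i] + a$rmin_half[j]
    eij <- sqrt(a$eps[i] * a$eps[j])
    e_vdw <- e_vdw + s_v * eij * ((rij / r)^12 - 2 * (rij / r)^6)
  }
  c(E_ele = e_ele, E_vdw = e_vdw)
}

# independent OBC-II GB: recompute Born radii and pair sum with plain
# loops (oracle for born_radii / gb_polar)
brute_gb <- function(frame, top, eps_in = 1, eps_out = 80, offset = 0.09) {
  a <- top$atoms
  n <- nrow(a)
  rho <- a$gb_radius; rhot <- rho - offset
  R <- numeric(n)
  for (i in seq_len(n)) {
    I <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
      s <- a$gb_screen[j] * rhot[j]
      U <- r + s
      if (rhot[i] >= U) next
      L <- max(rhot[i], abs(r - s))
      t <- 0.5 * (1 / L - 1 / U + 0.25 * (r - s^2 / r) * (1 / U^2 - 1 / L^2) +
                    0.5 * log(L / U) / r)
      if (s >= r + rhot[i]) t <- t + (1 / rhot[i] - 1 / L)
      I <- I + t
    }
    psi <- I * rhot[i]
    R[i] <- 1 / (1 / rhot[i] - tanh(1.0 * psi - 0.8 * psi^2 + 4.85 * psi^3) / rho[i])
  }
  g <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((frame[i, ] - frame[j, ])^2)
    f <- sqrt(r2 + R[i] * R[j] * exp(-r2 / (4 * R[i] * R[j])))
    g <- g - 0.5 * 332.0637 * (1 / eps_in - 1 / eps_out) *
      a$charge[i] * a$charge[j] / f
  }
  list(radii = R, G_GB = g)
}
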