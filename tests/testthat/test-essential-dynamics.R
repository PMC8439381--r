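test_that("fit_to_mean converges immediately on aligned input and undoes rigid motion", {
  top <- ca_chain(10)
  set.seed(2)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  ens <- gaussian_ensemble(ref, 0.09, 60, seed = 3)
  # an ensemble already at the fitted fixed point converges in one pass
  pre <- fit_to_mean(ens, top, "all")
  ft0 <- fit_to_mean(pre$ensemble, top, "all")
  expect_equal(ft0$iterations, 1L)
  # per-frame RMSD to the mean is restored after random rigid motions
  base <- ft0$ensemble
  rms_to_mean <- function(e, mu) {
    vapply(seq_len(n_frames(e)), function(f) {
      sqrt(mean(rowSums((frame_coords(e, f) - mu)^2)))
    }, numeric(1))
  }
  r0 <- rms_to_mean(base, ft0$mean)
  arr <- base$coords
  set.seed(11)
  for (f in seq_len(dim(arr)[1])) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    arr[f, , ] <- matrix(arr[f, , ], ncol = 3) %*% R +
      matrix(runif(3, -8, 8), 10, 3, byrow = TRUE)
  }
  ft1 <- fit_to_mean(ensemble(arr), top, "all")
  r1 <- rms_to_mean(ft1$ensemble, ft1$mean)
  expect_equal(r1, r0, tolerance = 1e-6)
})

test_that("covariance: zero for static input, sampled variances, trace identity", {
  top <- ca_chain(6)
  x <- matrix(rnorm(18, sd = 4), 6, 3)
  arr <- array(NA_real_, c(2, 6, 3)); arr[1, , ] <- x; arr[2, , ] <- x
  C0 <- covariance_matrix(ensemble(arr), top, "all")
  expect_true(all(abs(C0) < 1e-12))
  expect_error(covariance_matrix(ensemble(array(x, c(1, 6, 3))), top),
               "2 frames")
  ens <- gaussian_ensemble(x, 0.25, 5000, seed = 21)
  C <- covariance_matrix(ens, top, "all")
  expect_true(all(abs(diag(C) - 0.25) < 0.025))
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 0.03)
})

test_that("principal components: degenerate cases and spectral identity", {
  v <- c(1, 2, 3, 4) / sqrt(30)
  m1 <- principal_components(outer(v, v) * 5)
  expect_equal(m1$frac[1], 1, tolerance = 1e-12)
  iso <- principal_components(diag(0.5, 9))
  expect_equal(iso$frac, rep(1 / 9, 9), tolerance = 1e-12)
  expect_equal(sum(iso$frac), 1, tolerance = 1e-12)
  set.seed(4)
  A <- crossprod(matrix(rnorm(64), 8, 8))
  m <- principal_components(A)
  recon <- m$vectors %*% diag(m$values) %*% t(m$vectors)
  expect_lt(norm(recon - A, "F"), 1e-8)
  expect_true(all(diff(m$values) <= 1e-12))
  # sign convention: largest-magnitude component positive
  for (k in 1:8) {
    expect_gte(m$vectors[which.max(abs(m$vectors[, k])), k], 0)
  }
  B <- A; B[1, 2] <- B[1, 2] + 1
  expect_error(principal_components(B), "symmetric")
})

test_that("projections: mean maps to zero, variance equals eigenvalue", {
  top <- ca_chain(8)
  set.seed(5)
  ref <- matrix(rnorm(24, sd = 5), 8, 3)
  ens <- gaussian_ensemble(ref, 0.16, 3000, seed = 6)
  ft <- fit_to_mean(ens, top, "all")
  C <- covariance_matrix(ft$ensemble, top, "all")
  m <- principal_components(C)
  p1 <- project_mode(ft$ensemble, m, 1)
  # ensemble-average variance convention (1/n), matching the covariance
  v1 <- mean(p1$values^2) - mean(p1$values)^2
  expect_equal(v1, m$values[1], tolerance = 1e-6)
  expect_equal(mean(p1$values), 0, tolerance = 1e-8)
  p2 <- project_mode(ft$ensemble, m, 2)
  cov12 <- mean(p1$values * p2$values) - mean(p1$values) * mean(p2$values)
  expect_lt(abs(cov12), 1e-8)
  expect_error(project_mode(ft$ensemble, m, 99), "out of range")
})

test_that("PCA recovers a planted low-rank covariance", {
  set.seed(99)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  V <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  lam <- c(4, 2, 1)
  ens <- gaussian_ensemble(ref, list(vectors = V, values = lam, iso = 0.01),
                           5000, seed = 7)
  top <- ca_chain(10)
  C <- covariance_matrix(ens, top, "all")  # generator output is aligned
  m <- principal_components(C)
  expect_true(all(abs(m$values[1:3] - (lam + 0.01)) / (lam + 0.01) < 0.10))
  ang <- acos(pmin(1, svd(t(V) %*% m$vectors[, 1:3])$d)) * 180 / pi
  expect_lt(max(ang), 5)
})

test_that("DCCM: unit diagonal, perfect anticorrelation, independence bound", {
  top <- ca_chain(2)
  arr <- array(NA_real_, c(200, 2, 3))
  set.seed(8)
  for (f in 1:200) {
    d <- rnorm(3, sd = 0.3)
    arr[f, 1, ] <- c(0, 0, 0) + d
    arr[f, 2, ] <- c(5, 0, 0) - d
  }
  M <- dccm_matrix(ensemble(arr), top, "all")
  expect_equal(diag(M), c(`1` = 1, `2` = 1))
  expect_equal(M[1, 2], -1, tolerance = 1e-9)
  # independent atoms stay near zero at 5000 frames
  topn <- ca_chain(6)
  ens <- gaussian_ensemble(matrix(rnorm(18, sd = 5), 6, 3), 0.2, 5000,
                           seed = 9)
  Mi <- dccm_matrix(ens, topn, "all")
  expect_lt(max(abs(Mi[upper.tri(Mi)])), 0.1)
  # zero-variance atom flagged as undefined
  arr2 <- arr; arr2[, 2, ] <- 1.5
  M2 <- dccm_matrix(ensemble(arr2), top, "all")
  expect_true(is.na(M2[1, 2]))
  expect_equal(attr(M2, "undefined"), 2L)
})

test_that("free-energy landscape follows G = -kT ln(P/Pmax)", {
  # engineered counts: 40 frames at the mode, 40/e ~ 15 in a second bin
  p1 <- c(rep(0, 400), rep(5, 147))
  p2 <- rep(0, length(p1))
  g <- free_energy_landscape(p1, p2, n_bins = 10, temperature = 300)
  kT <- 0.0019872041 * 300
  occupied <- sort(g$G[!is.na(g$G)])
  expect_equal(occupied[1], 0)
  expect_equal(occupied[2], -kT * log(147 / 400), tolerance = 1e-9)
  expect_equal(sum(g$P), 1, tolerance = 1e-12)
  # a bin with P = Pmax/e sits exactly kT above the minimum
  expect_equal(-kT * log(1 / exp(1)), kT, tolerance = 1e-12)
  # empty bins are NA, not zero or a large constant
  expect_true(anyNA(g$G))
})

test_that("FEL is invariant under joint frame reordering", {
  set.seed(10)
  p1 <- rnorm(500); p2 <- rnorm(500)
  g1 <- free_energy_landscape(p1, p2, n_bins = 20)
  o <- sample.int(500)
  g2 <- free_energy_landscape(p1[o], p2[o], n_bins = 20)
  expect_equal(g1$G, g2$G)
})

test_that("minima: one basin for a Gaussian, two for a two-state mixture", {
  set.seed(11)
  p1 <- rnorm(4000); p2 <- rnorm(4000)
  g <- free_energy_landscape(p1, p2, n_bins = 30)
  mins <- locate_minima(g, p1, p2)
  expect_equal(nrow(mins), 1L)
  expect_lt(abs(mins$pc1), 3 * diff(g$x_mids[1:2]))
  # single-frame grid: one occupied bin, one minimum
  gs <- free_energy_landscape(0.5, -0.2, n_bins = 5)
  ms <- locate_minima(gs, 0.5, -0.2)
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$G, 0)
  # two-state ensemble through the full PCA path
  r1 <- matrix(0, 5, 3); r2 <- r1; r2[, 1] <- 3
  tt <- ca_chain(5)
  ts <- two_state_ensemble(r1, r2, 0.8, 0.15, 5000, seed = 11)
  C <- covariance_matrix(ts, tt, "all")
  m <- principal_components(C)
  q1 <- project_mode(ts, m, 1); q2 <- project_mode(ts, m, 2)
  gg <- free_energy_landscape(q1, q2, n_bins = 50)
  mm <- locate_minima(gg, q1, q2)
  expect_equal(nrow(mm), 2L)
  # representative frames belong to the right states
  labs <- attr(ts, "state_labels")
  expect_true(labs[mm$frame[1]] != labs[mm$frame[2]])
})

test_that("NMD export round-trips and refuses a zero-variance system", {
  top <- ca_chain(6)
  ens <- gaussian_ensemble(matrix(rnorm(18, sd = 4), 6, 3), 0.2, 200,
                           seed = 12)
  ft <- fit_to_mean(ens, top, "all")
  m <- principal_components(covariance_matrix(ft$ensemble, top, "all"))
  tf <- tempfile(fileext = ".nmd")
  export_porcupine(m, top, 1, tf)
  nmd <- read_nmd(tf)
  expect_equal(sqrt(sum(nmd$vector^2)), 1, tolerance = 1e-6)
  v <- m$vectors[, 1] / sqrt(sum(m$vectors[, 1]^2))
  expect_equal(nmd$vector, v, tolerance = 1e-5)
  expect_equal(nmd$coordinates, unname(m$mean), tolerance = 1e-5)
  zero <- principal_components(matrix(0, 6, 6))
  expect_error(export_porcupine(zero, top, 1, tf), "zero-variance")
})
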