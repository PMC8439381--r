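test_that("superposition is exact for identity and rigid motions", {
  set.seed(1)
  x <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_lt(superpose(x, x)$rmsd, 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  y <- x %*% R + matrix(c(3, -2, 5), 10, 3, byrow = TRUE)
  fit <- superpose(y, x)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(x[1:2, ], x[1:2, ]), "degenerate")
  col <- cbind(1:5, 0, 0)
  expect_error(superpose(col, col), "collinear")
})

test_that("planar-square superposition matches exhaustive rotation search", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  dist <- rbind(c(-0.05, 0.02, 0), c(1.04, -0.03, 0), c(0.97, 1.06, 0),
                c(0.02, 0.95, 0))
  fit <- superpose(dist, sq)
  # brute force: both planar and centred, so optimum is a rotation about z
  a0 <- sweep(dist, 2, colMeans(dist)); b0 <- sweep(sq, 2, colMeans(sq))
  best <- Inf
  for (deg in seq(0, 359.75, by = 0.25)) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    best <- min(best, sqrt(mean(rowSums((a0 %*% R - b0)^2))))
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-3)
})

test_that("rmsd series: zeros for identical frames, hand value for a shift", {
  tc <- toy_complex(n_frames = 1, seed = 1)
  arr <- array(NA_real_, c(3, n_atoms(tc$topology), 3))
  for (f in 1:3) arr[f, , ] <- frame_coords(tc$ensemble, 1)
  same <- ensemble(arr)
  ts <- rmsd_series(same, tc$topology, reference = 1, fit_sel = "all")
  expect_true(all(ts$values < 1e-9))
  # half the measured atoms shifted 1 A after perfect fit of the other half
  f1 <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0),
              c(5, 5, 3), c(2, 8, 1), c(7, 3, 2), c(9, 9, 4))
  f2 <- f1; f2[5:8, 3] <- f2[5:8, 3] + 1
  arr <- array(NA_real_, c(2, 8, 3)); arr[1, , ] <- f1; arr[2, , ] <- f2
  t8 <- ca_chain(8)
  ts2 <- rmsd_series(ensemble(arr), t8, reference = 1, fit_sel = 1:4,
                     measure_sel = 1:8)
  expect_equal(ts2$values[2], sqrt(0.5), tolerance = 1e-9)
})

test_that("rmsf matches the 3-D Gaussian closed form and the trace identity", {
  top <- ca_chain(50)
  set.seed(10)
  ref <- matrix(rnorm(150, sd = 8), 50, 3)
  ens <- gaussian_ensemble(ref, 0.25, 2000, seed = 4)
  rf <- rmsf(ens, top, "all")
  expect_equal(mean(rf$rmsf), sqrt(3) * 0.5, tolerance = 0.05)
  ft <- fit_to_mean(ens, top, "all")
  C <- covariance_matrix(ft$ensemble, top, "all")
  expect_equal(sum(diag(C)), sum(rf$rmsf^2), tolerance = 1e-9)
  expect_error(rmsf(ensemble(ref), top), "2 frames")
})

test_that("radius of gyration: symmetry cases and direct-formula oracle", {
  top <- ca_chain(2)
  arr <- array(NA_real_, c(1, 2, 3))
  arr[1, , ] <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(ensemble(arr), top, "all",
                                  mass_weighted = FALSE)$values, 1.0)
  expect_equal(radius_of_gyration(ensemble(arr), top, 1L)$values, 0)
  set.seed(3)
  n <- 50
  topn <- ca_chain(n)
  x <- matrix(rnorm(3 * n, sd = 6), n, 3)
  rg <- radius_of_gyration(ensemble(x), topn, "all", mass_weighted = FALSE)
  cm <- colMeans(x)
  direct <- sqrt(sum(sweep(x, 2, cm)^2) / n)
  expect_equal(rg$values, direct, tolerance = 1e-9)
})

test_that("SASA: sphere closed form, additivity, fused-sphere cap oracle", {
  one <- topology(data.frame(serial = 1, name = "C", element = "C",
                             resname = "LIG", resid = 1, chain = "A",
                             vdw_radius = 1.7))
  s1 <- sasa(matrix(0, 1, 3), one, n_sphere_points = 960)
  expect_equal(s1$total, 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)
  two <- topology(data.frame(serial = 1:2, name = "C", element = "C",
                             resname = "LIG", resid = 1:2, chain = "A",
                             vdw_radius = 1.7))
  far <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), two, n_sphere_points = 960)
  expect_equal(far$total, 2 * s1$total, tolerance = 1e-9)
  # fused spheres at 2 A: exact exposed area from the spherical-cap
  # formula A_i = 2 pi R_i (R_i + (d^2 + R_i^2 - R_j^2) / (2 d))
  d <- 2; R <- 3.1
  exact <- 2 * (2 * pi * R * (R + d / 2))
  fused <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), two, n_sphere_points = 960)
  expect_equal(fused$total, exact, tolerance = 0.02 * exact)
})

test_that("SASA is monotonically non-increasing as two atoms approach", {
  two <- topology(data.frame(serial = 1:2, name = "C", element = "C",
                             resname = "LIG", resid = 1:2, chain = "A",
                             vdw_radius = 1.7))
  prev <- Inf
  for (d in seq(8, 0.5, by = -0.5)) {
    tot <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), two,
                n_sphere_points = 480)$total
    expect_lte(tot, prev + 1e-9)
    prev <- tot
  }
})

test_that("angles, torsions, triangle areas: closed forms and Heron oracle", {
  top <- ca_chain(4)
  arr <- array(NA_real_, c(1, 4, 3))
  arr[1, , ] <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))
  e <- ensemble(arr)
  expect_equal(angle_series(e, top, 1, 2, 3)$values, 90)
  arr2 <- arr; arr2[1, 3, ] <- c(-1, 0, 0)
  expect_equal(angle_series(ensemble(arr2), top, 1, 2, 3)$values, 180)
  # coplanar four atoms: torsion is 0 or 180
  tv <- torsion_series(e, top, 1, 2, 3, 4)$values
  expect_true(abs(tv) < 1e-9 || abs(abs(tv) - 180) < 1e-9)
  # IUPAC sign: positive torsion for a right-handed twist
  arr3 <- arr; arr3[1, 4, ] <- c(0.5, 1, 0.8)
  tv3 <- torsion_series(ensemble(arr3), top, 1, 2, 3, 4)$values
  arr4 <- arr3; arr4[1, 4, 3] <- -0.8
  tv4 <- torsion_series(ensemble(arr4), top, 1, 2, 3, 4)$values
  expect_equal(tv3, -tv4, tolerance = 1e-9)
  # triangle area: unit right triangle then Heron on random triples
  expect_equal(triangle_area_series(e, top, 2, 1, 3)$values, 0.5)
  set.seed(7)
  for (k in 1:5) {
    arr5 <- array(rnorm(12, sd = 3), c(1, 4, 3))
    x <- matrix(arr5[1, , ], ncol = 3)
    a <- sqrt(sum((x[1, ] - x[2, ])^2)); b <- sqrt(sum((x[2, ] - x[3, ])^2))
    cc <- sqrt(sum((x[1, ] - x[3, ])^2)); s <- (a + b + cc) / 2
    heron <- sqrt(max(0, s * (s - a) * (s - b) * (s - cc)))
    expect_equal(triangle_area_series(ensemble(arr5), top, 1, 2, 3)$values,
                 heron, tolerance = 1e-9)
  }
  # collinear triple has zero area
  arr6 <- array(0, c(1, 4, 3)); arr6[1, , 1] <- 1:4
  expect_equal(triangle_area_series(ensemble(arr6), top, 1, 2, 3)$values, 0)
  expect_error(distance_series(e, top, 1, 1), "distinct")
})

test_that("contact shell applies strict threshold and class priority", {
  # centre atom at origin; residues with nearest heavy atoms at 3.9 / 4.1 A
  atoms <- data.frame(
    serial = 1:4,
    name = c("C1", "CD1", "OG", "CD2"),
    element = c("C", "C", "O", "C"),
    resname = c("LIG", "LEU", "SER", "LEU"),
    resid = c(1L, 10L, 11L, 12L), chain = c("L", "A", "A", "A"),
    stringsAsFactors = FALSE)
  top <- topology(atoms)
  fr <- rbind(c(0, 0, 0), c(3.9, 0, 0), c(0, 3.2, 0), c(4.1, 0, 0))
  ct <- contact_shell(fr, top, "chain L", shell_radius = 4.0,
                      classify = TRUE)
  expect_setequal(ct$resid, c(10L, 11L))
  expect_equal(ct$class[ct$resid == 10], "hydrophobic")
  expect_equal(ct$class[ct$resid == 11], "polar")
  expect_equal(attr(ct, "shell_radius"), 4.0)
})

test_that("histogram summary normalizes and handles edge cases", {
  h1 <- histogram_summary(rep(3.3, 50), n_bins = 10)
  expect_equal(sum(h1$prob), 1)
  expect_equal(length(h1$prob), 1L)
  set.seed(12)
  h2 <- histogram_summary(runif(10000), n_bins = 10)
  expect_equal(sum(h2$prob), 1, tolerance = 1e-12)
  # each bin 0.1 within a generous binomial bound (4 sigma ~ 0.012)
  expect_true(all(abs(h2$prob - 0.1) < 0.015))
  expect_error(histogram_summary(numeric(0)), "empty")
})
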