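empty_top <- function() {
  topology(data.frame(serial = 1L, name = "C", element = "C",
                      resname = "XXX", resid = 1L, chain = "A"))
}

far_frame <- function() ensemble(matrix(c(500, 500, 500), 1, 3))

test_that("empty inclusion sphere recovers the analytic volume", {
  reg <- build_region(list(list(center = c(0, 0, 0), radius = 5)),
                      spacing = 0.5)
  vs <- pocket_volume_series(far_frame(), empty_top(), reg,
                             occluder_sel = "none")
  expect_equal(vs$volume, 4 / 3 * pi * 125, tolerance = 0.02 * 4 / 3 * pi * 125)
  expect_equal(vs$volume, vs$n_points * 0.5^3)
})

test_that("halving the spacing changes the empty-sphere volume by < 1%", {
  mk <- function(sp) {
    reg <- build_region(list(list(center = c(0, 0, 0), radius = 6)),
                        spacing = sp)
    pocket_volume_series(far_frame(), empty_top(), reg,
                         occluder_sel = "none")$volume
  }
  expect_lt(abs(mk(0.5) / mk(0.25) - 1), 0.01)
})

test_that("overlapping inclusions form a union; exclusions subtract", {
  # two coincident spheres must not double count
  reg1 <- build_region(list(list(center = c(0, 0, 0), radius = 4),
                            list(center = c(0, 0, 0), radius = 4)),
                       spacing = 0.5)
  reg2 <- build_region(list(list(center = c(0, 0, 0), radius = 4)),
                       spacing = 0.5)
  v1 <- pocket_volume_series(far_frame(), empty_top(), reg1,
                             occluder_sel = "none")$volume
  v2 <- pocket_volume_series(far_frame(), empty_top(), reg2,
                             occluder_sel = "none")$volume
  expect_equal(v1, v2)
  # exclusion wholly inside the inclusion removes its own volume
  reg3 <- build_region(list(list(center = c(0, 0, 0), radius = 5)),
                       exclusion = list(list(center = c(0, 0, 0), radius = 2)),
                       spacing = 0.4)
  reg4 <- build_region(list(list(center = c(0, 0, 0), radius = 5)),
                       spacing = 0.4)
  v3 <- pocket_volume_series(far_frame(), empty_top(), reg3,
                             occluder_sel = "none")$volume
  v4 <- pocket_volume_series(far_frame(), empty_top(), reg4,
                             occluder_sel = "none")$volume
  expect_equal(v4 - v3, 4 / 3 * pi * 8, tolerance = 0.05 * 4 / 3 * pi * 8)
})

test_that("occluded volume matches Monte-Carlo rejection sampling", {
  set.seed(14)
  n <- 12
  atoms <- data.frame(serial = seq_len(n), name = "C", element = "C",
                      resname = "PRO", resid = seq_len(n), chain = "A",
                      vdw_radius = 1.7)
  top <- topology(atoms)
  x <- matrix(runif(3 * n, -4, 4), n, 3)
  reg <- build_region(list(list(center = c(0, 0, 0), radius = 6)),
                      spacing = 0.5, padding = 1.09)
  vs <- pocket_volume_series(ensemble(x), top, reg, occluder_sel = "all")
  # MC oracle: rejection sampling in the bounding cube
  m <- 2e5
  pts <- matrix(runif(3 * m, -6, 6), m, 3)
  inside <- rowSums(pts^2) <= 36
  for (i in seq_len(n)) {
    inside <- inside & rowSums(sweep(pts, 2, x[i, ])^2) > (1.7 + 1.09)^2
  }
  mc <- 12^3 * mean(inside)
  expect_equal(vs$volume, mc, tolerance = 0.03 * mc)
})

test_that("volume is monotone in occupancy and zero when fully packed", {
  reg <- build_region(list(list(center = c(0, 0, 0), radius = 4)),
                      spacing = 0.5)
  prev <- Inf
  for (n in c(1, 4, 8, 16)) {
    set.seed(n)
    atoms <- data.frame(serial = seq_len(n), name = "C", element = "C",
                        resname = "PRO", resid = seq_len(n), chain = "A",
                        vdw_radius = 1.7)
    top <- topology(atoms)
    x <- matrix(runif(3 * n, -2.5, 2.5), n, 3)
    # nested atom sets: reuse the first n of a fixed pool
    set.seed(42)
    pool <- matrix(runif(48, -2.5, 2.5), 16, 3)
    v <- pocket_volume_series(ensemble(pool[seq_len(n), , drop = FALSE]),
                              top, reg, occluder_sel = "all")$volume
    expect_lte(v, prev + 1e-9)
    prev <- v
  }
  # one huge atom covering the sphere
  big <- topology(data.frame(serial = 1L, name = "C", element = "C",
                             resname = "PRO", resid = 1L, chain = "A",
                             vdw_radius = 10))
  expect_warning(
    v0 <- pocket_volume_series(ensemble(matrix(0, 1, 3)), big, reg,
                               occluder_sel = "all")$volume,
    "empty")
  expect_equal(v0, 0)
})

test_that("volume is invariant under joint rigid transformation", {
  set.seed(15)
  n <- 6
  atoms <- data.frame(serial = seq_len(n), name = "C", element = "C",
                      resname = "PRO", resid = seq_len(n), chain = "A",
                      vdw_radius = 1.7)
  top <- topology(atoms)
  x <- matrix(runif(3 * n, -3, 3), n, 3)
  ctr <- c(0.5, -0.3, 0.2)
  reg <- build_region(list(list(center = ctr, radius = 5)), spacing = 0.5)
  v0 <- pocket_volume_series(ensemble(x), top, reg,
                             occluder_sel = "all")$volume
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr <- c(7, -4, 11)
  reg2 <- build_region(list(list(center = as.numeric(ctr %*% R + tr),
                                 radius = 5)), spacing = 0.5)
  v1 <- pocket_volume_series(ensemble(x %*% R + matrix(tr, n, 3, byrow = TRUE)),
                             top, reg2, occluder_sel = "all")$volume
  # grid registration shifts allow a one-shell difference
  expect_equal(v1, v0, tolerance = 0.05 * v0)
})

test_that("atom-anchored inclusion centres track the trajectory", {
  top <- ca_chain(1)
  arr <- array(NA_real_, c(2, 1, 3))
  arr[1, , ] <- c(0, 0, 0); arr[2, , ] <- c(50, 0, 0)
  reg <- build_region(list(list(center = "name CA", radius = 4)),
                      spacing = 0.5)
  vs <- pocket_volume_series(ensemble(arr), top, reg, occluder_sel = "none")
  # the sphere follows the atom, so both frames give the same volume
  expect_equal(vs$volume[1], vs$volume[2])
  expect_gt(vs$volume[1], 200)
})
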