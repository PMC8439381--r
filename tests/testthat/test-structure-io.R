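pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     altloc = " ", occ = 1.00, record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, paste0(" ", name), altloc, resname, chain, resid,
          x, y, z, occ, 0)
}

test_that("multi-model PDB reads one ensemble frame per MODEL", {
  tf <- tempfile(fileext = ".pdb")
  body <- function(shift) {
    vapply(1:5, function(i) {
      pdb_line(i, "CA", "ALA", "A", i, i * 1.5 + shift, 0, 0)
    }, character(1))
  }
  writeLines(c("MODEL        1", body(0), "ENDMDL",
               "MODEL        2", body(1), "ENDMDL",
               "MODEL        3", body(2), "ENDMDL", "END"), tf)
  st <- read_structure(tf)
  expect_equal(n_frames(st$ensemble), 3L)
  expect_equal(n_atoms(st$topology), 5L)
  expect_equal(st$ensemble$coords[2, 1, 1], 2.5)
})

test_that("altloc resolution keeps highest occupancy, ties favour A", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0, altloc = "A", occ = 0.6),
    pdb_line(2, "CA", "ALA", "A", 1, 2, 0, 0, altloc = "B", occ = 0.4),
    pdb_line(3, "CB", "ALA", "A", 1, 3, 0, 0, altloc = "A", occ = 0.3),
    pdb_line(4, "CB", "ALA", "A", 1, 4, 0, 0, altloc = "B", occ = 0.7),
    "END"), tf)
  st <- read_structure(tf)
  expect_equal(n_atoms(st$topology), 2L)
  # CA: A wins on occupancy; CB: B wins on occupancy
  expect_equal(st$ensemble$coords[1, , 1], c(1, 4))
})

test_that("malformed and empty PDB inputs fail with location", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0),
               "ATOM      2  CB ALA A   1      bad_x   0.000   0.000"), tf)
  expect_error(read_structure(tf), "line 2")
  tf2 <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), tf2)
  expect_error(read_structure(tf2), "empty input")
})

test_that("PDB round trip preserves identity exactly, coordinates to 3 dp", {
  tc <- toy_complex(n_frames = 3, seed = 2)
  tf <- tempfile(fileext = ".pdb")
  write_structure(tc$topology, tc$ensemble, tf)
  rt <- read_structure(tf)
  expect_identical(rt$topology$atoms$name, tc$topology$atoms$name)
  expect_identical(rt$topology$atoms$resid, tc$topology$atoms$resid)
  expect_identical(rt$topology$atoms$chain, tc$topology$atoms$chain)
  expect_equal(rt$ensemble$coords, round(tc$ensemble$coords, 3),
               tolerance = 1e-9)
  # HETATM flag survives the round trip
  expect_true(all(rt$topology$atoms$is_het[rt$topology$atoms$resname == "LIG"]))
})

test_that("DCD round trip is exact to single precision, stride works", {
  tc <- toy_complex(n_frames = 10, seed = 5)
  td <- tempfile(fileext = ".dcd")
  write_trajectory(tc$ensemble, td)
  rd <- read_trajectory(tc$topology, td, "dcd")
  expect_lt(max(abs(rd$coords - tc$ensemble$coords)), 1e-4)
  rs <- read_trajectory(tc$topology, td, "dcd", stride = 3)
  expect_equal(n_frames(rs), 4L)  # frames 1, 4, 7, 10
  expect_equal(rs$coords[2, , ], rd$coords[4, , ])
  wrong <- ca_chain(4)
  expect_error(read_trajectory(wrong, td, "dcd"), "mismatch")
})

test_that("parameter table populates all fields and builds exclusions", {
  # TIP3P-style water
  atoms <- data.frame(serial = 1:3, name = c("O", "H1", "H2"),
                      element = c("O", "H", "H"), resname = "WAT",
                      resid = 1L, chain = "W", stringsAsFactors = FALSE)
  top <- topology(atoms, bonds = matrix(c(1L, 2L, 1L, 3L), ncol = 2,
                                        byrow = TRUE))
  tf <- tempfile()
  writeLines(c("resname name charge eps rmin_half gb_radius gb_screen",
               "WAT O -0.834 0.152 1.7683 1.5 0.85",
               "WAT H1 0.417 0.0 0.0001 1.2 0.85",
               "WAT H2 0.417 0.0 0.0001 1.2 0.85"), tf)
  pt <- read_parameters(top, tf)
  expect_true(is_parameterized(pt))
  expect_lt(abs(sum(pt$atoms$charge)), 1e-6)
  expect_equal(nrow(pt$exclusions$ex12), 2L)
  expect_equal(pt$exclusions$ex13, matrix(c(2L, 3L), 1))
  # missing rows are reported by atom
  writeLines(c("resname name charge eps rmin_half gb_radius gb_screen",
               "WAT O -0.834 0.152 1.7683 1.5 0.85"), tf)
  expect_error(read_parameters(top, tf), "incomplete parameterization")
})

test_that("exclusion sets: none without bonds, 1-2 for a diatomic", {
  top <- ca_chain(2)
  expect_equal(nrow(build_exclusions(top)$ex12), 0L)
  top2 <- topology(top$atoms, bonds = matrix(c(1L, 2L), ncol = 2))
  expect_equal(top2$exclusions$ex12, matrix(c(1L, 2L), 1))
  expect_equal(nrow(top2$exclusions$ex13), 0L)
})

test_that("selection grammar resolves deterministically and reports errors", {
  tc <- toy_complex(seed = 1)
  top <- tc$topology
  expect_equal(length(select_atoms(top, "name CA and resid 2")), 1L)
  expect_equal(length(select_atoms(top, "chain L")), 3L)
  expect_equal(as.integer(select_atoms(top, "resid 1:3 and chain R")), 1:9)
  expect_equal(length(select_atoms(top, "not element H")), n_atoms(top))
  # idempotent + sorted
  s <- select_atoms(top, "element O or chain L")
  expect_identical(as.integer(s), sort(unique(as.integer(s))))
  expect_error(select_atoms(top, "bogus CA"), "position 1")
  expect_error(select_atoms(top, "name CA and (resid 2"), "missing '\\)'")
  expect_error(select_atoms(top, "resid x"), "bad resid")
})

test_that("selection algebra |A or B| + |A and B| = |A| + |B|", {
  tc <- toy_complex(seed = 1)
  top <- tc$topology
  exprs <- c("element O", "resid 2", "chain L", "name CA CB", "resid 1:2",
             "not chain L")
  for (i in seq_along(exprs)) for (j in seq_along(exprs)) {
    a <- length(select_atoms(top, exprs[i]))
    b <- length(select_atoms(top, exprs[j]))
    or_ab <- length(select_atoms(top, paste(exprs[i], "or", exprs[j])))
    and_ab <- length(select_atoms(top, paste(exprs[i], "and", exprs[j])))
    expect_equal(or_ab + and_ab, a + b)
  }
})

test_that("water detection uses the configured residue-name set", {
  atoms <- data.frame(serial = 1:2, name = "O", element = "O",
                      resname = c("HOH", "XYZ"), resid = 1:2, chain = "A")
  top <- topology(atoms)
  expect_equal(as.integer(select_atoms(top, "water")), 1L)
  top2 <- topology(atoms, water_resnames = c("XYZ"))
  expect_equal(as.integer(select_atoms(top2, "water")), 2L)
})

test_that("pairwise sequence identity counts aligned identical columns", {
  expect_equal(sequence_identity("AAGT", "AAGT")$identity, 100)
  r <- sequence_identity("AAAA", "AATA")
  expect_equal(r$identity, 75)
  expect_equal(r$n_aligned, 4L)
  # a gap costs alignment columns but identity is over aligned pairs only
  g <- sequence_identity("ACDEFG", "ACEFG")
  expect_equal(g$n_identical, 5L)
  expect_error(sequence_identity("", "A"), "empty")
})
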