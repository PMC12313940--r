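test_that("noiseless construction realises the requested distances exactly", {
  b <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9)
  r <- b$truth$realized
  expect_equal(r$d_OG_NE2, 2.8, tolerance = 1e-6)
  expect_equal(r$d_ND1_acidO, 4.0, tolerance = 1e-6)
  expect_equal(r$d_ND1_water, 2.9, tolerance = 1e-6)
  expect_equal(r$d_water_acidO, 2.9, tolerance = 1e-6)
  # arbitrary other geometry, all four acid types
  for (acid in c("ASP", "ASN", "GLU", "GLN")) {
    b2 <- build_site_fixture("WATER_MEDIATED_TRIAD", 3.1, 4.3, 2.7, 3.0,
                             acid_resname = acid)
    r2 <- b2$truth$realized
    expect_equal(r2$d_ND1_acidO, 4.3, tolerance = 1e-6)
    expect_equal(r2$d_ND1_water, 2.7, tolerance = 1e-6)
    expect_equal(r2$d_water_acidO, 3.0, tolerance = 1e-6)
  }
})

test_that("contradictory or unsatisfiable specs are refused", {
  expect_error(build_site_fixture("WATER_MEDIATED_TRIAD", d_ND1_acidO = 2.5),
               "contradictory")
  expect_error(build_site_fixture("CONVENTIONAL_TRIAD", d_ND1_acidO = 3.5),
               "contradictory")
  # triangle violation: 2.2 + 2.2 < 6
  expect_error(build_site_fixture("WATER_MEDIATED_TRIAD", 2.8,
                                  d_ND1_acidO = 6.0, d_ND1_water = 2.2,
                                  d_water_acidO = 2.2),
               "triangle")
  expect_error(build_rotamer_fixture(-1), "unreachable")
})

test_that("fixtures are seeded-deterministic and differ across seeds", {
  a <- build_site_fixture("WATER_MEDIATED_TRIAD", noise_sigma = 0.1, seed = 1)
  b <- build_site_fixture("WATER_MEDIATED_TRIAD", noise_sigma = 0.1, seed = 1)
  c2 <- build_site_fixture("WATER_MEDIATED_TRIAD", noise_sigma = 0.1, seed = 2)
  expect_identical(a$structure$atoms, b$structure$atoms)
  expect_false(isTRUE(all.equal(a$structure$atoms$x, c2$structure$atoms$x)))
  expect_error(build_site_fixture("BARE_DYAD", noise_sigma = 0.1), "seed")
  # byte-identical files from the same seed
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  build_site_fixture("CONVENTIONAL_TRIAD", noise_sigma = 0.05, seed = 9,
                     path = p1)
  build_site_fixture("CONVENTIONAL_TRIAD", noise_sigma = 0.05, seed = 9,
                     path = p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("panel generation is balanced, reproducible and label-recoverable", {
  p1 <- build_panel(3, sigma = 0, seed = 17)
  p2 <- build_panel(3, sigma = 0, seed = 17)
  expect_length(p1, 12L)
  expect_identical(lapply(p1, function(b) b$structure$atoms),
                   lapply(p2, function(b) b$structure$atoms))
  labs <- vapply(p1, function(b) b$truth$label, character(1))
  expect_equal(unname(table(labs)[unique(labs)]), rep(3L, 4),
               ignore_attr = TRUE)
  # noiseless labels recoverable at 100%
  got <- vapply(p1, function(b)
    classify_third_position(b$structure, "A:112", "A:515")$label, character(1))
  expect_equal(got, labs)
})

test_that("generated files are valid inputs to the whole pipeline", {
  dir <- withr::local_tempdir()
  bundles <- build_panel(1, sigma = 0, seed = 23, outdir = dir)
  files <- vapply(bundles, function(b) b$path, character(1))
  expect_true(all(file.exists(files)))
  wm_file <- files[vapply(bundles, function(b)
    b$truth$label == "WATER_MEDIATED_TRIAD", logical(1))]
  s <- read_structure(wm_file)
  # classifier
  expect_equal(classify_third_position(s, "A:112", "A:515")$label,
               "WATER_MEDIATED_TRIAD")
  # B-factors
  expect_equal(nrow(catalytic_bfactors(s, list("A:112", "A:515", "A:513"))), 3L)
  # motif screen against the panel files
  q <- motif_query(s, "A:112", "A:515", "A:513")
  tab <- screen_panel(q, files)
  expect_equal(attr(tab, "n_passing_targets"), 1L)
  # rotamer scan runs on the re-read structure
  r <- scan_min_distance(s, "A:515", "A:513", grid_step = 60)
  expect_true(is.finite(r$min_distance_unconstrained))
})

test_that("residue templates have sane covalent geometry", {
  for (resn in c("SER", "HIS", "ASP", "ASN", "GLU", "GLN", "ALA")) {
    t <- residue_template(resn)
    expect_true(all(c("N", "CA", "C", "O") %in% t$name))
    ca <- as.numeric(t[t$name == "CA", c("x", "y", "z")])
    n <- as.numeric(t[t$name == "N", c("x", "y", "z")])
    expect_equal(vec_distance(ca, n), 1.458, tolerance = 1e-6)
  }
  h <- residue_template("HIS")
  g <- function(nm) as.numeric(h[h$name == nm, c("x", "y", "z")])
  # ring closure: the CD2-CG bond implied by the pentagon construction
  expect_equal(vec_distance(g("CD2"), g("CG")), 1.37, tolerance = 0.02)
  # across-ring chord of a regular pentagon with 1.37 A sides
  expect_equal(vec_distance(g("ND1"), g("NE2")), 2 * 1.1654 * sin(72 * pi / 180),
               tolerance = 0.05)
})
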