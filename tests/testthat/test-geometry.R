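test_that("distance and angle primitives are exact on analytic cases", {
  expect_equal(vec_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(vec_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(vec_angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(vec_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # ideal tetrahedron: centre-to-vertex angles are 109.47
  d <- tetra_dirs()
  expect_equal(vec_angle(d[1, ], c(0, 0, 0), d[2, ]), 109.4712, tolerance = 1e-4)
  expect_error(vec_distance(c(0, 0, 0), c(NA, 0, 0)), "finite")
  expect_error(vec_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero-length")
  # symmetry over random pairs
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(vec_distance(a, b), vec_distance(b, a), tolerance = 1e-12)
  }
})

test_that("hydrogen-bond search equals the all-pairs brute-force scan", {
  for (seed in 1:10) {
    s <- random_structure(500, seed)
    # query: first oxygen atom
    o_idx <- which(s$atoms$element == "O")[1]
    atom <- s$atoms[o_idx, , drop = FALSE]
    got <- find_hbond_partners(s, atom, window = c(2.2, 3.5))
    want <- brute_force_partners(s, atom, c(2.2, 3.5))
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$distance, want$distance, tolerance = 1e-12)
      expect_equal(paste(got$chain, got$seqnum, got$name),
                   paste(want$chain, want$seqnum, want$name))
    }
  }
})

test_that("widening the window never removes partners", {
  s <- random_structure(400, 99)
  atom <- s$atoms[which(s$atoms$element == "N")[1], , drop = FALSE]
  narrow <- find_hbond_partners(s, atom, window = c(2.5, 3.2))
  wide <- find_hbond_partners(s, atom, window = c(2.2, 3.8))
  key <- function(h) paste(h$chain, h$seqnum, h$name)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("distances, angles and classification survive rigid motion", {
  b <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9)
  s <- b$structure
  site0 <- classify_third_position(s, "A:112", "A:515")
  for (seed in c(2, 3)) {
    s2 <- rigid_motion(s, seed)
    site2 <- classify_third_position(s2, "A:112", "A:515")
    expect_equal(site2$label, site0$label)
    expect_equal(site2$d_ND1_acidO, site0$d_ND1_acidO, tolerance = 1e-9)
    expect_equal(site2$d_OG_NE2, site0$d_OG_NE2, tolerance = 1e-9)
  }
})

test_that("water coordination reports partners, angles and tetrahedrality", {
  # isolated water: no partners
  lone <- new_structure(data.frame(
    serial = 1L, name = "O", altloc = "", resname = "HOH", chain = "W",
    seqnum = 1L, icode = "", x = 0, y = 0, z = 0, occupancy = 1,
    bfactor = 20, element = "O"), "lone")
  rep0 <- water_coordination(lone, "W:1")
  expect_equal(rep0$count, 0L)
  expect_false(rep0$is_tetrahedral)

  # four partners on ideal tetrahedral directions: deviation ~ 0
  d <- tetra_dirs() * 2.9
  atoms <- data.frame(
    serial = 1:5,
    name = c("O", "OD1", "OD1", "OD1", "OD1"), altloc = "",
    resname = c("HOH", "ASP", "ASP", "ASP", "ASP"),
    chain = c("W", "A", "A", "A", "A"), seqnum = c(1L, 2L, 3L, 4L, 5L),
    icode = "", x = c(0, d[, 1]), y = c(0, d[, 2]), z = c(0, d[, 3]),
    occupancy = 1, bfactor = 20, element = "O", stringsAsFactors = FALSE)
  s4 <- new_structure(atoms, "tetra")
  rep4 <- water_coordination(s4, "W:1")
  expect_equal(rep4$count, 4L)
  expect_equal(length(rep4$pair_angles), 6L)
  # the metric is defined against 109.5; the exact tetrahedral angle is
  # 109.4712, so even ideal geometry scores ~0.03
  expect_lt(rep4$tetrahedrality, 0.05)
  expect_true(rep4$is_tetrahedral)

  # the published bridge geometry: His ND1, acid O, carbonyl probe, 2nd water
  b <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9)
  repw <- water_coordination(b$structure, "W:701")
  expect_equal(repw$count, 4L)
  expect_setequal(repw$partners$name[repw$partners$resname == "HIS"], "ND1")
  expect_true("HOH" %in% repw$partners$resname)

  # a fixture water placed 2.9 from both ND1 and OD1 finds exactly those two
  b2 <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9,
                           include_carbonyl_probe = FALSE,
                           second_water = FALSE)
  rep2 <- water_coordination(b2$structure, "W:701")
  expect_equal(rep2$count, 2L)
  expect_equal(sort(rep2$partners$name), c("ND1", "OD1"))
  expect_equal(rep2$partners$distance, c(2.9, 2.9), tolerance = 1e-6)

  # multi-oxygen "water" is rejected
  bad <- s4
  bad$atoms$resname[2] <- "HOH"
  bad$atoms$chain[2] <- "W"
  bad$atoms$seqnum[2] <- 1L
  expect_error(water_coordination(bad, "W:1"), "exactly one oxygen")
})
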