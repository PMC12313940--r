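test_that("Ser-His pair detection enforces the N-epsilon rule", {
  b <- build_site_fixture("BARE_DYAD", d_OG_NE2 = 2.8)
  pairs <- find_ser_his_pairs(b$structure)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$d_OG_NE2, 2.8, tolerance = 1e-6)

  # decoy placements >= 4 A apart yield no pairs
  set.seed(5)
  for (i in 1:10) {
    ser <- residue_template("SER")
    his <- residue_template("HIS")
    shift <- runif(3, 8, 15)  # whole Ser far from the His
    ser$x <- ser$x + shift[1]; ser$y <- ser$y + shift[2]
    ser$z <- ser$z + shift[3]
    atoms <- rbind(
      cbind(data.frame(serial = seq_len(nrow(his)), name = his$name,
                       altloc = "", resname = "HIS", chain = "A",
                       seqnum = 1L, icode = ""),
            his[, c("x", "y", "z")],
            data.frame(occupancy = 1, bfactor = 20, element = his$element)),
      cbind(data.frame(serial = nrow(his) + seq_len(nrow(ser)),
                       name = ser$name, altloc = "", resname = "SER",
                       chain = "A", seqnum = 2L, icode = ""),
            ser[, c("x", "y", "z")],
            data.frame(occupancy = 1, bfactor = 20, element = ser$element)))
    s <- new_structure(atoms, "decoy")
    expect_equal(nrow(find_ser_his_pairs(s)), 0L)
  }
})

test_that("the decision cascade assigns each architecture by its rule", {
  # rule 1: direct contact at 2.8 A
  b1 <- build_site_fixture("CONVENTIONAL_TRIAD", d_ND1_acidO = 2.8)
  s1 <- classify_third_position(b1$structure, "A:112", "A:515")
  expect_equal(s1$label, "CONVENTIONAL_TRIAD")
  expect_equal(s1$d_ND1_acidO, 2.8, tolerance = 1e-6)
  expect_null(s1$bridge_water)

  # rule 2: the published 4.0 / 2.9 / 2.9 geometry
  b2 <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9)
  s2 <- classify_third_position(b2$structure, "A:112", "A:515")
  expect_equal(s2$label, "WATER_MEDIATED_TRIAD")
  expect_equal(s2$d_ND1_acidO, 4.0, tolerance = 1e-6)
  expect_equal(s2$d_ND1_water, 2.9, tolerance = 1e-6)
  expect_equal(s2$d_water_acidO, 2.9, tolerance = 1e-6)
  expect_false(is.null(s2$bridge_water))
  expect_gte(s2$d_ND1_acidO, s2$direct_cutoff)

  # rule 3: backbone carbonyl O at 2.9 A, no acid anywhere
  b3 <- build_site_fixture("MAINCHAIN_DYAD", d_ND1_mainchainO = 2.9)
  s3 <- classify_third_position(b3$structure, "A:112", "A:515")
  expect_equal(s3$label, "MAINCHAIN_DYAD")
  expect_equal(s3$mainchain_partner$name, "O")
  expect_equal(s3$mainchain_partner$distance, 2.9, tolerance = 1e-6)

  # rule 4
  b4 <- build_site_fixture("BARE_DYAD")
  expect_equal(classify_third_position(b4$structure, "A:112", "A:515")$label,
               "BARE_DYAD")

  # His without ND1 cannot be classified
  s_broken <- b1$structure
  s_broken$atoms <- s_broken$atoms[s_broken$atoms$name != "ND1", ]
  expect_error(classify_third_position(s_broken, "A:112", "A:515"), "ND1")
})

test_that("rule 1 strictly precedes rule 2 and the cutoff boundary flips labels", {
  # both a direct contact and a water bridge present -> CONVENTIONAL
  b <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9,
                          include_carbonyl_probe = FALSE, second_water = FALSE)
  s <- b$structure
  # drag the acid terminal O inside the direct cutoff along the O-ND1 line
  nd1 <- s$atoms[s$atoms$name == "ND1", ]
  od <- which(s$atoms$name == "OD1" & s$atoms$resname == "ASP")
  p_o <- as.numeric(s$atoms[od, c("x", "y", "z")])
  p_n <- as.numeric(nd1[, c("x", "y", "z")])
  u <- (p_o - p_n) / sqrt(sum((p_o - p_n)^2))
  for (d_target in c(2.8, 2.999)) {
    s_mod <- s
    s_mod$atoms[od, c("x", "y", "z")] <- p_n + d_target * u
    expect_equal(classify_third_position(s_mod, "A:112", "A:515")$label,
                 "CONVENTIONAL_TRIAD")
  }
  for (d_target in c(3.0, 3.2)) {
    s_mod <- s
    s_mod$atoms[od, c("x", "y", "z")] <- p_n + d_target * u
    lab <- classify_third_position(s_mod, "A:112", "A:515")$label
    expect_true(lab %in% c("WATER_MEDIATED_TRIAD", "BARE_DYAD"))
  }
})

test_that("classification is exact on the noiseless panel", {
  panel <- build_panel(2, sigma = 0, seed = 21)
  labs <- vapply(panel, function(b)
    classify_third_position(b$structure, "A:112", "A:515")$label, character(1))
  expect_equal(labs, vapply(panel, function(b) b$truth$label, character(1)))
})

test_that("analyze_site bundles classification, coordination and B-factors", {
  b <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9,
                          bfactors = c(17.7, 29.7, 20.0))
  rep <- analyze_site(b$structure, "A:112", "A:515", "A:513")
  expect_equal(rep$site$label, "WATER_MEDIATED_TRIAD")
  expect_equal(rep$site$d_ND1_acidO, 4.0, tolerance = 1e-6)
  expect_equal(rep$coordination$count, 4L)
  expect_equal(attr(rep$bfactors, "max"), 29.7)
  expect_true(rep$ser_nucleophile)

  conv <- build_site_fixture("CONVENTIONAL_TRIAD")
  rep2 <- analyze_site(conv$structure, "A:112", "A:515", "A:513")
  expect_equal(rep2$site$label, "CONVENTIONAL_TRIAD")
  expect_null(rep2$coordination)
})

test_that("a covalently modified Ser OG still counts as a nucleophile", {
  b <- build_site_fixture("WATER_MEDIATED_TRIAD")
  s <- b$structure
  # move the Ser OG out of hydrogen-bond range of NE2, then attach an
  # adduct heavy atom 1.6 A from OG (a cacodylate-like modification)
  og <- which(s$atoms$name == "OG")
  s$atoms[og, c("x", "y", "z")] <- s$atoms[og, c("x", "y", "z")] + c(3, 3, 3)
  expect_false(suppressWarnings(ser_is_nucleophile(s, "A:112", "A:515")))
  adduct <- s$atoms[og, ]
  adduct$serial <- max(s$atoms$serial) + 1L
  adduct$name <- "AS"; adduct$element <- "AS"
  adduct$resname <- "CAC"; adduct$seqnum <- 900L
  adduct$x <- adduct$x + 1.6
  s$atoms <- rbind(s$atoms, adduct)
  expect_warning(ok <- ser_is_nucleophile(s, "A:112", "A:515"), "modified")
  expect_true(ok)
})
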