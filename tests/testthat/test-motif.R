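test_that("Kabsch superposition is exact on identity and rigid motions", {
  set.seed(31)
  A <- matrix(rnorm(15), 5, 3)
  expect_equal(kabsch_rmsd(A, A)$rmsd, 0, tolerance = 1e-12)
  # rigid motion of A superposes to zero
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- sweep(A %*% t(R), 2, c(4, -2, 9), FUN = "+")
  fit <- kabsch_rmsd(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_rmsd(A[1:2, ], A[1:2, ]), "at least 3")
  coll <- cbind(1:4, 2 * (1:4), -(1:4))  # collinear points
  expect_error(kabsch_rmsd(coll, coll), "degenerate")
})

test_that("Kabsch RMSD matches the quaternion oracle on random point sets", {
  set.seed(32)
  for (i in 1:25) {
    A <- matrix(rnorm(15, sd = 3), 5, 3)
    B <- matrix(rnorm(15, sd = 3), 5, 3)
    expect_equal(kabsch_rmsd(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-9)
  }
})

test_that("a query site matches itself and a rigid transplant into a decoy", {
  wm <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9)
  q <- motif_query(wm$structure, "A:112", "A:515", "A:513")
  self <- match_motif(q, wm$structure)
  expect_equal(nrow(self), 1L)
  expect_lt(self$rmsd, 1e-9)

  # rigidly moved copy embedded among decoy atoms
  moved <- rigid_motion(wm$structure, 41)
  decoy <- random_structure(120, 42, box = 60)
  decoy$atoms$seqnum <- decoy$atoms$seqnum + 1000L
  merged <- moved
  merged$atoms <- rbind(moved$atoms, decoy$atoms)
  merged$atoms$serial <- seq_len(nrow(merged$atoms))
  hits <- match_motif(q, merged)
  expect_equal(nrow(hits), 1L)
  expect_lt(hits$rmsd, 0.01)
})

test_that("the motif RMSD stage is invariant under rigid motion of the target", {
  wm <- build_site_fixture("WATER_MEDIATED_TRIAD")
  conv <- build_site_fixture("CONVENTIONAL_TRIAD")
  q <- motif_query(wm$structure, "A:112", "A:515", "A:513")
  h0 <- match_motif(q, conv$structure)
  h1 <- match_motif(q, rigid_motion(conv$structure, 8))
  expect_equal(nrow(h0), nrow(h1))
  if (nrow(h0)) expect_equal(h0$rmsd, h1$rmsd, tolerance = 1e-9)
})

test_that("tightening cutoffs never adds hits; the cascade never alters RMSD", {
  wm <- build_site_fixture("WATER_MEDIATED_TRIAD")
  target <- wm$structure
  loose <- match_motif(motif_query(target, "A:112", "A:515", "A:513",
                                   rmsd_cutoff = 2.0), target)
  tight <- match_motif(motif_query(target, "A:112", "A:515", "A:513",
                                   rmsd_cutoff = 0.5), target)
  expect_lte(nrow(tight), nrow(loose))
  flagged <- filter_cascade(loose, target)
  expect_equal(flagged$rmsd, loose$rmsd)
  expect_equal(flagged$passes_all,
               flagged$no_direct_his_acid_hbond & flagged$ser_is_nucleophile &
                 flagged$ser_OG_his_NE2_hbond & flagged$water_bridges_gap)
})

test_that("the filter cascade separates the four architectures", {
  wm <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9)
  q <- motif_query(wm$structure, "A:112", "A:515", "A:513")

  # water-mediated fixture: all four flags true
  h <- filter_cascade(match_motif(q, wm$structure), wm$structure)
  expect_true(all(h$passes_all))

  # conventional triad (ND1-OD 2.8): flag 1 false
  conv <- build_site_fixture("CONVENTIONAL_TRIAD", d_ND1_acidO = 2.8)
  hc <- filter_cascade(match_motif(q, conv$structure), conv$structure)
  if (nrow(hc)) {
    expect_false(any(hc$no_direct_his_acid_hbond))
    expect_false(any(hc$passes_all))
  }

  # water bridge present but Ser OG moved out of NE2 range: flag 3 false
  broken <- wm$structure
  og <- which(broken$atoms$name == "OG")
  broken$atoms[og, c("x", "y", "z")] <-
    broken$atoms[og, c("x", "y", "z")] + c(2.5, 2.5, 2.5)
  hb <- filter_cascade(match_motif(q, broken), broken)
  if (nrow(hb)) {
    expect_false(any(hb$ser_OG_his_NE2_hbond))
    expect_false(any(hb$passes_all))
  }
})

test_that("panel screening counts passing targets and survives bad files", {
  wm <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9)
  q <- motif_query(wm$structure, "A:112", "A:515", "A:513")

  expect_equal(nrow(screen_panel(q, list())), 0L)

  targets <- list(wm$structure,
                  build_site_fixture("CONVENTIONAL_TRIAD")$structure,
                  build_site_fixture("MAINCHAIN_DYAD")$structure)
  tab <- screen_panel(q, targets)
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "n_passing_targets"), 1L)
  expect_equal(tab$n_passing_hits[1], 1L)

  # an unreadable file gets an error row; the screen continues
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("not a pdb", bad)
  good <- withr::local_tempfile(fileext = ".pdb")
  write_structure(wm$structure, good)
  tab2 <- screen_panel(q, c(bad, good))
  expect_match(tab2$status[1], "error")
  expect_equal(tab2$n_passing_hits[2], 1L)
})
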