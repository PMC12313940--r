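# Synthetic active-site fixtures: miniature labelled coordinate models
# with controllable geometry, built from ideal residue templates
# (standard bond lengths/angles, assembled from internal coordinates in
# code -- no external monomer library). Each residue carries a minimal
# backbone (N, CA, C, O) so main-chain rules, B-factor extraction and
# rotamer axes are exercisable.

# --- internal-coordinate (NeRF) construction ------------------------------

# position of atom D bonded to C, with angle B-C-D and dihedral A-B-C-D
place_atom <- function(A, B, C, r, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
}

# backbone common to all templates (local frame)
template_backbone <- function() {
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  O <- place_atom(N, CA, C, 1.231, 120.8, 180)
  list(N = N, CA = CA, C = C, O = O)
}

template_cb <- function(bb) {
  # dihedral C'-N-CA-CB ~ -122 puts the side chain out of the backbone plane
  place_atom(bb$C, bb$N, bb$CA, 1.530, 110.5, -122)
}

#' Ideal residue template
#'
#' Builds a residue from standard internal coordinates (bond lengths and
#' angles) in a local frame, with chi1/chi2 set to the requested values.
#' Supported: SER, ALA, GLY, HIS, ASP, ASN, GLU, GLN, HOH.
#'
#' @param resname three-letter residue name.
#' @param chi1,chi2 side-chain torsions in degrees.
#' @return data.frame with columns `name`, `element`, `x`, `y`, `z`.
#' @export
residue_template <- function(resname, chi1 = 180, chi2 = 90) {
  if (resname == "HOH") {
    return(data.frame(name = "O", element = "O", x = 0, y = 0, z = 0,
                      stringsAsFactors = FALSE))
  }
  bb <- template_backbone()
  atoms <- list(N = bb$N, CA = bb$CA, C = bb$C, O = bb$O)
  el <- c(N = "N", CA = "C", C = "C", O = "O")
  add <- function(nm, pos, elem) {
    atoms[[nm]] <<- pos
    el[nm] <<- elem
  }
  if (resname != "GLY") add("CB", template_cb(bb), "C")
  if (resname == "SER") {
    add("OG", place_atom(atoms$N, atoms$CA, atoms$CB, 1.417, 110.8, chi1), "O")
  } else if (resname == "HIS") {
    add("CG", place_atom(atoms$N, atoms$CA, atoms$CB, 1.50, 113.8, chi1), "C")
    add("ND1", place_atom(atoms$CA, atoms$CB, atoms$CG, 1.378, 126, chi2), "N")
    add("CE1", place_atom(atoms$CB, atoms$CG, atoms$ND1, 1.37, 108, 180), "C")
    add("NE2", place_atom(atoms$CG, atoms$ND1, atoms$CE1, 1.37, 108, 0), "N")
    add("CD2", place_atom(atoms$ND1, atoms$CE1, atoms$NE2, 1.37, 108, 0), "C")
  } else if (resname %in% c("ASP", "ASN")) {
    add("CG", place_atom(atoms$N, atoms$CA, atoms$CB, 1.52, 112.6, chi1), "C")
    t1 <- if (resname == "ASP") c("OD1", "O", 1.25) else c("OD1", "O", 1.23)
    t2 <- if (resname == "ASP") c("OD2", "O", 1.25) else c("ND2", "N", 1.33)
    add(t1[1], place_atom(atoms$CA, atoms$CB, atoms$CG,
                          as.numeric(t1[3]), 118.4, chi2), t1[2])
    add(t2[1], place_atom(atoms$CA, atoms$CB, atoms$CG,
                          as.numeric(t2[3]), 118.4, chi2 + 180), t2[2])
  } else if (resname %in% c("GLU", "GLN")) {
    add("CG", place_atom(atoms$N, atoms$CA, atoms$CB, 1.52, 114.1, chi1), "C")
    add("CD", place_atom(atoms$CA, atoms$CB, atoms$CG, 1.52, 112.6, chi2), "C")
    t1 <- c("OE1", "O", "1.25")
    t2 <- if (resname == "GLU") c("OE2", "O", "1.25") else c("NE2", "N", "1.33")
    add(t1[1], place_atom(atoms$CB, atoms$CG, atoms$CD,
                          as.numeric(t1[3]), 118.4, 0), t1[2])
    add(t2[1], place_atom(atoms$CB, atoms$CG, atoms$CD,
                          as.numeric(t2[3]), 118.4, 180), t2[2])
  } else if (resname != "ALA" && resname != "GLY") {
    stop("no template for residue ", resname)
  }
  xyz <- do.call(rbind, atoms)
  data.frame(name = names(atoms), element = unname(el[names(atoms)]),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# rotation taking unit vector a onto unit vector b (minimal rotation)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3],
            a[1] * p[2] - a[2] * p[1])
    return(rotation_about_axis(ax, 180))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# rigidly place a template so `atom` lands at `target` and the template
# vector (ref_atom - atom) aligns with `direction`
place_by_atom <- function(tpl, atom, target, direction, ref_atom) {
  p0 <- as.numeric(tpl[tpl$name == atom, c("x", "y", "z")])
  p1 <- as.numeric(tpl[tpl$name == ref_atom, c("x", "y", "z")])
  R <- rotation_between(p1 - p0, direction)
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, p0) %*% t(R)
  xyz <- sweep(xyz, 2, target, FUN = "+")
  tpl$x <- xyz[, 1]; tpl$y <- xyz[, 2]; tpl$z <- xyz[, 3]
  tpl
}

unitv <- function(v) v / sqrt(sum(v^2))

# --- the site fixture builder ---------------------------------------------

#' Build a labelled synthetic active-site fixture
#'
#' Constructs a miniature coordinate model realising one of the four
#' active-site architectures with exactly the requested heavy-atom
#' distances (at zero noise). The His is placed first; the Ser OG is set
#' on the NE2 in-plane lone-pair direction (the N-epsilon geometry); the
#' bridge water and acid are placed on the ND1 side. Optional probes
#' complete the water's tetrahedral shell: a main-chain-like carbonyl
#' oxygen (mimicking the ancillary-domain Tyr carbonyl) and a second
#' water. Seeded isotropic Gaussian noise is applied last, so labels are
#' guaranteed only in distribution at sigma > 0.
#'
#' @param label one of `"CONVENTIONAL_TRIAD"`, `"WATER_MEDIATED_TRIAD"`,
#'   `"MAINCHAIN_DYAD"`, `"BARE_DYAD"`.
#' @param d_OG_NE2 Ser OG to His NE2 distance, Angstrom.
#' @param d_ND1_acidO His ND1 to nearest acid terminus (conventional:
#'   < 3; water-mediated: >= 3, the exemplar prints 4.0).
#' @param d_ND1_water,d_water_acidO water bridge bond lengths (exemplar:
#'   2.9 and 2.9).
#' @param d_ND1_mainchainO carbonyl-to-ND1 distance for the main-chain
#'   dyad.
#' @param include_carbonyl_probe,second_water complete the bridge water's
#'   4-coordination (defaults TRUE for the water-mediated label).
#' @param acid_resname ASP, ASN, GLU or GLN.
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom.
#' @param seed integer seed for the noise (required when sigma > 0).
#' @param bfactors length-3 numeric: CA B-factors for Ser/His/acid.
#' @param path optional output PDB path; a `.json` truth sidecar is
#'   written next to it.
#' @return A `fixture_bundle`: list with `structure` (a `structure3d`),
#'   `truth` (label, spec'd and realized distances, residue ids), and
#'   `path` (or NULL).
#' @export
build_site_fixture <- function(label,
                               d_OG_NE2 = 2.8,
                               d_ND1_acidO = if (label == "CONVENTIONAL_TRIAD") 2.8 else 4.0,
                               d_ND1_water = 2.9,
                               d_water_acidO = 2.9,
                               d_ND1_mainchainO = 2.8,
                               include_carbonyl_probe = label == "WATER_MEDIATED_TRIAD",
                               second_water = label == "WATER_MEDIATED_TRIAD",
                               acid_resname = "ASP",
                               noise_sigma = 0, seed = NULL,
                               bfactors = c(20, 20, 20),
                               path = NULL) {
  label <- match.arg(label, c("CONVENTIONAL_TRIAD", "WATER_MEDIATED_TRIAD",
                              "MAINCHAIN_DYAD", "BARE_DYAD"))
  stopifnot(acid_resname %in% ACID_RESNAMES)
  direct_cutoff <- 3.0
  if (label == "WATER_MEDIATED_TRIAD") {
    if (d_ND1_acidO < direct_cutoff)
      stop("contradictory spec: WATER_MEDIATED_TRIAD with d_ND1_acidO < ",
           direct_cutoff, " would classify as CONVENTIONAL_TRIAD")
    a <- d_ND1_water; b <- d_water_acidO; cc <- d_ND1_acidO
    if (cc > a + b)
      stop("triangle violation: d_ND1_acidO > d_ND1_water + d_water_acidO")
    if (cc < abs(a - b))
      stop("triangle violation: d_ND1_acidO < |d_ND1_water - d_water_acidO|")
  }
  if (label == "CONVENTIONAL_TRIAD" && d_ND1_acidO >= direct_cutoff)
    stop("contradictory spec: CONVENTIONAL_TRIAD needs d_ND1_acidO < ",
         direct_cutoff)

  his <- residue_template("HIS")
  gp <- function(res, nm) as.numeric(res[res$name == nm, c("x", "y", "z")])
  nd1 <- gp(his, "ND1"); ne2 <- gp(his, "NE2")
  ce1 <- gp(his, "CE1"); cd2 <- gp(his, "CD2"); cg <- gp(his, "CG")
  # in-plane lone-pair directions
  u_ne2 <- unitv(-(unitv(ce1 - ne2) + unitv(cd2 - ne2)))
  u_nd1 <- unitv(-(unitv(cg - nd1) + unitv(ce1 - nd1)))
  ring_normal <- unitv(cross3(cg - nd1, ce1 - nd1))

  residues <- list(list(tpl = his, resname = "HIS", chain = "A",
                        seqnum = 515L, bf = bfactors[2]))

  ser <- residue_template("SER")
  og_target <- ne2 + d_OG_NE2 * u_ne2
  ser <- place_by_atom(ser, "OG", og_target, u_ne2, "CB")
  residues[[length(residues) + 1L]] <- list(tpl = ser, resname = "SER",
                                            chain = "A", seqnum = 112L,
                                            bf = bfactors[1])
  truth <- list(label = label, d_OG_NE2 = d_OG_NE2)
  waters <- list()
  term1 <- acid_sidechain_atoms(acid_resname)[1]
  branch <- if (acid_resname %in% c("ASP", "ASN")) "CG" else "CD"

  if (label == "CONVENTIONAL_TRIAD") {
    o_target <- nd1 + d_ND1_acidO * u_nd1
    acid <- residue_template(acid_resname)
    acid <- place_by_atom(acid, term1, o_target, u_nd1, branch)
    residues[[length(residues) + 1L]] <- list(tpl = acid, resname = acid_resname,
                                              chain = "A", seqnum = 513L,
                                              bf = bfactors[3])
    truth$d_ND1_acidO <- d_ND1_acidO
  } else if (label == "WATER_MEDIATED_TRIAD") {
    w_pos <- nd1 + d_ND1_water * u_nd1
    a <- d_ND1_water; b <- d_water_acidO; cc <- d_ND1_acidO
    cos_g <- (a^2 + cc^2 - b^2) / (2 * a * cc)
    cos_g <- min(1, max(-1, cos_g))
    sin_g <- sqrt(1 - cos_g^2)
    w_perp <- unitv(cross3(ring_normal, u_nd1))
    o_target <- nd1 + cc * (cos_g * u_nd1 + sin_g * w_perp)
    acid <- residue_template(acid_resname)
    d_out <- unitv(o_target - 0.5 * (nd1 + w_pos))
    acid <- place_by_atom(acid, term1, o_target, d_out, branch)
    residues[[length(residues) + 1L]] <- list(tpl = acid, resname = acid_resname,
                                              chain = "A", seqnum = 513L,
                                              bf = bfactors[3])
    waters[[length(waters) + 1L]] <- list(pos = w_pos, seqnum = 701L)
    truth$d_ND1_acidO <- cc
    truth$d_ND1_water <- a
    truth$d_water_acidO <- b
    # complete tetrahedral coordination of the bridge water
    if (include_carbonyl_probe || second_water) {
      u1 <- unitv(nd1 - w_pos); u2 <- unitv(o_target - w_pos)
      mdir <- -(u1 + u2)
      mdir <- if (sqrt(sum(mdir^2)) < 1e-6) ring_normal else unitv(mdir)
      n2 <- unitv(cross3(u1, u2))
      half <- 54.75 * pi / 180
      d3 <- unitv(cos(half) * mdir + sin(half) * n2)
      d4 <- unitv(cos(half) * mdir - sin(half) * n2)
      if (include_carbonyl_probe) {
        probe <- residue_template("ALA")
        probe <- place_by_atom(probe, "O", w_pos + 2.8 * d3, d3, "C")
        residues[[length(residues) + 1L]] <- list(tpl = probe, resname = "ALA",
                                                  chain = "A", seqnum = 334L,
                                                  bf = mean(bfactors))
      }
      if (second_water)
        waters[[length(waters) + 1L]] <- list(pos = w_pos + 2.8 * d4,
                                              seqnum = 702L)
    }
  } else if (label == "MAINCHAIN_DYAD") {
    probe <- residue_template("ALA")
    probe <- place_by_atom(probe, "O", nd1 + d_ND1_mainchainO * u_nd1,
                           u_nd1, "C")
    residues[[length(residues) + 1L]] <- list(tpl = probe, resname = "ALA",
                                              chain = "A", seqnum = 334L,
                                              bf = mean(bfactors))
    truth$d_ND1_mainchainO <- d_ND1_mainchainO
  }

  atoms <- assemble_atoms(residues, waters)
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sigma > 0")
    set.seed(as.integer(seed))
    n <- nrow(atoms)
    atoms$x <- atoms$x + rnorm(n, 0, noise_sigma)
    atoms$y <- atoms$y + rnorm(n, 0, noise_sigma)
    atoms$z <- atoms$z + rnorm(n, 0, noise_sigma)
  }
  s <- new_structure(atoms, source_id = paste0("fixture_", tolower(label)))
  truth$noise_sigma <- noise_sigma
  truth$seed <- seed
  truth$ser <- "A:112"; truth$his <- "A:515"
  truth$acid <- if (label %in% c("CONVENTIONAL_TRIAD", "WATER_MEDIATED_TRIAD"))
    "A:513" else NULL
  truth$acid_resname <- if (!is.null(truth$acid)) acid_resname else NULL
  truth$realized <- realized_distances(s, truth)
  out <- list(structure = s, truth = truth, path = NULL)
  class(out) <- "fixture_bundle"
  if (!is.null(path)) {
    write_structure(s, path)
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    writeLines(mini_json(truth), sidecar)
    out$path <- path
  }
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

assemble_atoms <- function(residues, waters) {
  rows <- list()
  serial <- 0L
  for (r in residues) {
    t <- r$tpl
    n <- nrow(t)
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial + seq_len(n), name = t$name, altloc = "",
      resname = r$resname, chain = r$chain, seqnum = r$seqnum, icode = "",
      x = t$x, y = t$y, z = t$z, occupancy = 1,
      bfactor = r$bf, element = t$element, stringsAsFactors = FALSE)
    serial <- serial + n
  }
  for (w in waters) {
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial, name = "O", altloc = "", resname = "HOH",
      chain = "W", seqnum = w$seqnum, icode = "", x = w$pos[1], y = w$pos[2],
      z = w$pos[3], occupancy = 1, bfactor = 30, element = "O",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

realized_distances <- function(s, truth) {
  gp <- function(sel, nm) {
    res <- resolve_residue(s, sel)
    a <- residue_atom(res, nm, required = FALSE)
    if (is.null(a)) return(NULL)
    c(a$x, a$y, a$z)
  }
  out <- list()
  nd1 <- gp("A:515", "ND1"); ne2 <- gp("A:515", "NE2")
  og <- gp("A:112", "OG")
  if (!is.null(og) && !is.null(ne2)) out$d_OG_NE2 <- vec_distance(og, ne2)
  if (!is.null(truth$acid)) {
    res <- resolve_residue(s, truth$acid)
    term <- res[res$name %in% acid_sidechain_atoms(truth$acid_resname), ,
                drop = FALSE]
    d <- sqrt((term$x - nd1[1])^2 + (term$y - nd1[2])^2 + (term$z - nd1[3])^2)
    out$d_ND1_acidO <- min(d)
    if (!is.null(truth$d_ND1_water)) {
      w <- gp("W:701", "O")
      out$d_ND1_water <- vec_distance(w, nd1)
      dw <- sqrt((term$x - w[1])^2 + (term$y - w[2])^2 + (term$z - w[3])^2)
      out$d_water_acidO <- min(dw)
    }
  }
  out
}

# minimal JSON writer for flat named lists of scalars (truth sidecars)
mini_json <- function(x) {
  enc <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v))
      return(paste0("{", paste(sprintf("\"%s\": %s", names(v),
                                       vapply(v, enc, character(1))),
                               collapse = ", "), "}"))
    if (is.character(v)) return(sprintf("\"%s\"", v))
    if (is.logical(v)) return(if (v) "true" else "false")
    format(v, digits = 12)
  }
  enc(x)
}

#' Build a balanced labelled fixture panel
#'
#' Generates `n_per_label` fixtures for each of the four architectures
#' with randomised nuisance parameters (distances jittered inside
#' label-consistent ranges, random global rigid motion) and seeded
#' Gaussian coordinate noise. Fully reproducible from the seed.
#'
#' @param n_per_label fixtures per label (>= 1).
#' @param sigma coordinate noise, Angstrom.
#' @param seed integer seed.
#' @param outdir optional directory to write PDB + sidecar files into.
#' @return List of `fixture_bundle` objects.
#' @export
build_panel <- function(n_per_label, sigma = 0, seed = 1, outdir = NULL) {
  stopifnot(n_per_label >= 1)
  set.seed(as.integer(seed))
  labels <- c("CONVENTIONAL_TRIAD", "WATER_MEDIATED_TRIAD",
              "MAINCHAIN_DYAD", "BARE_DYAD")
  bundles <- list()
  k <- 0L
  for (lab in labels) {
    for (i in seq_len(n_per_label)) {
      k <- k + 1L
      d_og <- runif(1, 2.6, 3.2)
      args <- list(label = lab, d_OG_NE2 = d_og, noise_sigma = 0)
      if (lab == "CONVENTIONAL_TRIAD") {
        args$d_ND1_acidO <- runif(1, 2.5, 2.9)
      } else if (lab == "WATER_MEDIATED_TRIAD") {
        args$d_ND1_acidO <- runif(1, 3.7, 4.5)
        args$d_ND1_water <- runif(1, 2.5, 3.1)
        args$d_water_acidO <- runif(1, 2.5, 3.1)
        args$acid_resname <- sample(c("ASP", "ASN", "GLU", "GLN"), 1)
      } else if (lab == "MAINCHAIN_DYAD") {
        args$d_ND1_mainchainO <- runif(1, 2.5, 2.9)
      }
      b <- do.call(build_site_fixture, args)
      # random rigid motion + noise, drawn from the panel's RNG stream
      s <- b$structure
      R <- random_rotation()
      tr <- runif(3, -20, 20)
      xyz <- coords_of(s$atoms) %*% t(R)
      xyz <- sweep(xyz, 2, tr, FUN = "+")
      if (sigma > 0) xyz <- xyz + matrix(rnorm(3 * nrow(xyz), 0, sigma),
                                         ncol = 3)
      s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
      s$source_id <- sprintf("panel_%03d_%s", k, tolower(lab))
      b$structure <- s
      b$truth$noise_sigma <- sigma
      b$truth$realized <- realized_distances(s, b$truth)
      if (!is.null(outdir)) {
        p <- file.path(outdir, paste0(s$source_id, ".pdb"))
        write_structure(s, p)
        writeLines(mini_json(b$truth),
                   file.path(outdir, paste0(s$source_id, ".json")))
        b$path <- p
      }
      bundles[[k]] <- b
    }
  }
  bundles
}

random_rotation <- function() {
  # uniform random rotation from a normalised quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a His/acid pair with a known attainable contact distance
#'
#' Constructs a His-Asp pair in which, at the chi offsets `at_chis`
#' (degrees, c(his chi1, his chi2, acid chi1, acid chi2)), the Asp OD1
#' sits exactly `target_min_distance` from the His ND1. Two construction
#' modes trade exactness against chemical realism:
#'
#' * `approach = "axis"`: OD1 approaches along the extended CB-ND1 axis.
#'   Because chi rotations preserve every side-chain atom's distance to
#'   its own CB, and both ND1 and OD1 then sit on the CB-CB line, the
#'   target *is* the global unconstrained scan minimum (`min_bound ==
#'   target` in the truth record). The price: approaches below about 3.3
#'   Angstrom pass within hard-sphere distance of the His CE1, so this
#'   mode is for building *unattainability* fixtures (target above the
#'   contact cutoff, no grid point can beat it).
#' * `approach = "lonepair"`: OD1 approaches along the ND1 in-plane
#'   lone-pair direction -- a chemically sensible, clash-free hydrogen
#'   bond geometry; use it for *attainable* contacts. The scan minimum is
#'   then at most the target (other poses may be closer); `min_bound`
#'   reports the CB-CB slack lower bound.
#'
#' In both modes the acid is rolled about the approach axis to maximise
#' clearance between the two residues' remaining atoms. Offsets should be
#' multiples of the scan grid step so the target pose is on-grid.
#'
#' @param target_min_distance Angstrom, > 0.
#' @param at_chis numeric length-4 offsets in degrees.
#' @param approach `"lonepair"` (default) or `"axis"`.
#' @return A `fixture_bundle` with residues HIS A:515 and ASP A:513;
#'   `truth` holds `target_min_distance`, `at_chis`, `approach` and
#'   `min_bound`.
#' @export
build_rotamer_fixture <- function(target_min_distance, at_chis = c(0, 0, 0, 0),
                                  approach = c("lonepair", "axis")) {
  approach <- match.arg(approach)
  if (target_min_distance <= 0)
    stop("unreachable target: minimum distance must be positive")
  # conformations at the target offsets
  his_t <- as_residue(residue_template("HIS"), "HIS")
  his_t <- rotate_chi12(his_t, at_chis[1], at_chis[2])
  acid_t <- as_residue(residue_template("ASP"), "ASP")
  acid_t <- rotate_chi12(acid_t, at_chis[3], at_chis[4])
  ga <- function(res, nm) as.numeric(residue_atom(res, nm)[, c("x", "y", "z")])
  nd1 <- ga(his_t, "ND1"); cbh <- ga(his_t, "CB")
  cg_h <- ga(his_t, "CG"); ce1 <- ga(his_t, "CE1")
  v <- if (approach == "axis") unitv(nd1 - cbh)
       else unitv(-(unitv(cg_h - nd1) + unitv(ce1 - nd1)))  # ND1 lone pair
  od1 <- ga(acid_t, "OD1"); cba <- ga(acid_t, "CB")
  # the acid body sits beyond OD1 as seen from ND1: (OD1 - CB) points -v
  w <- unitv(od1 - cba)
  R <- rotation_between(w, -v)
  xyz <- as.matrix(acid_t[, c("x", "y", "z")]) %*% t(R)
  od1_idx <- which(acid_t$name == "OD1")
  od1_target <- nd1 + target_min_distance * v
  xyz <- sweep(xyz, 2, od1_target - xyz[od1_idx, ], FUN = "+")
  # roll about the approach axis for maximum clearance of the other atoms
  his_xyz <- as.matrix(his_t[!his_t$is_hydrogen, c("x", "y", "z")])
  best <- NULL; best_score <- -Inf
  for (roll in seq(0, 350, by = 10)) {
    Rr <- rotation_about_axis(v, roll)
    cand <- sweep(sweep(xyz, 2, od1_target) %*% t(Rr), 2, od1_target, FUN = "+")
    other <- cand[-od1_idx, , drop = FALSE]
    dmin <- min(vapply(seq_len(nrow(other)), function(i) {
      min(sqrt(rowSums(sweep(his_xyz, 2, other[i, ])^2)))
    }, numeric(1)))
    if (dmin > best_score) { best_score <- dmin; best <- cand }
  }
  xyz <- best
  acid_t$x <- xyz[, 1]; acid_t$y <- xyz[, 2]; acid_t$z <- xyz[, 3]
  cba_new <- ga(acid_t, "CB")
  r_h <- vec_distance(nd1, cbh)
  r_a <- max(vec_distance(ga(acid_t, "OD1"), cba_new),
             vec_distance(ga(acid_t, "OD2"), cba_new))
  min_bound <- vec_distance(cbh, cba_new) - r_h - r_a
  # wind the side chains back so the target pose sits at the offsets
  his_0 <- unwind_chis(his_t, at_chis[1], at_chis[2])
  acid_0 <- unwind_chis(acid_t, at_chis[3], at_chis[4])
  residues <- list(
    list(tpl = as.data.frame(his_0)[, c("name", "element", "x", "y", "z")],
         resname = "HIS", chain = "A", seqnum = 515L, bf = 20),
    list(tpl = as.data.frame(acid_0)[, c("name", "element", "x", "y", "z")],
         resname = "ASP", chain = "A", seqnum = 513L, bf = 20))
  atoms <- assemble_atoms(residues, list())
  s <- new_structure(atoms, source_id = "rotamer_fixture")
  out <- list(structure = s,
              truth = list(target_min_distance = target_min_distance,
                           at_chis = at_chis, approach = approach,
                           min_bound = min_bound),
              path = NULL)
  class(out) <- "fixture_bundle"
  out
}

# wrap a template data.frame into a residue3d (for rotate_about_chi)
as_residue <- function(tpl, resname, chain = "A", seqnum = 1L) {
  df <- data.frame(serial = seq_len(nrow(tpl)), name = tpl$name, altloc = "",
                   resname = resname, chain = chain, seqnum = seqnum,
                   icode = "", x = tpl$x, y = tpl$y, z = tpl$z,
                   occupancy = 1, bfactor = 20, element = tpl$element,
                   is_water = FALSE,
                   is_hydrogen = tpl$element %in% c("H", "D"),
                   stringsAsFactors = FALSE)
  structure(df, class = c("residue3d", "data.frame"),
            chain = chain, seqnum = seqnum, resname = resname)
}

# inverse of rotate_chi12 (which applies chi2 then chi1)
unwind_chis <- function(res, d1, d2) {
  if (d1 != 0) res <- rotate_about_chi(res, 1L, -d1)
  if (d2 != 0 && length(moved_names(res, 2L)) > 0 &&
      !is.null(residue_atom(res, "CG", required = FALSE)))
    res <- rotate_about_chi(res, 2L, -d2)
  res
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle> ", x$structure$source_id, "\n", sep = "")
  if (!is.null(x$truth$label)) cat("  label:", x$truth$label, "\n")
  if (!is.null(x$truth$realized)) {
    r <- x$truth$realized
    for (nm in names(r)) cat(sprintf("  %s = %.3f A\n", nm, r[[nm]]))
  }
  invisible(x)
}
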