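# Side-chain chi1/chi2 rotamer scanning. Existing coordinates are rotated
# rigidly about the chi axes (no idealised rebuild), preserving the
# crystal's internal geometry; the backbone stays fixed, as justified by
# the low B-factors of the catalytic residues.

MAINCHAIN_ATOM_NAMES <- c("N", "CA", "C", "O", "OXT")

sidechain_heavy <- function(res) {
  res[!res$name %in% MAINCHAIN_ATOM_NAMES & !res$is_hydrogen, , drop = FALSE]
}

# atom names moved by a chi rotation (distal to the axis)
moved_names <- function(res, chi_index) {
  sc <- sidechain_heavy(res)$name
  if (chi_index == 1L) setdiff(sc, "CB") else setdiff(sc, c("CB", "CG"))
}

rotation_about_axis <- function(axis, theta_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (k %o% k)
}

#' Rotate a side chain about a chi torsion axis
#'
#' Rotates the atoms distal to the axis (beyond CB for chi1, beyond CG
#' for chi2) rigidly about the CA-CB (chi1) or CB-CG (chi2) bond by
#' `delta` degrees. Bond lengths and angles are preserved exactly;
#' backbone and proximal atoms are untouched.
#'
#' @param residue a `residue3d`.
#' @param chi_index 1 or 2.
#' @param delta rotation in degrees (positive = right-handed about the
#'   proximal-to-distal axis direction).
#' @return The residue with rotated coordinates.
#' @export
rotate_about_chi <- function(residue, chi_index, delta) {
  stopifnot(chi_index %in% c(1L, 2L))
  axis_names <- if (chi_index == 1L) c("CA", "CB") else c("CB", "CG")
  a1 <- residue_atom(residue, axis_names[1], required = FALSE)
  a2 <- residue_atom(residue, axis_names[2], required = FALSE)
  if (is.null(a1) || is.null(a2))
    stop("residue ", residue$resname[1], " lacks chi", chi_index,
         " axis atom ", axis_names[if (is.null(a1)) 1 else 2])
  p1 <- c(a1$x, a1$y, a1$z); p2 <- c(a2$x, a2$y, a2$z)
  axis <- p2 - p1
  if (sqrt(sum(axis^2)) < 1e-6)
    stop("degenerate chi", chi_index, " axis: coincident axis atoms")
  mv <- residue$name %in% moved_names(residue, chi_index)
  if (!any(mv)) return(residue)
  R <- rotation_about_axis(axis, delta)
  xyz <- coords_of(residue[mv, , drop = FALSE])
  xyz <- sweep(xyz, 2, p2)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, p2, FUN = "+")
  residue$x[mv] <- xyz[, 1]
  residue$y[mv] <- xyz[, 2]
  residue$z[mv] <- xyz[, 3]
  residue
}

# joint (chi1, chi2) conformer: rotate chi2 first (about the original
# CB-CG axis), then chi1; final torsions are original + deltas
rotate_chi12 <- function(residue, d1, d2) {
  has_chi2 <- !is.null(residue_atom(residue, "CG", required = FALSE)) &&
    length(moved_names(residue, 2L)) > 0
  if (d2 != 0 && has_chi2) residue <- rotate_about_chi(residue, 2L, d2)
  if (d1 != 0) residue <- rotate_about_chi(residue, 1L, d1)
  residue
}

#' Exhaustive joint chi1/chi2 scan for the minimum His-acid distance
#'
#' Scans the full 360-degree range of chi1 and chi2 of both the His and
#' the acid (Asp/Asn/Glu/Gln) on a joint grid of angular offsets from the
#' crystal conformation and reports the minimum achievable distance from
#' His ND1 to any hydrogen-bond-capable acid side-chain terminus, with
#' and without clash filtering. A grid point is clash-free when no moved
#' heavy atom comes within `clash_cutoff` of any static heavy atom of the
#' rest of the structure (waters excluded -- they can relocate) and the
#' two moved side chains do not clash with each other. For Asn/Gln, both
#' the amide O and N are tried as the contact terminus, since the
#' crystallographic O/N assignment is ambiguous.
#'
#' @param s a `structure3d`.
#' @param his,acid residue selectors.
#' @param grid_step grid spacing in degrees (default 10; 360 restricts
#'   the grid to the original conformation).
#' @param clash_cutoff hard-sphere heavy-atom clash floor, Angstrom.
#' @param contact_cutoff direct-contact threshold, Angstrom (strict `<`).
#' @param clash_filter set `FALSE` to skip clash checking (then the
#'   clash-free minimum equals the unconstrained one).
#' @return An object of class `rotamer_scan`: list with `grid_step`,
#'   `min_distance_unconstrained`, `min_distance_clashfree`,
#'   `argmin_chis` (offsets in degrees, c(his chi1, his chi2, acid chi1,
#'   acid chi2)), `original_distance`, `feasible_direct_contact`,
#'   `contact_cutoff`, `clash_cutoff`.
#' @export
scan_min_distance <- function(s, his, acid, grid_step = 10,
                              clash_cutoff = 2.5, contact_cutoff = 3.0,
                              clash_filter = TRUE) {
  his <- resolve_residue(s, his)
  acid <- resolve_residue(s, acid)
  contact_names <- acid_sidechain_atoms(attr(acid, "resname"))
  if (!length(contact_names))
    stop("acid residue must be ASP/ASN/GLU/GLN, got ", attr(acid, "resname"))
  deltas <- seq(0, 360 - grid_step, by = grid_step)
  if (grid_step >= 360) deltas <- 0

  his_conf <- conformer_bank(his, deltas, track = "ND1")
  acid_conf <- conformer_bank(acid, deltas, track = contact_names)

  nh <- nrow(his_conf$track[[1]])
  na_ <- nrow(acid_conf$track[[1]])
  H <- his_conf$track[[1]]                   # nh x 3 ND1 positions
  D <- NULL
  for (k in seq_along(acid_conf$track)) {
    A <- acid_conf$track[[k]]                # na x 3 positions of one O
    cross <- outer(rowSums(H^2), rep(1, na_)) +
      outer(rep(1, nh), rowSums(A^2)) - 2 * H %*% t(A)
    cross[cross < 0] <- 0
    D <- if (is.null(D)) cross else pmin(D, cross)
  }
  D <- sqrt(D)
  orig_i <- 1L  # offsets (0,0) are the first grid point by construction
  original_distance <- D[orig_i, orig_i]
  imin <- arrayInd(which.min(D), dim(D))
  min_unc <- D[imin[1], imin[2]]
  argmin <- c(his_conf$chis[imin[1], ], acid_conf$chis[imin[2], ])

  if (clash_filter) {
    env <- clash_environment(s, his, acid)
    his_ok <- conformer_clashfree(his_conf, env$static_for_his, clash_cutoff)
    acid_ok <- conformer_clashfree(acid_conf, env$static_for_acid, clash_cutoff)
    cf <- find_min_clashfree(D, his_conf, acid_conf, his_ok, acid_ok,
                             clash_cutoff)
    min_cf <- cf$dist
    if (is.finite(min_cf)) argmin_cf <- cf$chis else argmin_cf <- rep(NA_real_, 4)
  } else {
    min_cf <- min_unc
    argmin_cf <- argmin
  }

  out <- list(grid_step = grid_step,
              chi_grid = deltas,
              min_distance_unconstrained = min_unc,
              min_distance_clashfree = min_cf,
              argmin_chis = if (is.finite(min_cf)) argmin_cf else argmin,
              original_distance = original_distance,
              feasible_direct_contact = is.finite(min_cf) && min_cf < contact_cutoff,
              contact_cutoff = contact_cutoff,
              clash_cutoff = clash_cutoff,
              clash_filter = clash_filter)
  class(out) <- "rotamer_scan"
  out
}

# all conformers of one residue over the (chi1, chi2) offset grid;
# track = atom names whose positions are collected per grid point
conformer_bank <- function(res, deltas, track) {
  has_chi2 <- !is.null(residue_atom(res, "CG", required = FALSE)) &&
    length(moved_names(res, 2L)) > 0
  d2set <- if (has_chi2) deltas else 0
  grid <- expand.grid(d2 = d2set, d1 = deltas)  # d2 varies fastest
  grid <- grid[order(grid$d1, grid$d2), , drop = FALSE]
  n <- nrow(grid)
  mv_names <- moved_names(res, 1L)
  mv_idx <- which(res$name %in% mv_names)
  track_pos <- lapply(track, function(nm) matrix(NA_real_, n, 3))
  names(track_pos) <- track
  moved <- array(NA_real_, c(n, length(mv_idx), 3))
  for (g in seq_len(n)) {
    conf <- rotate_chi12(res, grid$d1[g], grid$d2[g])
    xyz <- coords_of(conf)
    moved[g, , ] <- xyz[mv_idx, , drop = FALSE]
    for (nm in track) {
      i <- which(conf$name == nm)
      if (length(i)) track_pos[[nm]][g, ] <- xyz[i[1], ]
    }
  }
  track_pos <- Filter(function(m) all(is.finite(m)), track_pos)
  if (!length(track_pos))
    stop("residue ", res$resname[1], " lacks all tracked atoms: ",
         paste(track, collapse = ", "))
  list(chis = as.matrix(grid[, c("d1", "d2")]), moved = moved,
       moved_names = res$name[mv_idx], track = track_pos, n = n)
}

clash_environment <- function(s, his, acid) {
  at <- s$atoms
  heavy <- at[!at$is_water & !at$is_hydrogen, , drop = FALSE]
  his_key <- paste(attr(his, "chain"), attr(his, "seqnum"))
  acid_key <- paste(attr(acid, "chain"), attr(acid, "seqnum"))
  keys <- paste(heavy$chain, heavy$seqnum)
  acid_moved <- moved_names(acid, 1L)
  his_moved <- moved_names(his, 1L)
  # static set for the His check: everything except the His residue itself
  # and the mobile atoms of the acid (those are checked pairwise)
  sfh <- heavy[keys != his_key &
                 !(keys == acid_key & heavy$name %in% acid_moved), , drop = FALSE]
  sfa <- heavy[keys != acid_key &
                 !(keys == his_key & heavy$name %in% his_moved), , drop = FALSE]
  list(static_for_his = coords_of(sfh), static_for_acid = coords_of(sfa))
}

conformer_clashfree <- function(conf, static_xyz, cutoff) {
  n <- conf$n
  ok <- rep(TRUE, n)
  if (nrow(static_xyz) == 0L) return(ok)
  c2 <- cutoff^2
  for (g in seq_len(n)) {
    m <- conf$moved[g, , , drop = FALSE]
    dim(m) <- c(dim(conf$moved)[2], 3)
    for (a in seq_len(nrow(m))) {
      d2 <- (static_xyz[, 1] - m[a, 1])^2 + (static_xyz[, 2] - m[a, 2])^2 +
        (static_xyz[, 3] - m[a, 3])^2
      if (any(d2 < c2)) { ok[g] <- FALSE; break }
    }
  }
  ok
}

# minimum of D over pairs whose conformers are individually clash-free
# and mutually clash-free; pairs are visited in ascending distance order
# so the first mutually clash-free pair is the minimum
find_min_clashfree <- function(D, his_conf, acid_conf, his_ok, acid_ok,
                               cutoff) {
  mask <- outer(his_ok, acid_ok, "&")
  idx <- which(mask)
  if (!length(idx)) return(list(dist = Inf, chis = rep(NA_real_, 4)))
  ord <- idx[order(D[idx])]
  c2 <- cutoff^2
  nh_atoms <- dim(his_conf$moved)[2]
  na_atoms <- dim(acid_conf$moved)[2]
  chunk <- 4096L
  nr <- nrow(D)
  for (start in seq(1L, length(ord), by = chunk)) {
    block <- ord[start:min(start + chunk - 1L, length(ord))]
    i <- ((block - 1L) %% nr) + 1L
    j <- ((block - 1L) %/% nr) + 1L
    free <- rep(TRUE, length(block))
    for (a in seq_len(nh_atoms)) {
      for (b in seq_len(na_atoms)) {
        d2 <- (his_conf$moved[cbind(i, a, 1)] - acid_conf$moved[cbind(j, b, 1)])^2 +
          (his_conf$moved[cbind(i, a, 2)] - acid_conf$moved[cbind(j, b, 2)])^2 +
          (his_conf$moved[cbind(i, a, 3)] - acid_conf$moved[cbind(j, b, 3)])^2
        free <- free & (d2 >= c2)
      }
    }
    hit <- which(free)
    if (length(hit)) {
      k <- hit[1]
      return(list(dist = D[block[k]],
                  chis = c(his_conf$chis[i[k], ], acid_conf$chis[j[k], ])))
    }
  }
  list(dist = Inf, chis = rep(NA_real_, 4))
}

#' Is a direct His-acid contact attainable?
#'
#' True when the clash-free scan minimum is strictly below the contact
#' cutoff recorded in the scan (matching the "shorter than 3 Angstrom"
#' rule -- a minimum of exactly 3.0 is not a contact).
#'
#' @param r a `rotamer_scan`.
#' @return logical scalar.
#' @export
direct_contact_feasible <- function(r) {
  stopifnot(inherits(r, "rotamer_scan"))
  is.finite(r$min_distance_clashfree) &&
    r$min_distance_clashfree < r$contact_cutoff
}

#' @export
print.rotamer_scan <- function(x, ...) {
  cat("<rotamer_scan> grid step ", x$grid_step, " deg\n", sep = "")
  cat(sprintf("  original d(ND1-acidO): %.2f A\n", x$original_distance))
  cat(sprintf("  min unconstrained:     %.2f A\n", x$min_distance_unconstrained))
  if (is.finite(x$min_distance_clashfree))
    cat(sprintf("  min clash-free:        %.2f A  at offsets (%s) deg\n",
                x$min_distance_clashfree,
                paste(round(x$argmin_chis), collapse = ", ")))
  else
    cat("  min clash-free:        none (all grid points clash)\n")
  cat(sprintf("  direct contact < %.1f A attainable: %s\n",
              x$contact_cutoff, x$feasible_direct_contact))
  invisible(x)
}
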