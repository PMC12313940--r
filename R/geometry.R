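# Metric geometry: distances, angles, hydrogen-bond partner detection,
# and the tetrahedrality of a water's coordination shell.
#
# Hydrogen-bond criteria are heavy-atom and distance-only: the
# crystallographic structures this package targets carry no hydrogens,
# and the published classification rules are pure distance cutoffs.

#' Euclidean distance between two points
#'
#' @param a,b numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
vec_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite coordinates")
  sqrt(sum((a - b)^2))
}

#' Angle subtended at a vertex
#'
#' @param a,vertex,c numeric 3-vectors; the angle a-vertex-c is returned.
#' @return Angle in degrees, in \[0, 180\].
#' @export
vec_angle <- function(a, vertex, c) {
  u <- as.numeric(a) - as.numeric(vertex)
  v <- as.numeric(c) - as.numeric(vertex)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (!all(is.finite(c(u, v)))) stop("non-finite coordinates")
  if (nu == 0 || nv == 0) stop("zero-length arm in angle computation")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# residue key for "same residue" tests
res_key <- function(at) paste(at$chain, at$seqnum, at$icode, sep = "\r")

# Uniform-grid neighbour search: indices of rows of `pts` within `r` of
# point p. Falls back to the trivial scan for small n.
grid_neighbours <- function(pts, p, r) {
  n <- nrow(pts)
  if (n <= 200L) {
    d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
    return(which(d2 <= r^2))
  }
  cell <- r
  key <- function(m) {
    i <- floor(m / cell)
    paste(i[, 1], i[, 2], i[, 3], sep = ",")
  }
  keys <- key(pts)
  buckets <- split(seq_len(n), keys)
  pi0 <- floor(p / cell)
  cand <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- paste(pi0[1] + dx, pi0[2] + dy, pi0[3] + dz, sep = ",")
    b <- buckets[[k]]
    if (!is.null(b)) cand <- c(cand, b)
  }
  if (!length(cand)) return(integer(0))
  d2 <- (pts[cand, 1] - p[1])^2 + (pts[cand, 2] - p[2])^2 + (pts[cand, 3] - p[3])^2
  cand[d2 <= r^2]
}

#' Find hydrogen-bond partners of an atom
#'
#' Returns every nitrogen or oxygen atom of *other* residues (protein
#' main chain, side chains, and waters) whose distance from the query
#' atom lies inside the detection window, sorted by distance. The default
#' window of \[2.2, 3.5\] Angstrom is the common crystallographic
#' heavy-atom hydrogen-bond range; stricter cutoffs (e.g. the 3.0
#' Angstrom "direct interaction" rule) belong to the classifier, not
#' here.
#'
#' @param s a `structure3d`.
#' @param atom a one-row atom record (e.g. `residue_atom` of a residue),
#'   or a list/character selector `"A:700:O"` (chain:seqnum:name).
#' @param window numeric length-2, `c(min, max)` in Angstrom.
#' @return A data.frame of class `hbond_list` with one row per partner:
#'   `chain`, `seqnum`, `resname`, `name`, `element`, `distance`,
#'   `category` (one of `sidechain-sidechain`, `sidechain-water`,
#'   `mainchain`, `water-water`).
#' @export
find_hbond_partners <- function(s, atom, window = c(2.2, 3.5)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  atom <- resolve_atom(s, atom)
  if (!atom$element %in% c("N", "O"))
    stop("hydrogen-bond query atom must be N or O, got ", atom$element)
  at <- s$atoms
  elig <- at$element %in% c("N", "O") & !at$is_hydrogen &
    res_key(at) != res_key(atom)
  cand <- at[elig, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_hbond_list())
  p <- c(atom$x, atom$y, atom$z)
  idx <- grid_neighbours(coords_of(cand), p, window[2])
  if (!length(idx)) return(empty_hbond_list())
  cand <- cand[idx, , drop = FALSE]
  d <- sqrt((cand$x - p[1])^2 + (cand$y - p[2])^2 + (cand$z - p[3])^2)
  keep <- d >= window[1] & d <= window[2]
  cand <- cand[keep, , drop = FALSE]
  d <- d[keep]
  if (nrow(cand) == 0L) return(empty_hbond_list())
  mainchain_names <- c("N", "O", "C", "CA", "OXT")
  cat <- character(nrow(cand))
  query_water <- isTRUE(atom$is_water)
  for (i in seq_len(nrow(cand))) {
    if (cand$is_water[i]) {
      cat[i] <- if (query_water) "water-water" else "sidechain-water"
    } else if (cand$name[i] %in% mainchain_names) {
      cat[i] <- "mainchain"
    } else {
      cat[i] <- if (query_water) "sidechain-water" else "sidechain-sidechain"
    }
  }
  out <- data.frame(chain = cand$chain, seqnum = cand$seqnum,
                    icode = cand$icode, resname = cand$resname,
                    name = cand$name, element = cand$element,
                    distance = d, category = cat, stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_list", "data.frame")
  out
}

empty_hbond_list <- function() {
  out <- data.frame(chain = character(0), seqnum = integer(0),
                    icode = character(0), resname = character(0),
                    name = character(0), element = character(0),
                    distance = numeric(0), category = character(0))
  class(out) <- c("hbond_list", "data.frame")
  out
}

resolve_atom <- function(s, atom) {
  if (is.data.frame(atom) && nrow(atom) == 1L) return(atom)
  if (is.character(atom) && length(atom) == 1L) {
    parts <- strsplit(atom, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("atom selector must be 'chain:seqnum:name'")
    res <- select_residue(s, parts[1], as.integer(parts[2]))
    return(residue_atom(res, parts[3]))
  }
  stop("cannot interpret atom selector")
}

#' Analyse the coordination shell of a water molecule
#'
#' Finds all hydrogen-bond partners of the water oxygen, measures every
#' partner-O-partner angle, and summarises how close the arrangement is
#' to ideal tetrahedral geometry. `tetrahedrality` is the mean absolute
#' deviation of the pair angles from 109.5 degrees; the water is called
#' tetrahedrally coordinated when it has exactly four partners and the
#' deviation does not exceed `angle_tol` (default 25 degrees, loose
#' enough to admit real crystallographic waters).
#'
#' @param s a `structure3d`.
#' @param water a residue selector for the water (e.g. `"W:700"`).
#' @param window hydrogen-bond detection window, Angstrom.
#' @param angle_tol tolerance on the mean deviation from 109.5 degrees.
#' @return An object of class `coordination_report`: list with `center`
#'   (the water O atom record), `partners` (an `hbond_list`), `count`,
#'   `pair_angles` (degrees), `tetrahedrality`, `is_tetrahedral`.
#' @export
water_coordination <- function(s, water, window = c(2.2, 3.5), angle_tol = 25) {
  res <- resolve_residue(s, water)
  o <- res[res$element == "O" & !res$is_hydrogen, , drop = FALSE]
  if (nrow(o) != 1L)
    stop("water residue must contain exactly one oxygen, found ", nrow(o))
  partners <- find_hbond_partners(s, o, window)
  n <- nrow(partners)
  angles <- numeric(0)
  if (n >= 2L) {
    pcoords <- t(vapply(seq_len(n), function(i) {
      res_i <- select_residue(s, partners$chain[i], partners$seqnum[i],
                              partners$icode[i])
      a <- residue_atom(res_i, partners$name[i])
      c(a$x, a$y, a$z)
    }, numeric(3)))
    ctr <- c(o$x, o$y, o$z)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      angles <- c(angles, vec_angle(pcoords[i, ], ctr, pcoords[j, ]))
  }
  tet <- if (length(angles)) mean(abs(angles - 109.5)) else NA_real_
  out <- list(center = o, partners = partners, count = n,
              pair_angles = angles, tetrahedrality = tet,
              is_tetrahedral = (n == 4L && is.finite(tet) && tet <= angle_tol),
              window = window, angle_tol = angle_tol)
  class(out) <- "coordination_report"
  out
}

#' @export
print.coordination_report <- function(x, ...) {
  cat("<coordination_report> water ", x$center$chain, ":", x$center$seqnum,
      "\n  partners: ", x$count, "\n", sep = "")
  if (x$count > 0) print.data.frame(x$partners, row.names = FALSE)
  if (is.finite(x$tetrahedrality))
    cat(sprintf("  tetrahedrality (mean |angle - 109.5|): %.1f deg\n",
                x$tetrahedrality))
  cat("  tetrahedral:", x$is_tetrahedral, "\n")
  invisible(x)
}
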