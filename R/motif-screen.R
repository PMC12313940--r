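# Three-residue structural motif matching by optimal rigid superposition
# (Kabsch), with the four-stage hydrogen-bond filter cascade that
# distinguishes a water-mediated triad from conventional triads and dyads:
#   1. no direct His-acid hydrogen bond (>= 3 A)
#   2. the Ser is a potential nucleophile
#   3. Ser OG hydrogen-bonds His NE2 (N-epsilon rule)
#   4. a water bridges the His-acid gap

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of two paired point sets, constrained to a
#' proper rotation (no reflection).
#'
#' @param coords_a,coords_b N x 3 matrices with paired rows, N >= 3.
#' @return List with `rmsd` (Angstrom), `rotation` (3 x 3, applied to
#'   centred `coords_b` to match centred `coords_a`), `translation`.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b) || ncol(coords_a) != 3 ||
      ncol(coords_b) != 3)
    stop("coordinate sets must be paired N x 3 matrices")
  n <- nrow(coords_a)
  if (n < 3) stop("superposition needs at least 3 points")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  if (max(svd(A)$d) < 1e-12 || max(svd(B)$d) < 1e-12)
    stop("degenerate point set")
  H <- t(B) %*% A
  sv <- svd(H)
  if (min(sv$d) < 1e-10 && sv$d[2] < 1e-10)
    stop("degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  Brot <- B %*% t(R)
  rmsd <- sqrt(sum((A - Brot)^2) / n)
  list(rmsd = rmsd, rotation = R, translation = ca - as.numeric(R %*% cb))
}

# mapped atom sets for the 13-atom superposition:
#   Ser: CA CB OG; His: CA CB CG ND1 NE2;
#   acid: CA CB branch-C terminal-1 terminal-2 (Glu/Gln CD in the branch slot)
motif_atom_map <- function(resname, slot) {
  switch(slot,
    ser = c("CA", "CB", "OG"),
    his = c("CA", "CB", "CG", "ND1", "NE2"),
    acid = switch(resname,
      ASP = c("CA", "CB", "CG", "OD1", "OD2"),
      ASN = c("CA", "CB", "CG", "OD1", "ND2"),
      GLU = c("CA", "CB", "CD", "OE1", "OE2"),
      GLN = c("CA", "CB", "CD", "OE1", "NE2"),
      stop("unsupported acid residue: ", resname)))
}

motif_coords <- function(res, slot, swap_terminals = FALSE) {
  nm <- motif_atom_map(attr(res, "resname") %||% res$resname[1], slot)
  if (swap_terminals && slot == "acid") nm[4:5] <- nm[5:4]
  rows <- lapply(nm, function(a) residue_atom(res, a, required = FALSE))
  if (any(vapply(rows, is.null, logical(1)))) return(NULL)
  do.call(rbind, lapply(rows, coords_of))
}

#' Build a three-residue motif query from a structure
#'
#' @param s a `structure3d`.
#' @param ser,his,acid residue selectors for the query site.
#' @param allowed_resnames residue names accepted in the acid slot of a
#'   target (default Asp with Asn/Glu/Gln exchanges).
#' @param rmsd_cutoff superposition cutoff, Angstrom (default 2.0).
#' @param ca_prefilter_tol tolerance on the three CA-CA distances used to
#'   prune candidate triples before superposition, Angstrom.
#' @return An object of class `motif_query`.
#' @export
motif_query <- function(s, ser, his, acid,
                        allowed_resnames = c("ASP", "ASN", "GLU", "GLN"),
                        rmsd_cutoff = 2.0, ca_prefilter_tol = 2.0) {
  ser <- resolve_residue(s, ser)
  his <- resolve_residue(s, his)
  acid <- resolve_residue(s, acid)
  cs <- motif_coords(ser, "ser"); ch <- motif_coords(his, "his")
  ca <- motif_coords(acid, "acid")
  if (is.null(cs) || is.null(ch) || is.null(ca))
    stop("query site is missing motif atoms")
  ca_d <- c(sh = vec_distance(cs[1, ], ch[1, ]),
            sa = vec_distance(cs[1, ], ca[1, ]),
            ha = vec_distance(ch[1, ], ca[1, ]))
  structure(list(coords = rbind(cs, ch, ca), ca_dists = ca_d,
                 allowed_resnames = allowed_resnames,
                 rmsd_cutoff = rmsd_cutoff,
                 ca_prefilter_tol = ca_prefilter_tol,
                 source_id = s$source_id),
            class = "motif_query")
}

# unique residues of given resnames having a CA, as a list of residue3d
residues_by_name <- function(s, resnames) {
  at <- s$atoms
  sel <- at[at$resname %in% resnames & !at$is_water, , drop = FALSE]
  if (!nrow(sel)) return(list())
  ids <- unique(sel[, c("chain", "seqnum")])
  out <- list()
  for (i in seq_len(nrow(ids))) {
    res <- select_residue(s, ids$chain[i], ids$seqnum[i])
    if ("CA" %in% res$name) out[[length(out) + 1L]] <- res
  }
  out
}

#' Match a three-residue motif against a target structure
#'
#' Enumerates all (Ser, His, acid) triples of the target whose three
#' CA-CA distances each lie within the prefilter tolerance of the
#' query's, superposes the 13-atom mapped sets by [kabsch_rmsd()]
#' (terminal-atom swap ambiguity resolved by taking the smaller RMSD of
#' the two assignments), and keeps hits at or below the RMSD cutoff.
#' This is the superposition stage only; [filter_cascade()] applies the
#' hydrogen-bond rules.
#'
#' @param query a `motif_query`.
#' @param target a `structure3d`.
#' @return data.frame of class `motif_hits` with one row per hit: residue
#'   identifiers of the triple and `rmsd`.
#' @export
match_motif <- function(query, target) {
  stopifnot(inherits(query, "motif_query"))
  sers <- residues_by_name(target, "SER")
  hiss <- residues_by_name(target, "HIS")
  acids <- residues_by_name(target, query$allowed_resnames)
  tol <- query$ca_prefilter_tol
  hits <- list()
  ca_pos <- function(res) coords_of(residue_atom(res, "CA"))
  for (sr in sers) for (hr in hiss) for (ar in acids) {
    ps <- ca_pos(sr); ph <- ca_pos(hr); pa <- ca_pos(ar)
    if (abs(vec_distance(ps, ph) - query$ca_dists["sh"]) > tol) next
    if (abs(vec_distance(ps, pa) - query$ca_dists["sa"]) > tol) next
    if (abs(vec_distance(ph, pa) - query$ca_dists["ha"]) > tol) next
    cs <- motif_coords(sr, "ser"); ch <- motif_coords(hr, "his")
    if (is.null(cs) || is.null(ch)) {
      warning("triple skipped: incomplete motif atoms at ",
              attr(sr, "chain"), ":", attr(sr, "seqnum"), " / ",
              attr(hr, "chain"), ":", attr(hr, "seqnum"))
      next
    }
    best <- Inf
    for (swap in c(FALSE, TRUE)) {
      caa <- motif_coords(ar, "acid", swap_terminals = swap)
      if (is.null(caa)) next
      r <- kabsch_rmsd(query$coords, rbind(cs, ch, caa))$rmsd
      best <- min(best, r)
    }
    if (!is.finite(best)) {
      warning("triple skipped: incomplete acid atoms at ",
              attr(ar, "chain"), ":", attr(ar, "seqnum"))
      next
    }
    if (best <= query$rmsd_cutoff)
      hits[[length(hits) + 1L]] <- data.frame(
        ser_chain = attr(sr, "chain"), ser_seqnum = attr(sr, "seqnum"),
        his_chain = attr(hr, "chain"), his_seqnum = attr(hr, "seqnum"),
        acid_chain = attr(ar, "chain"), acid_seqnum = attr(ar, "seqnum"),
        acid_resname = attr(ar, "resname"), rmsd = best,
        stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(ser_chain = character(0), ser_seqnum = integer(0),
               his_chain = character(0), his_seqnum = integer(0),
               acid_chain = character(0), acid_seqnum = integer(0),
               acid_resname = character(0), rmsd = numeric(0))
  out <- out[order(out$rmsd), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Apply the four-stage hydrogen-bond filter cascade to motif hits
#'
#' Sets, per hit: `no_direct_his_acid_hbond` (min His ND1 to acid
#' side-chain terminus distance at or above `direct_cutoff`),
#' `ser_is_nucleophile`, `ser_OG_his_NE2_hbond` (OG-NE2 inside the
#' window), `water_bridges_gap` (some water O inside the window of both
#' ND1 and an acid terminus of the hit's acid), and `passes_all` (their
#' conjunction). RMSD values are untouched.
#'
#' @param hits a `motif_hits` table from [match_motif()].
#' @param target the same `structure3d` the hits came from.
#' @param direct_cutoff Angstrom, default 3.0.
#' @param window hydrogen-bond window, Angstrom.
#' @return The hits table with the four flag columns and `passes_all`.
#' @export
filter_cascade <- function(hits, target, direct_cutoff = 3.0,
                           window = c(2.2, 3.5)) {
  n <- nrow(hits)
  f1 <- f2 <- f3 <- f4 <- logical(n)
  at <- target$atoms
  waters <- at[at$is_water & at$element == "O", , drop = FALSE]
  for (i in seq_len(n)) {
    his <- select_residue(target, hits$his_chain[i], hits$his_seqnum[i])
    ser <- select_residue(target, hits$ser_chain[i], hits$ser_seqnum[i])
    acid <- select_residue(target, hits$acid_chain[i], hits$acid_seqnum[i])
    nd1 <- residue_atom(his, "ND1", required = FALSE)
    ne2 <- residue_atom(his, "NE2", required = FALSE)
    og <- residue_atom(ser, "OG", required = FALSE)
    term <- acid[acid$name %in% acid_sidechain_atoms(attr(acid, "resname")), ,
                 drop = FALSE]
    if (is.null(nd1) || nrow(term) == 0L) {
      warning("hit ", i, ": missing His ND1 or acid terminus; flags FALSE")
      next
    }
    p_nd1 <- c(nd1$x, nd1$y, nd1$z)
    d_ha <- sqrt((term$x - p_nd1[1])^2 + (term$y - p_nd1[2])^2 +
                   (term$z - p_nd1[3])^2)
    f1[i] <- min(d_ha) >= direct_cutoff
    f2[i] <- suppressWarnings(ser_is_nucleophile(target, ser, his, window))
    if (!is.null(og) && !is.null(ne2)) {
      d_og <- vec_distance(c(og$x, og$y, og$z), c(ne2$x, ne2$y, ne2$z))
      f3[i] <- d_og >= window[1] && d_og <= window[2]
    }
    if (nrow(waters)) {
      d_wn <- sqrt((waters$x - p_nd1[1])^2 + (waters$y - p_nd1[2])^2 +
                     (waters$z - p_nd1[3])^2)
      ok_n <- d_wn >= window[1] & d_wn <= window[2]
      if (any(ok_n)) {
        for (wi in which(ok_n)) {
          d_wa <- sqrt((term$x - waters$x[wi])^2 + (term$y - waters$y[wi])^2 +
                         (term$z - waters$z[wi])^2)
          if (any(d_wa >= window[1] & d_wa <= window[2])) { f4[i] <- TRUE; break }
        }
      }
    }
  }
  hits$no_direct_his_acid_hbond <- f1
  hits$ser_is_nucleophile <- f2
  hits$ser_OG_his_NE2_hbond <- f3
  hits$water_bridges_gap <- f4
  hits$passes_all <- f1 & f2 & f3 & f4
  hits
}

#' Screen a panel of structures for the water-mediated triad motif
#'
#' Runs [match_motif()] plus [filter_cascade()] on each target file and
#' summarises hits per target. Unreadable targets get an error-status row
#' and the screen continues.
#'
#' @param query a `motif_query`.
#' @param targets character vector of structure file paths, or a list of
#'   `structure3d` objects.
#' @param direct_cutoff,window cascade parameters.
#' @return data.frame of class `screen_table`: one row per target with
#'   `target_id`, `n_rmsd_hits`, `n_passing_hits`, `best_rmsd`,
#'   `best_triple`, `status`; attribute `n_passing_targets`.
#' @export
screen_panel <- function(query, targets, direct_cutoff = 3.0,
                         window = c(2.2, 3.5)) {
  rows <- lapply(targets, function(tg) {
    s <- tryCatch(
      if (inherits(tg, "structure3d")) tg else read_structure(tg),
      error = function(e) e)
    if (inherits(s, "error")) {
      id <- if (is.character(tg)) tools::file_path_sans_ext(basename(tg))
            else "<object>"
      return(data.frame(target_id = id, n_rmsd_hits = NA_integer_,
                        n_passing_hits = NA_integer_, best_rmsd = NA_real_,
                        best_triple = NA_character_,
                        status = paste("error:", conditionMessage(s)),
                        stringsAsFactors = FALSE))
    }
    hits <- match_motif(query, s)
    hits <- filter_cascade(hits, s, direct_cutoff, window)
    pass <- hits[hits$passes_all, , drop = FALSE]
    best <- if (nrow(pass)) pass[1, ] else if (nrow(hits)) hits[1, ] else NULL
    data.frame(
      target_id = s$source_id,
      n_rmsd_hits = nrow(hits),
      n_passing_hits = nrow(pass),
      best_rmsd = if (is.null(best)) NA_real_ else best$rmsd,
      best_triple = if (is.null(best)) NA_character_ else
        sprintf("%s:%d/%s:%d/%s:%d", best$ser_chain, best$ser_seqnum,
                best$his_chain, best$his_seqnum, best$acid_chain,
                best$acid_seqnum),
      status = "ok", stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(0), n_rmsd_hits = integer(0),
               n_passing_hits = integer(0), best_rmsd = numeric(0),
               best_triple = character(0), status = character(0))
  rownames(out) <- NULL
  class(out) <- c("screen_table", "data.frame")
  attr(out, "n_passing_targets") <-
    sum(out$n_passing_hits >= 1L, na.rm = TRUE)
  out
}

#' @export
print.screen_table <- function(x, ...) {
  cat("Motif screen:", nrow(x), "targets,",
      attr(x, "n_passing_targets"), "with a passing hit\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
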