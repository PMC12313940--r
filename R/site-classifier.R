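# Classification of Ser-His active sites into four architectures:
#   CONVENTIONAL_TRIAD   acid side chain directly H-bonded to His ND1 (< 3 A)
#   WATER_MEDIATED_TRIAD a water bridges His ND1 and the acid side chain
#   MAINCHAIN_DYAD       a main-chain carbonyl O (or N) orients the His
#   BARE_DYAD            nothing within range of ND1
# The Ser pairs with His through OG-NE2 (the N-epsilon rule), leaving ND1
# free for the third partner.

CLASSIFICATION_LABELS <- c("CONVENTIONAL_TRIAD", "WATER_MEDIATED_TRIAD",
                           "MAINCHAIN_DYAD", "BARE_DYAD", "NOT_SITE")

ACID_RESNAMES <- c("ASP", "ASN", "GLU", "GLN")

# hydrogen-bond-capable side-chain termini of the acid/amide position
acid_sidechain_atoms <- function(resname) {
  switch(resname,
         ASP = c("OD1", "OD2"),
         ASN = c("OD1", "ND2"),
         GLU = c("OE1", "OE2"),
         GLN = c("OE1", "NE2"),
         character(0))
}

#' Find Ser-His pairs obeying the N-epsilon rule
#'
#' A catalytic Ser-His pair requires the Ser OG to hydrogen-bond the His
#' NE2 (epsilon nitrogen); pairings through ND1 are rejected, since ND1
#' must stay free for the acid (or bridging water).
#'
#' @param s a `structure3d`.
#' @param window hydrogen-bond window in Angstrom.
#' @return data.frame with one row per pair: `ser_chain`, `ser_seqnum`,
#'   `his_chain`, `his_seqnum`, `d_OG_NE2`.
#' @export
find_ser_his_pairs <- function(s, window = c(2.2, 3.5)) {
  at <- s$atoms
  og <- at[at$resname == "SER" & at$name == "OG", , drop = FALSE]
  ne2 <- at[at$resname == "HIS" & at$name == "NE2", , drop = FALSE]
  nd1 <- at[at$resname == "HIS" & at$name == "ND1", , drop = FALSE]
  out <- data.frame(ser_chain = character(0), ser_seqnum = integer(0),
                    his_chain = character(0), his_seqnum = integer(0),
                    d_OG_NE2 = numeric(0), stringsAsFactors = FALSE)
  if (nrow(og) == 0L || nrow(ne2) == 0L) return(out)
  for (i in seq_len(nrow(og))) {
    for (j in seq_len(nrow(ne2))) {
      d <- vec_distance(c(og$x[i], og$y[i], og$z[i]),
                        c(ne2$x[j], ne2$y[j], ne2$z[j]))
      if (d < window[1] || d > window[2]) next
      # reject pairing via ND1: OG must face the epsilon nitrogen
      k <- which(nd1$chain == ne2$chain[j] & nd1$seqnum == ne2$seqnum[j])
      if (length(k)) {
        d_nd1 <- vec_distance(c(og$x[i], og$y[i], og$z[i]),
                              c(nd1$x[k[1]], nd1$y[k[1]], nd1$z[k[1]]))
        if (d_nd1 < d) next
      }
      out <- rbind(out, data.frame(
        ser_chain = og$chain[i], ser_seqnum = og$seqnum[i],
        his_chain = ne2$chain[j], his_seqnum = ne2$seqnum[j],
        d_OG_NE2 = d, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Is the Ser a potential nucleophile?
#'
#' True when the Ser has an OG that either hydrogen-bonds the His NE2
#' (within the window) or carries a covalent modification -- any
#' non-water heavy atom of another residue within 1.8 Angstrom of OG.
#' Covalently modified serines (e.g. cacodylate adducts from the
#' crystallisation buffer) are accepted with a warning rather than
#' rejected: the modification marks the OG as reactive.
#'
#' @param s a `structure3d`.
#' @param ser,his residue selectors.
#' @param window hydrogen-bond window, Angstrom.
#' @return logical scalar.
#' @export
ser_is_nucleophile <- function(s, ser, his, window = c(2.2, 3.5)) {
  ser <- resolve_residue(s, ser)
  his <- resolve_residue(s, his)
  og <- residue_atom(ser, "OG", required = FALSE)
  if (is.null(og)) return(FALSE)
  ne2 <- residue_atom(his, "NE2", required = FALSE)
  if (!is.null(ne2)) {
    d <- vec_distance(c(og$x, og$y, og$z), c(ne2$x, ne2$y, ne2$z))
    if (d >= window[1] && d <= window[2]) return(TRUE)
  }
  at <- s$atoms
  other <- at[!at$is_water & !at$is_hydrogen &
                res_key(at) != res_key(og), , drop = FALSE]
  if (nrow(other)) {
    d2 <- (other$x - og$x)^2 + (other$y - og$y)^2 + (other$z - og$z)^2
    if (any(d2 <= 1.8^2)) {
      warning("Ser ", attr(ser, "chain"), ":", attr(ser, "seqnum"),
              " OG appears covalently modified; accepted as nucleophile")
      return(TRUE)
    }
  }
  FALSE
}

#' Classify the third catalytic position of a Ser-His pair
#'
#' Applies, in strict order: (1) any Asp/Asn/Glu/Gln side-chain terminus
#' closer than `direct_cutoff` to His ND1 gives a conventional triad;
#' (2) otherwise a water oxygen inside the hydrogen-bond window of both
#' ND1 and such an acid terminus gives a water-mediated triad (the water
#' closest to ND1 wins); (3) otherwise a main-chain carbonyl O or amide N
#' of any other residue within `direct_cutoff` of ND1 gives a main-chain
#' dyad; (4) otherwise a bare dyad. The 3 Angstrom direct cutoff is the
#' published "direct hydrogen bond" rule; in the CE20 exemplar the acid
#' sits 4.0 Angstrom from ND1 with the bridging water 2.9 Angstrom from
#' each side.
#'
#' @param s a `structure3d`.
#' @param ser,his residue selectors for a valid N-epsilon pair.
#' @param direct_cutoff direct-contact cutoff, Angstrom (default 3.0).
#' @param window hydrogen-bond window, Angstrom.
#' @param acid optional residue selector restricting the acid position to
#'   one named residue (used by [analyze_site()]).
#' @return An object of class `catalytic_site`: list with `label`, the
#'   residues involved, and all measured distances (`d_OG_NE2`,
#'   `d_ND1_acidO`, `d_ND1_water`, `d_water_acidO`), plus
#'   `mainchain_partner` for dyads.
#' @export
classify_third_position <- function(s, ser, his, direct_cutoff = 3.0,
                                    window = c(2.2, 3.5), acid = NULL) {
  ser <- resolve_residue(s, ser)
  his <- resolve_residue(s, his)
  nd1 <- residue_atom(his, "ND1", required = FALSE)
  if (is.null(nd1))
    stop("His ", attr(his, "chain"), ":", attr(his, "seqnum"),
         " lacks the ND1 atom; cannot classify")
  ne2 <- residue_atom(his, "NE2", required = FALSE)
  og <- residue_atom(ser, "OG", required = FALSE)
  d_og_ne2 <- if (!is.null(og) && !is.null(ne2))
    vec_distance(c(og$x, og$y, og$z), c(ne2$x, ne2$y, ne2$z)) else NA_real_
  p_nd1 <- c(nd1$x, nd1$y, nd1$z)

  at <- s$atoms
  # candidate acid termini
  acid_rows <- at[at$resname %in% ACID_RESNAMES & !at$is_water, , drop = FALSE]
  if (!is.null(acid)) {
    aid <- parse_res_id(acid)
    acid_rows <- acid_rows[acid_rows$chain == aid$chain &
                             acid_rows$seqnum == aid$seqnum, , drop = FALSE]
  }
  # exclude the His itself (GLN NE2 shares a name with His NE2 but His is
  # not an acid resname, so only self-exclusion by residue is needed)
  acid_rows <- acid_rows[res_key(acid_rows) != res_key(nd1), , drop = FALSE]
  if (nrow(acid_rows)) {
    keep <- mapply(function(rn, nm) nm %in% acid_sidechain_atoms(rn),
                   acid_rows$resname, acid_rows$name)
    acid_rows <- acid_rows[as.logical(keep), , drop = FALSE]
  }

  site <- list(ser = res_id_of(ser), his = res_id_of(his), acid = NULL,
               bridge_water = NULL, d_OG_NE2 = d_og_ne2,
               d_ND1_acidO = NA_real_, d_ND1_water = NA_real_,
               d_water_acidO = NA_real_, mainchain_partner = NULL,
               direct_cutoff = direct_cutoff, window = window,
               label = "BARE_DYAD")
  class(site) <- "catalytic_site"

  if (nrow(acid_rows)) {
    d_acid <- sqrt((acid_rows$x - p_nd1[1])^2 + (acid_rows$y - p_nd1[2])^2 +
                     (acid_rows$z - p_nd1[3])^2)
    # rule (1): direct contact
    if (any(d_acid < direct_cutoff)) {
      i <- which.min(d_acid)
      site$acid <- list(chain = acid_rows$chain[i],
                        seqnum = acid_rows$seqnum[i],
                        resname = acid_rows$resname[i])
      site$d_ND1_acidO <- min(d_acid[acid_rows$chain == acid_rows$chain[i] &
                                       acid_rows$seqnum == acid_rows$seqnum[i]])
      site$label <- "CONVENTIONAL_TRIAD"
      return(site)
    }
  }

  # rule (2): water bridge
  waters <- at[at$is_water & at$element == "O", , drop = FALSE]
  if (nrow(waters) && nrow(acid_rows)) {
    d_w <- sqrt((waters$x - p_nd1[1])^2 + (waters$y - p_nd1[2])^2 +
                  (waters$z - p_nd1[3])^2)
    in_win <- d_w >= window[1] & d_w <= window[2]
    cand <- which(in_win)[order(d_w[in_win])]  # closest water wins
    for (wi in cand) {
      p_w <- c(waters$x[wi], waters$y[wi], waters$z[wi])
      d_wa <- sqrt((acid_rows$x - p_w[1])^2 + (acid_rows$y - p_w[2])^2 +
                     (acid_rows$z - p_w[3])^2)
      ok <- d_wa >= window[1] & d_wa <= window[2]
      if (any(ok)) {
        ai <- which(ok)[which.min(d_wa[ok])]
        same_acid <- acid_rows$chain == acid_rows$chain[ai] &
          acid_rows$seqnum == acid_rows$seqnum[ai]
        d_acid_nd1 <- sqrt((acid_rows$x[same_acid] - p_nd1[1])^2 +
                             (acid_rows$y[same_acid] - p_nd1[2])^2 +
                             (acid_rows$z[same_acid] - p_nd1[3])^2)
        site$acid <- list(chain = acid_rows$chain[ai],
                          seqnum = acid_rows$seqnum[ai],
                          resname = acid_rows$resname[ai])
        site$bridge_water <- list(chain = waters$chain[wi],
                                  seqnum = waters$seqnum[wi])
        site$d_ND1_water <- d_w[wi]
        site$d_water_acidO <- d_wa[ai]
        site$d_ND1_acidO <- min(d_acid_nd1)
        site$label <- "WATER_MEDIATED_TRIAD"
        return(site)
      }
    }
  }

  # rule (3): main-chain partner
  mc <- at[!at$is_water & !at$is_hydrogen & at$name %in% c("O", "N") &
             res_key(at) != res_key(nd1), , drop = FALSE]
  if (nrow(mc)) {
    d_mc <- sqrt((mc$x - p_nd1[1])^2 + (mc$y - p_nd1[2])^2 +
                   (mc$z - p_nd1[3])^2)
    if (any(d_mc < direct_cutoff)) {
      i <- which.min(d_mc)
      site$mainchain_partner <- list(chain = mc$chain[i], seqnum = mc$seqnum[i],
                                     resname = mc$resname[i], name = mc$name[i],
                                     distance = d_mc[i])
      site$label <- "MAINCHAIN_DYAD"
      return(site)
    }
  }

  site  # rule (4): BARE_DYAD
}

res_id_of <- function(res) {
  list(chain = attr(res, "chain"), seqnum = attr(res, "seqnum"),
       resname = attr(res, "resname"))
}

#' Full evidence bundle for a named catalytic site
#'
#' Runs [classify_third_position()] constrained to the named acid,
#' [water_coordination()] on the bridging water if one is found, and
#' [catalytic_bfactors()] on the three residues, returning a single
#' report.
#'
#' @param s a `structure3d`.
#' @param ser,his,acid residue selectors (e.g. `"A:112"`, `"A:515"`,
#'   `"A:513"`).
#' @param direct_cutoff,window as in [classify_third_position()].
#' @return An object of class `site_report`: list with elements `site`
#'   (a `catalytic_site`), `coordination` (a `coordination_report` or
#'   NULL), `bfactors` (a `bfactor_table`), `ser_nucleophile` (logical).
#' @export
analyze_site <- function(s, ser, his, acid, direct_cutoff = 3.0,
                         window = c(2.2, 3.5)) {
  site <- classify_third_position(s, ser, his, direct_cutoff = direct_cutoff,
                                  window = window, acid = acid)
  coord <- NULL
  if (!is.null(site$bridge_water)) {
    coord <- water_coordination(
      s, sprintf("%s:%d", site$bridge_water$chain, site$bridge_water$seqnum),
      window = window)
  }
  bf <- catalytic_bfactors(s, list(ser, his, acid))
  nuc <- ser_is_nucleophile(s, ser, his, window)
  out <- list(site = site, coordination = coord, bfactors = bf,
              ser_nucleophile = nuc)
  class(out) <- "site_report"
  out
}

#' @export
print.catalytic_site <- function(x, ...) {
  cat("<catalytic_site> ", x$label, "\n", sep = "")
  fmt_id <- function(id) if (is.null(id)) "-" else
    paste0(id$resname %||% "", " ", id$chain, ":", id$seqnum)
  cat("  Ser: ", fmt_id(x$ser), "   His: ", fmt_id(x$his),
      "   acid: ", fmt_id(x$acid), "\n", sep = "")
  d <- function(v) if (is.na(v)) "  -  " else sprintf("%5.2f", v)
  cat("  d(OG-NE2) ", d(x$d_OG_NE2), "  d(ND1-acidO) ", d(x$d_ND1_acidO),
      "  d(ND1-water) ", d(x$d_ND1_water), "  d(water-acidO) ",
      d(x$d_water_acidO), " A\n", sep = "")
  if (!is.null(x$mainchain_partner))
    cat(sprintf("  main-chain partner: %s %s:%d %s at %.2f A\n",
                x$mainchain_partner$resname, x$mainchain_partner$chain,
                x$mainchain_partner$seqnum, x$mainchain_partner$name,
                x$mainchain_partner$distance))
  invisible(x)
}

#' @export
print.site_report <- function(x, ...) {
  print(x$site)
  cat("  Ser nucleophile:", x$ser_nucleophile, "\n")
  if (!is.null(x$coordination))
    cat(sprintf("  bridge water: %d partners, tetrahedrality %.1f deg\n",
                x$coordination$count,
                x$coordination$tetrahedrality))
  if (nrow(x$bfactors))
    cat(sprintf("  CA B-factors: %.2f - %.2f A^2\n",
                attr(x$bfactors, "min"), attr(x$bfactors, "max")))
  invisible(x)
}
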