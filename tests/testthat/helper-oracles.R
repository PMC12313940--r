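# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: the quaternion RMSD is Horn's closed-form
# eigenvalue method (vs the SVD Kabsch), the hydrogen-bond scan is a
# plain all-pairs loop (vs the grid search), and the rotamer oracle is a
# naive nested loop over rotate_about_chi.

# Horn's quaternion absolute-orientation RMSD
quaternion_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  M <- t(B) %*% A
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# all-pairs hydrogen-bond partner scan (no grid, no sorting shortcuts)
brute_force_partners <- function(s, atom, window) {
  at <- s$atoms
  key <- paste(at$chain, at$seqnum, at$icode)
  akey <- paste(atom$chain, atom$seqnum, atom$icode)
  hits <- data.frame()
  for (i in seq_len(nrow(at))) {
    if (key[i] == akey) next
    if (!(at$element[i] %in% c("N", "O")) || at$is_hydrogen[i]) next
    d <- sqrt((at$x[i] - atom$x)^2 + (at$y[i] - atom$y)^2 +
                (at$z[i] - atom$z)^2)
    if (d >= window[1] && d <= window[2])
      hits <- rbind(hits, data.frame(chain = at$chain[i],
                                     seqnum = at$seqnum[i],
                                     name = at$name[i], distance = d))
  }
  if (nrow(hits)) hits[order(hits$distance), ] else hits
}

# random protein-like structure: n atoms in a box, random N/C/O elements
random_structure <- function(n, seed, box = 20) {
  set.seed(seed)
  el <- sample(c("N", "O", "C"), n, replace = TRUE)
  atoms <- data.frame(
    serial = seq_len(n),
    name = paste0(el, seq_len(n) %% 10),
    altloc = "", resname = "GLY",
    chain = "A", seqnum = rep(seq_len(ceiling(n / 4)), each = 4)[seq_len(n)],
    icode = "",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    occupancy = 1, bfactor = 20, element = el,
    stringsAsFactors = FALSE)
  new_structure(atoms, source_id = paste0("random", seed))
}

# apply a random rigid motion (seeded) to a structure
rigid_motion <- function(s, seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  tr <- runif(3, -15, 15)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, tr, FUN = "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# naive joint rotamer scan: nested loops over rotate_about_chi, direct
# distance evaluation, no precomputation or ordering tricks
naive_scan_min <- function(s, his_sel, acid_sel, step) {
  his <- hydrotriad:::resolve_residue(s, his_sel)
  acid <- hydrotriad:::resolve_residue(s, acid_sel)
  terms <- hydrotriad:::acid_sidechain_atoms(attr(acid, "resname"))
  deltas <- seq(0, 360 - step, by = step)
  best <- Inf
  for (h1 in deltas) for (h2 in deltas) {
    hh <- hydrotriad:::rotate_chi12(his, h1, h2)
    nd1 <- hydrotriad:::residue_atom(hh, "ND1")
    p <- c(nd1$x, nd1$y, nd1$z)
    for (a1 in deltas) for (a2 in deltas) {
      aa <- hydrotriad:::rotate_chi12(acid, a1, a2)
      tt <- aa[aa$name %in% terms, ]
      d <- min(sqrt((tt$x - p[1])^2 + (tt$y - p[2])^2 + (tt$z - p[3])^2))
      if (d < best) best <- d
    }
  }
  best
}

# ideal tetrahedron directions (unit vectors from the centre)
tetra_dirs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

# Michaelis-Menten assay world: the seven published substrate
# concentrations, in triplicate as assays are run
mm_world <- function() {
  list(S = c(0.05, 0.1, 0.2, 0.5, 1, 2, 4), n_rep = 3L,
       enzyme_conc_M = 1e-7, kcat = 9.70, km = 0.62)
}
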