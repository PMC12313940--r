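# Coordinate model I/O: fixed-column PDB and mmCIF (atom_site loop).
# A structure is a flat atom table; residues are views into it.

WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD")

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by [read_structure()] and the fixture
#' generator. Validates the atom-record invariants: finite coordinates,
#' occupancy in \[0, 1\], non-negative B-factors.
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `seqnum`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `bfactor`, `element`.
#' @param source_id free-text identifier (file stem or accession).
#' @param model model number the coordinates came from.
#' @return An object of class `structure3d`: a list with elements `atoms`
#'   (the table, with derived logical columns `is_water`, `is_hydrogen`),
#'   `source_id` and `model`.
#' @export
new_structure <- function(atoms, source_id = "structure", model = 1L) {
  needed <- c("serial", "name", "altloc", "resname", "chain", "seqnum",
              "icode", "x", "y", "z", "occupancy", "bfactor", "element")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  if (any(atoms$bfactor < 0, na.rm = TRUE))
    stop("negative B-factor")
  atoms$element <- infer_elements(atoms$element, atoms$name)
  atoms$is_water <- atoms$resname %in% WATER_RESNAMES
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id, model = as.integer(model)),
            class = "structure3d")
}

infer_elements <- function(element, name) {
  element <- toupper(trimws(as.character(element)))
  name <- toupper(trimws(as.character(name)))
  blank <- is.na(element) | element == "" | element == "?" | element == "."
  if (any(blank)) {
    guess <- vapply(name[blank], function(nm) {
      letters_only <- gsub("[^A-Z]", "", nm)
      if (nchar(letters_only) == 0L) return("X")
      # leading digit (e.g. 1HB) marks a hydrogen per PDB convention
      if (grepl("^[0-9]", nm)) return(substr(letters_only, 1L, 1L))
      substr(letters_only, 1L, 1L)
    }, character(1))
    element[blank] <- guess
  }
  element
}

#' Read a macromolecular coordinate file
#'
#' Parses a PDB or mmCIF file into a single-conformer atom model. Only the
#' first model is retained; within each alternate-location group the
#' conformer with the highest occupancy is kept (ties broken by the
#' alphabetically lowest altloc id). Hydrogens are retained but flagged;
#' waters (residue names HOH/WAT/H2O/DOD) are flagged by `is_water`.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (sniff from extension,
#'   then content).
#' @return A `structure3d` object.
#' @seealso [write_structure()], [select_residue()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
              else if (ext %in% c("pdb", "ent")) "pdb"
              else if (any(grepl("^_atom_site\\.", lines))) "mmcif"
              else "pdb"
  }
  atoms <- switch(format,
    pdb = parse_pdb_lines(lines, path),
    mmcif = parse_mmcif_lines(lines, path))
  if (nrow(atoms) == 0L)
    stop("empty structure: no atom records in ", path)
  atoms <- resolve_altlocs(atoms)
  s <- new_structure(atoms, source_id = tools::file_path_sans_ext(basename(path)),
                     model = attr(atoms, "model") %||% 1L)
  check_waters(s)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_waters <- function(s) {
  w <- s$atoms[s$atoms$is_water, , drop = FALSE]
  if (nrow(w)) {
    key <- paste(w$chain, w$seqnum, w$icode)
    has_o <- tapply(w$element == "O", key, any)
    if (!all(has_o))
      warning("water residue(s) without an oxygen atom: ",
              paste(names(has_o)[!has_o], collapse = "; "))
  }
  invisible(s)
}

parse_pdb_lines <- function(lines, path) {
  model <- 1L
  in_model <- 0L
  keep <- logical(length(lines))
  rec <- substr(lines, 1, 6)
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      in_model <- in_model + 1L
    } else if (startsWith(r, "ENDMDL")) {
      if (in_model >= 1L) break
    } else if (r == "ATOM  " || r == "HETATM") {
      if (in_model <= 1L) keep[i] <- TRUE
    }
  }
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(serial = integer(0), name = character(0),
                      altloc = character(0), resname = character(0),
                      chain = character(0), seqnum = integer(0),
                      icode = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), occupancy = numeric(0),
                      bfactor = numeric(0), element = character(0)))
  ln <- lines[idx]
  num <- function(from, to, what, default = NA_real_) {
    txt <- trimws(substr(ln, from, to))
    out <- suppressWarnings(as.numeric(txt))
    bad <- is.na(out) & txt != ""
    if (any(bad))
      stop("cannot parse ", what, " at line ", idx[which(bad)[1]],
           " of ", path, ": '", txt[which(bad)[1]], "'")
    out[txt == ""] <- default
    out
  }
  occ <- num(55, 60, "occupancy", default = 1)
  bf <- num(61, 66, "B-factor", default = 0)
  occ[is.na(occ)] <- 1
  bf[is.na(bf)] <- 0
  data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = trimws(substr(ln, 13, 16)),
    altloc = trimws(substr(ln, 17, 17)),
    resname = trimws(substr(ln, 18, 20)),
    chain = trimws(substr(ln, 22, 22)),
    seqnum = as.integer(num(23, 26, "residue number")),
    icode = trimws(substr(ln, 27, 27)),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = occ, bfactor = bf,
    element = trimws(substr(ln, 77, 78)),
    stringsAsFactors = FALSE)
}

parse_mmcif_lines <- function(lines, path) {
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx))
    stop("no _atom_site loop found in ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  after <- lines[(max(tag_idx) + 1L):length(lines)]
  stop_at <- grep("^(_|loop_|#|data_)", trimws(after))
  if (length(stop_at)) after <- after[seq_len(min(stop_at) - 1L)]
  after <- after[trimws(after) != ""]
  tokens <- scan(text = paste(after, collapse = "\n"), what = "character",
                 quote = "'\"", quiet = TRUE)
  ncol <- length(tags)
  if (length(tokens) %% ncol != 0L)
    stop("malformed _atom_site loop in ", path, ": ", length(tokens),
         " values for ", ncol, " fields")
  m <- matrix(tokens, ncol = ncol, byrow = TRUE)
  colnames(m) <- tags
  col <- function(auth, label, default = NA_character_) {
    if (auth %in% tags) m[, auth]
    else if (!is.na(label) && label %in% tags) m[, label]
    else rep(default, nrow(m))
  }
  clean <- function(x) { x[x %in% c(".", "?")] <- ""; x }
  numcol <- function(auth, label, what, default = NA_real_) {
    txt <- clean(col(auth, label))
    out <- suppressWarnings(as.numeric(txt))
    bad <- is.na(out) & txt != ""
    if (any(bad))
      stop("cannot parse _atom_site field ", what, " in ", path,
           ": '", txt[which(bad)[1]], "'")
    out[txt == ""] <- default
    out
  }
  model_num <- numcol("pdbx_PDB_model_num", NA, "model", default = 1)
  first_model <- model_num == min(model_num, na.rm = TRUE)
  at <- data.frame(
    serial = as.integer(numcol("id", NA, "id")),
    name = clean(col("auth_atom_id", "label_atom_id")),
    altloc = clean(col("label_alt_id", NA)),
    resname = clean(col("auth_comp_id", "label_comp_id")),
    chain = clean(col("auth_asym_id", "label_asym_id")),
    seqnum = as.integer(numcol("auth_seq_id", "label_seq_id", "residue number")),
    icode = clean(col("pdbx_PDB_ins_code", NA, "")),
    x = numcol("Cartn_x", NA, "Cartn_x"),
    y = numcol("Cartn_y", NA, "Cartn_y"),
    z = numcol("Cartn_z", NA, "Cartn_z"),
    occupancy = numcol("occupancy", NA, "occupancy", default = 1),
    bfactor = numcol("B_iso_or_equiv", NA, "B_iso_or_equiv", default = 0),
    element = clean(col("type_symbol", NA, "")),
    stringsAsFactors = FALSE)
  at <- at[first_model, , drop = FALSE]
  attr(at, "model") <- as.integer(min(model_num, na.rm = TRUE))
  at
}

# Within each (chain, seqnum, icode, atom name) group keep the conformer
# with the highest occupancy; ties go to the lowest altloc character.
resolve_altlocs <- function(atoms) {
  if (!any(atoms$altloc != "")) return(atoms)
  key <- paste(atoms$chain, atoms$seqnum, atoms$icode, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- atoms[keep, , drop = FALSE]
  out[order(out$serial), , drop = FALSE]
}

#' Select a residue by chain and author residue number
#'
#' Lookup is by *author* numbering (the numbering printed in structure
#' papers), so e.g. `select_residue(s, "A", 515)` addresses His515.
#'
#' @param s a `structure3d`.
#' @param chain chain identifier.
#' @param seqnum integer author residue number.
#' @param icode insertion code (default empty).
#' @return A `residue3d` object: the residue's atom rows with attributes
#'   `chain`, `seqnum`, `resname`.
#' @export
select_residue <- function(s, chain, seqnum, icode = "") {
  at <- s$atoms
  hit <- at$chain == chain & at$seqnum == seqnum & at$icode == icode
  if (!any(hit)) {
    in_chain <- at$seqnum[at$chain == chain]
    rng <- if (length(in_chain))
      paste0(min(in_chain), "-", max(in_chain)) else "none"
    stop("residue ", chain, ":", seqnum,
         " not found (chain ", chain, " residue range: ", rng, ")")
  }
  res <- at[hit, , drop = FALSE]
  structure(res, class = c("residue3d", "data.frame"),
            chain = chain, seqnum = seqnum, resname = res$resname[1])
}

# parse "A:112" selectors
parse_res_id <- function(x) {
  if (inherits(x, "residue3d"))
    return(list(chain = attr(x, "chain"), seqnum = attr(x, "seqnum")))
  if (is.character(x) && length(x) == 1L && grepl(":", x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    return(list(chain = parts[1], seqnum = as.integer(parts[2])))
  }
  if (is.list(x) || (is.vector(x) && length(x) == 2L))
    return(list(chain = as.character(x[[1]]), seqnum = as.integer(x[[2]])))
  stop("cannot interpret residue selector")
}

resolve_residue <- function(s, x) {
  if (inherits(x, "residue3d")) return(x)
  id <- parse_res_id(x)
  select_residue(s, id$chain, id$seqnum)
}

#' Write a structure to PDB format
#'
#' Fixed-column PDB text; occupancy and B-factor are written to two
#' decimals, coordinates to three.
#'
#' @param s a `structure3d`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  if (any(abs(c(at$x, at$y, at$z)) >= 10000))
    stop("coordinate overflow: |coordinate| >= 10000 does not fit PDB columns")
  if (any(at$seqnum > 9999 | at$seqnum < -999))
    stop("residue number overflows PDB columns")
  fmt_name <- function(nm, el) {
    # element symbols of one char start at column 14
    ifelse(nchar(nm) >= 4L, substr(nm, 1, 4),
           ifelse(nchar(el) == 2L, sprintf("%-4s", nm),
                  sprintf(" %-3s", nm)))
  }
  rec <- ifelse(at$is_water, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, at$serial %% 100000L,
                   fmt_name(at$name, at$element), substr(at$altloc, 1, 1),
                   at$resname, substr(at$chain, 1, 1), at$seqnum,
                   substr(at$icode, 1, 1), at$x, at$y, at$z,
                   at$occupancy, at$bfactor, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Tabulate C-alpha B-factors of catalytic residues
#'
#' Extracts the isotropic B-factor of the CA atom of each named residue.
#' Low, uniform values indicate a rigid, well-ordered catalytic machinery
#' (in the CE20 exemplar, all catalytic CA B-factors fall in 17.7-29.7
#' Angstrom squared).
#'
#' @param s a `structure3d`.
#' @param residues list of residue selectors (`"A:112"` strings,
#'   `c(chain, seqnum)` pairs, or `residue3d` objects).
#' @return A data.frame with columns `chain`, `seqnum`, `resname`,
#'   `ca_bfactor`, of class `bfactor_table`, with attributes `min` and
#'   `max` summarising the rows. Residues lacking a CA atom are dropped
#'   from the summary with a warning.
#' @export
catalytic_bfactors <- function(s, residues) {
  rows <- lapply(residues, function(r) {
    id <- parse_res_id(r)
    res <- tryCatch(select_residue(s, id$chain, id$seqnum),
                    error = function(e) NULL)
    if (is.null(res)) {
      warning("residue ", id$chain, ":", id$seqnum, " not found; skipped")
      return(NULL)
    }
    ca <- res[res$name == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) {
      warning("residue ", id$chain, ":", id$seqnum,
              " lacks a CA atom; excluded from summary")
      return(NULL)
    }
    data.frame(chain = id$chain, seqnum = id$seqnum,
               resname = res$resname[1], ca_bfactor = ca$bfactor[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chain = character(0), seqnum = integer(0),
                      resname = character(0), ca_bfactor = numeric(0))
  class(out) <- c("bfactor_table", "data.frame")
  attr(out, "min") <- if (nrow(out)) min(out$ca_bfactor) else NA_real_
  attr(out, "max") <- if (nrow(out)) max(out$ca_bfactor) else NA_real_
  out
}

#' @export
print.structure3d <- function(x, ...) {
  at <- x$atoms
  prot <- at[!at$is_water, , drop = FALSE]
  chains <- unique(prot$chain)
  cat("<structure3d> ", x$source_id, "\n", sep = "")
  cat("  atoms: ", nrow(at), " (", sum(at$is_hydrogen), " hydrogens)\n", sep = "")
  for (ch in chains) {
    sq <- prot$seqnum[prot$chain == ch]
    cat("  chain ", ch, ": residues ", min(sq), "-", max(sq), "\n", sep = "")
  }
  nw <- length(unique(paste(at$chain, at$seqnum, at$icode)[at$is_water]))
  cat("  waters: ", nw, "\n", sep = "")
  invisible(x)
}

#' @export
print.bfactor_table <- function(x, ...) {
  cat("C-alpha B-factors (A^2):\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("  range: %.2f - %.2f\n", attr(x, "min"), attr(x, "max")))
  invisible(x)
}

# coordinates of a residue3d / atom rows as an n x 3 matrix
coords_of <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# single named atom of a residue; errors if absent
residue_atom <- function(res, name, required = TRUE) {
  hit <- which(res$name == name)
  if (!length(hit)) {
    if (required)
      stop("residue ", attr(res, "chain") %||% res$chain[1], ":",
           attr(res, "seqnum") %||% res$seqnum[1], " (", res$resname[1],
           ") lacks atom ", name)
    return(NULL)
  }
  res[hit[1], , drop = FALSE]
}
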