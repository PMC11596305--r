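#' Protein structure container
#'
#' A `Structure` is an ordered table of atom records from one model of a
#' PDB or mmCIF file: chain id, author residue number, residue name, atom
#' name and Cartesian coordinates in Angstrom. Atom order is the file order;
#' selections preserve it.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `x`, `y`, `z`.
#' @param model integer model number.
#' @return An object of class `Structure`.
#' @export
structure_from_atoms <- function(atoms, model = 1L) {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, need]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$atom))) stop("empty atom names in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) records: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, model = as.integer(model))
  class(out) <- "Structure"
  out
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d chain(s), model %d\n",
              nrow(x$atoms), length(unique(x$atoms$chain)), x$model))
  invisible(x)
}

#' Read a protein structure from PDB or mmCIF text
#'
#' Parses all ATOM/HETATM coordinate records of one model. Alternate
#' locations are resolved by keeping the highest-occupancy location (first
#' wins on ties). Author chain ids and residue numbers are preserved.
#'
#' @param path file to read (PDB fixed-column or mmCIF). Exactly one of
#'   `path`/`text` must be given.
#' @param text character scalar (or vector of lines) with file content.
#' @param model model number to extract (default 1; files without MODEL
#'   records are treated as model 1).
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return A [structure_from_atoms()] `Structure`.
#' @export
read_structure <- function(path = NULL, text = NULL, model = 1L,
                           format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (is.null(text) == is.null(path))
    stop("give exactly one of 'path' or 'text'")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  if (format == "auto") {
    format <- if (any(grepl("^_atom_site\\.", lines)) ||
                  any(grepl("^data_", lines)) ||
                  any(grepl("^loop_", lines))) "cif" else "pdb"
  }
  atoms <- if (format == "pdb") parse_pdb_atoms(lines, model)
           else parse_cif_atoms(lines, model)
  if (nrow(atoms) == 0L)
    stop("model ", model, " not found (no coordinate records)")
  atoms <- resolve_altloc(atoms)
  atoms$altloc <- NULL
  atoms$occ <- NULL
  structure_from_atoms(atoms, model)
}

parse_pdb_atoms <- function(lines, model) {
  cur_model <- 1L
  keep <- logical(length(lines))
  model_of <- integer(length(lines))
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (startsWith(rec, "MODEL")) {
      cur_model <- suppressWarnings(as.integer(substr(lines[i], 7, 14)))
      if (is.na(cur_model)) stop("malformed MODEL record at line ", i)
    } else if (rec == "ATOM  " || rec == "HETATM") {
      keep[i] <- TRUE
      model_of[i] <- cur_model
    }
  }
  idx <- which(keep & model_of == model)
  if (!length(idx)) return(empty_atoms())
  ln <- lines[idx]
  num <- function(chars, what) {
    v <- suppressWarnings(as.numeric(trimws(chars)))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed ", what, " in coordinate record at line ", idx[bad[1]])
    v
  }
  occ_raw <- trimws(substr(ln, 55, 60))
  occ <- suppressWarnings(as.numeric(occ_raw))
  occ[is.na(occ)] <- 1
  data.frame(
    chain = trimws(substr(ln, 22, 22)),
    resno = as.integer(num(substr(ln, 23, 26), "residue number")),
    resname = trimws(substr(ln, 18, 20)),
    atom = trimws(substr(ln, 13, 16)),
    altloc = trimws(substr(ln, 17, 17)),
    x = num(substr(ln, 31, 38), "x coordinate"),
    y = num(substr(ln, 39, 46), "y coordinate"),
    z = num(substr(ln, 47, 54), "z coordinate"),
    occ = occ,
    stringsAsFactors = FALSE
  )
}

parse_cif_atoms <- function(lines, model) {
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) stop("no _atom_site loop found in mmCIF input")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  first_row <- max(tag_idx) + 1L
  rows <- list()
  for (i in first_row:length(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l)) next
    if (startsWith(l, "#") || startsWith(l, "_") || startsWith(l, "loop_") ||
        startsWith(l, "data_")) break
    f <- strsplit(l, "[[:space:]]+")[[1]]
    if (length(f) != length(tags))
      stop("malformed _atom_site row at line ", i,
           " (", length(f), " fields, expected ", length(tags), ")")
    rows[[length(rows) + 1L]] <- f
  }
  if (!length(rows)) return(empty_atoms())
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  pick <- function(a, b) if (a %in% tags) m[, a] else m[, b]
  model_col <- if ("pdbx_PDB_model_num" %in% tags)
    as.integer(m[, "pdbx_PDB_model_num"]) else rep(1L, nrow(m))
  sel <- m[, "group_PDB"] %in% c("ATOM", "HETATM") & model_col == model
  if (!any(sel)) return(empty_atoms())
  m <- m[sel, , drop = FALSE]
  strip_q <- function(v) gsub('^["\']|["\']$', "", v)
  occ <- if ("occupancy" %in% tags)
    suppressWarnings(as.numeric(m[, "occupancy"])) else rep(1, nrow(m))
  occ[is.na(occ)] <- 1
  alt <- if ("label_alt_id" %in% tags) m[, "label_alt_id"] else rep(".", nrow(m))
  alt[alt %in% c(".", "?")] <- ""
  resno <- suppressWarnings(as.integer(pick("auth_seq_id", "label_seq_id")))
  if (any(is.na(resno))) stop("malformed residue numbers in _atom_site loop")
  xyz <- function(tag) {
    v <- suppressWarnings(as.numeric(m[, tag]))
    if (any(is.na(v))) stop("malformed ", tag, " in _atom_site loop")
    v
  }
  data.frame(
    chain = strip_q(pick("auth_asym_id", "label_asym_id")),
    resno = resno,
    resname = strip_q(pick("auth_comp_id", "label_comp_id")),
    atom = strip_q(pick("auth_atom_id", "label_atom_id")),
    altloc = alt,
    x = xyz("Cartn_x"), y = xyz("Cartn_y"), z = xyz("Cartn_z"),
    occ = occ,
    stringsAsFactors = FALSE
  )
}

empty_atoms <- function() {
  data.frame(chain = character(), resno = integer(), resname = character(),
             atom = character(), altloc = character(),
             x = numeric(), y = numeric(), z = numeric(), occ = numeric(),
             stringsAsFactors = FALSE)
}

resolve_altloc <- function(atoms) {
  if (!any(nzchar(atoms$altloc))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom)), ]
  atoms[order(as.integer(rownames(atoms))), ]
}

#' Write a Structure as PDB fixed-column text
#'
#' @param s a `Structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  an <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom), a$atom)
  rec <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                 seq_len(nrow(a)), an, a$resname, a$chain, a$resno,
                 a$x, a$y, a$z)
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Select atoms by chain, residue range and atom names
#'
#' Returns the matching atoms in their original order.
#'
#' @param s a `Structure`.
#' @param chain chain id(s), or NULL for all.
#' @param residues integer vector of residue numbers, or NULL for all.
#' @param atoms atom name set (e.g. `"CA"` or `c("N","CA","C","O")`),
#'   or NULL for all.
#' @return A `Structure` holding the selection.
#' @export
select_atoms <- function(s, chain = NULL, residues = NULL, atoms = NULL) {
  stopifnot(inherits(s, "Structure"))
  keep <- rep(TRUE, nrow(s$atoms))
  if (!is.null(chain)) keep <- keep & s$atoms$chain %in% chain
  if (!is.null(residues)) keep <- keep & s$atoms$resno %in% residues
  if (!is.null(atoms)) keep <- keep & s$atoms$atom %in% atoms
  structure_from_atoms(s$atoms[keep, , drop = FALSE], s$model)
}

#' Parse a "chain:start-end" selection string
#'
#' @param sel string like `"A:10-25"` (or `"A:12"` for one residue).
#' @return list with `chain`, `residues`.
#' @export
parse_selection <- function(sel) {
  m <- regmatches(sel, regexec("^([^:]+):([0-9]+)(?:-([0-9]+))?$", sel))[[1]]
  if (!length(m)) stop("cannot parse selection '", sel,
                       "'; expected chain:start-end")
  start <- as.integer(m[3])
  end <- if (nzchar(m[4])) as.integer(m[4]) else start
  list(chain = m[2], residues = start:end)
}

#' Coordinate matrix of a Structure
#' @param s a `Structure`.
#' @return N x 3 numeric matrix.
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "Structure"))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' sum ||R m_i + t - x_i||^2 between paired point sets. Reflections are
#' excluded by flipping the sign of the smallest singular vector when the
#' determinant is negative.
#'
#' @param mobile N x 3 matrix of points to move.
#' @param target N x 3 matrix of reference points.
#' @return `Superposition`: list with `rotation` (3x3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3)
    stop("point sets must be equal-size N x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points for a superposition")
  cm <- colMeans(mobile); ct <- colMeans(target)
  p <- sweep(mobile, 2, cm); q <- sweep(target, 2, ct)
  h <- crossprod(p, q)
  sv <- svd(h)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate geometry: points are (near-)collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- p %*% t(rot)
  rmsd <- sqrt(sum((moved - q)^2) / n)
  out <- list(rotation = rot,
              translation = as.numeric(ct - rot %*% cm),
              rmsd = rmsd)
  class(out) <- "Superposition"
  out
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a Superposition to coordinates or a Structure
#' @param sp a `Superposition`.
#' @param x N x 3 matrix or `Structure`.
#' @return object of the same kind, transformed.
#' @export
apply_superposition <- function(sp, x) {
  stopifnot(inherits(sp, "Superposition"))
  if (inherits(x, "Structure")) {
    xy <- coords(x) %*% t(sp$rotation)
    xy <- sweep(xy, 2, sp$translation, "+")
    x$atoms$x <- xy[, 1]; x$atoms$y <- xy[, 2]; x$atoms$z <- xy[, 3]
    return(x)
  }
  sweep(as.matrix(x) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Backbone RMSD between paired residue selections of two structures
#'
#' Collects the requested backbone atoms for every paired residue and
#' reports the RMSD. With `fit = TRUE` (default) the selected atoms are
#' first best-fit superposed onto each other (local-site comparison, as
#' when isolated binding sites are compared); with `fit = FALSE` the RMSD
#' is taken in the current (global) frame.
#'
#' @param a,b `Structure` objects.
#' @param pairs data.frame with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`; one row per paired residue.
#' @param atoms backbone atom set; `"CA"` (default) or e.g.
#'   `c("N","CA","C","O")`.
#' @param fit superpose the selections before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(a, b, pairs, atoms = "CA", fit = TRUE) {
  stopifnot(inherits(a, "Structure"), inherits(b, "Structure"))
  need <- c("chain_a", "resno_a", "chain_b", "resno_b")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns ", paste(need, collapse = ", "))
  xa <- gather_backbone(a, pairs$chain_a, pairs$resno_a, atoms, "a")
  xb <- gather_backbone(b, pairs$chain_b, pairs$resno_b, atoms, "b")
  if (!fit) return(sqrt(mean(rowSums((xa - xb)^2))))
  kabsch_superpose(xa, xb)$rmsd
}

gather_backbone <- function(s, chains, resnos, atoms, label) {
  idx <- integer(0)
  absent <- character(0)
  at <- s$atoms
  for (i in seq_along(resnos)) {
    for (an in atoms) {
      j <- which(at$chain == chains[i] & at$resno == resnos[i] & at$atom == an)
      if (length(j) != 1L)
        absent <- c(absent, sprintf("%s:%d:%s", chains[i], resnos[i], an))
      else idx <- c(idx, j)
    }
  }
  if (length(absent))
    stop("selection not resolvable in structure '", label, "': ",
         paste(unique(absent), collapse = ", "))
  as.matrix(at[idx, c("x", "y", "z")])
}
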