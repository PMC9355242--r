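# structure_io: PDB reading/writing, residue addressing, in-silico Cys
# substitution. Parsing is delegated to bio3d; this module resolves alternate
# locations by occupancy, keeps only the first model and drops waters.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")
BACKBONE_KEEP <- c("N", "CA", "C", "O", "OXT", "CB", "H", "HA", "HA2", "HA3")

#' Construct a spin_structure from an atom table
#'
#' The central container of the structure module: an ordered atom table with
#' author residue numbering. Most users will obtain one via [read_structure()]
#' or [make_toy_structure()].
#'
#' @param atoms data.frame with columns `serial` (integer), `name` (atom name),
#'   `resname` (3-letter residue name), `chain`, `resno` (author numbering),
#'   `x`, `y`, `z` (Angstrom), `element`, and optionally `occ`.
#' @param id identifier string.
#' @return object of class `spin_structure`.
#' @export
spin_structure <- function(atoms, id = "structure") {
  req <- c("serial", "name", "resname", "chain", "resno", "x", "y", "z", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("a spin_structure must contain at least one atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbols in atom table")
  if (is.null(atoms$occ)) atoms$occ <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom-name) addresses in atom table")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id), class = "spin_structure")
}

#' @export
print.spin_structure <- function(x, ...) {
  a <- x$atoms
  cat("<spin_structure> ", x$id, "\n", sep = "")
  cat("  atoms: ", nrow(a), " (", sum(!is_hydrogen(a$element)), " heavy)\n", sep = "")
  cat("  chains: ", paste(unique(a$chain), collapse = " "), "\n", sep = "")
  cat("  residues: ", nrow(unique(a[, c("chain", "resno")])), "\n", sep = "")
  invisible(x)
}

is_hydrogen <- function(element) toupper(element) %in% c("H", "D")

#' Read a PDB structure
#'
#' Reads ATOM/HETATM records of the first model. Alternate locations are
#' resolved to the highest-occupancy copy (ties: first occurrence); waters are
#' excluded by default. Elements missing from columns 77-78 are inferred from
#' the atom name.
#'
#' @param pdb path to a PDB file, or a character scalar/vector of PDB text.
#' @param keep_waters keep water molecules (default `FALSE`).
#' @param id identifier; defaults to the file name.
#' @return a [spin_structure()].
#' @export
read_structure <- function(pdb, keep_waters = FALSE, id = NULL) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1]) ||
      (!file.exists(pdb[1]) && grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK|CRYST)", pdb[1]))) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1L) pdb else strsplit(pdb, "\n")[[1]], path)
    on.exit(unlink(path))
    if (is.null(id)) id <- "pdb-text"
  }
  if (!file.exists(path)) stop("PDB input not found: ", path)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("no ATOM/HETATM records could be parsed from '", id, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- p$atom
  if (nrow(at) == 0L) stop("no ATOM/HETATM records in '", id, "'")
  if (!keep_waters) at <- at[!(at$resid %in% WATER_RESNAMES), , drop = FALSE]
  if (nrow(at) == 0L) stop("no non-water atoms in '", id, "'")
  # altloc resolution: within (chain, resno, insert, name) keep highest
  # occupancy, first on ties (stable order).
  occ <- ifelse(is.na(at$o), 1, at$o)
  grp <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert), at$elety)
  ord <- order(factor(grp, levels = unique(grp)), -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno,
                             ifelse(is.na(at$insert), "", at$insert), at$elety)), , drop = FALSE]
  at <- at[order(match(at$eleno, p$atom$eleno)), , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  if (any(bad)) elem[bad] <- guess_element(at$elety[bad])
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain), resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    element = trimws(elem), occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)
  spin_structure(atoms, id = id)
}

guess_element <- function(name) {
  n <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(n, 1, 2))
  el <- substr(n, 1, 1)
  el[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA ")] <- two[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA")]
  toupper(el)
}

#' Write a spin_structure to a PDB file
#' @param structure a [spin_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain, o = a$occ,
    b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

# Parse "A:195" or "A:195:CB" (or list/vector forms) into a residue/atom address.
parse_address <- function(addr) {
  if (is.list(addr)) addr <- unlist(addr)
  if (length(addr) == 1L && is.character(addr)) addr <- strsplit(addr, ":")[[1]]
  if (length(addr) < 2L) stop("address must be 'chain:resno' or 'chain:resno:atom'")
  list(chain = as.character(addr[1]), resno = as.integer(addr[2]),
       name = if (length(addr) >= 3L) as.character(addr[3]) else NA_character_)
}

residue_atoms <- function(structure, chain, resno) {
  a <- structure$atoms
  a[a$chain == chain & a$resno == resno, , drop = FALSE]
}

atom_xyz <- function(structure, chain, resno, name) {
  r <- residue_atoms(structure, chain, resno)
  r <- r[r$name == name, , drop = FALSE]
  if (nrow(r) == 0L)
    stop("atom ", chain, ":", resno, ":", name, " not found in '", structure$id, "'")
  as.numeric(r[1, c("x", "y", "z")])
}

#' Distance between two addressed atoms
#'
#' @param structure a [spin_structure()].
#' @param a,b atom addresses, `"chain:resno:atom"` (e.g. `"A:195:CB"`).
#' @return Euclidean distance in Angstrom.
#' @export
atom_distance <- function(structure, a, b) {
  pa <- parse_address(a)
  pb <- parse_address(b)
  if (is.na(pa$name) || is.na(pb$name)) stop("atom_distance needs full 'chain:resno:atom' addresses")
  va <- atom_xyz(structure, pa$chain, pa$resno, pa$name)
  vb <- atom_xyz(structure, pb$chain, pb$resno, pb$name)
  vec_norm(va - vb)
}

#' Substitute a residue to cysteine in silico
#'
#' Removes side-chain atoms beyond CB and renames the residue CYS, leaving all
#' backbone coordinates bit-identical — the preparation step before attaching a
#' spin-label model at the site. Glycine (no CB) is rejected.
#'
#' @param structure a [spin_structure()].
#' @param chain chain identifier.
#' @param residue_number author residue number.
#' @return a new [spin_structure()] with the substitution applied.
#' @export
substitute_to_cys <- function(structure, chain, residue_number) {
  a <- structure$atoms
  sel <- a$chain == chain & a$resno == residue_number
  if (!any(sel))
    stop("residue ", chain, ":", residue_number, " not found in '", structure$id, "'")
  res <- a[sel, , drop = FALSE]
  if (any(res$resname == "GLY") || !("CB" %in% res$name))
    stop("residue ", chain, ":", residue_number,
         " has no CB atom (glycine or incomplete); cannot model a Cys there")
  need <- c("N", "CA", "C")
  if (!all(need %in% res$name))
    stop("residue ", chain, ":", residue_number, " lacks backbone atoms ",
         paste(setdiff(need, res$name), collapse = ", "))
  drop <- sel & !(a$name %in% BACKBONE_KEEP)
  a <- a[!drop, , drop = FALSE]
  a$resname[a$chain == chain & a$resno == residue_number] <- "CYS"
  spin_structure(a, id = structure$id)
}

heavy_atoms <- function(structure) {
  a <- structure$atoms
  a[!is_hydrogen(a$element), , drop = FALSE]
}
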