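#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM records of a (optionally gzipped) PDB file into a
#' `structure_model`: a flat atom table ordered as in the file, with
#' author residue numbering kept untouched. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by the
#' lexicographically first alt-loc identifier). Waters and other
#' heteroatoms are retained but flagged, so that protein-only analyses
#' can drop them by default.
#'
#' @param file Path to a PDB file (plain or gzip-compressed).
#' @param model Model number to extract from a multi-model file (1-based).
#' @param id Identifier stored with the structure; defaults to the file
#'   base name.
#' @return An object of class `structure_model`: a list with elements
#'   `id` (character) and `atoms` (data.frame with columns `type`,
#'   `serial`, `name`, `alt_loc`, `resname`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `occupancy`, `b`, `element`, `het`, `water`).
#' @examples
#' pdb <- system.file("extdata", "toy_dimer_synthetic.pdb", package = "dimerlink")
#' s <- read_pdb(pdb)
#' nrow(s$atoms)
#' @export
read_pdb <- function(file, model = 1L, id = NULL) {
  lines <- .read_text_lines(file)
  .validate_pdb_lines(lines)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  multi <- sum(grepl("^MODEL", lines)) > 1L
  pdb <- bio3d::read.pdb(tmp, multi = multi, rm.alt = FALSE, verbose = FALSE)
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model < 1L || model > nmod)
    stop("requested model ", model, " but file has ", nmod, " model(s)")
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  a <- pdb$atom
  atoms <- data.frame(
    type = a$type,
    serial = a$eleno,
    name = a$elety,
    alt_loc = ifelse(is.na(a$alt), "", a$alt),
    resname = a$resid,
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = xyz[seq(1, length(xyz), 3)],
    y = xyz[seq(2, length(xyz), 3)],
    z = xyz[seq(3, length(xyz), 3)],
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    element = .infer_elements(a$elesy, a$elety, a$resid),
    stringsAsFactors = FALSE
  )
  atoms$het <- atoms$type == "HETATM"
  atoms$water <- atoms$resname %in% .WATER_RESNAMES
  atoms <- .resolve_altloc(atoms)
  structure_model(atoms, id = if (is.null(id)) sub("\\.(pdb|ent)(\\.gz)?$", "",
                                                  basename(file)) else id)
}

#' Construct a structure_model from an atom table
#'
#' @param atoms Atom data.frame (see [read_pdb()] for columns; missing
#'   optional columns are filled with defaults).
#' @param id Identifier.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, id = "structure") {
  needed <- c("name", "resname", "chain", "resno", "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$type)) atoms$type <- rep("ATOM", n)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$alt_loc)) atoms$alt_loc <- rep("", n)
  if (is.null(atoms$insert)) atoms$insert <- rep("", n)
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1, n)
  if (is.null(atoms$b)) atoms$b <- rep(0, n)
  if (is.null(atoms$element))
    atoms$element <- .infer_elements(NULL, atoms$name, atoms$resname)
  if (is.null(atoms$het)) atoms$het <- atoms$type == "HETATM"
  if (is.null(atoms$water)) atoms$water <- atoms$resname %in% .WATER_RESNAMES
  if (!all(is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in atom table")
  rownames(atoms) <- NULL
  out <- list(id = id, atoms = atoms)
  class(out) <- "structure_model"
  out
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model", sQuote(x$id), ":", nrow(a), "atoms,",
      length(unique(a$chain[!a$het])), "protein chain(s),",
      sum(a$het & !a$water), "hetero atoms,", sum(a$water), "water atoms\n")
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' Coordinates are printed at the standard PDB precision (3 decimals),
#' occupancies and B-factors at 2 decimals.
#'
#' @param structure A `structure_model`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_pdb <- function(structure, file) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = a$type, resno = a$resno, resid = a$resname,
    eleno = a$serial, elety = a$name, chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$insert == "", "", a$insert),
    o = a$occupancy, b = a$b, elesy = a$element
  )
  invisible(file)
}

#' Heavy-atom view of a structure
#'
#' Drops hydrogen and deuterium atoms, preserving atom order.
#'
#' @param structure A `structure_model`.
#' @return A `structure_model` containing only heavy atoms.
#' @export
heavy_atoms <- function(structure) {
  keep <- !(structure$atoms$element %in% c("H", "D"))
  structure_model(structure$atoms[keep, , drop = FALSE], id = structure$id)
}

#' Subset a structure by chain, residue or atom name
#'
#' @param structure A `structure_model`.
#' @param chain,resno,name Optional filters; `NULL` keeps everything.
#' @param protein_only Drop heteroatoms and waters.
#' @return A `structure_model` view (order preserved).
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL, name = NULL,
                         protein_only = FALSE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (protein_only) keep <- keep & !a$het & !a$water
  if (!any(keep)) stop("selection matches no atoms")
  structure_model(a[keep, , drop = FALSE], id = structure$id)
}

# ---- internal helpers -------------------------------------------------------

.read_text_lines <- function(file) {
  con <- gzfile(file, "rt")  # transparent for plain text too
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  if (!length(idx)) stop("no ATOM/HETATM records found")
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": record shorter than 54 columns")
    fields <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop("malformed PDB record at line ", i, ": non-numeric coordinate field")
  }
  invisible(TRUE)
}

# Element inference: use the element column when present, otherwise guess
# from the atom name (older PDB entries leave columns 77-78 blank).
.infer_elements <- function(elesy, elety, resname) {
  n <- length(elety)
  out <- if (is.null(elesy)) rep(NA_character_, n) else toupper(trimws(elesy))
  out[!is.na(out) & out == ""] <- NA_character_
  fill <- which(is.na(out))
  if (length(fill))
    out[fill] <- mapply(.guess_element, elety[fill], resname[fill],
                        USE.NAMES = FALSE)
  if (any(is.na(out) | out == ""))
    stop("could not assign an element to atom name(s): ",
         paste(unique(elety[is.na(out) | out == ""]), collapse = ", "))
  out
}

.guess_element <- function(name, resname = "") {
  nm <- toupper(trimws(name))
  # two-letter elements only outside standard residues: within an amino
  # acid, "CA" is the alpha carbon, never calcium
  standard <- toupper(resname) %in% c(names(.AA_THREE_TO_ONE), .WATER_RESNAMES)
  two <- substr(nm, 1, 2)
  if (!standard && nchar(nm) <= 2 &&
      two %in% c("FE", "ZN", "MG", "MN", "CU", "SE", "CL", "BR", "NA", "CA"))
    return(two)
  stripped <- gsub("[0-9']", "", nm)
  if (grepl("^[0-9]", nm) || substr(stripped, 1, 1) == "H") return("H")
  if (stripped == "") return(NA_character_)
  substr(stripped, 1, 1)
}

# Keep, per (chain, resno, insert, atom name), the conformer with the
# highest occupancy; ties go to the lexicographically first alt_loc.
.resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname, atoms$name,
               sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$alt_loc, seq_len(nrow(atoms)))
  first <- !duplicated(key[ord])
  keep <- sort(ord[first])
  atoms <- atoms[keep, , drop = FALSE]
  atoms$alt_loc <- ""
  rownames(atoms) <- NULL
  atoms
}

# n x 3 coordinate matrix of the structure's atoms.
.coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# Residue-level grouping key for an atom table.
.residue_key <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resno,
         ifelse(atoms$insert == "", "", atoms$insert))
}
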