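# Molecular structure container built on bio3d's PDB reader.

AMINO3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common protonation/tautomer variants produced by MD packages
  "HID", "HIE", "HIP", "ASH", "GLH", "LYN", "CYX", "CYM"
)

ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  MG = 24.305, "NA" = 22.990, K = 39.098, CL = 35.45, ZN = 65.38, FE = 55.845
)

new_mdstruct <- function(atoms, xyz, source = NA_character_) {
  stopifnot(nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  structure(
    list(atoms = atoms, xyz = xyz, source = source),
    class = "mdstruct"
  )
}

#' Read a structure from a PDB file
#'
#' Parses a PDB file into an `mdstruct` object: an atom table plus an
#' A x 3 coordinate matrix in Angstrom. Alternate locations are resolved to a
#' single atom per site by keeping the conformer with the highest occupancy
#' (ties broken in favour of altloc `"A"`). Heteroatoms (HETATM records,
#' solvent, ions, nucleic acids flagged per-residue) are retained and flagged
#' in the `het` column so that protein-only selections stay easy.
#'
#' @param path Path to a PDB file (single model; for multi-model trajectory
#'   files see [read_trajectory()]).
#' @param require_protein Error when the file contains no protein residue
#'   with a Cα atom (default `TRUE`).
#' @return An object of class `mdstruct` with elements `atoms` (a tibble with
#'   columns `eleno`, `elety`, `alt`, `resid`, `chain`, `resno`, `insert`,
#'   `het`, `occ`, `elem`), `xyz` (A x 3 numeric matrix, Angstrom) and
#'   `source`.
#' @seealso [select_atoms()], [write_structure()]
#' @export
read_structure <- function(path, require_protein = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("cannot read structure: file not found: ", path))
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  atoms <- tibble::tibble(
    eleno = as.integer(at$eleno),
    elety = as.character(at$elety),
    alt = as.character(at$alt),
    resid = as.character(at$resid),
    chain = ifelse(is.na(at$chain), " ", as.character(at$chain)),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    het = at$type != "ATOM",
    occ = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    elem = guess_element(at$elesy, at$elety)
  )
  xyz <- cbind(at$x, at$y, at$z)

  keep <- resolve_altloc(atoms)
  atoms <- atoms[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  atoms$het <- atoms$het | !(atoms$resid %in% AMINO3)

  x <- new_mdstruct(atoms, xyz, source = path)
  if (require_protein && length(protein_ca_indices(x)) == 0) {
    abort(paste0("no protein residues with C-alpha atoms in ", path))
  }
  x
}

# Highest occupancy wins; ties prefer altloc "A"; atom order preserved.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  pref <- order(
    key,
    -atoms$occ,
    ifelse(!is.na(atoms$alt) & atoms$alt == "A", 0L, 1L),
    seq_len(nrow(atoms))
  )
  first <- pref[!duplicated(key[pref])]
  sort(first)
}

guess_element <- function(elesy, elety) {
  e <- toupper(trimws(as.character(elesy)))
  missing <- is.na(e) | e == "" | e == "NA"
  fallback <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety)))
  fallback <- substr(fallback, 1, 1)
  e[missing] <- fallback[missing]
  e
}

protein_ca_indices <- function(x) {
  which(!x$atoms$het & x$atoms$elety == "CA" & x$atoms$resid %in% AMINO3)
}

#' @export
print.mdstruct <- function(x, ...) {
  prot <- !x$atoms$het
  cat(
    "<mdstruct> ", nrow(x$atoms), " atoms, ",
    length(unique(paste(x$atoms$chain, x$atoms$resno)[prot])),
    " protein residues, chains: ",
    paste(unique(x$atoms$chain), collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' @param x An `mdstruct`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "mdstruct"))
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(x$xyz)),
    type = ifelse(x$atoms$het & !(x$atoms$resid %in% AMINO3), "HETATM", "ATOM"),
    resno = x$atoms$resno,
    resid = x$atoms$resid,
    eleno = x$atoms$eleno,
    elety = x$atoms$elety,
    chain = x$atoms$chain,
    insert = ifelse(x$atoms$insert == "", NA, x$atoms$insert),
    o = x$atoms$occ,
    b = rep(0, nrow(x$atoms)),
    elesy = x$atoms$elem
  )
  invisible(path)
}

#' Select atoms of a structure
#'
#' Resolves a simple predicate (chain / residue numbers / atom names /
#' heteroatom flag) to atom indices. Resolution is deterministic and preserves
#' atom order, so repeated calls with the same arguments give identical
#' results regardless of argument order.
#'
#' @param x An `mdstruct` or a trajectory (its topology is used).
#' @param chain Optional chain id(s).
#' @param resno Optional residue numbers (vector; use `a:b` for ranges).
#' @param elety Optional atom-name set, e.g. `"CA"`.
#' @param het `NA` (default) keeps everything; `FALSE` protein only; `TRUE`
#'   heteroatoms only.
#' @return Integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(x, chain = NULL, resno = NULL, elety = NULL, het = NA) {
  x <- as_structure(x)
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.na(het)) keep <- keep & (a$het == het)
  which(keep)
}

as_structure <- function(x) {
  if (inherits(x, "mdtrajectory")) x$topology else x
}

# Resolve a config-style selection list(chain=, resno=|from=/to=, elety=)
resolve_selection <- function(x, sel) {
  if (is.numeric(sel)) {
    return(as.integer(sel))
  }
  resno <- sel$resno
  if (!is.null(sel$from)) resno <- seq(sel$from, sel$to)
  select_atoms(x, chain = sel$chain, resno = resno, elety = sel$elety)
}

atom_masses <- function(x, idx) {
  e <- x$atoms$elem[idx]
  m <- ATOMIC_MASS[e]
  m[is.na(m)] <- 12.011  # unknown elements treated as carbon-like
  unname(m)
}

#' Download a structure from the RCSB PDB
#'
#' Fetches `https://files.rcsb.org/download/<accession>.pdb` into `dir`.
#' Used by the validation suite to compare computed distances against
#' deposited experimental structures; requires network access.
#'
#' @param accession 4-character PDB accession, e.g. `"5F9R"`.
#' @param dir Directory for the downloaded file.
#' @param quiet Passed to [utils::download.file()].
#' @return Path to the downloaded PDB file.
#' @export
fetch_structure <- function(accession, dir = tempdir(), quiet = TRUE) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", accession))
  dest <- file.path(dir, paste0(toupper(accession), ".pdb"))
  if (!file.exists(dest)) {
    url <- paste0("https://files.rcsb.org/download/", toupper(accession), ".pdb")
    status <- tryCatch(
      utils::download.file(url, dest, quiet = quiet, mode = "wb"),
      error = function(e) -1L, warning = function(w) -1L
    )
    if (!identical(status, 0L)) {
      unlink(dest)
      abort(paste0("could not download ", accession, " from RCSB (offline?)"))
    }
  }
  dest
}
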