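# Structure data model: an ordered atom table plus a title. Atom order is the
# file order and is never silently changed; residue numbering is the author
# numbering from the file (insertion codes preserved).

#' Construct a Structure from an atom table
#'
#' A `Structure` is an ordered data frame of atoms with one row per atom and a
#' free-text title. Columns: `serial`, `name`, `altloc`, `resname`, `chain`,
#' `resid` (author residue number), `icode`, `x`, `y`, `z`, `occupancy`,
#' `element`, `het`.
#'
#' @param atoms data frame with the columns listed above.
#' @param title free-text description.
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, title = "") {
  required <- c("serial", "name", "altloc", "resname", "chain", "resid",
                "icode", "x", "y", "z", "occupancy", "element", "het")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[, required]
  rownames(atoms) <- NULL
  if (nrow(atoms) == 0) stop("a Structure must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element)))
    stop("every atom needs a non-empty element symbol")
  key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$name, atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, resid, icode, name, altloc): ",
         key[duplicated(key)][1])
  structure(list(atoms = atoms, title = title), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure: %d atoms, %d chains (%s)\n",
              nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ", ")))
  if (nzchar(x$title)) cat(" title:", x$title, "\n")
  invisible(x)
}

#' Coordinates of a Structure as a matrix
#' @param s a `Structure`.
#' @param idx optional integer atom indices (an atom set).
#' @return numeric n x 3 matrix.
#' @export
coords <- function(s, idx = NULL) {
  a <- s$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  m <- cbind(a$x, a$y, a$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace coordinates of a Structure
#' @param s a `Structure`.
#' @param xyz n x 3 matrix matching the atom count (or the index count).
#' @param idx optional atom indices to replace.
#' @return the modified `Structure`.
#' @export
set_coords <- function(s, xyz, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(s$atoms))
  stopifnot(nrow(xyz) == length(idx))
  s$atoms$x[idx] <- xyz[, 1]
  s$atoms$y[idx] <- xyz[, 2]
  s$atoms$z[idx] <- xyz[, 3]
  s
}

# residue-level grouping key (chain + author number + insertion code)
residue_key <- function(atoms) paste(atoms$chain, atoms$resid, atoms$icode)

#' Read a PDB file into a Structure
#'
#' Parsing is delegated to [bio3d::read.pdb()]. Alternate locations are
#' resolved to a single conformer: records with blank or 'A' altloc are kept;
#' if a residue atom has neither, the highest-occupancy record wins.
#' Hydrogens are retained if present but no package geometry needs them.
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @return a `Structure`.
#' @export
read_structure <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    path <- source
  } else {
    lines <- unlist(strsplit(paste(source, collapse = "\n"), "\n"))
    path <- NULL
  }
  if (!length(lines) || !any(grepl("^(ATOM|HETATM)", lines)))
    stop("no ATOM/HETATM records found: empty or non-PDB input")
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(is_atom &
                 (nchar(lines) < 54 |
                    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
                    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
                    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad))
    stop("malformed ATOM/HETATM record at line ", bad[1])
  if (is.null(path)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(lines, path)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resid = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    element = trimws(ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                            substr(trimws(a$elety), 1, 1), a$elesy)),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms)
  title <- if (!is.null(path)) basename(path) else "pdb-text"
  new_structure(atoms, title = title)
}

# keep altloc '' or 'A'; residues with neither keep the highest-occupancy
# record per atom name
resolve_altloc <- function(atoms) {
  keep <- atoms$altloc %in% c("", "A")
  if (all(keep)) return(atoms)
  atom_key <- paste(residue_key(atoms), atoms$name)
  out <- logical(nrow(atoms))
  for (k in unique(atom_key)) {
    i <- which(atom_key == k)
    j <- i[atoms$altloc[i] %in% c("", "A")]
    if (!length(j)) j <- i[which.max(atoms$occupancy[i])]
    out[j] <- TRUE
  }
  atoms <- atoms[out, , drop = FALSE]
  atoms$altloc <- ""
  rownames(atoms) <- NULL
  atoms
}

#' Write a Structure to PDB text
#'
#' @param s a `Structure`.
#' @param dest optional path; when `NULL` the PDB lines are returned invisibly
#'   only.
#' @return character vector of PDB lines, invisibly.
#' @export
write_structure <- function(s, dest = NULL) {
  a <- s$atoms
  if (any(nchar(a$name) > 4))
    stop("atom name longer than the 4-character PDB field: ",
         a$name[nchar(a$name) > 4][1])
  path <- if (is.null(dest)) tempfile(fileext = ".pdb") else dest
  bio3d::write.pdb(
    file = path,
    type = ifelse(a$het, "HETATM", "ATOM"),
    eleno = a$serial,
    elety = a$name,
    resid = a$resname,
    chain = a$chain,
    resno = a$resid,
    insert = ifelse(nzchar(a$icode), a$icode, NA),
    xyz = as.numeric(t(coords(s))),
    o = a$occupancy,
    b = rep(0, nrow(a)),
    elesy = a$element
  )
  lines <- readLines(path, warn = FALSE)
  if (is.null(dest)) unlink(path)
  invisible(lines)
}

#' Select atoms of a Structure
#'
#' All given fields must match (logical AND); within a field any of the given
#' values matches (logical OR). Matching atoms are returned as an integer
#' index vector in structure order — the package's atom-set representation.
#'
#' @param s a `Structure`.
#' @param chain,resid,resname,name,element,icode optional filter values.
#' @param het optional logical filter on HETATM records.
#' @param ... unknown query fields are an error, not silently ignored.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(s, chain = NULL, resid = NULL, resname = NULL,
                         name = NULL, element = NULL, icode = NULL,
                         het = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown selection field(s): ", paste(names(extra), collapse = ", "))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(icode)) keep <- keep & a$icode %in% icode
  if (!is.null(het)) keep <- keep & a$het == het
  which(keep)
}

# single-atom index with a clear error message
atom_index <- function(s, chain, resid, name, what = "atom") {
  i <- select_atoms(s, chain = chain, resid = resid, name = name)
  if (length(i) != 1)
    stop(sprintf("expected exactly one %s (chain %s, residue %s, name %s), found %d",
                 what, chain, resid, name, length(i)))
  i
}

# ideal side-chain internal coordinates used by the mutagenesis builder;
# each atom is placed by NERF from three previously placed atoms.
# bond lengths: C-C 1.52, C-N 1.49, C-O(carboxylate) 1.25; CA-CB 1.53.
.sidechain_recipes <- list(
  LYS = list(
    list(atom = "CB", ref = c("N", "C", "CA"), bond = 1.53, angle = 110.5, torsion = 122.6),
    list(atom = "CG", ref = c("N", "CA", "CB"), bond = 1.52, angle = 114.0, torsion = 180),
    list(atom = "CD", ref = c("CA", "CB", "CG"), bond = 1.52, angle = 111.3, torsion = 180),
    list(atom = "CE", ref = c("CB", "CG", "CD"), bond = 1.52, angle = 111.3, torsion = 180),
    list(atom = "NZ", ref = c("CG", "CD", "CE"), bond = 1.49, angle = 111.0, torsion = 180)
  ),
  ALA = list(
    list(atom = "CB", ref = c("N", "C", "CA"), bond = 1.53, angle = 110.5, torsion = 122.6)
  ),
  ASP = list(
    list(atom = "CB", ref = c("N", "C", "CA"), bond = 1.53, angle = 110.5, torsion = 122.6),
    list(atom = "CG", ref = c("N", "CA", "CB"), bond = 1.52, angle = 112.6, torsion = 180),
    list(atom = "OD1", ref = c("CA", "CB", "CG"), bond = 1.25, angle = 118.4, torsion = 180),
    list(atom = "OD2", ref = c("CA", "CB", "CG"), bond = 1.25, angle = 118.4, torsion = 0)
  ),
  GLU = list(
    list(atom = "CB", ref = c("N", "C", "CA"), bond = 1.53, angle = 110.5, torsion = 122.6),
    list(atom = "CG", ref = c("N", "CA", "CB"), bond = 1.52, angle = 114.0, torsion = 180),
    list(atom = "CD", ref = c("CA", "CB", "CG"), bond = 1.52, angle = 112.6, torsion = 180),
    list(atom = "OE1", ref = c("CB", "CG", "CD"), bond = 1.25, angle = 118.4, torsion = 180),
    list(atom = "OE2", ref = c("CB", "CG", "CD"), bond = 1.25, angle = 118.4, torsion = 0)
  )
)

#' Mutate a residue to lysine with an ideal-geometry side chain
#'
#' Backbone atoms (N, CA, C, O) are untouched; any existing side-chain heavy
#' atoms are removed and a lysine side chain CB-CG-CD-CE-NZ is built at ideal
#' bond lengths and angles with every side-chain torsion at 180 degrees (a
#' single extended rotamer — no rotamer search is attempted).
#'
#' @param s a `Structure`.
#' @param chain chain identifier.
#' @param resid author residue number.
#' @return the mutated `Structure`.
#' @export
mutate_to_lysine <- function(s, chain, resid) {
  a <- s$atoms
  res_rows <- which(a$chain == chain & a$resid == resid)
  if (!length(res_rows))
    stop(sprintf("residue %s/%s not found", chain, resid))
  backbone <- c("N", "CA", "C", "O", "OXT")
  for (need in c("N", "CA", "C")) {
    if (!need %in% a$name[res_rows])
      stop(sprintf("residue %s/%s lacks backbone atom %s; cannot mutate",
                   chain, resid, need))
  }
  keep_rows <- res_rows[a$name[res_rows] %in% backbone]
  drop_rows <- setdiff(res_rows, keep_rows)
  if (length(drop_rows)) a <- a[-drop_rows, , drop = FALSE]
  res_rows <- which(a$chain == chain & a$resid == resid)
  a$resname[res_rows] <- "LYS"

  pos <- function(nm) {
    i <- res_rows[a$name[res_rows] == nm]
    c(a$x[i], a$y[i], a$z[i])
  }
  placed <- list(N = pos("N"), CA = pos("CA"), C = pos("C"))
  new_atoms <- list()
  for (step in .sidechain_recipes$LYS) {
    p <- place_atom(placed[[step$ref[1]]], placed[[step$ref[2]]],
                    placed[[step$ref[3]]], step$bond, step$angle, step$torsion)
    placed[[step$atom]] <- p
    new_atoms[[step$atom]] <- p
  }
  last <- max(res_rows)
  add <- data.frame(
    serial = NA_integer_,
    name = names(new_atoms),
    altloc = "",
    resname = "LYS",
    chain = chain,
    resid = resid,
    icode = a$icode[res_rows[1]],
    x = vapply(new_atoms, `[`, 0, 1),
    y = vapply(new_atoms, `[`, 0, 2),
    z = vapply(new_atoms, `[`, 0, 3),
    occupancy = 1,
    element = substr(names(new_atoms), 1, 1),
    het = FALSE,
    stringsAsFactors = FALSE
  )
  a <- rbind(a[seq_len(last), , drop = FALSE], add,
             if (last < nrow(a)) a[(last + 1):nrow(a), , drop = FALSE])
  a$serial <- seq_len(nrow(a))
  new_structure(a, title = s$title)
}
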