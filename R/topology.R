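# Topology: atom/residue metadata plus reference coordinates.
# Units are Angstrom throughout; indices are 1-based R indices.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
          "SER", "THR", "TRP", "TYR", "VAL")

#' Default residue-name to ion-species mapping
#'
#' CHARMM-style ion residue names mapped to chemical species labels.
#' Residues not in the map and not recognized as protein/scaffold residues
#' are tagged \code{"other"}.
#'
#' @return Named character vector: names are PDB residue names, values are
#'   species labels.
#' @export
default_species_map <- function() {
  c(CLA = "Cl-", SOD = "Na+", BIC = "HCO3-", CO3 = "CO32-")
}

.species_from_resname <- function(resname, species_map, warn = TRUE) {
  species <- rep(NA_character_, length(resname))
  hit <- resname %in% names(species_map)
  species[hit] <- unname(species_map[resname[hit]])
  scaf <- !hit & (resname %in% c(.AA3, "WAL", "SCF", "HOH", "TIP", "TIP3"))
  species[scaf] <- "scaffold"
  unknown <- is.na(species)
  if (any(unknown)) {
    if (warn) {
      warning(sprintf("unknown residue name(s) %s tagged as species 'other'",
                      paste(unique(resname[unknown]), collapse = ", ")))
    }
    species[unknown] <- "other"
  }
  species
}

#' Construct a topology object
#'
#' @param atoms data.frame with columns \code{name}, \code{resname},
#'   \code{resid}, \code{chain}; one row per atom in file order.
#' @param coords numeric matrix (n_atoms x 3) of reference coordinates (A).
#' @param box orthorhombic box lengths (A), length-3 numeric.
#' @param species_map residue-name to species mapping
#'   (see \code{\link{default_species_map}}).
#' @param warn_unknown warn when a residue name maps to species "other".
#' @return An object of class \code{ion_topology}: a list with elements
#'   \code{atoms} (data.frame with added \code{species} column),
#'   \code{coords}, \code{box}.
#' @export
ion_topology <- function(atoms, coords, box,
                         species_map = default_species_map(),
                         warn_unknown = TRUE) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "resname", "resid", "chain") %in% names(atoms)))
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3)
    stop("coords must be an (n_atoms x 3) matrix matching `atoms`")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths (A)")
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  atoms$resid <- as.integer(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  atoms$species <- .species_from_resname(atoms$resname, species_map,
                                         warn = warn_unknown)
  rownames(atoms) <- NULL
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords, box = box),
            class = "ion_topology")
}

#' @export
print.ion_topology <- function(x, ...) {
  cat(sprintf("ion_topology: %d atoms, %d residues, box %.2f x %.2f x %.2f A\n",
              nrow(x$atoms), nrow(unique(x$atoms[c("chain", "resid")])),
              x$box[1], x$box[2], x$box[3]))
  sp <- table(x$atoms$species)
  cat("species:", paste(sprintf("%s=%d", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology an \code{ion_topology}.
#' @return Integer atom count.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Residue table of a topology
#'
#' One row per residue, identified by (chain, resid), in order of first
#' appearance.
#'
#' @param topology an \code{ion_topology}.
#' @return data.frame with columns \code{chain}, \code{resid},
#'   \code{resname}, \code{species}, \code{n_atoms}.
#' @export
residue_table <- function(topology) {
  a <- topology$atoms
  key <- paste(a$chain, a$resid)
  first <- !duplicated(key)
  out <- a[first, c("chain", "resid", "resname", "species")]
  out$n_atoms <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
}

#' Indices of ion atoms of given species
#'
#' @param topology an \code{ion_topology}.
#' @param species character vector of species labels (e.g. \code{"Cl-"});
#'   \code{NULL} selects every atom whose species is neither
#'   \code{"scaffold"} nor \code{"other"}.
#' @return Integer vector of 1-based atom indices.
#' @export
ion_indices <- function(topology, species = NULL) {
  sp <- topology$atoms$species
  if (is.null(species)) {
    which(!(sp %in% c("scaffold", "other")))
  } else {
    bad <- setdiff(species, unique(sp))
    if (length(bad))
      stop(sprintf("unknown species tag(s): %s", paste(bad, collapse = ", ")))
    which(sp %in% species)
  }
}

#' Read a topology from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records. The box is taken from a CRYST1
#' record when present, otherwise from the \code{box} argument.
#'
#' @param path PDB file path.
#' @param species_map residue-name to species mapping.
#' @param box fallback box lengths (A) when the file has no CRYST1 record.
#' @return An \code{ion_topology} (reference coordinates included).
#' @export
read_topology <- function(path, species_map = default_species_map(),
                          box = NULL) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  cryst <- which(rec == "CRYST1")
  if (length(cryst)) {
    fields <- strsplit(trimws(substr(lines[cryst[1]], 7, 54)), "\\s+")[[1]]
    box <- as.numeric(fields[1:3])
  }
  if (is.null(box))
    stop("no CRYST1 record in ", path, " and no `box` given")
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(sel)) stop("no ATOM/HETATM records in ", path)
  short <- sel[nchar(lines[sel]) < 54]
  if (length(short))
    stop(sprintf("truncated ATOM/HETATM record at line %d of %s",
                 short[1], path))
  ln <- lines[sel]
  num <- function(a, b) {
    v <- suppressWarnings(as.numeric(substr(ln, a, b)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("unparseable ATOM/HETATM record at line %d of %s",
                   sel[bad[1]], path))
    v
  }
  atoms <- data.frame(
    name = trimws(substr(ln, 13, 16)),
    resname = trimws(substr(ln, 18, 21)),
    chain = trimws(substr(ln, 22, 22)),
    resid = as.integer(num(23, 26)),
    stringsAsFactors = FALSE)
  atoms$chain[atoms$chain == ""] <- "A"
  coords <- cbind(num(31, 38), num(39, 46), num(47, 54))
  ion_topology(atoms[c("name", "resname", "resid", "chain")], coords, box,
               species_map = species_map)
}

#' Write a topology to a PDB file
#'
#' Scaffold atoms and ions are written as HETATM records (ions as
#' single-atom residues named by species, e.g. CLA/SOD/BIC/CO3); a CRYST1
#' record stores the box.
#'
#' @param topology an \code{ion_topology}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_topology <- function(topology, path) {
  a <- topology$atoms
  xyz <- topology$coords
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            topology$box[1], topology$box[2], topology$box[3], 90, 90, 90),
    sprintf("HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            seq_len(nrow(a)) %% 100000, substr(a$name, 1, 4),
            substr(a$resname, 1, 3), substr(a$chain, 1, 1),
            a$resid %% 10000, xyz[, 1], xyz[, 2], xyz[, 3]),
    "END")
  writeLines(lines, path)
  invisible(path)
}
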