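#' @useDynLib peptisite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# standard atomic masses (Da) for the elements that occur in proteins
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  "NA" = 22.990, CL = 35.45, K = 39.098, CA = 40.078, CU = 63.546
)

# single-bond covalent radii (A), used for distance-based bond perception
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07, SE = 1.20
)

#' Standard atomic mass by element symbol
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of masses in Da.
#' @export
element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  if (anyNA(m)) {
    abort(paste0("unknown element(s): ",
                 paste(unique(element[is.na(m)]), collapse = ", ")))
  }
  unname(m)
}

#' Infer the element symbol from a PDB atom name
#'
#' Strips digits and primes; hydrogens may be written "1HZ" etc.
#' @param name Character vector of atom names.
#' @return Character vector of element symbols.
#' @export
guess_element <- function(name) {
  s <- gsub("[0-9' ]", "", name)
  two <- toupper(substr(s, 1, 2))
  out <- ifelse(two %in% c("SE", "FE", "ZN", "MG", "CL", "CU"),
                two, toupper(substr(s, 1, 1)))
  out
}

#' Construct an atom table
#'
#' The atom table is the topology's backbone: one row per atom, ordered as in
#' the coordinate frames.
#'
#' @param serial Integer atom serials (unique).
#' @param name Atom names (e.g. "CA", "OE1").
#' @param chain Single-character chain identifiers.
#' @param res_name Three-letter residue codes.
#' @param res_seq Integer residue numbers (1-based, PDB convention).
#' @param element Element symbols; guessed from `name` when `NULL`.
#' @param mass Masses in Da; standard atomic masses when `NULL`.
#' @return A tibble with columns serial, name, element, chain, res_name,
#'   res_seq, mass, is_hydrogen.
#' @export
atom_table <- function(serial, name, chain, res_name, res_seq,
                       element = NULL, mass = NULL) {
  element <- element %||% guess_element(name)
  mass <- mass %||% element_mass(element)
  if (any(mass <= 0)) abort("atom masses must be positive")
  if (anyDuplicated(serial)) abort("atom serials must be unique")
  tibble(
    serial = as.integer(serial), name = as.character(name),
    element = toupper(element), chain = as.character(chain),
    res_name = as.character(res_name), res_seq = as.integer(res_seq),
    mass = as.numeric(mass), is_hydrogen = toupper(element) == "H"
  )
}

#' Construct a structural ensemble
#'
#' A fixed atomic topology plus `T` frames of coordinates. This is the unit
#' every trajectory-analysis stage consumes.
#'
#' @param atoms Atom table from [atom_table()].
#' @param coords Numeric array `T x N x 3` (or an `N x 3` matrix for a single
#'   frame), Angstrom.
#' @param bonds Two-column integer matrix of covalently bonded atom serial
#'   pairs.
#' @param bond_type Character vector along the rows of `bonds`: `"single"` or
#'   `"double_or_peptide"`. Defaults to typing by [type_bonds()].
#' @param times Frame times in ns, strictly increasing; defaults to 0.1 ns
#'   spacing starting at 0.
#' @param ligand_chain Chain id designating the peptide ligand.
#' @param source_run Integer label of the originating simulation run.
#' @param provenance Optional data frame carrying per-frame provenance
#'   (e.g. run and frame of origin for concatenated ensembles).
#' @return An object of class `"ensemble"`.
#' @export
new_ensemble <- function(atoms, coords, bonds = NULL, bond_type = NULL,
                         times = NULL, ligand_chain = "P", source_run = 1L,
                         provenance = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n <- nrow(atoms)
  if (dim(coords)[2] != n) {
    abort(sprintf("coordinate frames have %d atoms but topology has %d",
                  dim(coords)[2], n))
  }
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  tt <- dim(coords)[1]
  times <- times %||% (0.1 * (seq_len(tt) - 1L))
  if (length(times) != tt) abort("length(times) must equal the frame count")
  if (tt > 1 && any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (times[1] < 0) abort("times must be non-negative")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && !all(bonds %in% atoms$serial)) {
    abort("bonds reference atom serials not present in the topology")
  }
  bond_type <- bond_type %||% type_bonds(atoms, bonds)
  structure(list(
    atoms = atoms, coords = coords, bonds = bonds, bond_type = bond_type,
    times = as.numeric(times), ligand_chain = ligand_chain,
    source_run = as.integer(source_run), provenance = provenance
  ), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf(
    "<ensemble> %d frames x %d atoms (%d bonds), chains %s, ligand chain %s\n",
    n_frames(x), n_atoms(x), nrow(x$bonds),
    paste(unique(x$atoms$chain), collapse = ","), x$ligand_chain))
  cat(sprintf("  times %.3f..%.3f ns, run %d\n",
              x$times[1], x$times[n_frames(x)], x$source_run))
  invisible(x)
}

#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[2]

#' Extract one frame as an N x 3 coordinate matrix
#' @param ensemble An `ensemble`.
#' @param i Frame index.
#' @export
frame_coords <- function(ensemble, i) {
  matrix(ensemble$coords[i, , ], ncol = 3)
}

#' Resolve an atom selection to row indices
#'
#' All filters are optional and combined with AND; an empty result is legal
#' and returned as `integer(0)` (callers decide whether that is an error).
#'
#' @param x An `ensemble` or an atom table.
#' @param chains Optional character vector of chain ids.
#' @param res_seq Optional integer vector of residue numbers.
#' @param atom_names Optional character vector of atom names (e.g. "CA").
#' @param heavy_only Drop hydrogens if `TRUE`.
#' @return Integer vector of atom row indices.
#' @export
select_atoms <- function(x, chains = NULL, res_seq = NULL, atom_names = NULL,
                         heavy_only = FALSE) {
  atoms <- if (inherits(x, "ensemble")) x$atoms else x
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chains)) keep <- keep & atoms$chain %in% chains
  if (!is.null(res_seq)) keep <- keep & atoms$res_seq %in% res_seq
  if (!is.null(atom_names)) keep <- keep & atoms$name %in% atom_names
  if (heavy_only) keep <- keep & !atoms$is_hydrogen
  which(keep)
}

#' Subset an ensemble's frames
#' @param ensemble An `ensemble`.
#' @param idx Frame indices to keep (in order).
#' @export
subset_frames <- function(ensemble, idx) {
  idx <- as.integer(idx)
  out <- ensemble
  out$coords <- ensemble$coords[idx, , , drop = FALSE]
  out$times <- ensemble$times[idx]
  if (!is.null(ensemble$provenance)) {
    out$provenance <- ensemble$provenance[idx, , drop = FALSE]
  }
  out
}

#' Type covalent bonds by atom-name context
#'
#' Peptide bonds (backbone C-N across residues), carbonyls (C-O) and
#' carboxylate C-O pairs are typed `"double_or_peptide"` (they resist
#' torsion); everything else is `"single"`.
#'
#' @param atoms Atom table.
#' @param bonds Two-column serial matrix.
#' @return Character vector along bond rows.
#' @export
type_bonds <- function(atoms, bonds) {
  if (!nrow(bonds)) return(character(0))
  ia <- match(bonds[, 1], atoms$serial)
  ib <- match(bonds[, 2], atoms$serial)
  na_ <- atoms$name[ia]; nb <- atoms$name[ib]
  pep <- (na_ == "C" & nb == "N") | (na_ == "N" & nb == "C")
  carbonyl <- (na_ == "C" & nb == "O") | (na_ == "O" & nb == "C") |
    (na_ == "C" & nb == "OXT") | (na_ == "OXT" & nb == "C")
  carboxyl <- (na_ %in% c("CG", "CD") & grepl("^O[ED][12]$", nb)) |
    (nb %in% c("CG", "CD") & grepl("^O[ED][12]$", na_))
  # arginine guanidinium: resonant, planar
  guan <- (na_ == "CZ" & nb %in% c("NE", "NH1", "NH2")) |
    (nb == "CZ" & na_ %in% c("NE", "NH1", "NH2"))
  ifelse(pep | carbonyl | carboxyl | guan, "double_or_peptide", "single")
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance lies in
#' `[0.4, r1 + r2 + 0.4]` Angstrom, with single-bond covalent radii per
#' element. Used when a PDB file carries no (complete) CONECT records.
#'
#' @param atoms Atom table.
#' @param xyz N x 3 coordinate matrix for one frame.
#' @return Two-column matrix of bonded serial pairs.
#' @export
perceive_bonds <- function(atoms, xyz) {
  r <- .covalent_radii[atoms$element]
  if (anyNA(r)) {
    abort(paste0("no covalent radius for element(s): ",
                 paste(unique(atoms$element[is.na(r)]), collapse = ", ")))
  }
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  # grid-free O(n^2) in blocks; systems here are small (<= a few thousand)
  d2 <- as.matrix(stats::dist(xyz))^2
  cut <- outer(r, r, `+`) + 0.4
  hit <- d2 <= cut^2 & d2 >= 0.16
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  # never bond two hydrogens
  hh <- outer(atoms$is_hydrogen, atoms$is_hydrogen, `&`)
  hit[hh] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  cbind(atoms$serial[idx[, 1]], atoms$serial[idx[, 2]])
}
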