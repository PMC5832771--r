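# Internal-coordinate construction of peptide chains (ideal bond lengths and
# angles, placed sequentially), used by the synthetic-data generators.

.aa3 <- c(A = "ALA", G = "GLY", L = "LEU", K = "LYS", R = "ARG", Y = "TYR",
          E = "GLU", D = "ASP")

# one growing-chain builder: accumulates atoms, coordinates and bonds
chain_builder <- function(chain_id, first_serial = 1L, first_res = 1L) {
  env <- new.env(parent = emptyenv())
  env$name <- character(0); env$res_name <- character(0)
  env$res_seq <- integer(0); env$xyz <- matrix(numeric(0), ncol = 3)
  env$bonds <- matrix(integer(0), ncol = 2)
  env$chain <- chain_id; env$serial0 <- as.integer(first_serial)
  env$res0 <- as.integer(first_res)
  env
}

cb_add <- function(cb, name, res_name, res_seq, pos, bond_to = NULL) {
  cb$name <- c(cb$name, name)
  cb$res_name <- c(cb$res_name, res_name)
  cb$res_seq <- c(cb$res_seq, as.integer(res_seq))
  cb$xyz <- rbind(cb$xyz, pos)
  k <- length(cb$name)
  for (b in bond_to) cb$bonds <- rbind(cb$bonds, c(b, k))
  k  # local index; serials assigned at finish
}

cb_pos <- function(cb, k) cb$xyz[k, ]

cb_finish <- function(cb) {
  serial <- cb$serial0 + seq_along(cb$name) - 1L
  atoms <- atom_table(serial = serial, name = cb$name, chain = cb$chain,
                      res_name = cb$res_name, res_seq = cb$res_seq)
  bonds <- if (nrow(cb$bonds)) {
    cbind(serial[cb$bonds[, 1]], serial[cb$bonds[, 2]])
  } else matrix(integer(0), ncol = 2)
  list(atoms = atoms, xyz = cb$xyz, bonds = normalize_bonds(bonds))
}

# side-chain templates: each entry places atoms from backbone anchors
add_side_chain <- function(cb, res3, rs, iN, iCA, iC) {
  if (res3 %in% c("GLY")) return(invisible(NULL))
  pN <- cb_pos(cb, iN); pCA <- cb_pos(cb, iCA); pC <- cb_pos(cb, iC)
  CB <- place_atom(pN, pC, pCA, 1.53, 110.5, -122.6)
  iCB <- cb_add(cb, "CB", res3, rs, CB, iCA)
  if (res3 == "ALA") return(invisible(NULL))
  chi1 <- -60
  if (res3 %in% c("GLU", "ASP")) {
    iCG <- cb_add(cb, "CG", res3, rs,
                  place_atom(pN, pCA, CB, 1.52, 114, chi1), iCB)
    if (res3 == "GLU") {
      iCD <- cb_add(cb, "CD", res3, rs,
                    place_atom(pCA, CB, cb_pos(cb, iCG), 1.52, 114, 180), iCG)
      cb_add(cb, "OE1", res3, rs,
             place_atom(CB, cb_pos(cb, iCG), cb_pos(cb, iCD), 1.25, 118, 0), iCD)
      cb_add(cb, "OE2", res3, rs,
             place_atom(CB, cb_pos(cb, iCG), cb_pos(cb, iCD), 1.25, 118, 180), iCD)
    } else {
      cb_add(cb, "OD1", res3, rs,
             place_atom(pCA, CB, cb_pos(cb, iCG), 1.25, 118, 0), iCG)
      cb_add(cb, "OD2", res3, rs,
             place_atom(pCA, CB, cb_pos(cb, iCG), 1.25, 118, 180), iCG)
    }
  } else if (res3 == "LYS") {
    iCG <- cb_add(cb, "CG", res3, rs,
                  place_atom(pN, pCA, CB, 1.52, 111, chi1), iCB)
    iCD <- cb_add(cb, "CD", res3, rs,
                  place_atom(pCA, CB, cb_pos(cb, iCG), 1.52, 111, 180), iCG)
    iCE <- cb_add(cb, "CE", res3, rs,
                  place_atom(CB, cb_pos(cb, iCG), cb_pos(cb, iCD), 1.52, 111, 180), iCD)
    iNZ <- cb_add(cb, "NZ", res3, rs,
                  place_atom(cb_pos(cb, iCG), cb_pos(cb, iCD), cb_pos(cb, iCE),
                             1.49, 111, 180), iCE)
    for (j in 1:3) {
      cb_add(cb, paste0("HZ", j), res3, rs,
             place_atom(cb_pos(cb, iCD), cb_pos(cb, iCE), cb_pos(cb, iNZ),
                        1.01, 109.5, c(60, 180, 300)[j]), iNZ)
    }
  } else if (res3 == "ARG") {
    iCG <- cb_add(cb, "CG", res3, rs,
                  place_atom(pN, pCA, CB, 1.52, 111, chi1), iCB)
    iCD <- cb_add(cb, "CD", res3, rs,
                  place_atom(pCA, CB, cb_pos(cb, iCG), 1.52, 111, 180), iCG)
    iNE <- cb_add(cb, "NE", res3, rs,
                  place_atom(CB, cb_pos(cb, iCG), cb_pos(cb, iCD), 1.46, 111, 180), iCD)
    iCZ <- cb_add(cb, "CZ", res3, rs,
                  place_atom(cb_pos(cb, iCG), cb_pos(cb, iCD), cb_pos(cb, iNE),
                             1.33, 124, 180), iNE)
    iNH1 <- cb_add(cb, "NH1", res3, rs,
                   place_atom(cb_pos(cb, iCD), cb_pos(cb, iNE), cb_pos(cb, iCZ),
                              1.33, 120, 0), iCZ)
    iNH2 <- cb_add(cb, "NH2", res3, rs,
                   place_atom(cb_pos(cb, iCD), cb_pos(cb, iNE), cb_pos(cb, iCZ),
                              1.33, 120, 180), iCZ)
    cb_add(cb, "HE", res3, rs,
           place_atom(cb_pos(cb, iNH1), cb_pos(cb, iCZ), cb_pos(cb, iNE),
                      1.01, 120, 180), iNE)
    cb_add(cb, "HH11", res3, rs,
           place_atom(cb_pos(cb, iNE), cb_pos(cb, iCZ), cb_pos(cb, iNH1),
                      1.01, 120, 0), iNH1)
    cb_add(cb, "HH12", res3, rs,
           place_atom(cb_pos(cb, iNE), cb_pos(cb, iCZ), cb_pos(cb, iNH1),
                      1.01, 120, 180), iNH1)
    cb_add(cb, "HH21", res3, rs,
           place_atom(cb_pos(cb, iNE), cb_pos(cb, iCZ), cb_pos(cb, iNH2),
                      1.01, 120, 0), iNH2)
    cb_add(cb, "HH22", res3, rs,
           place_atom(cb_pos(cb, iNE), cb_pos(cb, iCZ), cb_pos(cb, iNH2),
                      1.01, 120, 180), iNH2)
  } else if (res3 == "TYR") {
    iCG <- cb_add(cb, "CG", res3, rs,
                  place_atom(pN, pCA, CB, 1.51, 114, chi1), iCB)
    iCD1 <- cb_add(cb, "CD1", res3, rs,
                   place_atom(pCA, CB, cb_pos(cb, iCG), 1.39, 120, 90), iCG)
    iCD2 <- cb_add(cb, "CD2", res3, rs,
                   place_atom(pCA, CB, cb_pos(cb, iCG), 1.39, 120, -90), iCG)
    iCE1 <- cb_add(cb, "CE1", res3, rs,
                   place_atom(CB, cb_pos(cb, iCG), cb_pos(cb, iCD1), 1.39, 120, 180), iCD1)
    iCE2 <- cb_add(cb, "CE2", res3, rs,
                   place_atom(CB, cb_pos(cb, iCG), cb_pos(cb, iCD2), 1.39, 120, 180), iCD2)
    iCZ <- cb_add(cb, "CZ", res3, rs,
                  place_atom(cb_pos(cb, iCG), cb_pos(cb, iCD1), cb_pos(cb, iCE1),
                             1.39, 120, 0), c(iCE1, iCE2))
    iOH <- cb_add(cb, "OH", res3, rs,
                  place_atom(cb_pos(cb, iCD1), cb_pos(cb, iCE1), cb_pos(cb, iCZ),
                             1.37, 120, 180), iCZ)
    cb_add(cb, "HH", res3, rs,
           place_atom(cb_pos(cb, iCE1), cb_pos(cb, iCZ), cb_pos(cb, iOH),
                      0.97, 109, 180), iOH)
  } else if (res3 == "LEU") {
    iCG <- cb_add(cb, "CG", res3, rs,
                  place_atom(pN, pCA, CB, 1.53, 116, chi1), iCB)
    cb_add(cb, "CD1", res3, rs,
           place_atom(pCA, CB, cb_pos(cb, iCG), 1.52, 111, 180), iCG)
    cb_add(cb, "CD2", res3, rs,
           place_atom(pCA, CB, cb_pos(cb, iCG), 1.52, 111, 60), iCG)
  }
  invisible(NULL)
}

#' Build a single peptide chain from a one-letter sequence
#'
#' Places an ideal-geometry backbone (with amide hydrogens) at the given
#' (phi, psi) backbone dihedrals, plus side chains for A/G/L/K/R/Y/E/D.
#' `(-57, -47)` gives an ideal alpha helix; `(-139, 135)` an extended chain.
#'
#' @param sequence One-letter amino-acid string (subset "AGLKRYED").
#' @param chain_id Chain identifier.
#' @param phi,psi Backbone dihedrals in degrees (recycled per residue).
#' @param first_serial,first_res Numbering offsets.
#' @return List with `atoms` (atom table), `xyz` (N x 3), `bonds`.
#' @export
build_chain <- function(sequence, chain_id = "P", phi = -57, psi = -47,
                        first_serial = 1L, first_res = 1L) {
  letters1 <- strsplit(sequence, "")[[1]]
  if (!all(letters1 %in% names(.aa3))) {
    abort(paste0("unsupported residue letter(s): ",
                 paste(setdiff(letters1, names(.aa3)), collapse = ",")))
  }
  res3 <- .aa3[letters1]
  nres <- length(res3)
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  cb <- chain_builder(chain_id, first_serial, first_res)

  rs <- cb$res0
  iN <- cb_add(cb, "N", res3[1], rs, c(0, 0, 0))
  iCA <- cb_add(cb, "CA", res3[1], rs, c(1.458, 0, 0), iN)
  dir <- c(cos(pi * (180 - 111.2) / 180), sin(pi * (180 - 111.2) / 180), 0)
  iC <- cb_add(cb, "C", res3[1], rs, cb_pos(cb, iCA) + 1.525 * dir, iCA)
  cb_add(cb, "H", res3[1], rs,
         place_atom(cb_pos(cb, iC), cb_pos(cb, iCA), cb_pos(cb, iN),
                    1.01, 119, 180), iN)
  add_side_chain(cb, res3[1], rs, iN, iCA, iC)

  for (i in seq_len(nres)) {
    rs <- cb$res0 + i - 1L
    pO <- place_atom(cb_pos(cb, iN), cb_pos(cb, iCA), cb_pos(cb, iC),
                     1.231, 120.5, psi[i] + 180)
    iO <- cb_add(cb, "O", res3[i], rs, pO, iC)
    if (i == nres) break
    rs2 <- rs + 1L
    iN2 <- cb_add(cb, "N", res3[i + 1], rs2,
                  place_atom(cb_pos(cb, iN), cb_pos(cb, iCA), cb_pos(cb, iC),
                             1.329, 116.2, psi[i]), iC)
    cb_add(cb, "H", res3[i + 1], rs2,
           place_atom(pO, cb_pos(cb, iC), cb_pos(cb, iN2), 1.01, 119, 180), iN2)
    iCA2 <- cb_add(cb, "CA", res3[i + 1], rs2,
                   place_atom(cb_pos(cb, iCA), cb_pos(cb, iC), cb_pos(cb, iN2),
                              1.458, 121.7, 180), iN2)
    iC2 <- cb_add(cb, "C", res3[i + 1], rs2,
                  place_atom(cb_pos(cb, iC), cb_pos(cb, iN2), cb_pos(cb, iCA2),
                             1.525, 111.2, phi[i + 1]), iCA2)
    add_side_chain(cb, res3[i + 1], rs2, iN2, iCA2, iC2)
    iN <- iN2; iCA <- iCA2; iC <- iC2
  }
  cb_finish(cb)
}
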