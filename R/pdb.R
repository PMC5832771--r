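# Multi-model PDB reading and writing (fixed-width v3 columns).
#
# A hand-rolled parser is used deliberately: the package needs per-model
# atom-count diagnostics, CONECT bonds, and per-model frame-time REMARKs,
# none of which generic PDB readers expose.

.time_remark <- "REMARK 100 TIME_NS"

#' Read a multi-model PDB file into a structural ensemble
#'
#' Each MODEL becomes one frame (a file without MODEL records is a single
#' implicit model). Frame times are taken from `REMARK 100 TIME_NS <ns>`
#' records inside each model, from the `times` argument (numeric vector or
#' path to a sidecar file with one ns value per line), or default to 0.1 ns
#' spacing. Covalent bonds are the union of CONECT records and
#' distance-based perception on the first frame.
#'
#' @param path Path to a PDB file.
#' @param ligand_chain Chain id designating the peptide ligand.
#' @param times Optional numeric vector of frame times (ns) or path to a
#'   sidecar text file.
#' @return An [new_ensemble()] object.
#' @export
read_multimodel_pdb <- function(path, ligand_chain = "P", times = NULL) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_starts) != length(model_ends)) {
    abort("malformed PDB: unbalanced MODEL/ENDMDL records")
  }

  if (length(model_starts) == 0) {
    blocks <- list(which(is_atom))
  } else {
    blocks <- lapply(seq_along(model_starts), function(k) {
      idx <- seq(model_starts[k] + 1L, model_ends[k] - 1L)
      idx[is_atom[idx]]
    })
  }
  tt <- length(blocks)
  n <- length(blocks[[1]])
  if (n == 0) abort("PDB contains no ATOM/HETATM records")
  for (k in seq_len(tt)) {
    if (length(blocks[[k]]) != n) {
      abort(sprintf("model %d: atom count %d != %d",
                    k, length(blocks[[k]]), n))
    }
  }

  first <- lines[blocks[[1]]]
  num <- function(x) suppressWarnings(as.numeric(x))
  name <- trimws(substr(first, 13, 16))
  elem <- trimws(substr(first, 77, 78))
  elem <- ifelse(elem == "", guess_element(name), toupper(elem))
  atoms <- atom_table(
    serial = as.integer(num(substr(first, 7, 11))),
    name = name,
    chain = substr(first, 22, 22),
    res_name = trimws(substr(first, 18, 20)),
    res_seq = as.integer(num(substr(first, 23, 26))),
    element = elem
  )

  coords <- array(NA_real_, c(tt, n, 3))
  for (k in seq_len(tt)) {
    ln <- lines[blocks[[k]]]
    xyz <- cbind(num(substr(ln, 31, 38)), num(substr(ln, 39, 46)),
                 num(substr(ln, 47, 54)))
    if (anyNA(xyz)) abort(sprintf("model %d: unreadable coordinates", k))
    coords[k, , ] <- xyz
  }

  # frame times: explicit arg > per-model REMARK > default spacing
  if (is.character(times)) times <- as.numeric(readLines(times))
  if (is.null(times) && length(model_starts)) {
    tl <- vapply(seq_len(tt), function(k) {
      idx <- seq(model_starts[k], model_ends[k])
      hit <- grep(.time_remark, lines[idx], fixed = TRUE, value = TRUE)
      if (length(hit)) num(sub(.time_remark, "", hit[1])) else NA_real_
    }, numeric(1))
    if (!anyNA(tl)) times <- tl
  }

  # CONECT bonds (columns 7-31, four partners max per record)
  con <- lines[startsWith(lines, "CONECT")]
  cbonds <- matrix(integer(0), ncol = 2)
  if (length(con)) {
    pieces <- lapply(con, function(l) {
      f <- c(substr(l, 7, 11), substr(l, 12, 16), substr(l, 17, 21),
             substr(l, 22, 26), substr(l, 27, 31))
      v <- suppressWarnings(as.integer(trimws(f)))
      v <- v[!is.na(v)]
      if (length(v) >= 2) cbind(v[1], v[-1]) else NULL
    })
    cbonds <- do.call(rbind, pieces) %||% cbonds
  }
  pbonds <- perceive_bonds(atoms, matrix(coords[1, , ], ncol = 3))
  bonds <- unique(rbind(normalize_bonds(cbonds), normalize_bonds(pbonds)))

  new_ensemble(atoms, coords, bonds = bonds, times = times,
               ligand_chain = ligand_chain)
}

# orient each pair low-high and drop duplicates/self-bonds
normalize_bonds <- function(b) {
  if (!nrow(b)) return(matrix(integer(0), ncol = 2))
  b <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  unique(b[b[, 1] != b[, 2], , drop = FALSE])
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL pair per frame, a `REMARK 100 TIME_NS` record per model,
#' and CONECT records for all covalent bonds.
#'
#' @param ensemble An `ensemble`.
#' @param path Output file path.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  if (any(abs(ensemble$coords) > 9999.999)) {
    abort("coordinate out of PDB field range (|x| > 9999.999 A)")
  }
  atoms <- ensemble$atoms
  # PDB atom-name column convention: 1-char elements start in column 14
  fmt_name <- ifelse(nchar(atoms$name) <= 3 & nchar(atoms$element) == 1,
                     sprintf(" %-3s", atoms$name),
                     sprintf("%-4s", atoms$name))
  out <- character(0)
  for (k in seq_len(n_frames(ensemble))) {
    xyz <- frame_coords(ensemble, k)
    out <- c(out,
      sprintf("MODEL     %4d", k),
      sprintf("%s %.4f", .time_remark, ensemble$times[k]),
      sprintf("ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              atoms$serial, fmt_name, atoms$res_name, atoms$chain,
              atoms$res_seq, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
              atoms$element),
      "ENDMDL")
  }
  if (nrow(ensemble$bonds)) {
    out <- c(out, sprintf("CONECT%5d%5d", ensemble$bonds[, 1],
                          ensemble$bonds[, 2]))
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
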