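# Rigid-body geometry primitives: superposition, COM, RMSD/RMSF.

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mobile` onto `reference` over a fit
#' selection, via SVD of the covariance matrix with the usual determinant
#' correction so the returned rotation is proper (det = +1).
#'
#' @param mobile N x 3 coordinate matrix.
#' @param reference N x 3 coordinate matrix (same atom ordering).
#' @param fit_idx Integer atom indices used for the fit (default: all).
#' @param weights Optional fit weights (e.g. masses).
#' @return List with `rotation` (3 x 3), `translation` (length-3), and
#'   `rmsd_fit` (Angstrom over the fit selection). The superposed mobile
#'   frame is `mobile %*% t(rotation) + translation` (rowwise).
#' @export
kabsch_superpose <- function(mobile, reference, fit_idx = NULL,
                             weights = NULL) {
  fit_idx <- fit_idx %||% seq_len(nrow(mobile))
  if (length(fit_idx) < 3) {
    abort("degenerate fit selection: need at least 3 atoms")
  }
  m <- mobile[fit_idx, , drop = FALSE]
  r <- reference[fit_idx, , drop = FALSE]
  w <- weights %||% rep(1, nrow(m))
  w <- w / sum(w)
  cm <- colSums(m * w); cr <- colSums(r * w)
  m0 <- sweep(m, 2, cm); r0 <- sweep(r, 2, cr)
  # collinearity check: rank of the centred fit coordinates
  if (qr(m0)$rank < 2) abort("degenerate fit selection: atoms are collinear")
  h <- t(m0 * w) %*% r0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(rot %*% cm)
  fitted <- m %*% t(rot) + matrix(trans, nrow(m), 3, byrow = TRUE)
  rmsd_fit <- sqrt(sum(w * rowSums((fitted - r)^2)))
  list(rotation = rot, translation = trans, rmsd_fit = rmsd_fit)
}

#' Apply a rigid transform to a coordinate matrix
#' @param xyz N x 3 matrix.
#' @param rotation 3 x 3 proper rotation.
#' @param translation Length-3 vector.
#' @export
apply_transform <- function(xyz, rotation, translation) {
  xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
}

#' Mass-weighted centre of mass
#'
#' @param xyz N x 3 coordinate matrix for one frame.
#' @param topology An `ensemble` or atom table supplying masses.
#' @param idx Atom indices of the selection (default: all).
#' @return Length-3 numeric vector, Angstrom.
#' @export
center_of_mass <- function(xyz, topology, idx = NULL) {
  atoms <- if (inherits(topology, "ensemble")) topology$atoms else topology
  idx <- idx %||% seq_len(nrow(atoms))
  if (length(idx) == 0) abort("empty selection: centre of mass undefined")
  m <- atoms$mass[idx]
  colSums(xyz[idx, , drop = FALSE] * m) / sum(m)
}

#' Plain coordinate RMSD between two frames
#' @param a,b N x 3 matrices (same ordering); no superposition is performed.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Superpose every frame of an ensemble onto a reference frame
#'
#' @param ensemble An `ensemble`.
#' @param reference_frame Frame index of the reference (default 1), or an
#'   N x 3 matrix to superpose onto external coordinates.
#' @param fit_idx Atom indices of the fit selection; defaults to receptor
#'   C-alpha atoms (all chains except the ligand chain).
#' @return The ensemble with all frames superposed.
#' @export
superpose_ensemble <- function(ensemble, reference_frame = 1, fit_idx = NULL) {
  fit_idx <- fit_idx %||% receptor_calpha_idx(ensemble)
  ref <- if (is.matrix(reference_frame)) reference_frame else
    frame_coords(ensemble, reference_frame)
  out <- ensemble
  for (t in seq_len(n_frames(ensemble))) {
    fr <- frame_coords(ensemble, t)
    tr <- kabsch_superpose(fr, ref, fit_idx)
    out$coords[t, , ] <- apply_transform(fr, tr$rotation, tr$translation)
  }
  out
}

#' Receptor C-alpha atom indices (fit-selection default)
#' @param ensemble An `ensemble`.
#' @export
receptor_calpha_idx <- function(ensemble) {
  rec <- setdiff(unique(ensemble$atoms$chain), ensemble$ligand_chain)
  select_atoms(ensemble, chains = rec, atom_names = "CA")
}

#' Per-residue C-alpha root-mean-square fluctuation
#'
#' Every frame is first superposed onto the reference frame over the fit
#' selection; RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2) for each C-alpha.
#'
#' @param ensemble An `ensemble` with at least two frames.
#' @param reference_frame Index of the reference frame (default 1).
#' @param fit_idx Fit-selection atom indices; defaults to receptor C-alpha.
#' @param chains Chains to report (default: receptor chains).
#' @return A tibble (chain, res_seq, res_name, rmsf) in Angstrom.
#' @export
rmsf_calpha <- function(ensemble, reference_frame = 1, fit_idx = NULL,
                        chains = NULL) {
  if (n_frames(ensemble) < 2) {
    abort("RMSF undefined for fewer than 2 frames")
  }
  chains <- chains %||%
    setdiff(unique(ensemble$atoms$chain), ensemble$ligand_chain)
  sup <- superpose_ensemble(ensemble, reference_frame, fit_idx)
  ca <- select_atoms(sup, chains = chains, atom_names = "CA")
  if (!length(ca)) abort("no C-alpha atoms in the requested chains")
  xs <- sup$coords[, ca, , drop = FALSE]                  # T x n x 3
  mu <- apply(xs, c(2, 3), mean)
  dev2 <- sweep(xs, c(2, 3), mu)^2
  rmsf <- sqrt(apply(dev2, 2, sum) / dim(xs)[1])
  tibble(
    chain = sup$atoms$chain[ca], res_seq = sup$atoms$res_seq[ca],
    res_name = sup$atoms$res_name[ca], rmsf = as.numeric(rmsf)
  )
}

# --- internal-coordinate construction (NeRF) ---------------------------------

#' Place an atom from internal coordinates
#'
#' Given positions of three predecessors a-b-c, returns the position d with
#' bond length |cd|, angle b-c-d and dihedral a-b-c-d.
#'
#' @param a,b,c Length-3 vectors.
#' @param bond Bond length, Angstrom.
#' @param angle Bond angle in degrees.
#' @param dihedral Dihedral in degrees.
#' @return Length-3 vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# minimal cross product (avoids importing pracma for one call)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Rotation matrix about an axis
#' @param axis Length-3 axis vector (normalised internally).
#' @param angle Angle in degrees.
#' @export
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2)); th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# uniform random rotation (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
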