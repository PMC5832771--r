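# Geometric hydrogen-bond and salt-bridge detection.
#
# The ligand is always the donor and the receptor the acceptor, matching the
# directionality used to count receptor contacts in the mapping stage.

#' Hydrogen-bond / salt-bridge criterion
#'
#' Defaults: donor-acceptor distance <= 3.5 A and D-H...A angle >= 135 deg;
#' salt bridge when a ligand side-chain nitrogen (Lys NZ, Arg NE/NH1/NH2)
#' lies within 4.0 A of a receptor carboxylate oxygen. With
#' `heavy_only_fallback` the angle test is skipped for topologies without
#' hydrogens.
#'
#' @param da_cutoff Donor-acceptor cutoff, A.
#' @param dha_min_angle Minimum D-H...A angle, degrees (0, 180].
#' @param saltbridge_cutoff Charged N...O cutoff, A.
#' @param heavy_only_fallback Allow distance-only detection when the
#'   topology has no hydrogens.
#' @export
hbond_criterion <- function(da_cutoff = 3.5, dha_min_angle = 135,
                            saltbridge_cutoff = 4.0,
                            heavy_only_fallback = FALSE) {
  stopifnot(da_cutoff > 0, saltbridge_cutoff > 0,
            dha_min_angle > 0, dha_min_angle <= 180)
  structure(list(da_cutoff = da_cutoff, dha_min_angle = dha_min_angle,
                 saltbridge_cutoff = saltbridge_cutoff,
                 heavy_only_fallback = heavy_only_fallback),
            class = "hbond_criterion")
}

.sb_donor_names <- c("NZ", "NH1", "NH2", "NE")
.carboxylate_o <- c("OE1", "OE2", "OD1", "OD2")

# precompute donor/acceptor bookkeeping for repeated per-frame evaluation
contact_context <- function(ensemble, criterion) {
  atoms <- ensemble$atoms
  lig <- atoms$chain == ensemble$ligand_chain
  has_h <- any(atoms$is_hydrogen[lig])
  if (!has_h && !criterion$heavy_only_fallback) {
    abort(paste0("ligand topology has no hydrogens; set heavy_only_fallback",
                 " = TRUE for distance-only detection"))
  }
  # hydrogens bonded to each atom
  h_of <- vector("list", nrow(atoms))
  if (nrow(ensemble$bonds)) {
    i1 <- match(ensemble$bonds[, 1], atoms$serial)
    i2 <- match(ensemble$bonds[, 2], atoms$serial)
    for (k in seq_along(i1)) {
      if (atoms$is_hydrogen[i2[k]]) h_of[[i1[k]]] <- c(h_of[[i1[k]]], i2[k])
      if (atoms$is_hydrogen[i1[k]]) h_of[[i2[k]]] <- c(h_of[[i2[k]]], i1[k])
    }
  }
  don <- which(lig & atoms$element %in% c("N", "O") &
                 (!has_h | lengths(h_of) > 0))
  acc <- which(!lig & atoms$element %in% c("N", "O") & !atoms$is_hydrogen)
  sb_don <- which(lig & atoms$name %in% .sb_donor_names)
  sb_acc <- which(!lig & atoms$name %in% .carboxylate_o)
  list(don = don, don_h = h_of[don], acc = acc,
       acc_res = paste(atoms$chain[acc], atoms$res_seq[acc]),
       sb_don = sb_don, sb_acc = sb_acc,
       sb_res = paste(atoms$chain[sb_acc], atoms$res_seq[sb_acc]),
       has_h = has_h)
}

# residues (as "chain res_seq" keys) contacted by the ligand in one frame
frame_contact_residues <- function(xyz, ctx, criterion) {
  hit <- character(0)
  if (length(ctx$don) && length(ctx$acc)) {
    dmat <- cross_dist(xyz[ctx$don, , drop = FALSE],
                       xyz[ctx$acc, , drop = FALSE])
    pairs <- which(dmat <= criterion$da_cutoff, arr.ind = TRUE)
    if (nrow(pairs)) {
      ok <- vapply(seq_len(nrow(pairs)), function(p) {
        di <- pairs[p, 1]; ai <- pairs[p, 2]
        if (!ctx$has_h) return(TRUE)
        hs <- ctx$don_h[[di]]
        if (!length(hs)) return(FALSE)
        d <- xyz[ctx$don[di], ]; a <- xyz[ctx$acc[ai], ]
        any(vapply(hs, function(h) {
          v1 <- d - xyz[h, ]; v2 <- a - xyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi >= criterion$dha_min_angle
        }, logical(1)))
      }, logical(1))
      hit <- ctx$acc_res[pairs[ok, 2]]
    }
  }
  if (length(ctx$sb_don) && length(ctx$sb_acc)) {
    smat <- cross_dist(xyz[ctx$sb_don, , drop = FALSE],
                       xyz[ctx$sb_acc, , drop = FALSE])
    sp <- which(smat <= criterion$saltbridge_cutoff, arr.ind = TRUE)
    if (nrow(sp)) hit <- c(hit, ctx$sb_res[sp[, 2]])
  }
  unique(hit)
}

# all-pairs Euclidean distances between two coordinate sets
cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
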