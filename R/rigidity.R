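# Constraint-network rigidity analysis: network construction (covalent,
# hydrogen-bond/salt-bridge, hydrophobic constraints), body-bar pebble-game
# decomposition, constraint dilution, and the per-residue stability change
# upon removal of the ligand's constraints.

#' Constraint-network parameters
#'
#' @param hbond_include_cutoff Hydrogen bonds with `E_HB <=` this value
#'   (kcal/mol) enter the network.
#' @param d_cut_hydrophobic Hydrophobic tether slack added to the sum of
#'   van der Waals radii, A.
#' @param vdw_radii Named map element -> vdW radius, A (C 1.7, S 1.8).
#' @param bars Bar multiplicities per constraint type.
#' @param dilution_start,dilution_stop,dilution_step Energy ladder for the
#'   dilution (kcal/mol); H-bonds with `E_HB <= sigma` are retained at each
#'   rung sigma. The ladder has `(start - stop) / step` rungs starting at
#'   `dilution_start`.
#' @param v0,d0 Hydrogen-bond potential depth (kcal/mol) and optimum
#'   donor-acceptor distance (A).
#' @export
network_params <- function(hbond_include_cutoff = 0,
                           d_cut_hydrophobic = 0.25,
                           vdw_radii = c(C = 1.7, S = 1.8),
                           bars = c(covalent = 5, double_or_peptide = 6,
                                    hbond = 5, saltbridge = 5,
                                    hydrophobic = 2),
                           dilution_start = 0, dilution_stop = -8,
                           dilution_step = 0.1,
                           v0 = 8, d0 = 2.8) {
  stopifnot(d_cut_hydrophobic >= 0, dilution_step > 0,
            all(bars >= 1 & bars <= 6),
            dilution_start > dilution_stop)
  structure(list(hbond_include_cutoff = hbond_include_cutoff,
                 d_cut_hydrophobic = d_cut_hydrophobic,
                 vdw_radii = vdw_radii, bars = bars,
                 dilution_start = dilution_start,
                 dilution_stop = dilution_stop,
                 dilution_step = dilution_step, v0 = v0, d0 = d0),
            class = "network_params")
}

# descending dilution ladder sigma_1 = start, ..., length (start-stop)/step
dilution_ladder <- function(params) {
  L <- round((params$dilution_start - params$dilution_stop) /
               params$dilution_step)
  if (L < 1) abort("empty dilution ladder")
  params$dilution_start - params$dilution_step * (seq_len(L) - 1)
}

#' Hydrogen-bond energy (Mayo-style 12-10 potential with angular weight)
#'
#' `E_HB = V0 * (5 (d0/d)^12 - 6 (d0/d)^10) * cos^2(theta)` with
#' `d` the donor-acceptor distance and `theta` the D-H...A angle; geometries
#' with `theta < 90` degrees return `+Inf` (excluded).
#'
#' @param donor,hydrogen,acceptor Length-3 coordinate vectors, A.
#' @param v0 Well depth, kcal/mol. @param d0 Optimum D-A distance, A.
#' @return Energy in kcal/mol (negative = attractive).
#' @export
hbond_energy <- function(donor, hydrogen, acceptor, v0 = 8, d0 = 2.8) {
  d <- sqrt(sum((donor - acceptor)^2))
  if (d < 1e-6) abort("coincident donor and acceptor atoms")
  v1 <- donor - hydrogen; v2 <- acceptor - hydrogen
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (theta < 90) return(Inf)
  v0 * (5 * (d0 / d)^12 - 6 * (d0 / d)^10) * cosang^2
}

#' Build the constraint network for one frame
#'
#' Bodies are atoms; constraints are covalent bonds (5 bars; peptide/double
#' bonds 6), hydrogen bonds and salt bridges with `E_HB` below the
#' inclusion cutoff (5 bars), and hydrophobic tethers between side-chain
#' C/S atoms closer than the sum of their vdW radii plus `d_cut` (2 bars).
#' Ligand-interface constraints follow the same rules and are included only
#' when `include_ligand = TRUE`.
#'
#' @param ensemble An `ensemble` (supplies topology and bonds).
#' @param frame Frame index to build from.
#' @param params A [network_params()].
#' @param include_ligand Include constraints touching the ligand chain.
#' @return An object of class `"constraint_network"`.
#' @export
build_network <- function(ensemble, frame = 1, params = network_params(),
                          include_ligand = TRUE) {
  atoms <- ensemble$atoms
  xyz <- frame_coords(ensemble, frame)
  lig <- atoms$chain == ensemble$ligand_chain
  serial <- atoms$serial
  n <- nrow(atoms)

  # covalent
  cb <- ensemble$bonds
  ctype <- ifelse(ensemble$bond_type == "double_or_peptide",
                  "double_or_peptide", "covalent")
  cons <- tibble(i = as.integer(cb[, 1]), j = as.integer(cb[, 2]),
                 type = as.character(ctype), e_hb = rep(NA_real_, nrow(cb)))

  # adjacency for 1-2/1-3 exclusion
  idx_of <- match(seq_len(max(serial)), serial)
  adj <- vector("list", n)
  for (k in seq_len(nrow(cb))) {
    a <- idx_of[cb[k, 1]]; b <- idx_of[cb[k, 2]]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  near_bonded <- function(a, b) {
    (b %in% adj[[a]]) || length(intersect(adj[[a]], adj[[b]])) > 0
  }

  # hydrogen bonds / salt bridges
  has_h <- atoms$is_hydrogen
  h_of <- vector("list", n)
  for (k in seq_len(nrow(cb))) {
    a <- idx_of[cb[k, 1]]; b <- idx_of[cb[k, 2]]
    if (has_h[b]) h_of[[a]] <- c(h_of[[a]], b)
    if (has_h[a]) h_of[[b]] <- c(h_of[[b]], a)
  }
  don <- which(atoms$element %in% c("N", "O") & lengths(h_of) > 0)
  acc <- which(atoms$element %in% c("N", "O") & !has_h)
  hb <- list()
  if (length(don) && length(acc)) {
    dmat <- cross_dist(xyz[don, , drop = FALSE], xyz[acc, , drop = FALSE])
    cand <- which(dmat <= 4.5, arr.ind = TRUE)
    for (p in seq_len(nrow(cand))) {
      a <- don[cand[p, 1]]; b <- acc[cand[p, 2]]
      if (a == b || near_bonded(a, b)) next
      e <- min(vapply(h_of[[a]], function(h)
        hbond_energy(xyz[a, ], xyz[h, ], xyz[b, ], params$v0, params$d0),
        numeric(1)))
      if (is.finite(e) && e <= params$hbond_include_cutoff) {
        sb <- atoms$name[a] %in% .sb_donor_names &&
          atoms$name[b] %in% .carboxylate_o
        hb[[length(hb) + 1]] <- tibble(
          i = serial[a], j = serial[b],
          type = if (sb) "saltbridge" else "hbond", e_hb = e)
      }
    }
  }

  # hydrophobic tethers between side-chain C/S atoms
  backbone <- c("N", "CA", "C", "O", "OXT")
  hyd <- which(atoms$element %in% c("C", "S") & !(atoms$name %in% backbone))
  hp <- list()
  if (length(hyd) > 1) {
    r <- params$vdw_radii[atoms$element[hyd]]
    hmat <- cross_dist(xyz[hyd, , drop = FALSE], xyz[hyd, , drop = FALSE])
    cut <- outer(r, r, `+`) + params$d_cut_hydrophobic
    pair <- which(hmat < cut & upper.tri(hmat), arr.ind = TRUE)
    for (p in seq_len(nrow(pair))) {
      a <- hyd[pair[p, 1]]; b <- hyd[pair[p, 2]]
      if (near_bonded(a, b)) next
      hp[[length(hp) + 1]] <- tibble(i = serial[a], j = serial[b],
                                     type = "hydrophobic", e_hb = NA_real_)
    }
  }

  cons <- dplyr::bind_rows(cons, dplyr::bind_rows(hb), dplyr::bind_rows(hp))
  cons$ligand <- lig[idx_of[cons$i]] | lig[idx_of[cons$j]]
  if (!include_ligand) cons <- cons[!cons$ligand, , drop = FALSE]
  # one constraint per unordered atom pair
  cons <- cons[!duplicated(cbind(pmin(cons$i, cons$j),
                                 pmax(cons$i, cons$j))), , drop = FALSE]
  cons$bars <- as.integer(params$bars[ifelse(cons$type == "covalent",
                                             "covalent", cons$type)])

  structure(list(
    atoms = atoms, bodies = serial, constraints = as_tibble(cons),
    ligand_chain = ensemble$ligand_chain,
    frame_provenance = c(run = ensemble$source_run, frame = frame),
    params = params
  ), class = "constraint_network")
}

#' @export
print.constraint_network <- function(x, ...) {
  tb <- table(x$constraints$type)
  cat(sprintf("<constraint_network> %d bodies, %d constraints (%s)\n",
              length(x$bodies), nrow(x$constraints),
              paste(names(tb), tb, sep = ":", collapse = ", ")))
  invisible(x)
}

# expand constraints into per-bar endpoint lists, deterministically ordered
# by ascending serial pairs
expand_bars <- function(constraints, serial_index) {
  if (!nrow(constraints)) {
    return(list(u = integer(0), v = integer(0)))
  }
  lo <- pmin(constraints$i, constraints$j)
  hi <- pmax(constraints$i, constraints$j)
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]; bars <- constraints$bars[o]
  list(u = serial_index[rep(lo, bars)], v = serial_index[rep(hi, bars)])
}

#' Rigid-cluster decomposition of a constraint network
#'
#' Runs the body-bar (6,6) pebble game: every atom is a body with 6 degrees
#' of freedom, every constraint contributes its bar count, bars are
#' processed in ascending atom-serial order. Rigid clusters are maximal
#' mutually rigid body sets.
#'
#' @param network A [build_network()] result.
#' @return List with `labels` (integer cluster label per body, named by atom
#'   serial), `dof` (global residual degrees of freedom), `n_redundant`
#'   (redundant bar count), and `giant` (label of the largest cluster;
#'   ties resolved toward the cluster containing the lowest serial).
#' @export
pebble_game_rigid_clusters <- function(network) {
  serial_index <- integer(max(network$bodies))
  serial_index[network$bodies] <- seq_along(network$bodies)
  e <- expand_bars(network$constraints, serial_index)
  res <- pebble_game_cpp(length(network$bodies), e$u, e$v)
  labels <- stats::setNames(res$labels, network$bodies)
  sizes <- table(res$labels)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  # tie-break: cluster containing the lowest atom serial (bodies are in
  # ascending-serial order, so the first occurrence wins)
  giant <- big[which.min(vapply(big, function(g)
    which(res$labels == g)[1], integer(1)))]
  list(labels = labels, dof = res$dof, n_redundant = res$n_redundant,
       giant = giant)
}

#' Per-residue stability from constraint dilution
#'
#' Steps an energy cutoff sigma down the dilution ladder; at each rung only
#' hydrogen-bond/salt-bridge constraints with `E_HB <= sigma` are retained
#' (covalent and hydrophobic constraints persist). Residue i is stable at a
#' rung when its C-alpha body belongs to the giant rigid cluster;
#' `g_i = step * #\{rungs at which i is stable\}` (kcal/mol).
#'
#' @param networks A `constraint_network` or list of them.
#' @param params A [network_params()] (supplies the ladder).
#' @return Tibble (network, chain, res_seq, g).
#' @export
dilution_stability <- function(networks, params = network_params()) {
  if (inherits(networks, "constraint_network")) networks <- list(networks)
  sig <- sort(dilution_ladder(params))  # ascending: strongest rung first
  out <- lapply(seq_along(networks), function(k) {
    nw <- networks[[k]]
    serial_index <- integer(max(nw$bodies))
    serial_index[nw$bodies] <- seq_along(nw$bodies)
    ishb <- nw$constraints$type %in% c("hbond", "saltbridge")
    base <- expand_bars(nw$constraints[!ishb, , drop = FALSE], serial_index)
    hbc <- nw$constraints[ishb, , drop = FALSE]
    hb <- expand_bars(hbc, serial_index)
    # energies per expanded bar follow the same ordering as expand_bars
    o <- order(pmin(hbc$i, hbc$j), pmax(hbc$i, hbc$j))
    hb_e <- rep(hbc$e_hb[o], hbc$bars[o])
    res <- dilution_cpp(length(nw$bodies), base$u, base$v,
                        hb$u, hb$v, hb_e, sig)
    ca <- which(nw$atoms$name == "CA" &
                  nw$atoms$chain != nw$ligand_chain)
    g <- params$dilution_step * rowSums(res$giant[ca, , drop = FALSE])
    tibble(network = k, chain = nw$atoms$chain[ca],
           res_seq = nw$atoms$res_seq[ca], g = g)
  })
  dplyr::bind_rows(out)
}

#' Remove the ligand's constraints from a network (perturbed state)
#'
#' Drops every constraint with at least one ligand atom, and the ligand
#' bodies themselves, tallying removed hydrogen-bond/salt-bridge and
#' hydrophobic constraints (counts and percentage of each class).
#'
#' @param network A `constraint_network` built with `include_ligand = TRUE`.
#' @return The perturbed network, with the tally in `attr(, "removal_tally")`.
#' @export
perturb_remove_ligand <- function(network) {
  cons <- network$constraints
  islig <- cons$ligand
  lig_atoms <- network$atoms$chain == network$ligand_chain
  if (!any(islig) && !any(lig_atoms)) {
    warn("network has no ligand constraints; returning it unchanged")
    attr(network, "removal_tally") <-
      tibble(class = c("hbond", "hydrophobic"), removed = c(0, 0),
             total = c(sum(cons$type %in% c("hbond", "saltbridge")),
                       sum(cons$type == "hydrophobic")),
             percent = c(0, 0))
    return(network)
  }
  hb_all <- sum(cons$type %in% c("hbond", "saltbridge"))
  hp_all <- sum(cons$type == "hydrophobic")
  hb_rm <- sum(islig & cons$type %in% c("hbond", "saltbridge"))
  hp_rm <- sum(islig & cons$type == "hydrophobic")
  out <- network
  out$constraints <- cons[!islig, , drop = FALSE]
  out$atoms <- network$atoms[!lig_atoms, , drop = FALSE]
  out$bodies <- out$atoms$serial
  attr(out, "removal_tally") <- tibble(
    class = c("hbond", "hydrophobic"),
    removed = c(hb_rm, hp_rm), total = c(hb_all, hp_all),
    percent = 100 * c(ifelse(hb_all > 0, hb_rm / hb_all, 0),
                      ifelse(hp_all > 0, hp_rm / hp_all, 0)))
  out
}

#' Per-residue stability change upon ligand removal
#'
#' `Delta G_i = <g_i(ground)> - <g_i(perturbed)>` averaged over the network
#' ensemble, with the perturbed networks produced by
#' [perturb_remove_ligand()]. Positive values mean the ligand stabilizes
#' residue i; residues above the reporting threshold are flagged.
#'
#' @param ground_networks List of ground-state networks (ligand included).
#' @param params A [network_params()].
#' @param threshold Reporting threshold, kcal/mol (default 0.1).
#' @return Tibble (chain, res_seq, delta_g, flagged) of class
#'   `"stability_profile"`, with the mean removal tally in
#'   `attr(, "removal_tally")`.
#' @export
delta_g_profile <- function(ground_networks, params = network_params(),
                            threshold = 0.1) {
  if (inherits(ground_networks, "constraint_network")) {
    ground_networks <- list(ground_networks)
  }
  if (!length(ground_networks)) abort("empty network ensemble")
  perturbed <- lapply(ground_networks, perturb_remove_ligand)
  g0 <- dilution_stability(ground_networks, params)
  g1 <- dilution_stability(perturbed, params)
  m0 <- dplyr::summarise(dplyr::group_by(g0, chain, res_seq),
                         g_ground = mean(g), .groups = "drop")
  m1 <- dplyr::summarise(dplyr::group_by(g1, chain, res_seq),
                         g_perturbed = mean(g), .groups = "drop")
  prof <- dplyr::left_join(m0, m1, by = c("chain", "res_seq"))
  prof$delta_g <- prof$g_ground - prof$g_perturbed
  prof$flagged <- prof$delta_g > threshold
  tallies <- lapply(perturbed, attr, "removal_tally")
  tally <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(tallies), class),
    removed = mean(removed), total = mean(total), percent = mean(percent),
    .groups = "drop")
  out <- prof[, c("chain", "res_seq", "delta_g", "flagged")]
  out <- as_tibble(out)
  class(out) <- c("stability_profile", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "removal_tally") <- tally
  out
}
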