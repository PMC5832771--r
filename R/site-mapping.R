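# Binding-site mapping: occupancy grids of the ligand centre of mass,
# per-residue contact propensities, bound-frame extraction, and bound/apo
# RMSF comparison.

#' Occupancy grid of the ligand centre of mass
#'
#' Every frame with time <= `window_end_ns`, pooled over runs, is superposed
#' onto the reference over receptor C-alpha atoms; the ligand centre of mass
#' is then binned on a cubic grid (half-open bins
#' `[origin + k*edge, origin + (k+1)*edge)`). The grid spans the bounding
#' box of all contributing centres of mass plus a one-bin margin.
#'
#' @param runs List of ensembles sharing one topology.
#' @param window_end_ns Upper time bound (ns) of contributing frames.
#' @param bin_edge Cubic bin edge, A (default 3).
#' @param reference Reference coordinates (N x 3 matrix); defaults to frame
#'   1 of the first run.
#' @return An object of class `"occupancy_grid"`: origin, bin_edge, shape,
#'   counts (3-d integer array), window_end_ns, n_frames.
#' @export
occupancy_grid <- function(runs, window_end_ns, bin_edge = 3,
                           reference = NULL) {
  stopifnot(window_end_ns > 0, bin_edge > 0)
  if (inherits(runs, "ensemble")) runs <- list(runs)
  reference <- reference %||% frame_coords(runs[[1]], 1)
  coms <- ligand_com_series(runs, window_end_ns, reference)
  if (nrow(coms) == 0) {
    warn("no frames fall inside the requested time window; grid is empty")
    return(structure(list(origin = c(0, 0, 0), bin_edge = bin_edge,
                          shape = c(1L, 1L, 1L),
                          counts = array(0L, c(1, 1, 1)),
                          window_end_ns = window_end_ns, n_frames = 0L),
                     class = "occupancy_grid"))
  }
  origin <- apply(coms, 2, min) - bin_edge
  shape <- as.integer(floor((apply(coms, 2, max) - origin) / bin_edge)) + 2L
  idx <- floor(sweep(coms, 2, origin) / bin_edge) + 1L
  counts <- array(0L, shape)
  flat <- (idx[, 3] - 1L) * shape[1] * shape[2] + (idx[, 2] - 1L) * shape[1] +
    idx[, 1]
  tab <- table(flat)
  counts[as.integer(names(tab))] <- as.integer(tab)
  structure(list(origin = origin, bin_edge = bin_edge, shape = shape,
                 counts = counts, window_end_ns = window_end_ns,
                 n_frames = nrow(coms)),
            class = "occupancy_grid")
}

# superposed ligand COM per contributing frame, pooled over runs
ligand_com_series <- function(runs, window_end_ns, reference) {
  out <- list()
  for (ens in runs) {
    keep <- which(ens$times <= window_end_ns)
    if (!length(keep)) next
    fit <- receptor_calpha_idx(ens)
    lig <- select_atoms(ens, chains = ens$ligand_chain)
    m <- matrix(NA_real_, length(keep), 3)
    for (j in seq_along(keep)) {
      fr <- frame_coords(ens, keep[j])
      tr <- kabsch_superpose(fr, reference, fit)
      sup <- apply_transform(fr, tr$rotation, tr$translation)
      m[j, ] <- center_of_mass(sup, ens, lig)
    }
    out[[length(out) + 1]] <- m
  }
  do.call(rbind, out) %||% matrix(numeric(0), ncol = 3)
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("<occupancy_grid> %s bins of edge %.2f A, %d frames (t <= %g ns)\n",
              paste(x$shape, collapse = "x"), x$bin_edge, x$n_frames,
              x$window_end_ns))
  invisible(x)
}

#' @export
as_tibble.occupancy_grid <- function(x, ...) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  cx <- x$origin[1] + (idx[, 1] - 0.5) * x$bin_edge
  cy <- x$origin[2] + (idx[, 2] - 0.5) * x$bin_edge
  cz <- x$origin[3] + (idx[, 3] - 0.5) * x$bin_edge
  cnt <- x$counts[idx]
  tibble(x = cx, y = cy, z = cz, count = cnt)
}

#' Top occupied sites of a grid
#'
#' Greedy selection of the `k` highest-count bins, suppressing bins closer
#' than `min_separation` to an already-selected site. Ties are broken by
#' lexicographic bin index.
#'
#' @param grid An [occupancy_grid()].
#' @param k Maximum number of sites.
#' @param min_separation Minimum distance between reported sites, A.
#' @return Tibble (site, x, y, z, count), sites ordered by count.
#' @export
top_sites <- function(grid, k = 3, min_separation = 6) {
  if (k < 1) abort("k must be >= 1")
  if (sum(grid$counts) == 0) abort("grid is empty")
  tb <- as_tibble(grid)
  # lexicographic bin order is the row order of which(); sort by count
  # descending with stable ties
  tb <- tb[order(-tb$count), , drop = FALSE]
  sel <- list()
  for (i in seq_len(nrow(tb))) {
    p <- c(tb$x[i], tb$y[i], tb$z[i])
    if (length(sel)) {
      dmin <- min(vapply(sel, function(s)
        sqrt(sum((s$pos - p)^2)), numeric(1)))
      if (dmin < min_separation) next
    }
    sel[[length(sel) + 1]] <- list(pos = p, count = tb$count[i])
    if (length(sel) == k) break
  }
  tibble(
    site = seq_along(sel),
    x = vapply(sel, function(s) s$pos[1], numeric(1)),
    y = vapply(sel, function(s) s$pos[2], numeric(1)),
    z = vapply(sel, function(s) s$pos[3], numeric(1)),
    count = vapply(sel, function(s) s$count, numeric(1))
  )
}

#' Per-residue hydrogen-bond / salt-bridge propensity
#'
#' For each receptor residue, the fraction of all frames (pooled over runs)
#' in which at least one ligand-donor to residue-acceptor hydrogen bond or
#' salt bridge passes the criterion.
#'
#' @param runs List of ensembles sharing one topology.
#' @param criterion An [hbond_criterion()].
#' @param average_chains Average homologous residues of the two receptor
#'   chains (matched by residue number) and report each residue once.
#' @return Tibble (chain, res_seq, res_name, propensity); without the chain
#'   column when `average_chains = TRUE`. Attribute `averaged_over_chains`
#'   records the flag.
#' @export
hbond_saltbridge_propensity <- function(runs, criterion = hbond_criterion(),
                                        average_chains = FALSE) {
  if (inherits(runs, "ensemble")) runs <- list(runs)
  atoms <- runs[[1]]$atoms
  lig_chain <- runs[[1]]$ligand_chain
  rec <- atoms[atoms$chain != lig_chain, ]
  res <- dplyr::distinct(rec, chain, res_seq, res_name)
  key <- paste(res$chain, res$res_seq)
  nhit <- stats::setNames(numeric(length(key)), key)
  total <- 0L
  for (ens in runs) {
    ctx <- contact_context(ens, criterion)
    for (t in seq_len(n_frames(ens))) {
      hits <- frame_contact_residues(frame_coords(ens, t), ctx, criterion)
      if (length(hits)) nhit[hits] <- nhit[hits] + 1
      total <- total + 1L
    }
  }
  res$propensity <- as.numeric(nhit[key]) / total
  out <- if (average_chains) {
    dplyr::summarise(dplyr::group_by(res, res_seq, res_name),
                     propensity = mean(propensity), .groups = "drop")
  } else res
  out <- as_tibble(out)
  attr(out, "averaged_over_chains") <- average_chains
  out
}

#' Extract bound-state frames anchored at given residues
#'
#' Frames sampled every `stride_ns` whose ligand hydrogen-bonds at least one
#' anchor residue (OR over anchors) are concatenated into one ensemble.
#' Run/frame provenance is preserved in `$provenance`.
#'
#' @param runs List of ensembles.
#' @param anchor_residues Data frame (`chain`, `res_seq`) of anchor
#'   residues.
#' @param criterion An [hbond_criterion()]; only the hydrogen-bond part is
#'   applied.
#' @param stride_ns Sampling stride, ns (default 2). Must not be smaller
#'   than the frame spacing.
#' @return A bound-state `ensemble` (frames renumbered at `stride_ns`
#'   spacing), or an empty-frame ensemble with a warning when no frame
#'   qualifies.
#' @export
extract_bound_frames <- function(runs, anchor_residues,
                                 criterion = hbond_criterion(),
                                 stride_ns = 2) {
  if (inherits(runs, "ensemble")) runs <- list(runs)
  anchor_key <- paste(anchor_residues$chain, anchor_residues$res_seq)
  atoms <- runs[[1]]$atoms
  if (!all(anchor_key %in% paste(atoms$chain, atoms$res_seq))) {
    abort("anchor residues not present in the topology")
  }
  sel_coords <- list(); prov <- list()
  for (ens in runs) {
    dt <- if (n_frames(ens) > 1) min(diff(ens$times)) else stride_ns
    if (stride_ns < dt - 1e-9) {
      abort(sprintf("stride %g ns is smaller than the frame spacing %g ns",
                    stride_ns, dt))
    }
    strided <- which(abs(ens$times / stride_ns -
                           round(ens$times / stride_ns)) < 1e-9)
    ctx <- contact_context(ens, criterion)
    for (t in strided) {
      xyz <- frame_coords(ens, t)
      hits <- frame_contact_hbond_only(xyz, ctx, criterion)
      if (any(hits %in% anchor_key)) {
        sel_coords[[length(sel_coords) + 1]] <- xyz
        prov[[length(prov) + 1]] <-
          tibble(run = ens$source_run, frame = t, time_ns = ens$times[t])
      }
    }
  }
  k <- length(sel_coords)
  if (k == 0) {
    warn("no bound frames satisfy the anchor criterion")
    ref <- runs[[1]]
    empty <- subset_frames(ref, 1)
    empty$coords <- empty$coords[0, , , drop = FALSE]
    empty$times <- numeric(0)
    empty$provenance <- tibble(run = integer(0), frame = integer(0),
                               time_ns = numeric(0))
    return(empty)
  }
  coords <- array(NA_real_, c(k, n_atoms(runs[[1]]), 3))
  for (i in seq_len(k)) coords[i, , ] <- sel_coords[[i]]
  new_ensemble(runs[[1]]$atoms, coords, bonds = runs[[1]]$bonds,
               bond_type = runs[[1]]$bond_type,
               times = stride_ns * (seq_len(k) - 1L),
               ligand_chain = runs[[1]]$ligand_chain,
               source_run = runs[[1]]$source_run,
               provenance = dplyr::bind_rows(prov))
}

# hydrogen-bond-only variant of frame_contact_residues (no salt bridges)
frame_contact_hbond_only <- function(xyz, ctx, criterion) {
  ctx$sb_don <- integer(0); ctx$sb_acc <- integer(0)
  frame_contact_residues(xyz, ctx, criterion)
}

#' Compare bound and apo per-residue RMSF
#'
#' Pools frames over runs within each condition (after superposing all
#' frames of all runs onto one reference) and reports per-residue C-alpha
#' RMSF for both conditions and their difference `delta = apo - bound`
#' (positive where binding rigidifies).
#'
#' @param bound_runs,apo_runs Lists of ensembles; receptor topologies must
#'   match.
#' @param reference Reference coordinates (N x 3 of the bound topology);
#'   defaults to frame 1 of the first bound run.
#' @return Tibble (chain, res_seq, res_name, rmsf_bound, rmsf_apo, delta).
#' @export
rmsf_compare <- function(bound_runs, apo_runs, reference = NULL) {
  if (inherits(bound_runs, "ensemble")) bound_runs <- list(bound_runs)
  if (inherits(apo_runs, "ensemble")) apo_runs <- list(apo_runs)
  rb <- pooled_receptor_rmsf(bound_runs, reference)
  ra <- pooled_receptor_rmsf(apo_runs, reference)
  if (!identical(rb[c("chain", "res_seq")], ra[c("chain", "res_seq")])) {
    abort("bound and apo runs have mismatched receptor topologies")
  }
  tibble(chain = rb$chain, res_seq = rb$res_seq, res_name = rb$res_name,
         rmsf_bound = rb$rmsf, rmsf_apo = ra$rmsf,
         delta = ra$rmsf - rb$rmsf)
}

# concatenate receptor frames of all runs and compute one pooled RMSF
pooled_receptor_rmsf <- function(runs, reference = NULL) {
  ref_ens <- runs[[1]]
  rec_idx <- select_atoms(ref_ens,
                          chains = setdiff(unique(ref_ens$atoms$chain),
                                           ref_ens$ligand_chain))
  atoms <- ref_ens$atoms[rec_idx, ]
  total <- sum(vapply(runs, n_frames, integer(1)))
  coords <- array(NA_real_, c(total, length(rec_idx), 3))
  at <- 0L
  for (ens in runs) {
    sub <- ens$coords[, rec_idx, , drop = FALSE]
    coords[at + seq_len(n_frames(ens)), , ] <- sub
    at <- at + n_frames(ens)
  }
  pooled <- new_ensemble(atoms, coords, times = 0.1 * (seq_len(total) - 1),
                         ligand_chain = ref_ens$ligand_chain)
  ref <- if (is.null(reference)) NULL else reference[rec_idx, , drop = FALSE]
  rmsf_calpha(pooled, reference_frame = ref %||% 1)
}
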