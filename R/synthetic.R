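# Synthetic study systems: a C2-symmetric helical receptor dimer, a basic
# octapeptide ligand, seeded diffusion/dwell trajectories with planted
# binding sites, and one-site MST isotherms. These generators emulate the
# study conditions (15 independent runs, 25 nM labelled protein) so that
# every downstream estimator can be tested against exact bookkeeping.

#' Specification for the toy receptor dimer
#'
#' @param helices_per_chain Number of helices per chain (>= 1).
#' @param residues_per_helix Residues per helix (>= 4).
#' @param acidic_site_residues Integer vector of residue numbers to plant as
#'   glutamate (side-chain carboxylate acceptors). Planted on both chains so
#'   the dimer stays exactly homomeric.
#' @param acidic_res_name `"GLU"` or `"ASP"`.
#' @param seed Integer seed (construction is deterministic; kept for API
#'   symmetry with the other generators).
#' @return A validated spec list.
#' @export
toy_dimer_spec <- function(helices_per_chain = 2, residues_per_helix = 12,
                           acidic_site_residues = integer(0),
                           acidic_res_name = "GLU", seed = 1L) {
  stopifnot(helices_per_chain >= 1, residues_per_helix >= 4,
            acidic_res_name %in% c("GLU", "ASP"))
  nres <- helices_per_chain * residues_per_helix
  if (length(acidic_site_residues) &&
      !all(acidic_site_residues %in% seq_len(nres))) {
    abort("acidic_site_residues outside the chain's residue range")
  }
  list(helices_per_chain = as.integer(helices_per_chain),
       residues_per_helix = as.integer(residues_per_helix),
       acidic_site_residues = as.integer(acidic_site_residues),
       acidic_res_name = acidic_res_name, seed = as.integer(seed))
}

#' Build the toy receptor dimer
#'
#' Two chains ("A", "B") of ideal alpha helices (phi = -57, psi = -47; rise
#' ~1.5 A, ~100 deg/residue, C-alpha radius ~2.3 A) related by an exact C2
#' rotation about the z axis. Planted acidic residues carry side-chain
#' carboxylate oxygens; backbone amide hydrogens are present.
#'
#' @param spec A [toy_dimer_spec()].
#' @return A single-frame [new_ensemble()].
#' @export
build_toy_dimer <- function(spec = toy_dimer_spec()) {
  letter <- if (spec$acidic_res_name == "GLU") "E" else "D"
  nres <- spec$residues_per_helix
  seqs <- lapply(seq_len(spec$helices_per_chain), function(j) {
    res0 <- (j - 1L) * nres
    s <- rep("A", nres)
    plant <- spec$acidic_site_residues - res0
    s[plant[plant >= 1 & plant <= nres]] <- letter
    paste(s, collapse = "")
  })

  helix_y <- (seq_len(spec$helices_per_chain) -
                (spec$helices_per_chain + 1) / 2) * 10
  parts <- list(); serial0 <- 1L
  for (j in seq_along(seqs)) {
    h <- build_chain(seqs[[j]], chain_id = "A", phi = -57, psi = -47,
                     first_serial = serial0,
                     first_res = (j - 1L) * nres + 1L)
    # orient the helix axis along z and centre it
    ca <- h$xyz[h$atoms$name == "CA", , drop = FALSE]
    axis <- stats::prcomp(ca, center = TRUE)$rotation[, 1]
    rot <- rotation_between(axis, c(0, 0, 1))
    xyz <- sweep(h$xyz, 2, colMeans(ca)) %*% t(rot)
    xyz <- sweep(xyz, 2, c(5.5, helix_y[j], 0), `+`)
    h$xyz <- xyz
    parts[[j]] <- h
    serial0 <- serial0 + nrow(h$atoms)
  }
  atomsA <- dplyr::bind_rows(lapply(parts, `[[`, "atoms"))
  xyzA <- do.call(rbind, lapply(parts, `[[`, "xyz"))
  bondsA <- do.call(rbind, lapply(parts, `[[`, "bonds"))

  c2 <- rotation_about(c(0, 0, 1), 180)
  atomsB <- atomsA
  atomsB$chain <- "B"
  atomsB$serial <- atomsA$serial + nrow(atomsA)
  xyzB <- xyzA %*% t(c2)
  bondsB <- bondsA + nrow(atomsA)

  atoms <- dplyr::bind_rows(atomsA, atomsB)
  new_ensemble(atoms, rbind(xyzA, xyzB), bonds = rbind(bondsA, bondsB),
               ligand_chain = "P")
}

# rotation taking unit direction a to unit direction b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- pracma_cross(a, b); c_ <- sum(a * b)
  if (sum(v^2) < 1e-16) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 deg about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- pracma_cross(a, p)
    return(rotation_about(ax, 180))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Build the octapeptide ligand template
#'
#' An extended-conformation basic octapeptide (default LKRYKRRL, the
#' NLS-derived inhibitory sequence) with lysine/arginine side-chain donor
#' nitrogens and their hydrogens.
#'
#' @param sequence One-letter sequence.
#' @param chain_id Ligand chain id.
#' @return List with `atoms`, `xyz`, `bonds` (see [build_chain()]).
#' @export
build_peptide <- function(sequence = "LKRYKRRL", chain_id = "P") {
  build_chain(sequence, chain_id = chain_id, phi = -139, psi = 135)
}

# side-chain donor nitrogens of the ligand, in residue order
ligand_donor_idx <- function(atoms) {
  which(atoms$name %in% c("NZ", "NH1", "NH2", "NE") & !atoms$is_hydrogen)
}

#' Specification for the diffusion/dwell trajectory generator
#'
#' @param site_centers Named list of length-3 site centre vectors (A).
#' @param hbond_contact_residues Named list (same names) of data frames with
#'   columns `chain`, `res_seq`: the receptor residues the peptide
#'   hydrogen-bonds while dwelling at that site.
#' @param dwell_fractions Named numeric vector (same names): stationary
#'   fraction of frames dwelling at each site. The free fraction is
#'   `1 - sum(dwell_fractions)`.
#' @param n_runs Number of independent runs (study condition: 15).
#' @param frames_per_run Frames per run.
#' @param positional_noise_sd Gaussian positional noise on the dwell centre
#'   of mass, A.
#' @param frame_dt Frame spacing in ns (study condition: 0.1).
#' @param stay_prob Markov self-transition weight in [0, 1); higher values
#'   give longer dwells at the same stationary fractions.
#' @param seed Integer seed.
#' @return A validated spec list.
#' @export
diffusion_spec <- function(site_centers, hbond_contact_residues,
                           dwell_fractions, n_runs = 15L,
                           frames_per_run = 2000L,
                           positional_noise_sd = 0.5, frame_dt = 0.1,
                           stay_prob = 0.5, seed = 1L) {
  stopifnot(length(site_centers) == length(dwell_fractions),
            length(site_centers) == length(hbond_contact_residues))
  if (is.null(names(site_centers))) {
    names(site_centers) <- paste0("site", seq_along(site_centers))
  }
  names(dwell_fractions) <- names(site_centers)
  names(hbond_contact_residues) <- names(site_centers)
  if (any(dwell_fractions < 0) || sum(dwell_fractions) > 1 + 1e-9) {
    abort("dwell_fractions must be in [0,1] and sum to at most 1")
  }
  if (positional_noise_sd < 0) abort("positional_noise_sd must be >= 0")
  list(site_centers = site_centers,
       hbond_contact_residues = hbond_contact_residues,
       dwell_fractions = dwell_fractions, n_runs = as.integer(n_runs),
       frames_per_run = as.integer(frames_per_run),
       positional_noise_sd = positional_noise_sd, frame_dt = frame_dt,
       stay_prob = stay_prob, seed = as.integer(seed))
}

#' Derive site centres and contact residues from planted acidic residues
#'
#' For each site, the centre is placed outward from the first contact
#' residue's carboxylate oxygen at the distance that lets the rigid peptide
#' reach hydrogen-bond geometry with its first donor.
#'
#' @param receptor Single-frame receptor ensemble.
#' @param peptide Peptide template from [build_peptide()].
#' @param site_residues Named list of data frames (`chain`, `res_seq`).
#' @return List with `site_centers` and `hbond_contact_residues`, ready for
#'   [diffusion_spec()].
#' @export
plant_sites <- function(receptor, peptide, site_residues) {
  xyz <- frame_coords(receptor, 1)
  rcom <- center_of_mass(xyz, receptor)
  don <- ligand_donor_idx(peptide$atoms)
  pcom <- colSums(peptide$xyz * peptide$atoms$mass) / sum(peptide$atoms$mass)
  arm <- sqrt(sum((peptide$xyz[don[1], ] - pcom)^2))
  centers <- lapply(site_residues, function(df) {
    a <- acceptor_positions(receptor, xyz, df)[[1]]
    u <- (a - rcom); u <- u / sqrt(sum(u^2))
    a + (arm + 2.9) * u
  })
  list(site_centers = centers, hbond_contact_residues = site_residues)
}

# carboxylate-oxygen positions of contact residues, one per residue
acceptor_positions <- function(receptor, xyz, contacts) {
  lapply(seq_len(nrow(contacts)), function(i) {
    idx <- select_atoms(receptor, chains = contacts$chain[i],
                        res_seq = contacts$res_seq[i],
                        atom_names = c("OE1", "OE2", "OD1", "OD2", "O"))
    if (!length(idx)) {
      abort(sprintf("contact residue %s:%d has no acceptor oxygen",
                    contacts$chain[i], contacts$res_seq[i]))
    }
    xyz[idx[1], ]
  })
}

#' Simulate peptide diffusion/dwell runs around the receptor
#'
#' Per frame the peptide either dwells at a planted site (centre of mass at
#' the site centre plus Gaussian noise, designated donors in hydrogen-bond
#' geometry with the site's contact residues) or diffuses freely in a shell
#' 8-40 A from the receptor surface. The per-frame state follows a seeded
#' Markov chain whose stationary fractions equal `dwell_fractions`. The
#' receptor is held fixed; only the peptide moves.
#'
#' @param receptor Single-frame receptor ensemble.
#' @param peptide Peptide template ([build_peptide()]).
#' @param spec A [diffusion_spec()].
#' @return List with `runs` (list of ensembles, ligand chain appended) and
#'   `truth` (tibble run, frame, time_ns, state) recording the generator's
#'   true per-frame state.
#' @export
simulate_diffusion_runs <- function(receptor, peptide, spec) {
  set.seed(spec$seed)
  rxyz <- frame_coords(receptor, 1)
  rcom <- center_of_mass(rxyz, receptor)
  rext <- sqrt(max(rowSums(sweep(rxyz, 2, rcom)^2)))

  for (nm in names(spec$site_centers)) {
    c_k <- spec$site_centers[[nm]]
    if (min(sqrt(rowSums(sweep(rxyz, 2, c_k)^2))) < 2.0) {
      abort(sprintf("site centre %s lies inside the receptor van der Waals volume", nm))
    }
  }

  patoms <- peptide$atoms
  pmass <- patoms$mass
  pcom <- colSums(peptide$xyz * pmass) / sum(pmass)
  p0 <- sweep(peptide$xyz, 2, pcom)  # template centred on its COM
  pext <- sqrt(max(rowSums(p0^2)))
  bonded_h <- function(idx) {
    lapply(idx, function(d) {
      s <- patoms$serial[d]
      nb <- c(peptide$bonds[peptide$bonds[, 1] == s, 2],
              peptide$bonds[peptide$bonds[, 2] == s, 1])
      which(patoms$serial %in% nb & patoms$is_hydrogen)
    })
  }

  # per-site docking: acceptors, paired donor atoms, template orientation.
  # With >= 3 donor/acceptor pairs the orientation is the least-squares
  # (Kabsch) fit of the donors onto ideal hydrogen-bond positions;
  # otherwise the first donor arm is pointed at the first acceptor.
  sites <- names(spec$site_centers)
  dock <- lapply(sites, function(nm) {
    contacts <- spec$hbond_contact_residues[[nm]]
    acc <- acceptor_positions(receptor, rxyz, contacts)
    c_k <- spec$site_centers[[nm]]
    don <- site_donor_idx(patoms, contacts)
    npair <- min(length(acc), length(don))
    don <- don[seq_len(npair)]
    if (npair >= 3) {
      targets <- t(vapply(acc[seq_len(npair)], function(a) {
        u <- a - rcom; a + 2.9 * u / sqrt(sum(u^2))
      }, numeric(3)))
      tr <- kabsch_superpose(p0[don, , drop = FALSE], targets)
      rot <- tr$rotation
    } else {
      rot <- rotation_between(p0[don[1], ], acc[[1]] - c_k)
    }
    list(center = c_k, acc = acc[seq_len(npair)], rotated = p0 %*% t(rot),
         npair = npair, don = don, don_h = bonded_h(don))
  })
  names(dock) <- sites

  # combined topology
  latoms <- patoms
  latoms$serial <- latoms$serial + max(receptor$atoms$serial)
  lbonds <- peptide$bonds + max(receptor$atoms$serial)
  atoms <- dplyr::bind_rows(receptor$atoms, latoms)
  bonds <- rbind(receptor$bonds, lbonds)
  nrec <- nrow(receptor$atoms); npep <- nrow(latoms)

  pi_free <- 1 - sum(spec$dwell_fractions)
  probs <- c(spec$dwell_fractions, free = pi_free)
  states <- names(probs)

  runs <- vector("list", spec$n_runs)
  truth <- vector("list", spec$n_runs)
  tt <- spec$frames_per_run
  times <- spec$frame_dt * (seq_len(tt) - 1L)
  for (r in seq_len(spec$n_runs)) {
    st <- character(tt)
    st[1] <- sample(states, 1, prob = probs)
    for (t in seq_len(tt - 1L)) {
      st[t + 1] <- if (stats::runif(1) < spec$stay_prob) st[t] else
        sample(states, 1, prob = probs)
    }
    coords <- array(NA_real_, c(tt, nrec + npep, 3))
    for (t in seq_len(tt)) {
      coords[t, seq_len(nrec), ] <- rxyz
      coords[t, nrec + seq_len(npep), ] <-
        place_peptide(st[t], dock, spec, p0, pmass, rcom, rext, pext)
    }
    runs[[r]] <- new_ensemble(atoms, coords, bonds = bonds, times = times,
                              ligand_chain = latoms$chain[1], source_run = r)
    truth[[r]] <- tibble(run = r, frame = seq_len(tt), time_ns = times,
                         state = st)
  }
  list(runs = runs, truth = dplyr::bind_rows(truth))
}

# donor atoms paired with a site's contact residues: explicit columns
# donor_res_seq/donor_name when present, else side-chain N donors in order
site_donor_idx <- function(patoms, contacts) {
  if (all(c("donor_res_seq", "donor_name") %in% names(contacts))) {
    idx <- vapply(seq_len(nrow(contacts)), function(i) {
      w <- which(patoms$res_seq == contacts$donor_res_seq[i] &
                   patoms$name == contacts$donor_name[i])
      if (!length(w)) {
        abort(sprintf("designated donor %s of residue %d not in the peptide",
                      contacts$donor_name[i], contacts$donor_res_seq[i]))
      }
      w[1]
    }, integer(1))
    return(idx)
  }
  ligand_donor_idx(patoms)
}

# one peptide placement; returns npep x 3 coordinates.
# Free frames sit in a shell 8-40 A beyond the receptor extent, padded by
# the peptide's own radius so that no peptide atom comes within 8 A of the
# receptor (the generator's minimum-distance condition is molecule to
# molecule, not centre of mass).
place_peptide <- function(state, dock, spec, p0, pmass, rcom, rext, pext) {
  if (state == "free") {
    w <- stats::rnorm(3); w <- w / sqrt(sum(w^2))
    p <- rcom + w * (rext + pext + 8 + stats::runif(1, 0, 32))
    return(sweep(p0 %*% t(random_rotation()), 2, p, `+`))
  }
  d <- dock[[state]]
  eps <- stats::rnorm(3, 0, spec$positional_noise_sd)
  xyz <- sweep(d$rotated, 2, d$center + eps, `+`)
  # snap designated donors (and their hydrogens) to exact H-bond geometry
  for (j in seq_len(d$npair)) {
    a <- d$acc[[j]]
    u <- xyz[d$don[j], ] - a
    u <- u / sqrt(sum(u^2))
    delta <- (a + 2.9 * u) - xyz[d$don[j], ]
    grp <- c(d$don[j], d$don_h[[j]])
    xyz[grp, ] <- sweep(xyz[grp, , drop = FALSE], 2, delta, `+`)
    if (length(d$don_h[[j]])) xyz[d$don_h[[j]][1], ] <- a + 1.9 * u
  }
  # restore the exact centre of mass (noise 0 => COM == site centre)
  com_now <- colSums(xyz * pmass) / sum(pmass)
  sweep(xyz, 2, (d$center + eps) - com_now, `+`)
}

#' Derive a bridging site from designated donor/acceptor pairs
#'
#' Computes the site centre implied by least-squares docking of the
#' designated peptide donors onto ideal hydrogen-bond positions above the
#' contact residues' acceptors. With contacts on two structural elements
#' this yields a dwell pose whose constraints bridge them, which is what a
#' rigidity-perturbation analysis responds to.
#'
#' @param receptor Single-frame receptor ensemble.
#' @param peptide Peptide template.
#' @param contacts Data frame with columns `chain`, `res_seq`,
#'   `donor_res_seq`, `donor_name` (>= 3 rows).
#' @param site_name Name for the site.
#' @return List with `site_centers` and `hbond_contact_residues` for
#'   [diffusion_spec()].
#' @export
plant_bridge_site <- function(receptor, peptide, contacts,
                              site_name = "site") {
  stopifnot(nrow(contacts) >= 3)
  rxyz <- frame_coords(receptor, 1)
  rcom <- center_of_mass(rxyz, receptor)
  acc <- acceptor_positions(receptor, rxyz, contacts)
  pmass <- peptide$atoms$mass
  pcom <- colSums(peptide$xyz * pmass) / sum(pmass)
  p0 <- sweep(peptide$xyz, 2, pcom)
  don <- site_donor_idx(peptide$atoms, contacts)
  npair <- min(length(acc), length(don))
  targets <- t(vapply(acc[seq_len(npair)], function(a) {
    u <- a - rcom; a + 2.9 * u / sqrt(sum(u^2))
  }, numeric(3)))
  tr <- kabsch_superpose(p0[don[seq_len(npair)], , drop = FALSE], targets)
  out <- list(site_centers = list(tr$translation),
              hbond_contact_residues = list(contacts))
  names(out$site_centers) <- site_name
  names(out$hbond_contact_residues) <- site_name
  out
}

#' Design of a synthetic MST dilution-series isotherm
#'
#' @param kd_true True dissociation constant, nM.
#' @param protein_conc Labelled protein concentration, nM (study condition:
#'   25).
#' @param amplitude_true,offset_true Response amplitude and offset in
#'   Delta F_norm units.
#' @param dilution_points Number of 2-fold dilution points.
#' @param top_conc Highest ligand concentration, nM.
#' @param replicates Number of replicate series.
#' @param noise_sd Gaussian noise sd as a fraction of the amplitude.
#' @param seed Integer seed.
#' @export
isotherm_design <- function(kd_true = 100, protein_conc = 25,
                            amplitude_true = 1, offset_true = 0,
                            dilution_points = 16L, top_conc = 10000,
                            replicates = 3L, noise_sd = 0.05, seed = 1L) {
  stopifnot(kd_true > 0, protein_conc > 0, dilution_points >= 2,
            top_conc > 0, replicates >= 1, noise_sd >= 0)
  list(kd_true = kd_true, protein_conc = protein_conc,
       amplitude_true = amplitude_true, offset_true = offset_true,
       dilution_points = as.integer(dilution_points), top_conc = top_conc,
       replicates = as.integer(replicates), noise_sd = noise_sd,
       seed = as.integer(seed))
}

#' Generate a synthetic MST isotherm
#'
#' Concentrations form a 2-fold dilution series from `top_conc`;
#' `Delta F_norm = offset + amplitude * fb(c; K_d, P) + noise`, with the
#' bound fraction `fb` from the one-site ligand-depletion model
#' ([fraction_bound()]).
#'
#' @param design An [isotherm_design()].
#' @return Tibble (conc, delta_fnorm, replicate) with the design stored in
#'   `attr(, "design")` and the protein concentration in
#'   `attr(, "protein_conc")`.
#' @export
generate_isotherm <- function(design = isotherm_design()) {
  set.seed(design$seed)
  conc <- design$top_conc * 2^(-(seq_len(design$dilution_points) - 1L))
  out <- lapply(seq_len(design$replicates), function(rep) {
    fb <- fraction_bound(conc, design$kd_true, design$protein_conc)
    y <- design$offset_true + design$amplitude_true * fb +
      stats::rnorm(length(conc), 0, design$noise_sd * abs(design$amplitude_true))
    tibble(conc = conc, delta_fnorm = y, replicate = rep)
  })
  iso <- dplyr::bind_rows(out)
  attr(iso, "design") <- design
  attr(iso, "protein_conc") <- design$protein_conc
  iso
}
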