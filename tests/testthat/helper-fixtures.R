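# Shared fixtures, built in code. The heavier simulated objects are
# constructed lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# standard toy receptor: 2 helices per chain, 12 residues each, glutamates
# planted on both helices of each chain
toy_receptor <- function() {
  fixture("toy_receptor", function() {
    build_toy_dimer(toy_dimer_spec(helices_per_chain = 2,
                                   residues_per_helix = 12,
                                   acidic_site_residues = c(3, 16, 21)))
  })
}

toy_peptide <- function() fixture("toy_peptide", function() build_peptide())

# three planted sites on distinct helices, used by the mapping tests
three_site_sim <- function(n_runs = 3, frames_per_run = 400, seed = 42) {
  key <- sprintf("sim_%d_%d_%d", n_runs, frames_per_run, seed)
  fixture(key, function() {
    rec <- toy_receptor()
    pep <- toy_peptide()
    sites <- plant_sites(rec, pep, list(
      siteI = data.frame(chain = "A", res_seq = 3),
      siteII = data.frame(chain = "B", res_seq = 16),
      siteIII = data.frame(chain = "A", res_seq = 21)))
    spec <- diffusion_spec(
      sites$site_centers, sites$hbond_contact_residues,
      dwell_fractions = c(siteI = 0.2, siteII = 0.2, siteIII = 0.3),
      n_runs = n_runs, frames_per_run = frames_per_run, seed = seed)
    c(simulate_diffusion_runs(rec, pep, spec), list(sites = sites))
  })
}

# helical peptide bridging two helices of chain A: the configuration whose
# removal perturbs receptor rigidity
bridge_sim <- function() {
  fixture("bridge_sim", function() {
    rec <- toy_receptor()
    pep <- build_chain("LKRYKRRL", chain_id = "P", phi = -57, psi = -47)
    contacts <- data.frame(chain = "A", res_seq = c(4, 5, 16, 17),
                           donor_res_seq = c(2, 3, 6, 7), donor_name = "N")
    site <- plant_bridge_site(rec, pep, contacts, "bridge")
    spec <- diffusion_spec(site$site_centers, site$hbond_contact_residues,
                           dwell_fractions = c(bridge = 0.7), n_runs = 2,
                           frames_per_run = 60, positional_noise_sd = 0.3,
                           seed = 11)
    c(simulate_diffusion_runs(rec, pep, spec),
      list(receptor = rec, peptide = pep, contacts = contacts))
  })
}

# strided frames of the truth table (times divisible by stride)
truth_strided <- function(truth, stride_ns = 2) {
  truth[abs(truth$time_ns / stride_ns - round(truth$time_ns / stride_ns)) <
          1e-9, , drop = FALSE]
}

# minimal two-atom "residue pair" ensemble for contact-rule tests:
# a ligand donor group (N + H) and a receptor acceptor at distance d and
# D-H...A angle theta (degrees)
donor_acceptor_ensemble <- function(d, theta_deg) {
  th <- theta_deg * pi / 180
  # H at origin, donor N at (1,0,0); acceptor placed so the angle at H is th
  hpos <- c(0, 0, 0)
  npos <- c(1.0, 0, 0)
  adir <- c(cos(th), sin(th), 0)
  # acceptor at donor-acceptor distance d from N (solve along the H-ray)
  f <- function(t) sqrt(sum((t * adir - npos)^2)) - d
  tt <- stats::uniroot(f, c(0.01, d + 2))$root
  apos <- tt * adir
  atoms <- atom_table(
    serial = 1:3, name = c("N", "H", "OE1"), chain = c("P", "P", "A"),
    res_name = c("ALA", "ALA", "GLU"), res_seq = c(1L, 1L, 5L),
    element = c("N", "H", "O"))
  xyz <- rbind(npos, hpos, apos)
  new_ensemble(atoms, xyz, bonds = cbind(1L, 2L), ligand_chain = "P")
}

# hand-built three-block network for the dilution/perturbation arithmetic:
# a 5-atom rigid block G (receptor chain A, residues 1-5), a 3-atom rigid
# block H (residues 6-8), a 2-atom ligand L. G-L strong interface bonds
# (e_gl), H-L weaker bonds (e_hl); blocks are internally rigid via 6-bar
# covalent links.
block_network <- function(e_gl = -6, e_hl = -3,
                          params = network_params()) {
  nG <- 5; nH <- 3; nL <- 2
  n <- nG + nH + nL
  atoms <- atom_table(
    serial = seq_len(n), name = c(rep("CA", nG + nH), "C1", "C2"),
    chain = c(rep("A", nG + nH), rep("P", nL)),
    res_name = c(rep("ALA", nG + nH), "LIG", "LIG"),
    res_seq = c(1:(nG + nH), 9L, 9L),
    element = c(rep("C", nG + nH), "C", "C"))
  rigid_chain <- function(idx) cbind(idx[-length(idx)], idx[-1])
  cons <- tibble::tibble(
    i = c(rigid_chain(1:nG)[, 1], rigid_chain(6:8)[, 1], 9L,
          1L, 2L, 6L, 7L),
    j = c(rigid_chain(1:nG)[, 2], rigid_chain(6:8)[, 2], 10L,
          9L, 10L, 9L, 10L),
    type = c(rep("double_or_peptide", (nG - 1) + (nH - 1) + 1),
             rep("hbond", 4)),
    e_hb = c(rep(NA_real_, (nG - 1) + (nH - 1) + 1),
             e_gl, e_gl, e_hl, e_hl),
    ligand = c(rep(FALSE, (nG - 1) + (nH - 1)), TRUE, TRUE, TRUE, TRUE,
               TRUE))
  cons$bars <- as.integer(params$bars[cons$type])
  structure(list(atoms = atoms, bodies = atoms$serial, constraints = cons,
                 ligand_chain = "P", frame_provenance = c(run = 1, frame = 1),
                 params = params),
            class = "constraint_network")
}
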