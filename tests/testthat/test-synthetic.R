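test_that("the toy dimer is exactly C2 symmetric with ideal helix geometry", {
  rec <- toy_receptor()
  xyz <- frame_coords(rec, 1)
  a <- select_atoms(rec, chains = "A")
  b <- select_atoms(rec, chains = "B")
  c2 <- rotation_about(c(0, 0, 1), 180)
  expect_lt(coord_rmsd(xyz[a, ] %*% t(c2), xyz[b, ]), 1e-8)
  # consecutive C-alpha distances 3.8 +/- 0.1 A within each helix
  for (ch in c("A", "B")) {
    for (helix in 0:1) {
      ca <- select_atoms(rec, chains = ch, atom_names = "CA",
                         res_seq = helix * 12 + 1:12)
      d <- sqrt(rowSums(diff(xyz[ca, ])^2))
      expect_true(all(abs(d - 3.8) < 0.1))
    }
  }
})

test_that("planted acidic residues carry carboxylate oxygens on both chains", {
  rec <- toy_receptor()
  for (ch in c("A", "B")) {
    for (rs in c(3, 16, 21)) {
      at <- rec$atoms[rec$atoms$chain == ch & rec$atoms$res_seq == rs, ]
      expect_equal(unique(at$res_name), "GLU")
      expect_true(all(c("OE1", "OE2") %in% at$name))
    }
  }
  # backbone amide hydrogens exist
  expect_gt(sum(rec$atoms$name == "H"), 40)
})

test_that("diffusion runs are deterministic in the seed", {
  rec <- toy_receptor(); pep <- toy_peptide()
  sites <- plant_sites(rec, pep,
                       list(siteI = data.frame(chain = "A", res_seq = 3)))
  spec <- diffusion_spec(sites$site_centers, sites$hbond_contact_residues,
                         dwell_fractions = c(siteI = 0.5), n_runs = 2,
                         frames_per_run = 30, seed = 99)
  s1 <- simulate_diffusion_runs(rec, pep, spec)
  s2 <- simulate_diffusion_runs(rec, pep, spec)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$runs[[2]]$coords, s2$runs[[2]]$coords)
})

test_that("pure dwell with zero noise pins the centre of mass to the site", {
  rec <- toy_receptor(); pep <- toy_peptide()
  sites <- plant_sites(rec, pep,
                       list(siteIII = data.frame(chain = "A", res_seq = 21)))
  spec <- diffusion_spec(sites$site_centers, sites$hbond_contact_residues,
                         dwell_fractions = c(siteIII = 1.0), n_runs = 1,
                         frames_per_run = 10, positional_noise_sd = 0,
                         seed = 5)
  sim <- simulate_diffusion_runs(rec, pep, spec)
  ens <- sim$runs[[1]]
  lig <- select_atoms(ens, chains = "P")
  for (t in seq_len(n_frames(ens))) {
    com <- center_of_mass(frame_coords(ens, t), ens, lig)
    expect_equal(com, sites$site_centers$siteIII, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_true(all(sim$truth$state == "siteIII"))
})

test_that("empirical dwell fractions match the Markov stationary law", {
  rec <- toy_receptor(); pep <- toy_peptide()
  sites <- plant_sites(rec, pep,
                       list(siteIII = data.frame(chain = "A", res_seq = 21)))
  spec <- diffusion_spec(sites$site_centers, sites$hbond_contact_residues,
                         dwell_fractions = c(siteIII = 0.6), n_runs = 1,
                         frames_per_run = 10000, seed = 31)
  sim <- simulate_diffusion_runs(rec, pep, spec)
  frac <- mean(sim$truth$state == "siteIII")
  expect_lt(abs(frac - 0.6), 0.02)
})

test_that("free frames respect the 8 A minimum receptor distance", {
  rec <- toy_receptor(); pep <- toy_peptide()
  sites <- plant_sites(rec, pep,
                       list(siteI = data.frame(chain = "A", res_seq = 3)))
  spec <- diffusion_spec(sites$site_centers, sites$hbond_contact_residues,
                         dwell_fractions = c(siteI = 0.3), n_runs = 1,
                         frames_per_run = 200, seed = 13)
  sim <- simulate_diffusion_runs(rec, pep, spec)
  ens <- sim$runs[[1]]
  rxyz <- frame_coords(toy_receptor(), 1)
  lig <- select_atoms(ens, chains = "P")
  free_frames <- which(sim$truth$state == "free")
  dmin <- vapply(free_frames, function(t) {
    com <- center_of_mass(frame_coords(ens, t), ens, lig)
    min(sqrt(rowSums(sweep(rxyz, 2, com)^2)))
  }, numeric(1))
  expect_true(all(dmin >= 8))
})

test_that("site centres inside the receptor are refused", {
  rec <- toy_receptor(); pep <- toy_peptide()
  inside <- frame_coords(rec, 1)[select_atoms(rec, atom_names = "CA")[1], ]
  spec <- diffusion_spec(list(bad = inside),
                         list(bad = data.frame(chain = "A", res_seq = 3)),
                         dwell_fractions = c(bad = 0.5), n_runs = 1,
                         frames_per_run = 5, seed = 1)
  expect_error(simulate_diffusion_runs(rec, pep, spec),
               "van der Waals")
})

test_that("noiseless isotherms lie exactly on the depletion curve", {
  d <- isotherm_design(kd_true = 104, noise_sd = 0, seed = 2)
  iso <- generate_isotherm(d)
  fb <- fraction_bound(iso$conc, 104, 25)
  expect_equal(iso$delta_fnorm, d$offset_true + d$amplitude_true * fb,
               tolerance = 1e-12)
  # a zero concentration responds with the offset exactly
  expect_equal(d$offset_true + d$amplitude_true * fraction_bound(0, 104, 25),
               d$offset_true)
})

test_that("isotherm noise has the designed magnitude", {
  d <- isotherm_design(kd_true = 100, noise_sd = 0.05, amplitude_true = 2,
                       dilution_points = 5, replicates = 200, seed = 17)
  iso <- generate_isotherm(d)
  fb <- fraction_bound(iso$conc, 100, 25)
  resid <- iso$delta_fnorm - (d$offset_true + d$amplitude_true * fb)
  expect_lt(abs(sd(resid) / (0.05 * 2) - 1), 0.1)
  # determinism
  expect_identical(generate_isotherm(d), generate_isotherm(d))
})
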