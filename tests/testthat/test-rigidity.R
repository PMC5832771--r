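test_that("the hydrogen-bond potential has its textbook closed forms", {
  # optimum: d = d0, linear geometry -> -V0
  d <- c(0, 0, 0); h <- c(1, 0, 0); a <- c(2.8, 0, 0)
  expect_equal(hbond_energy(d, h, a), -8, tolerance = 1e-12)
  # 90-degree geometry -> zero
  a90 <- c(1, sqrt(2.8^2 - 1), 0)
  expect_equal(hbond_energy(d, h, a90), 0, tolerance = 1e-10)
  # sub-90 geometries are excluded
  expect_equal(hbond_energy(d, h, c(0.5, 0.3, 0)), Inf)
  # independent evaluation at d = 3.2 A, theta = 160 degrees: place the
  # acceptor on a ray from H making 160 deg with the H->D direction
  th <- 160 * pi / 180
  ray <- c(-cos(th), sin(th), 0)      # angle at H relative to H->D = (-1,0,0)
  f <- function(s) sqrt(sum((h + s * ray - d)^2)) - 3.2
  apos <- h + uniroot(f, c(0.1, 6), tol = 1e-12)$root * ray
  expected <- 8 * (5 * (2.8 / 3.2)^12 - 6 * (2.8 / 3.2)^10) * cos(th)^2
  expect_equal(hbond_energy(d, h, apos), expected, tolerance = 1e-10)
  expect_error(hbond_energy(d, h, d), "coincident")
})

test_that("hydrophobic tethers follow the vdW + slack rule", {
  mk <- function(dist, elements = c("C", "C")) {
    atoms <- atom_table(1:2, c("CB", "CB"), c("A", "A"), c("ALA", "ALA"),
                       c(1L, 5L), element = elements)
    new_ensemble(atoms, rbind(c(0, 0, 0), c(dist, 0, 0)),
                 ligand_chain = "P")
  }
  # two carbons at 3.55 A: 1.7 + 1.7 + 0.25 = 3.65 >= 3.55 -> tether
  nw <- build_network(mk(3.55))
  expect_equal(sum(nw$constraints$type == "hydrophobic"), 1)
  expect_equal(nw$constraints$bars[nw$constraints$type == "hydrophobic"], 2L)
  # C and S at 3.80 A: 1.7 + 1.8 + 0.25 = 3.75 < 3.80 -> no tether
  nw2 <- build_network(mk(3.80, c("C", "S")))
  expect_equal(sum(nw2$constraints$type == "hydrophobic"), 0)
})

test_that("excluding the ligand leaves no constraint touching it", {
  sim <- bridge_sim()
  bnd <- extract_bound_frames(sim$runs, sim$contacts[, c("chain", "res_seq")],
                              stride_ns = 2)
  nw <- build_network(bnd, frame = 1, include_ligand = FALSE)
  lig_serials <- nw$atoms$serial[nw$atoms$chain == "P"]
  expect_false(any(nw$constraints$i %in% lig_serials |
                     nw$constraints$j %in% lig_serials))
  nw_full <- build_network(bnd, frame = 1, include_ligand = TRUE)
  expect_gt(sum(nw_full$constraints$ligand), 0)
})

test_that("two bodies follow exact bar-counting arithmetic", {
  g6 <- peptisite:::pebble_game_cpp(2, rep(1L, 6), rep(2L, 6))
  expect_equal(g6$dof, 6)
  expect_equal(length(unique(g6$labels)), 1)
  g5 <- peptisite:::pebble_game_cpp(2, rep(1L, 5), rep(2L, 5))
  expect_equal(g5$dof, 7)
  expect_equal(length(unique(g5$labels)), 2)
})

test_that("the pebble game equals the rigidity-matrix rank oracle", {
  set.seed(101)
  for (trial in 1:40) {
    net <- random_bar_network()
    g <- peptisite:::pebble_game_cpp(net$n, net$eu, net$ev)
    o <- rigidity_rank_oracle(net$n, net$eu, net$ev)
    expect_equal(g$dof, o$dof)
    expect_equal(canon_labels(g$labels), canon_labels(o$labels))
  }
})

test_that("the decomposition is independent of bar insertion order", {
  set.seed(55)
  net <- random_bar_network()
  ref <- peptisite:::pebble_game_cpp(net$n, net$eu, net$ev)
  for (k in 1:5) {
    p <- sample(length(net$eu))
    g <- peptisite:::pebble_game_cpp(net$n, net$eu[p], net$ev[p])
    expect_equal(g$dof, ref$dof)
    expect_equal(canon_labels(g$labels), canon_labels(ref$labels))
  }
})

test_that("connected networks keep at least 6 degrees of freedom", {
  set.seed(66)
  for (k in 1:10) {
    n <- sample(2:6, 1)
    # spanning chain with heavy multiplicities: connected, maybe rigid
    eu <- rep(1:(n - 1), each = 6)
    ev <- rep(2:n, each = 6)
    g <- peptisite:::pebble_game_cpp(n, eu, ev)
    expect_gte(g$dof, 6)
    # adding a bar never increases the DOF
    extra <- sample(n, 2)
    g2 <- peptisite:::pebble_game_cpp(n, c(eu, extra[1]), c(ev, extra[2]))
    expect_lte(g2$dof, g$dof)
  }
})

test_that("dilution integrates giant-cluster persistence over the ladder", {
  params <- network_params()
  nw <- block_network(e_gl = -6, e_hl = -3, params = params)
  g <- dilution_stability(nw, params)
  ladder <- peptisite:::dilution_ladder(params)
  # block G persists the whole ladder: g = 8.0
  expect_equal(g$g[g$res_seq %in% 1:5], rep(8, 5), tolerance = 1e-12)
  # block H is giant only while its -3 kcal/mol bonds are retained
  mass_h <- 0.1 * sum(ladder >= -3)
  expect_equal(g$g[g$res_seq %in% 6:8], rep(mass_h, 3), tolerance = 1e-12)
})

test_that("an isolated residue accrues no stability", {
  params <- network_params()
  nw <- block_network(params = params)
  # detach residue 8 from block H
  keep <- !(nw$constraints$i == 8 | nw$constraints$j == 8)
  nw$constraints <- nw$constraints[keep, , drop = FALSE]
  g <- dilution_stability(nw, params)
  expect_equal(g$g[g$res_seq == 8], 0)
})

test_that("stability is monotone when the ladder is truncated", {
  sim <- bridge_sim()
  bnd <- extract_bound_frames(sim$runs, sim$contacts[, c("chain", "res_seq")],
                              stride_ns = 2)
  nw <- build_network(bnd, frame = 1)
  full <- dilution_stability(nw, network_params(dilution_stop = -8))
  short <- dilution_stability(nw, network_params(dilution_stop = -4))
  expect_true(all(short$g <= full$g + 1e-12))
})

test_that("ligand removal tallies constraints and spares the receptor", {
  params <- network_params()
  nw <- block_network(params = params)
  pert <- perturb_remove_ligand(nw)
  tally <- attr(pert, "removal_tally")
  expect_equal(tally$removed[tally$class == "hbond"], 4)
  expect_equal(tally$percent[tally$class == "hbond"], 100)
  expect_equal(tally$removed[tally$class == "hydrophobic"], 0)
  # receptor-internal constraints identical before and after
  rec_before <- nw$constraints[!nw$constraints$ligand, ]
  expect_equal(pert$constraints, rec_before)
  expect_false(any(pert$atoms$chain == "P"))
  # a ligand-free network is a no-op with a warning
  expect_warning(same <- perturb_remove_ligand(pert), "no ligand")
  expect_equal(same$constraints, pert$constraints)
})

test_that("a ligand without interface constraints leaves delta G identically zero", {
  rec <- toy_receptor(); pep <- toy_peptide()
  # park the peptide far away and build ground networks
  latoms <- pep$atoms
  latoms$serial <- latoms$serial + max(rec$atoms$serial)
  atoms <- dplyr::bind_rows(rec$atoms, latoms)
  bonds <- rbind(rec$bonds, pep$bonds + max(rec$atoms$serial))
  rxyz <- frame_coords(rec, 1)
  co <- array(NA_real_, c(2, nrow(atoms), 3))
  for (k in 1:2) co[k, , ] <- rbind(rxyz, pep$xyz + 300 + k)
  ens <- new_ensemble(atoms, co, bonds = bonds, ligand_chain = "P")
  nets <- lapply(1:2, function(i) build_network(ens, frame = i))
  prof <- delta_g_profile(nets)
  expect_true(all(prof$delta_g == 0))
  # every ligand-flagged constraint is internal to the parked peptide;
  # nothing crosses the interface
  lig_serials <- latoms$serial
  for (nw in nets) {
    cl <- nw$constraints[nw$constraints$ligand, ]
    expect_true(all(cl$i %in% lig_serials & cl$j %in% lig_serials))
  }
})

test_that("a planted bridging ligand stabilizes the anchored helices", {
  sim <- bridge_sim()
  bnd <- extract_bound_frames(sim$runs, sim$contacts[, c("chain", "res_seq")],
                              stride_ns = 2)
  nets <- lapply(seq_len(min(4, n_frames(bnd))),
                 function(i) build_network(bnd, frame = i))
  prof <- delta_g_profile(nets)
  expect_true(all(prof$delta_g >= -1e-9))
  top <- prof[which.max(prof$delta_g), ]
  # the anchored helices of chain A span residues 1-24
  expect_equal(top$chain, "A")
  expect_gt(max(prof$delta_g), 0.1)
  # flagged residues include anchors or their helix neighbours
  flagged <- prof[prof$flagged, ]
  expect_gt(nrow(flagged), 0)
  expect_true(any(flagged$chain == "A" &
                    flagged$res_seq %in% c(4, 5, 16, 17)))
})
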