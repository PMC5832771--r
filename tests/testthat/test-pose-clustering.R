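# small bound-pose ensemble generator: k planted pose clusters of the
# ligand in a fixed receptor frame
planted_pose_ensemble <- function(n_per_cluster, centers, spread = 1,
                                  seed = 1) {
  set.seed(seed)
  rec <- toy_receptor()
  pep <- toy_peptide()
  latoms <- pep$atoms
  latoms$serial <- latoms$serial + max(rec$atoms$serial)
  atoms <- dplyr::bind_rows(rec$atoms, latoms)
  bonds <- rbind(rec$bonds, pep$bonds + max(rec$atoms$serial))
  rxyz <- frame_coords(rec, 1)
  p0 <- sweep(pep$xyz, 2, colMeans(pep$xyz))
  total <- sum(n_per_cluster)
  co <- array(NA_real_, c(total, nrow(atoms), 3))
  lab <- integer(total)
  t <- 0
  for (k in seq_along(centers)) {
    for (j in seq_len(n_per_cluster[k])) {
      t <- t + 1
      shift <- centers[[k]] + rnorm(3, sd = spread / sqrt(3))
      co[t, , ] <- rbind(rxyz, sweep(p0, 2, shift, `+`))
      lab[t] <- k
    }
  }
  list(ensemble = new_ensemble(atoms, co, bonds = bonds,
                               ligand_chain = "P"),
       labels = lab)
}

test_that("pairwise ligand RMSD has exact closed forms", {
  pp <- planted_pose_ensemble(c(3), list(c(40, 0, 0)), spread = 0)
  d <- pairwise_ligand_rmsd(pp$ensemble)
  expect_true(all(abs(d) < 1e-10))
  # rigid translation by exactly d
  pp2 <- planted_pose_ensemble(c(1, 1), list(c(40, 0, 0), c(47, 0, 0)),
                               spread = 0)
  d2 <- pairwise_ligand_rmsd(pp2$ensemble)
  expect_equal(d2[1, 2], 7, tolerance = 1e-10)
})

test_that("pairwise RMSD matches the brute-force per-atom sum", {
  pp <- planted_pose_ensemble(c(3, 3), list(c(40, 0, 0), c(10, 30, 0)),
                              spread = 2, seed = 8)
  ens <- pp$ensemble
  d <- pairwise_ligand_rmsd(ens)
  lig <- select_atoms(ens, chains = "P")
  for (s in 1:5) {
    for (t in (s + 1):6) {
      brute <- sqrt(mean(rowSums((ens$coords[s, lig, ] -
                                    ens$coords[t, lig, ])^2)))
      expect_equal(d[s, t], brute, tolerance = 1e-10)
    }
  }
  expect_equal(d, t(d), tolerance = 1e-12)
})

test_that("unsuperposed receptors trigger a warning", {
  pp <- planted_pose_ensemble(c(2), list(c(40, 0, 0)), spread = 0)
  ens <- pp$ensemble
  rec_idx <- select_atoms(ens, chains = c("A", "B"))
  ens$coords[2, rec_idx, 1] <- ens$coords[2, rec_idx, 1] + 3
  expect_warning(pairwise_ligand_rmsd(ens), "superposed")
})

test_that("Ward merge heights equal the naive sum-of-squares oracle", {
  set.seed(20)
  for (rep in 1:6) {
    n <- sample(5:20, 1)
    x <- matrix(rnorm(n * 3, sd = 4), n)
    tr <- ward_linkage(as.matrix(dist(x)))
    expect_equal(tr$merges$delta, naive_ward_deltas(x), tolerance = 1e-8)
    # ultrametric ordering
    expect_true(all(diff(tr$merges$delta) > -1e-10))
  }
})

test_that("singleton merges follow the closed form |a-b|/sqrt(2)", {
  d <- matrix(c(0, 11, 11, 0), 2)
  tr <- ward_linkage(d)
  expect_equal(tr$merges$delta, 11 / sqrt(2), tolerance = 1e-10)
  # identical poses: all heights zero
  dz <- matrix(0, 4, 4)
  expect_true(all(ward_linkage(dz)$merges$delta < 1e-12))
  expect_error(ward_linkage(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("Ward heights are invariant under leaf permutation", {
  set.seed(33)
  x <- matrix(rnorm(12 * 3), 12)
  d <- as.matrix(dist(x))
  h1 <- sort(ward_linkage(d)$merges$delta)
  p <- sample(12)
  h2 <- sort(ward_linkage(d[p, p])$merges$delta)
  expect_equal(h1, h2, tolerance = 1e-10)
})

test_that("cut_tree spans the threshold extremes and recovers planted clusters", {
  pp <- planted_pose_ensemble(c(12, 8), list(c(40, 0, 0), c(0, 45, 10)),
                              spread = 1, seed = 5)
  d <- pairwise_ligand_rmsd(pp$ensemble)
  tr <- ward_linkage(d)
  expect_equal(cut_tree(tr, threshold = max(tr$merges$delta) + 1)$n_clusters,
               1)
  tiny <- cut_tree(tr, threshold = min(tr$merges$delta[tr$merges$delta > 0])
                   * 0.5)
  expect_equal(tiny$n_clusters, 20)
  two <- cut_tree(tr, threshold = 10)
  expect_equal(two$n_clusters, 2)
  # cluster 1 is the larger planted cluster; memberships match the truth
  expect_equal(two$sizes, c(12, 8))
  expect_true(all(two$labels[pp$labels == 1] == two$labels[1]))
  expect_true(all(two$labels[pp$labels == 2] == two$labels[13]))
  # centroid is a medoid: member minimizing summed squared distance
  m1 <- which(two$labels == 1)
  expect_equal(two$centroid_leaf[1],
               m1[which.min(rowSums(d[m1, m1]^2))])
  # threshold and n_clusters cuts agree where both exist
  byk <- cut_tree(tr, n_clusters = 2)
  expect_equal(byk$labels, two$labels)
})

test_that("merge_clusters keeps the requested frames in order", {
  pp <- planted_pose_ensemble(c(12, 8), list(c(40, 0, 0), c(0, 45, 10)),
                              spread = 1, seed = 5)
  d <- pairwise_ligand_rmsd(pp$ensemble)
  two <- cut_tree(ward_linkage(d), threshold = 10)
  all_kept <- merge_clusters(pp$ensemble, two, 1:2)
  expect_equal(n_frames(all_kept), 20)
  expect_equal(all_kept$coords, pp$ensemble$coords)
  big <- merge_clusters(pp$ensemble, two, 1)
  expect_equal(n_frames(big), 12)
  expect_error(merge_clusters(pp$ensemble, two, 7), "unknown cluster")
  expect_error(merge_clusters(pp$ensemble, two, integer(0)), "empty")
})
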