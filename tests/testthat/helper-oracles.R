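# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package code.

# Horn's quaternion-based superposition: returns the minimal RMSD of mobile
# onto reference (no shared code with the SVD/Kabsch path).
quaternion_rmsd <- function(mobile, reference) {
  mc <- colMeans(mobile); rc <- colMeans(reference)
  m <- sweep(mobile, 2, mc); r <- sweep(reference, 2, rc)
  s <- t(m) %*% r
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE)$values)
  msd <- (sum(m^2) + sum(r^2) - 2 * lam) / nrow(m)
  sqrt(max(msd, 0))
}

# Naive greedy Ward on raw coordinates: recomputes within-cluster sums of
# squares from scratch at every step; returns merge deltas in order.
naive_ward_deltas <- function(points) {
  cl <- lapply(seq_len(nrow(points)), identity)
  ess <- function(idx) {
    m <- colMeans(points[idx, , drop = FALSE])
    sum(sweep(points[idx, , drop = FALSE], 2, m)^2)
  }
  deltas <- numeric(0)
  while (length(cl) > 1) {
    best <- c(Inf, 0, 0)
    for (i in 1:(length(cl) - 1)) {
      for (j in (i + 1):length(cl)) {
        d <- ess(c(cl[[i]], cl[[j]])) - ess(cl[[i]]) - ess(cl[[j]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    deltas <- c(deltas, sqrt(best[1]))
    cl[[best[2]]] <- c(cl[[best[2]]], cl[[best[3]]])
    cl[[best[3]]] <- NULL
  }
  deltas
}

# Generic body-bar rigidity-matrix rank oracle: DOF = 6n - rank, and bodies
# u, v are mutually rigid iff 6 extra generic bars between them leave the
# rank unchanged.
rigidity_rank_oracle <- function(n, eu, ev) {
  pos <- matrix(stats::rnorm(n * 3, sd = 5), n, 3)
  crossp <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  }
  rowz <- function(u, v) {
    pu <- pos[u, ] + stats::rnorm(3)
    pv <- pos[v, ] + stats::rnorm(3)
    e <- pu - pv
    r <- numeric(6 * n)
    r[(u - 1) * 6 + 1:3] <- e
    r[(u - 1) * 6 + 4:6] <- crossp(pu, e)
    r[(v - 1) * 6 + 1:3] <- r[(v - 1) * 6 + 1:3] - e
    r[(v - 1) * 6 + 4:6] <- r[(v - 1) * 6 + 4:6] - crossp(pv, e)
    r
  }
  m <- t(vapply(seq_along(eu), function(k) rowz(eu[k], ev[k]),
                numeric(6 * n)))
  rk <- qr(m, tol = 1e-9)$rank
  lab <- seq_len(n)
  if (n > 1) {
    for (u in 1:(n - 1)) {
      for (v in (u + 1):n) {
        extra <- t(vapply(1:6, function(k) rowz(u, v), numeric(6 * n)))
        if (qr(rbind(m, extra), tol = 1e-9)$rank == rk) {
          lab[lab == lab[v]] <- lab[u]
        }
      }
    }
  }
  list(dof = 6 * n - rk, labels = lab)
}

# canonical form of a partition labelling (first-appearance order)
canon_labels <- function(l) match(l, unique(l))

# random body-bar instance used by the pebble-game equivalence tests
random_bar_network <- function(max_bodies = 8) {
  n <- sample(2:max_bodies, 1)
  ne <- sample(1:14, 1)
  eu <- integer(0); ev <- integer(0)
  for (k in seq_len(ne)) {
    p <- sample(n, 2)
    m <- sample(1:6, 1)
    eu <- c(eu, rep(p[1], m))
    ev <- c(ev, rep(p[2], m))
  }
  list(n = n, eu = eu, ev = ev)
}
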