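# Shared fixtures and independent oracles for the test suite.
# The droplet study is expensive, so it is run once per session and memoised.

.fixtures <- new.env(parent = emptyenv())

# standard desk-scale droplet study (the package's documented protocol)
droplet_fixture <- function() {
  if (is.null(.fixtures$droplet))
    .fixtures$droplet <- suppressWarnings(droplet_study(seed = 101L))
  .fixtures$droplet
}

# random non-overlapping multi-chain configuration for force/pair tests;
# keeps all pair distances away from the potential's cutoff and minimum
# kinks so central finite differences of the energy are clean
random_config <- function(n_chains, chain_length, box, params,
                          min_sep = 0.75, kink_gap = 2e-3) {
  topo <- build_linear_topology(n_chains, chain_length)
  n <- topo$n_beads
  kinks <- c(params$pair_cutoff, params$coulomb_cutoff,
             2^(1 / 6) * max(params$sigma))
  min_image_dist <- function(pos) {
    d2 <- 0
    for (k in 1:3) {
      dx <- outer(pos[, k], pos[, k], "-")
      dx <- dx - box * round(dx / box)
      d2 <- d2 + dx^2
    }
    sqrt(d2)
  }
  repeat {
    pos <- matrix(stats::runif(3 * n, 0, box), n, 3)
    # rebuild chains as short random walks so bonds are near r0
    for (ch in seq_len(n_chains)) {
      rows <- (ch - 1) * chain_length + seq_len(chain_length)
      for (k in rows[-1]) {
        u <- stats::rnorm(3)
        pos[k, ] <- pos[k - 1, ] + params$bond_r0 * u / sqrt(sum(u^2))
      }
    }
    d <- min_image_dist(pos)
    diag(d) <- Inf
    bonded <- abs(row(d) - col(d)) == 1 &
      matrix(topo$chain_id[row(d)] == topo$chain_id[col(d)], n, n)
    if (min(d[!bonded]) < min_sep * max(params$sigma)) next
    if (min(abs(outer(c(d[is.finite(d)]), kinks, "-"))) < kink_gap) next
    return(list(frame = md_frame(pos, box), topology = topo))
  }
}

# brute-force chain connectivity oracle (O(n^2), plain R)
cluster_oracle <- function(frame, topology, cutoff) {
  pos <- frame$positions
  box <- frame$box
  n <- nrow(pos)
  adj <- matrix(FALSE, topology$n_chains, topology$n_chains)
  for (i in seq_len(n - 1)) {
    di <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    di <- di - sweep(round(sweep(di, 2, box, "/")), 2, box, "*")
    hit <- which(sqrt(rowSums(di^2)) < cutoff) + i
    for (j in hit) {
      ci <- topology$chain_id[i]; cj <- topology$chain_id[j]
      adj[ci, cj] <- adj[cj, ci] <- TRUE
    }
  }
  # BFS components
  comp <- rep(NA_integer_, topology$n_chains)
  cid <- 0L
  for (s in seq_len(topology$n_chains)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1)
    best <- best[which.min(vapply(best, function(b) min(which(comp == b)), 1L))]
  sort(which(comp == best))
}

# brute-force chord-placement oracle for the minimal folded segment angle:
# one chord end fixed at radius R, the other anywhere at distance re from it
# inside the ball of radius R; the folded angle is measured at the fixed end.
theta_min_oracle <- function(R, re, n_grid = 40000) {
  a <- seq(0, pi, length.out = n_grid)        # angle between u and v
  # |E2|^2 = R^2 + re^2 - 2 R re cos(a) must stay <= R^2
  feasible <- R^2 + re^2 - 2 * R * re * cos(a) <= R^2 * (1 + 1e-12)
  min(pmax(a, pi - a)[feasible])
}

# profile-likelihood grid-search oracle for the tanh interface fit:
# exhaustive grid over (d_mid, delta) with the closed-form linear solve for
# the two concentration parameters at each grid point
grid_fit_oracle <- function(profile, n_mid = 400, n_delta = 160) {
  e <- profile$bin_edges
  d <- (e[-1] + e[-length(e)]) / 2
  y <- profile$concentration
  dm_grid <- seq(min(d), max(d), length.out = n_mid)
  de_grid <- seq(diff(d[1:2]) / 2, (max(d) - min(d)) / 3,
                 length.out = n_delta)
  best <- list(ssr = Inf)
  for (de in de_grid) {
    tm <- tanh(outer(d, dm_grid, "-") / de)    # nbins x n_mid
    s_t <- colSums(tm); s_tt <- colSums(tm^2)
    s_y <- sum(y); s_ty <- colSums(tm * y)
    nb <- length(d)
    den <- nb * s_tt - s_t^2
    bb <- (nb * s_ty - s_t * s_y) / den        # slope on tanh
    aa <- (s_y - bb * s_t) / nb                # intercept
    ssr <- colSums((y - outer(rep(1, nb), aa) - tm * rep(bb, each = nb))^2)
    k <- which.min(ssr)
    if (ssr[k] < best$ssr)
      best <- list(ssr = ssr[k], d_mid = dm_grid[k], delta = de,
                   c_dense = aa[k] - bb[k], c_dilute = aa[k] + bb[k])
  }
  best
}

# pairwise (Lagrange-identity) radius of gyration oracle
rg_pairwise_oracle <- function(pos) {
  n <- nrow(pos)
  d2 <- as.matrix(stats::dist(pos))^2
  sqrt(sum(d2) / (2 * n^2))
}
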