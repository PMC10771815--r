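test_that("largest-cluster detection matches brute-force connectivity", {
  set.seed(51)
  ff <- force_field("reduced")
  for (rep in 1:50) {
    topo <- build_linear_topology(8, 5)
    # scatter compact chains so clusters form at random
    pos <- matrix(0, 40, 3)
    for (ch in 1:8) {
      ctr <- runif(3, 0, 20)
      rows <- (ch - 1) * 5 + 1:5
      pos[rows, ] <- sweep(matrix(rnorm(15, sd = 0.6), 5, 3), 2, ctr, `+`)
    }
    fr <- md_frame(pos, 20)
    got <- find_largest_cluster(fr, topo, 2.0)
    expect_identical(got, cluster_oracle(fr, topo, 2.0))
  }
})

test_that("cluster tie rule picks the component with the lowest chain id", {
  topo <- build_linear_topology(6, 2)
  # two 3-chain blobs far apart
  blob <- function(ctr) {
    p <- matrix(0, 6, 3)
    p[, 1] <- ctr + c(0, 0.5, 1, 1.5, 2, 2.5)
    sweep(p, 2, c(0, 10, 10), `+`)
  }
  pos <- rbind(blob(2), blob(50))
  fr <- md_frame(pos, 100)
  expect_identical(find_largest_cluster(fr, topo, 1.0), 1:3)
  # a strictly larger blob wins regardless of ids
  topo2 <- build_linear_topology(5, 2)
  pos2 <- rbind(blob(2)[1:4, ], blob(50))
  expect_identical(find_largest_cluster(md_frame(pos2, 100), topo2, 1.0), 3:5)
  # everything connected -> all chains
  expect_identical(find_largest_cluster(md_frame(blob(2)[rep(1:6, 2), ] +
                                                   matrix(rnorm(36, sd = 0.05), 12, 3),
                                                 100), topo, 5), 1:6)
})

test_that("droplet centre is symmetric, equivariant and periodicity-safe", {
  box <- c(30, 30, 30)
  set.seed(52)
  pts <- matrix(rnorm(300, sd = 2), 100, 3)
  sym <- rbind(pts, -pts)                      # symmetric about the origin
  ctr0 <- droplet_center(md_frame(sym %% 30, box))
  d0 <- ctr0 %% 30
  expect_true(all(pmin(d0, 30 - d0) < 1e-9))

  shift <- c(4.2, -3.3, 7.7)
  ctr1 <- droplet_center(md_frame(sweep(sym, 2, shift, `+`) %% 30, box))
  d <- (ctr1 - shift) %% 30
  expect_true(all(pmin(abs(d), 30 - abs(d)) < 1e-9))

  # droplet straddling the box corner: wrapped equals unwrapped (mod box)
  ball <- matrix(rnorm(600, sd = 1.5), 200, 3)       # centred at the origin
  ctr_wrap <- droplet_center(md_frame(ball %% 30, box))
  ctr_unwrap <- colMeans(ball)
  d <- (ctr_wrap - ctr_unwrap) %% 30
  expect_true(all(pmin(abs(d), 30 - abs(d)) < 1e-6))
})

test_that("radial profile conserves counts and converts units correctly", {
  set.seed(53)
  n <- 20000
  rad <- 15
  box <- 50
  r <- rad * runif(n)^(1 / 3)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- sweep(r * u, 2, rep(box / 2, 3), `+`)
  traj <- md_trajectory(topology_stub <- polydroplet:::topology_unbonded(n),
                        list(md_frame(pos, box)), units = "real")
  prof <- radial_concentration_profile(traj, bin_width = 1.5)
  # count conservation: every bead lands in a bin (r_max = 25 > 15)
  expect_equal(sum(prof$counts) + prof$n_outside, prof$beads_in_scope)
  expect_equal(prof$n_outside, 0)
  # bins beyond the ball are exactly zero
  centers <- (prof$bin_edges[-1] + prof$bin_edges[-length(prof$bin_edges)]) / 2
  expect_true(all(prof$concentration[centers > rad + 1.5] == 0))
  # interior bins flat at the known density (3 binomial sigma per bin)
  rho <- n / (4 / 3 * pi * rad^3)               # beads per A^3
  shell_v <- 4 / 3 * pi * diff(prof$bin_edges^3)
  inner <- which(prof$bin_edges[-1] <= rad - 1.5)
  p_bin <- shell_v[inner] / (4 / 3 * pi * rad^3)
  expected <- n * p_bin
  tol <- 3 * sqrt(n * p_bin * (1 - p_bin))
  expect_true(all(abs(prof$counts[inner] - expected) <= tol + 1))
  # concentration = counts / shell volume in mM
  expect_equal(prof$concentration[inner],
               prof$counts[inner] / shell_v[inner] * 1.66054e6)
})

test_that("tanh fit recovers a noiseless profile to 1e-6", {
  prof <- generate_noisy_profile(500, 0, 80, 10, noise_frac = 0)
  # an exactly-zero dilute phase may come back infinitesimally negative and
  # be clipped, which warns by design
  fit <- suppressWarnings(fit_tanh_profile(prof))
  expect_equal(fit$c_dense, 500, tolerance = 1e-6)
  expect_lt(abs(fit$c_dilute), 500 * 1e-6)
  expect_equal(fit$d_mid, 80, tolerance = 1e-6)
  expect_equal(fit$delta, 10, tolerance = 1e-6)
  expect_identical(fit$r_half, fit$d_mid)
  expect_lt(fit$inner_bound, fit$d_mid)
  expect_gt(fit$outer_bound, fit$d_mid)
  # fitted curve is non-increasing when c_dense > c_dilute
  dd <- seq(0, 130, 1)
  cc <- (fit$c_dense + fit$c_dilute) / 2 -
    (fit$c_dense - fit$c_dilute) / 2 * tanh((dd - fit$d_mid) / fit$delta)
  expect_true(all(diff(cc) <= 0))
  # a profile with nonzero dilute phase
  prof2 <- generate_noisy_profile(800, 60, 60, 15, noise_frac = 0)
  fit2 <- fit_tanh_profile(prof2)
  expect_equal(fit2$c_dilute, 60, tolerance = 1e-5)
})

test_that("negative fitted dilute concentrations are clipped and flagged", {
  clipped <- FALSE
  for (s in 1:25) {
    prof <- generate_noisy_profile(500, 0, 60, 8, noise_frac = 0.03, seed = s)
    fit <- withCallingHandlers(
      fit_tanh_profile(prof),
      warning = function(w) invokeRestart("muffleWarning"))
    if (fit$clipped_dilute) {
      clipped <- TRUE
      expect_identical(fit$c_dilute, 0)
      break
    }
  }
  expect_true(clipped)
})

test_that("interface bounds follow the coverage traversal rule", {
  fit <- list(d_mid = 100, delta = 10)
  b <- interface_bounds(fit, 0.8)
  expect_equal(unname(b), c(100 - 10 * atanh(0.8), 100 + 10 * atanh(0.8)))
  expect_equal(unname(b[2] - 100), unname(100 - b[1]))   # symmetric
  expect_equal(unname(interface_bounds(fit, 1e-9)), c(100, 100),
               tolerance = 1e-6)
  expect_error(interface_bounds(fit, 1), "coverage")
})

test_that("asphericity separates spheres from rods and is rotation-invariant", {
  set.seed(54)
  n <- 1e4
  r <- runif(n)^(1 / 3)
  u <- matrix(rnorm(3 * n), n, 3)
  ball <- r * u / sqrt(rowSums(u^2))
  expect_lt(as.numeric(asphericity(ball)), 0.01)

  rod <- cbind(seq(0, 1, length.out = 50), 0, 0)
  b_rod <- asphericity(rod)
  expect_equal(as.numeric(b_rod), 1.0, tolerance = 1e-12)
  expect_true(attr(b_rod, "degenerate"))

  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  pts <- matrix(rnorm(60), 20, 3) %*% diag(c(3, 2, 1))
  expect_equal(as.numeric(asphericity(pts)),
               as.numeric(asphericity(pts %*% rot)), tolerance = 1e-10)
  expect_error(asphericity(pts[1:3, ]), "4 beads")
})
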