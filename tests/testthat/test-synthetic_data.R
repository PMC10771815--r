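test_that("Gaussian chains reproduce ideal-chain closed forms", {
  set.seed(81)
  n <- 50; b <- 1.5
  rg2 <- replicate(1e4, chain_rg(sample_gaussian_chain(n, b))^2)
  expect_equal(mean(rg2), b^2 * (n^2 - 1) / (6 * n), tolerance = 0.02)
  # dimer end-to-end distance is Maxwell with scale b/sqrt(3)
  re <- replicate(1e4, chain_re(sample_gaussian_chain(2, b)))
  rgrid <- seq(0, 6 * b, length.out = 2000)
  s <- b / sqrt(3)
  cdf_maxwell <- stats::pgamma(rgrid^2 / (2 * s^2), shape = 1.5)
  ks <- max(abs(stats::ecdf(re)(rgrid) - cdf_maxwell))
  expect_lt(ks, 0.02)
  # determinism under a fixed seed
  expect_identical(sample_gaussian_chain(10, 1, seed = 3),
                   sample_gaussian_chain(10, 1, seed = 3))
})

test_that("synthetic droplets carry their planted truth and are reproducible", {
  sp <- synthetic_droplet_spec(chain_length = 15, b = 1.2, c_dense = 1000,
                               d_mid = 40, delta = 8, end_enrichment = 2,
                               orientation_mode = "tangential", seed = 82)
  t1 <- generate_synthetic_droplet(sp, n_frames = 2)
  t2 <- generate_synthetic_droplet(sp, n_frames = 2)
  expect_identical(t1$frames[[2]]$positions, t2$frames[[2]]$positions)
  tr <- t1$metadata$truth
  expect_equal(tr$d_mid, 40)
  expect_equal(tr$delta, 8)
  expect_equal(tr$orientation_mode, "tangential")
  expect_equal(tr$n_chains * 15, t1$topology$n_beads)
  # derived chain count realizes the planted concentration scale closely
  expect_equal(tr$c_dense, 1000, tolerance = 0.1)
  expect_error(synthetic_droplet_spec(c_dense = 10, c_dilute = 20), "c_dense")
  expect_error(synthetic_droplet_spec(end_enrichment = -1), "end_enrichment")
})

test_that("planted tanh density parameters are recovered by the profile fit", {
  sp <- synthetic_droplet_spec(chain_length = 20, b = 1.5, c_dense = 2000,
                               c_dilute = 0, d_mid = 60, delta = 12,
                               seed = 83)
  traj <- generate_synthetic_droplet(sp, n_frames = 30)
  truth <- traj$metadata$truth
  ctr <- traj$frames[[1]]$box / 2
  # bead-level profile: chain extent smears the planted chain-COM law, so
  # the midpoint is recovered within about one chain Rg and the width
  # within the Rg-broadened tolerance
  prof <- radial_concentration_profile(traj, bin_width = 4, center = ctr)
  fit <- suppressWarnings(fit_tanh_profile(prof))
  rg_chain <- sp$b * sqrt((20^2 - 1) / (6 * 20))
  expect_equal(fit$c_dense, truth$c_dense, tolerance = 0.10)
  expect_lt(abs(fit$d_mid - truth$d_mid), rg_chain)
  expect_lt(abs(fit$delta - truth$delta) / truth$delta, 0.25)
  expect_lt(fit$c_dilute, 0.02 * fit$c_dense)
  # chain-COM-level profile matches the planted law without the smearing:
  # build it by placing one pseudo-bead per chain COM
  ch <- chain_records(traj, center = ctr)
  com_counts <- hist(ch$d_com, breaks = seq(0, 132, 4), plot = FALSE)$counts
  shell_v <- 4 / 3 * pi * diff(seq(0, 132, 4)^3)
  prof_com <- structure(list(
    bin_edges = seq(0, 132, 4), counts = com_counts,
    concentration = com_counts / (30 * shell_v) * 1.66054e6 * 20,
    n_frames = 30, beads_in_scope = NA, n_outside = 0),
    class = "density_profile")
  fit_com <- suppressWarnings(fit_tanh_profile(prof_com))
  expect_lt(abs(fit_com$d_mid - truth$d_mid), 2)
  expect_lt(abs(fit_com$delta - truth$delta) / truth$delta, 0.15)
})

test_that("zero end enrichment leaves occupancy uniform in every region", {
  sp <- synthetic_droplet_spec(chain_length = 20, b = 1.5, c_dense = 2000,
                               d_mid = 60, delta = 12, end_enrichment = 0,
                               seed = 84)
  traj <- generate_synthetic_droplet(sp, n_frames = 25)
  ctr <- traj$frames[[1]]$box / 2
  fit <- list(inner_bound = 60 - 12 * atanh(0.8),
              outer_bound = 60 + 12 * atanh(0.8))
  sr <- segment_records(traj, 5, fit = fit, center = ctr)
  for (region in c("interior", "interface")) {
    occ <- segment_occupancy(sr, region)
    p0 <- 1 / nrow(occ)
    sigma <- sqrt(p0 * (1 - p0) / sum(occ$count))
    expect_true(all(abs(occ$probability - p0) <= 3 * sigma + 0.01),
                info = region)
  }
})

test_that("end enrichment biases terminal segments into the interface band", {
  # enrichment is a membership effect, so it needs an interface band
  # comparable to the chain size (thin interface, larger chains); the planted
  # signal is isolated by comparing against the zero-enrichment null at the
  # same geometry
  occ_of <- function(e) {
    sp <- synthetic_droplet_spec(chain_length = 20, b = 2, c_dense = 2000,
                                 d_mid = 60, delta = 3, end_enrichment = e,
                                 seed = 85)
    traj <- generate_synthetic_droplet(sp, n_frames = 40)
    fit <- list(inner_bound = 60 - 3 * atanh(0.8),
                outer_bound = 60 + 3 * atanh(0.8))
    sr <- segment_records(traj, 5, fit = fit,
                          center = traj$frames[[1]]$box / 2)
    segment_occupancy(sr, "interface")
  }
  occ0 <- occ_of(0)
  occ4 <- occ_of(4)
  n_idx <- nrow(occ4)
  term <- c(1, n_idx)
  central <- seq(n_idx %/% 2 - 2, n_idx %/% 2 + 3)
  expect_gt(mean(occ4$probability[term]), mean(occ4$probability[central]))
  expect_gt(mean(occ4$probability[term]), mean(occ0$probability[term]))
})

test_that("planted compactness profiles are recovered from chain records", {
  sp <- synthetic_droplet_spec(
    chain_length = 20, b = 1.5, c_dense = 2000, d_mid = 60, delta = 12,
    rg_scale_profile = list(d = c(0, 45, 75), s = c(1, 1, 0.7)),
    seed = 86)
  traj <- generate_synthetic_droplet(sp, n_frames = 25)
  ctr <- traj$frames[[1]]$box / 2
  ch <- chain_records(traj, center = ctr)
  out <- rg_distribution_by_bin(ch, seq(0, 80, 16))
  sm <- out$summary
  # chains planted at scale s(d): the mean Rg in far bins drops by the
  # planted factor relative to the core bins
  core <- sm$mean_rg[sm$bin_lo == 0 | sm$bin_lo == 16]
  far <- sm$mean_rg[sm$bin_lo == 64]
  expect_equal(mean(far) / mean(core), 0.72, tolerance = 0.08)
  # a flat planted profile stays flat within 3 standard errors
  sp0 <- synthetic_droplet_spec(chain_length = 20, b = 1.5, c_dense = 2000,
                                d_mid = 60, delta = 12, seed = 87)
  tr0 <- generate_synthetic_droplet(sp0, n_frames = 25)
  sr0 <- segment_records(tr0, 5, center = tr0$frames[[1]]$box / 2)
  prof0 <- segmental_rg_profile(sr0, seq(0, 80, 16))
  prof0 <- prof0[prof0$count >= 100, ]
  overall <- sum(prof0$mean_rg * prof0$count) / sum(prof0$count)
  expect_true(all(abs(prof0$mean_rg - overall) <=
                    3 * prof0$se_rg + 0.01 * overall))
})

test_that("noisy profile generator honours noise, clipping and determinism", {
  p0 <- generate_noisy_profile(500, 0, 80, 10, noise_frac = 0)
  cfun <- function(d) 250 - 250 * tanh((d - 80) / 10)
  centers <- (p0$bin_edges[-1] + p0$bin_edges[-length(p0$bin_edges)]) / 2
  expect_equal(p0$concentration, cfun(centers), tolerance = 1e-12)
  p1 <- generate_noisy_profile(500, 0, 80, 10, noise_frac = 0.02, seed = 1)
  p2 <- generate_noisy_profile(500, 0, 80, 10, noise_frac = 0.02, seed = 1)
  expect_identical(p1$concentration, p2$concentration)
  expect_false(identical(p0$concentration, p1$concentration))
  expect_true(all(p1$concentration >= 0))
  # strong noise on a zero-dilute profile must clip and flag
  p3 <- generate_noisy_profile(500, 0, 40, 5, noise_frac = 1.5, seed = 2)
  expect_true(attr(p3, "clipped"))
  expect_true(all(p3$concentration >= 0))
})
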