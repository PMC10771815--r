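test_that("chain Rg matches its closed forms and the pairwise identity", {
  expect_equal(chain_rg(matrix(1, 5, 3)), 0)
  two <- rbind(c(0, 0, 0), c(3, 4, 0))          # |d| = 5
  expect_equal(chain_rg(two), 2.5)
  expect_equal(chain_re(two), 5)
  set.seed(61)
  for (rep in 1:100) {
    pos <- matrix(rnorm(3 * sample(3:40, 1)), ncol = 3)
    expect_equal(chain_rg(pos), rg_pairwise_oracle(pos), tolerance = 1e-10)
  }
  # translation / rotation invariance
  pos <- matrix(rnorm(30), 10, 3)
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(chain_rg(pos), chain_rg(sweep(pos, 2, c(5, -2, 9), `+`)),
               tolerance = 1e-12)
  expect_equal(chain_rg(pos), chain_rg(pos %*% rot), tolerance = 1e-12)
})

test_that("wrapped chains are detected and unwrapping fixes them", {
  topo <- build_linear_topology(1, 4)
  box <- c(10, 10, 10)
  straight <- cbind(seq(8.5, 11.5, 1) %% 10, 5, 5)   # crosses the boundary
  expect_error(chain_rg(straight, box = box), "unwrap")
  un <- unwrap_chains(md_frame(straight, box), topo)
  expect_equal(diff(un[, 1]), rep(1, 3))
  expect_equal(chain_rg(un, box = box),
               chain_rg(cbind(seq(0, 3, 1), 5, 5)), tolerance = 1e-12)
})

test_that("region assignment partitions d_com with closed interface bounds", {
  fit <- list(inner_bound = 40, outer_bound = 60, d_mid = 50)
  expect_identical(assign_region(c(0, 39.99, 40, 50, 60, 60.01), fit),
                   c("interior", "interior", "interface", "interface",
                     "interface", "exterior"))
  # every value receives exactly one label
  d <- seq(0, 100, 0.5)
  expect_true(all(assign_region(d, fit) %in%
                    c("interior", "interface", "exterior")))
})

test_that("segment enumeration follows the middle-bead index rule", {
  s50 <- enumerate_segments(50, 50)
  expect_equal(nrow(s50), 1)
  expect_equal(s50$segment_index, 26)      # even length: larger middle bead

  s10 <- enumerate_segments(50, 10)
  expect_equal(nrow(s10), 41)
  expect_equal(s10$segment_index[1], 6)
  expect_equal(s10$segment_index, s10$start + 5)

  s5 <- enumerate_segments(5, 5)
  expect_equal(nrow(s5), 1)
  expect_equal(s5$segment_index, 3)        # odd length: exact middle

  expect_error(enumerate_segments(10, 11), "n_seg")
})

test_that("segment records: bookkeeping, consistency with chain records", {
  sp <- synthetic_droplet_spec(chain_length = 12, b = 1, c_dense = 900,
                               d_mid = 30, delta = 6, seed = 62)
  traj <- generate_synthetic_droplet(sp, n_frames = 4)
  fit <- list(inner_bound = 25, outer_bound = 36, d_mid = 30, delta = 6)
  sr <- segment_records(traj, 5, fit = fit)
  expect_equal(nrow(sr),
               4 * traj$topology$n_chains * (12 - 5 + 1))
  expect_true(all(sr$segment_index == sr$start + 2))
  expect_true(all(sr$rg_seg >= 0 & sr$re_seg >= 0))
  # whole-chain segments reproduce the chain-level statistics
  sr_full <- segment_records(traj, 12, fit = fit)
  ch <- chain_records(traj, fit = fit)
  expect_equal(sr_full$rg_seg, ch$rg, tolerance = 1e-10)
  expect_equal(sr_full$re_seg, ch$re, tolerance = 1e-10)
  expect_equal(sr_full$d_com, ch$d_com, tolerance = 1e-10)
  # occupancy is a probability distribution over indices
  occ <- segment_occupancy(sr, "interior")
  expect_equal(sum(occ$probability), 1)
  expect_error(segment_occupancy(sr[sr$region == "interior", ], "exterior"),
               "no segments")
})

test_that("windowed segment statistics equal direct per-segment computation", {
  set.seed(63)
  pos <- matrix(rnorm(60), 20, 3)
  ws <- polydroplet:::window_stats(pos, 7)
  for (s in c(1, 5, 14)) {
    seg <- pos[s:(s + 6), ]
    expect_equal(ws$com[s, ], colMeans(seg), tolerance = 1e-12)
    expect_equal(ws$rg[s], chain_rg(seg), tolerance = 1e-12)
    expect_equal(ws$re[s], chain_re(seg), tolerance = 1e-12)
  }
})

test_that("rg distributions by bin integrate to one and find planted means", {
  recs <- data.frame(d_com = rep(c(5, 15), each = 200),
                     rg = c(rep(2, 200), rep(4, 200)))
  out <- rg_distribution_by_bin(recs, c(0, 10, 20))
  expect_equal(out$summary$mean_rg, c(2, 4))
  expect_equal(out$summary$count, c(200, 200))
  for (h in out$histograms)
    expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-10)
  # delta distribution: mode at the common value
  expect_equal(out$summary$mode_rg[1], 2, tolerance = 0.5)
})

test_that("contact counting obeys exclusions and matches brute force", {
  # two chains beyond the cutoff never touch
  topo <- build_linear_topology(2, 3)
  pos <- rbind(cbind(10 + 0:2, 10, 10), cbind(30 + 0:2, 30, 30))
  traj <- md_trajectory(topo, list(md_frame(pos, 60)), units = "reduced")
  cp <- contact_profile(traj, contact_cutoff = 1.5, intra_exclusion = 2,
                        bin_width = 20)
  expect_true(all(cp$mean_interchain == 0))
  # straight chain at bond length below the cutoff: exclusion kills intra
  topo1 <- build_linear_topology(1, 10)
  pos1 <- cbind(20 + (0:9) * 1.0, 20, 20)
  tr1 <- md_trajectory(topo1, list(md_frame(pos1, 60)), units = "reduced")
  cp1 <- contact_profile(tr1, contact_cutoff = 1.5, intra_exclusion = 2,
                         bin_width = 10)
  expect_true(all(cp1$mean_intrachain == 0))
  cp1b <- contact_profile(tr1, contact_cutoff = 1.5, intra_exclusion = 0,
                          bin_width = 10)
  expect_gt(sum(cp1b$mean_intrachain * cp1b$n_monomers), 0)

  # brute-force oracle for total pair counts on random frames
  set.seed(64)
  ff <- force_field("reduced")
  for (rep in 1:50) {
    cfg <- random_config(3, 6, box = 12, params = ff, min_sep = 0.2,
                         kink_gap = 0)
    prs <- polydroplet:::cpp_pair_list(cfg$frame$positions, cfg$frame$box,
                                       1.5, "brute")
    d2 <- 0
    p <- cfg$frame$positions
    for (k in 1:3) {
      dx <- outer(p[, k], p[, k], "-")
      dx <- dx - 12 * round(dx / 12)
      d2 <- d2 + dx^2
    }
    n_oracle <- sum(sqrt(d2[upper.tri(d2)]) < 1.5)
    expect_equal(nrow(prs), n_oracle)
  }
})

test_that("segmental Rg profiles normalize against the interior plateau", {
  sp <- synthetic_droplet_spec(chain_length = 20, b = 1.5, c_dense = 1500,
                               d_mid = 50, delta = 10, seed = 65)
  traj <- generate_synthetic_droplet(sp, n_frames = 10)
  fit <- list(inner_bound = 50 - 10 * atanh(0.8),
              outer_bound = 50 + 10 * atanh(0.8), d_mid = 50, delta = 10)
  sr <- segment_records(traj, 5, fit = fit)
  prof <- segmental_rg_profile(sr, seq(0, 70, 10), "all", fit = fit)
  interior <- prof$d_mid_bin < fit$inner_bound
  w <- prof$count[interior]
  expect_equal(sum(prof$norm_rg[interior] * w) / sum(w), 1, tolerance = 1e-10)
  # end and middle subsets select the documented segments
  expect_setequal(unique(sr$position_class), c("end", "middle", "other"))
  expect_true(all(sr$start[sr$position_class == "end"] %in% c(1, 16)))
  expect_true(all(sr$segment_index[sr$position_class == "middle"] == 10))
})
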