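# The package's reference desk-scale study: a fully condensed hydrophobic
# homopolymer droplet in reduced units, plus the matching P = 0 bulk
# reference. These bundle the standard protocol (packed start, equilibration,
# production, profile, interface fit) behind one seeded call.

#' Desk-scale homopolymer droplet study
#'
#' Runs the package's standard droplet protocol in reduced units
#' (sigma = epsilon = 1): a pre-packed ball of strongly cohesive
#' (lambda = 1) chains with the bond/diameter ratio 3.8/6 of residue-level
#' coarse-grained models, equilibrated and sampled with Langevin dynamics at
#' a temperature in the liquid-droplet window (default kT = 2 epsilon, about
#' two thirds of the evaporation onset for this geometry), followed by the
#' radial concentration profile and hyperbolic-tangent interface fit. With
#' the defaults every chain belongs to the condensate and the fitted
#' dilute-phase concentration is zero.
#'
#' @param seed integer seed controlling packing, dynamics and analysis
#' @param n_chains,chain_length system size (default 20 x 20 beads)
#' @param temperature reduced temperature kT in epsilon
#' @param n_equil,n_production equilibration / production steps (dt = 0.005)
#' @param save_every production frame interval in steps
#' @param density0 initial packing density (beads/sigma^3)
#' @param box periodic box edge (sigma); kept well above 4x the droplet
#'   radius so the dilute phase is explicit
#' @param bin_width radial profile bin width (sigma)
#' @param cluster_cutoff chain-cluster cutoff for droplet detection (sigma)
#' @param params force field; default reduced preset with bond r0 = 3.8/6
#' @return list: `topology`, `params`, `trajectory` (production frames),
#'   `profile` (`density_profile`), `fit` (`interface_fit`),
#'   `cluster_cutoff`, `seed`
#' @export
droplet_study <- function(seed = 1L, n_chains = 20, chain_length = 20,
                          temperature = 2, n_equil = 30000,
                          n_production = 60000, save_every = 300,
                          density0 = 0.45, box = 40, bin_width = 1,
                          cluster_cutoff = 1.5,
                          params = force_field("reduced", bond_r0 = 3.8 / 6)) {
  seed <- as.integer(seed)
  topo <- build_linear_topology(n_chains, chain_length)
  start <- init_droplet_configuration(topo, params, seed = seed,
                                      density = density0, box = box)
  eq <- run_langevin(start, topo, params,
                     sim_settings(temperature, 0.005, 1, n_equil,
                                  max(1000L, n_equil %/% 10), seed = seed))
  prod <- run_langevin(md_frame(eq$state$positions, start$box), topo, params,
                       sim_settings(temperature, 0.005, 1, n_production,
                                    save_every, seed = seed + 1L),
                       velocities = eq$state$velocities)
  profile <- radial_concentration_profile(prod, bin_width = bin_width,
                                          cluster_cutoff = cluster_cutoff)
  fit <- fit_tanh_profile(profile)
  list(topology = topo, params = params, trajectory = prod, profile = profile,
       fit = fit, cluster_cutoff = cluster_cutoff, seed = seed)
}

#' Desk-scale P = 0 bulk reference study
#'
#' The interface-free counterpart of [droplet_study()]: the same force field
#' and temperature in a cubic box relaxed to its naturally preferred
#' concentration by Monte Carlo volume moves at zero external pressure. The
#' time-averaged bulk concentration is the reference for the
#' droplet-interior plateau.
#'
#' @param seed integer seed
#' @param n_chains,chain_length system size
#' @param temperature reduced temperature kT in epsilon
#' @param n_steps total MD steps (volume moves interleaved every 200)
#' @param density0 starting number density (beads/sigma^3), near the
#'   expected bulk value so the box relaxes quickly
#' @param params force field; must match the droplet study for comparisons
#' @return the [run_bulk_p0()] result list
#' @export
bulk_study <- function(seed = 1L, n_chains = 10, chain_length = 20,
                       temperature = 2, n_steps = 40000, density0 = 1.0,
                       params = force_field("reduced", bond_r0 = 3.8 / 6)) {
  topo <- build_linear_topology(n_chains, chain_length)
  st <- sim_settings(temperature, 0.005, 1, n_steps, 2000L,
                     seed = as.integer(seed), ensemble = "p0-bulk")
  run_bulk_p0(topo, params, st, density0 = density0)
}
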