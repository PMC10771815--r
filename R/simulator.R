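# Langevin-dynamics driver, droplet initial configurations, and the
# constant-pressure (P = 0) bulk ensemble.

#' Relax a configuration by capped steepest descent
#'
#' Removes the high-energy contacts left by random packing before dynamics
#' are started: beads move along the force direction with per-bead
#' displacements capped at `max_step`, with a backtracking step size
#' (accepted moves grow it, rejected moves shrink it).
#'
#' @param frame starting `md_frame`
#' @param topology `chain_topology`
#' @param params `force_field`
#' @param n_iter maximum iterations
#' @param max_step displacement cap per bead per iteration (default
#'   0.05 sigma)
#' @return relaxed `md_frame`; attribute `"energy"` holds the final
#'   potential energy
#' @export
minimize_energy <- function(frame, topology, params, n_iter = 300,
                            max_step = NULL) {
  if (is.null(max_step)) max_step <- 0.05 * max(params$sigma)
  pos <- frame$positions
  e <- potential_energy(pos, frame$box, topology, params)
  alpha <- 1e-4
  for (it in seq_len(n_iter)) {
    res <- compute_forces(md_frame(pos, frame$box), topology, params)
    f <- res$forces
    fmax <- max(sqrt(rowSums(f^2)))
    if (fmax < 1e-8) break
    step <- min(alpha, max_step / fmax)
    trial <- pos + step * f
    et <- potential_energy(trial, frame$box, topology, params)
    if (et < e) {
      pos <- trial; e <- et; alpha <- alpha * 1.2
    } else {
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
  }
  out <- md_frame(pos, frame$box, frame$time)
  attr(out, "energy") <- e
  out
}

#' Run Langevin dynamics
#'
#' Integrates the bead-spring model with a BAOAB-split Langevin integrator.
#' Seeded runs are bit-reproducible on a given platform; initial velocities
#' are drawn from the Maxwell distribution at the set temperature unless
#' supplied.
#'
#' @param start starting `md_frame` (non-overlapping configuration)
#' @param topology `chain_topology`
#' @param params `force_field`
#' @param settings `sim_settings`
#' @param velocities optional n x 3 starting velocity matrix (internal units);
#'   default draws from Maxwell at the set temperature
#' @return `md_trajectory` with extra fields: `log` (data frame of step,
#'   potential energy, instantaneous temperature) and `state` (final
#'   positions/velocities for continuation); trajectory metadata records the
#'   seed and unit system
#' @export
run_langevin <- function(start, topology, params, settings, velocities = NULL) {
  stopifnot(inherits(start, "md_frame"), inherits(settings, "sim_settings"))
  validate_topology(topology)
  iu <- internal_units(params, settings)
  res <- cpp_langevin(start$positions, start$box, topology$chain_id,
                      per_bead(params$sigma, topology),
                      per_bead(params$lambda, topology),
                      per_bead(params$charge, topology),
                      per_bead(params$mass, topology),
                      params$epsilon, params$bond_k, params$bond_r0,
                      params$debye_length, COULOMB_KCAL / params$dielectric,
                      params$pair_cutoff, params$coulomb_cutoff,
                      iu$dt, iu$gamma, iu$kT,
                      settings$n_steps, settings$save_every, settings$seed,
                      is.null(velocities), velocities)
  frames <- lapply(seq_along(res$frames), function(i)
    md_frame(res$frames[[i]], start$box, time = res$step[i]))
  traj <- md_trajectory(topology, frames, units = params$units, wrapped = TRUE)
  temp <- if (params$units == "real") res$kT_kin / KCAL_PER_MOL_K else res$kT_kin
  traj$log <- data.frame(step = res$step, e_pot = res$e_pot,
                         temperature = temp)
  traj$state <- list(positions = res$x_final, velocities = res$v_final,
                     box = start$box)
  traj$metadata$seed <- settings$seed
  traj$metadata$settings <- unclass(settings)
  traj
}

#' Pre-assembled droplet starting configuration
#'
#' Lays chains down as self-avoiding random walks inside a ball sized to a
#' target monomer concentration, so that droplet runs start from a compact
#' (near-equilibrium) condensate instead of waiting for self-assembly.
#'
#' @param topology `chain_topology`
#' @param params `force_field` (bond length and sigma set the walk geometry)
#' @param seed RNG seed; the same seed yields the identical frame
#' @param concentration target monomer concentration in mM (real units)
#' @param density alternative: target number density in beads/length^3
#'   (required in reduced units)
#' @param box periodic box edge(s); default `box_factor` times the ball radius
#' @param box_factor box edge as a multiple of the ball radius (default 4, so
#'   the dilute phase is explicit but negligible)
#' @param min_sep minimum allowed distance between non-bonded beads, as a
#'   fraction of sigma (default 0.8)
#' @param max_retries per-bead direction retries before restarting a chain
#' @param relax run [minimize_energy()] on the packed configuration
#'   (default TRUE); the raw walk leaves contacts near `min_sep` whose
#'   energies would destabilize dynamics at a production time step
#' @return `md_frame` centred in the box; attribute `"ball_radius"` carries
#'   the construction radius
#' @export
init_droplet_configuration <- function(topology, params, seed = 1L,
                                       concentration = NULL, density = NULL,
                                       box = NULL, box_factor = 4,
                                       min_sep = 0.8, max_retries = 60L,
                                       relax = TRUE) {
  validate_topology(topology)
  if (is.null(density)) {
    if (is.null(concentration))
      stop("supply a target `concentration` (mM) or a number `density`")
    density <- concentration / MM_PER_BEAD_A3
  }
  n <- topology$n_beads
  r_ball <- (3 * n / (4 * pi * density))^(1 / 3)
  sig <- max(params$sigma)
  b <- params$bond_r0
  if (is.null(box)) box <- max(box_factor * r_ball, 3 * params$pair_cutoff)
  if (length(box) == 1) box <- rep(box, 3)
  centre <- box / 2
  min2 <- (min_sep * sig)^2

  with_seed(seed, {
    pos <- matrix(NA_real_, n, 3)
    placed <- 0L
    # the walk grows outward from its start, so flip the bead order of
    # exactly half the chains (random assignment) to keep the two chain ends
    # statistically equivalent in the starting state
    flip <- sample(rep(c(TRUE, FALSE), length.out = topology$n_chains))
    for (ch in seq_len(topology$n_chains)) {
      len <- topology$chain_lengths[ch]
      ok <- FALSE
      for (restart in seq_len(20L)) {
        chain_pos <- matrix(NA_real_, len, 3)
        # chain start: uniform in the ball (with a bond-length margin)
        repeat {
          cand <- stats::runif(3, -1, 1) * r_ball
          if (sum(cand^2) <= (max(r_ball - b, 0.5 * r_ball))^2) break
        }
        chain_pos[1, ] <- cand
        good <- placed == 0L ||
          min(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2)) >= min2
        if (good) {
          grown <- TRUE
          for (ib in 2:len) {
            hit <- FALSE
            for (try in seq_len(max_retries)) {
              u <- stats::rnorm(3)
              cand <- chain_pos[ib - 1, ] + b * u / sqrt(sum(u^2))
              if (sum(cand^2) > (r_ball + b)^2) next
              prev <- chain_pos[seq_len(ib - 2), , drop = FALSE]  # skip bonded
              self_ok <- ib <= 2 ||
                min(colSums((t(prev) - cand)^2)) >= min2
              other_ok <- placed == 0L ||
                min(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2)) >= min2
              if (self_ok && other_ok) { chain_pos[ib, ] <- cand; hit <- TRUE; break }
            }
            if (!hit) { grown <- FALSE; break }
          }
          if (grown) { ok <- TRUE; break }
        }
      }
      if (!ok)
        stop("could not pack chain ", ch, " after retries; ",
             "lower the target density/concentration")
      if (flip[ch]) chain_pos <- chain_pos[len:1, , drop = FALSE]
      pos[placed + seq_len(len), ] <- chain_pos
      placed <- placed + len
    }
    fr <- md_frame(sweep(pos, 2, centre, `+`), box, time = 0)
    if (relax) {
      rb <- r_ball
      fr <- minimize_energy(fr, topology, params)
      r_ball <- rb
    }
    attr(fr, "ball_radius") <- r_ball
    fr
  })
}

#' Constant-pressure bulk run (P = 0)
#'
#' Simulates a concentrated solution in a cubic periodic box whose volume
#' fluctuates through Monte Carlo volume moves (isotropic, molecular
#' centre-of-mass scaling, log-volume steps) accepted with the isobaric
#' criterion at the stated pressure (default 0). At P = 0 the box relaxes to
#' the system's naturally preferred concentration — the bulk reference for
#' the droplet-interior plateau. The move amplitude is tuned during the
#' equilibration fraction toward a mid-range acceptance rate.
#'
#' @param topology `chain_topology`
#' @param params `force_field`
#' @param settings `sim_settings` with `ensemble = "p0-bulk"`
#' @param start optional starting `md_frame` (cubic box); default builds a
#'   dense configuration at `density0`
#' @param density0 initial number density (beads/length^3) when `start` is
#'   missing; default 0.3 in reduced units, 350 mM-equivalent in real units
#' @param pressure external pressure in internal units (energy/length^3);
#'   default 0
#' @param vol_every attempt one volume move per this many MD steps
#' @param equil_fraction fraction of the run discarded before averaging the
#'   concentration (and used for move-amplitude tuning)
#' @param max_edge box edge cap (expansion bound for purely repulsive runs)
#' @return list: `trajectory` (frames carry their own boxes),
#'   `bulk_concentration` (mM; in reduced units the same bead/length^3 to mM
#'   conversion is applied with the length unit read as Angstrom),
#'   `number_density` (beads/length^3), `acceptance` (volume-move rate over
#'   production), `box_series` (edge length per cycle)
#' @export
run_bulk_p0 <- function(topology, params, settings, start = NULL,
                        density0 = NULL, pressure = 0,
                        vol_every = 200L, equil_fraction = 0.5,
                        max_edge = Inf) {
  stopifnot(inherits(settings, "sim_settings"))
  if (settings$ensemble != "p0-bulk")
    stop("settings$ensemble must be 'p0-bulk'")
  validate_topology(topology)
  n <- topology$n_beads
  if (is.null(start)) {
    if (is.null(density0))
      density0 <- if (params$units == "reduced") 0.3 else 350 / MM_PER_BEAD_A3
    edge <- (n / density0)^(1 / 3)
    if (edge < 2 * params$pair_cutoff)
      stop("initial box (edge ", signif(edge, 4),
           ") below 2 * pair_cutoff; lower density0")
    start <- init_droplet_configuration(topology, params, seed = settings$seed,
                                        density = density0 * 1.3,
                                        box = edge)
  }
  if (length(unique(start$box)) != 1) stop("bulk ensemble requires a cubic box")
  iu <- internal_units(params, settings)
  sig <- per_bead(params$sigma, topology)
  lam <- per_bead(params$lambda, topology)
  chg <- per_bead(params$charge, topology)
  mas <- per_bead(params$mass, topology)
  n_cycles <- settings$n_steps %/% vol_every
  equil_cycles <- floor(equil_fraction * n_cycles)

  pos <- start$positions
  box <- start$box
  vel <- NULL
  d_lnV <- 0.01
  frames <- list()
  log <- list()
  box_series <- numeric(n_cycles)
  dens_acc <- c()
  acc <- 0L; att <- 0L; acc_tune <- 0L; att_tune <- 0L

  with_seed(settings$seed + 7L, {
    for (cy in seq_len(n_cycles)) {
      res <- cpp_langevin(pos, box, topology$chain_id, sig, lam, chg, mas,
                          params$epsilon, params$bond_k, params$bond_r0,
                          params$debye_length, COULOMB_KCAL / params$dielectric,
                          params$pair_cutoff, params$coulomb_cutoff,
                          iu$dt, iu$gamma, iu$kT,
                          vol_every, vol_every,
                          settings$seed + cy, is.null(vel), vel)
      pos <- res$x_final
      vel <- res$v_final
      # volume move: scale chain centres of mass, keep internal conformation
      V <- prod(box)
      lnV_new <- log(V) + stats::runif(1, -d_lnV, d_lnV)
      s <- exp((lnV_new - log(V)) / 3)
      if (s * box[1] >= 2 * params$pair_cutoff && s * box[1] <= max_edge) {
        coms <- rowsum(pos, topology$chain_id) / topology$chain_lengths
        shift <- (s - 1) * coms[topology$chain_id, , drop = FALSE]
        pos_new <- pos + shift
        box_new <- s * box
        u_old <- potential_energy(pos, box, topology, params)
        u_new <- potential_energy(pos_new, box_new, topology, params)
        V_new <- exp(lnV_new)
        ln_acc <- -(u_new - u_old) / iu$kT - pressure * (V_new - V) / iu$kT +
          (topology$n_chains + 1) * (lnV_new - log(V))
        att <- att + 1L
        if (cy > equil_cycles) att_tune <- att_tune + 1L
        if (log(stats::runif(1)) < ln_acc) {
          pos <- pos_new; box <- box_new
          acc <- acc + 1L
          if (cy > equil_cycles) acc_tune <- acc_tune + 1L
        }
      } else if (s * box[1] < 2 * params$pair_cutoff) {
        stop("box collapsed below 2 * pair_cutoff per edge")
      }
      # amplitude tuning during equilibration only
      if (cy <= equil_cycles && att > 0 && cy %% 10 == 0) {
        rate <- acc / att
        if (rate > 0.5) d_lnV <- min(d_lnV * 1.5, 0.5)
        if (rate < 0.25) d_lnV <- max(d_lnV / 1.5, 1e-4)
      }
      box_series[cy] <- box[1]
      if (cy > equil_cycles) {
        dens_acc <- c(dens_acc, n / prod(box))
        frames[[length(frames) + 1L]] <-
          md_frame(pos - floor(pos / rep(box, each = n)) * rep(box, each = n),
                   box, time = cy * vol_every)
        log[[length(log) + 1L]] <-
          c(step = cy * vol_every, e_pot = res$e_pot[length(res$e_pot)],
            kT_kin = res$kT_kin[length(res$kT_kin)])
      }
    }
  })
  traj <- md_trajectory(topology, frames, units = params$units, wrapped = TRUE)
  traj$metadata$seed <- settings$seed
  traj$log <- as.data.frame(do.call(rbind, log))
  mean_dens <- mean(dens_acc)
  list(trajectory = traj,
       bulk_concentration = mean_dens * MM_PER_BEAD_A3,
       number_density = mean_dens,
       acceptance = if (att_tune > 0) acc_tune / att_tune else acc / max(att, 1),
       vol_step = d_lnV,
       box_series = box_series)
}
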