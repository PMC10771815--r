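# Force-field parameter container and the analytic pair-energy functions.
#
# Energy model: hydropathy-scaled (Ashbaugh-Hatch) Lennard-Jones pair
# interactions, harmonic bonds U = k (r - r0)^2, and Debye-Hueckel screened
# electrostatics for charged bead types. Directly bonded bead pairs are
# excluded from nonbonded interactions.

KCAL_PER_MOL_K <- 0.0019872041   # Boltzmann constant, kcal/mol/K
COULOMB_KCAL <- 332.0637         # q^2/(4 pi eps0), kcal*Angstrom/mol/e^2
MM_PER_BEAD_A3 <- 1.66054e6      # 1 bead/Angstrom^3 expressed in mM

#' Force-field parameters
#'
#' Per-type bead parameters plus global bonded/electrostatic constants for the
#' implicit-solvent bead-spring model. Two presets are provided through
#' `units`:
#' \describe{
#'   \item{real}{Angstrom / kcal/mol / amu. Defaults follow common
#'     residue-level coarse-grained conventions: sigma 6 A, epsilon
#'     0.2 kcal/mol, bond r0 3.8 A with k 10 kcal/mol/A^2, Debye length 10 A,
#'     dielectric 80.}
#'   \item{reduced}{sigma = epsilon = mass = 1; bond r0 1, k 100 eps/sigma^2,
#'     pair cutoff 2.5 sigma. Convenient for toy and benchmark runs.}
#' }
#' Per-type entries (`sigma`, `lambda`, `charge`, `mass`) are named vectors
#' keyed by bead type; a single unnamed value applies to every type.
#'
#' @param units `"real"` or `"reduced"`
#' @param sigma per-type bead diameter
#' @param lambda per-type hydropathy in \[0, 1.1\] scaling the attractive part
#'   of the pair potential (0 = purely repulsive, 1 = full Lennard-Jones)
#' @param charge per-type charge (elementary charges)
#' @param mass per-type mass (amu; ignored dimensionally in reduced units)
#' @param epsilon global pair energy scale
#' @param bond_k,bond_r0 harmonic bond constants, convention U = k (r - r0)^2
#' @param debye_length Debye screening length
#' @param dielectric relative dielectric constant
#' @param pair_cutoff nonbonded cutoff (must be >= 2^(1/6) max sigma)
#' @param coulomb_cutoff electrostatic cutoff
#' @return object of class `force_field`
#' @export
force_field <- function(units = c("real", "reduced"),
                        sigma = NULL, lambda = NULL, charge = NULL, mass = NULL,
                        epsilon = NULL, bond_k = NULL, bond_r0 = NULL,
                        debye_length = NULL, dielectric = NULL,
                        pair_cutoff = NULL, coulomb_cutoff = NULL) {
  units <- match.arg(units)
  d <- if (units == "real") {
    list(sigma = 6, lambda = 1, charge = 0, mass = 100, epsilon = 0.2,
         bond_k = 10, bond_r0 = 3.8, debye_length = 10, dielectric = 80,
         pair_cutoff = 20, coulomb_cutoff = 35)
  } else {
    list(sigma = 1, lambda = 1, charge = 0, mass = 1, epsilon = 1,
         bond_k = 100, bond_r0 = 1, debye_length = 1, dielectric = 1,
         pair_cutoff = 2.5, coulomb_cutoff = 2.5)
  }
  p <- list(units = units,
            sigma = sigma %||% d$sigma, lambda = lambda %||% d$lambda,
            charge = charge %||% d$charge, mass = mass %||% d$mass,
            epsilon = epsilon %||% d$epsilon,
            bond_k = bond_k %||% d$bond_k, bond_r0 = bond_r0 %||% d$bond_r0,
            debye_length = debye_length %||% d$debye_length,
            dielectric = dielectric %||% d$dielectric,
            pair_cutoff = pair_cutoff %||% d$pair_cutoff,
            coulomb_cutoff = coulomb_cutoff %||% d$coulomb_cutoff)
  if (any(p$sigma <= 0) || any(p$mass <= 0) || p$pair_cutoff <= 0 ||
      p$coulomb_cutoff <= 0)
    stop("sigma, mass and cutoffs must be strictly positive")
  if (p$pair_cutoff < 2^(1 / 6) * max(p$sigma))
    stop("pair_cutoff must be >= 2^(1/6) * max sigma")
  if (any(p$lambda < 0) || any(p$lambda > 1.1))
    stop("lambda must lie in [0, 1.1]")
  if (p$debye_length <= 0) stop("debye_length must be positive")
  structure(p, class = "force_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expand per-type parameter vectors to per-bead vectors
per_bead <- function(value, topology) {
  if (length(value) == 1L && is.null(names(value)))
    return(rep(as.numeric(value), topology$n_beads))
  if (is.null(names(value)))
    stop("per-type parameters with >1 entry must be named by bead type")
  miss <- setdiff(unique(topology$bead_types), names(value))
  if (length(miss) > 0)
    stop("no parameter value for bead type(s): ", paste(miss, collapse = ", "))
  as.numeric(value[topology$bead_types])
}

#' Simulation settings
#'
#' @param temperature real units: K; reduced units: kT in epsilon
#' @param dt time step (fs in real units, tau in reduced)
#' @param friction Langevin friction (1/ps in real units, 1/tau in reduced)
#' @param n_steps number of integration steps
#' @param save_every save a frame (and energies) every this many steps
#' @param seed integer RNG seed, recorded in the output metadata
#' @param ensemble one of `"nvt-droplet"`, `"p0-bulk"`, `"single-chain"`
#' @return object of class `sim_settings`
#' @export
sim_settings <- function(temperature, dt, friction, n_steps, save_every,
                         seed = 1L,
                         ensemble = c("nvt-droplet", "p0-bulk", "single-chain")) {
  ensemble <- match.arg(ensemble)
  if (dt <= 0 || n_steps <= 0 || save_every <= 0)
    stop("dt, n_steps and save_every must be positive")
  if (friction <= 0) stop("friction must be positive")
  structure(list(temperature = temperature, dt = dt, friction = friction,
                 n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every),
                 seed = as.integer(seed), ensemble = ensemble),
            class = "sim_settings")
}

# internal-unit conversions (F = m a consistent system):
# real units use Angstrom, kcal/mol, amu; the derived time unit is
# sqrt(amu A^2 mol/kcal) = 48.88821 fs.
TIME_UNIT_FS <- 48.88821
internal_units <- function(params, settings) {
  if (params$units == "real") {
    list(kT = KCAL_PER_MOL_K * settings$temperature,
         dt = settings$dt / TIME_UNIT_FS,
         gamma = settings$friction * TIME_UNIT_FS / 1000)
  } else {
    list(kT = settings$temperature, dt = settings$dt, gamma = settings$friction)
  }
}

#' Hydropathy-scaled Lennard-Jones (Ashbaugh-Hatch) pair energy
#'
#' For separations up to the Lennard-Jones minimum `2^(1/6) sigma` the energy
#' is `U_LJ(r) + (1 - lambda) epsilon`;
#' beyond the minimum it is `lambda * U_LJ(r)`. The form is continuous at the
#' minimum; with a finite `cutoff` the attractive branch value at the cutoff
#' is subtracted so the potential vanishes there.
#'
#' @param r separation (> 0); vectorized
#' @param sigma bead diameter
#' @param epsilon pair energy scale
#' @param lambda hydropathy in \[0, 1.1\]
#' @param cutoff cutoff distance; `Inf` (default) gives the unshifted form
#' @return energy, same units as `epsilon`
#' @export
ashbaugh_hatch_energy <- function(r, sigma, epsilon, lambda, cutoff = Inf) {
  if (any(r <= 0)) stop("r must be positive")
  ulj <- function(r) 4 * epsilon * ((sigma / r)^12 - (sigma / r)^6)
  shift <- if (is.finite(cutoff)) lambda * ulj(cutoff) else 0
  rmin <- 2^(1 / 6) * sigma
  out <- ifelse(r <= rmin,
                ulj(r) + (1 - lambda) * epsilon - shift,
                lambda * ulj(r) - shift)
  if (is.finite(cutoff)) out[r >= cutoff] <- 0
  out
}

#' Harmonic bond energy, convention U = k (r - r0)^2
#' @param r bond length (>= 0); vectorized
#' @param k force constant (energy / length^2)
#' @param r0 equilibrium length
#' @export
harmonic_bond_energy <- function(r, k, r0) {
  if (any(r < 0)) stop("r must be non-negative")
  k * (r - r0)^2
}

#' Debye-Hueckel screened electrostatic pair energy
#' @param r separation (> 0); vectorized
#' @param qi,qj charges in elementary charges
#' @param debye_length screening length (> 0)
#' @param dielectric relative dielectric constant
#' @param cutoff cutoff; `Inf` gives the unshifted form
#' @return energy in kcal/mol (real-unit constant)
#' @export
debye_huckel_energy <- function(r, qi, qj, debye_length, dielectric = 80,
                                cutoff = Inf) {
  if (any(r <= 0)) stop("r must be positive")
  if (debye_length <= 0) stop("debye_length must be positive")
  pref <- COULOMB_KCAL / dielectric
  u <- pref * qi * qj / r * exp(-r / debye_length)
  if (is.finite(cutoff)) {
    u <- u - pref * qi * qj / cutoff * exp(-cutoff / debye_length)
    u[r >= cutoff] <- 0
  }
  u
}

#' Forces and potential energy of a configuration
#'
#' Assembles all force-field terms (pair, bond, electrostatic) under the
#' minimum-image convention and returns per-bead forces together with the
#' total potential energy and its components. Pairwise interactions only, so
#' the force vectors sum to zero.
#'
#' @param frame an `md_frame`
#' @param topology matching `chain_topology`
#' @param params a `force_field`
#' @param neighbor `"auto"` (cell list when the box is large enough),
#'   `"brute"`, or `"cell"`
#' @return list with `forces` (n x 3), `energy`, `e_pair`, `e_bond`, `e_coul`
#' @export
compute_forces <- function(frame, topology, params, neighbor = "auto") {
  stopifnot(inherits(frame, "md_frame"), inherits(params, "force_field"))
  validate_topology(topology)
  if (nrow(frame$positions) != topology$n_beads)
    stop("frame/topology bead count mismatch")
  nb <- match(match.arg(neighbor, c("auto", "brute", "cell")),
              c("auto", "brute", "cell")) - 1L
  res <- cpp_forces(frame$positions, frame$box, topology$chain_id,
                    per_bead(params$sigma, topology),
                    per_bead(params$lambda, topology),
                    per_bead(params$charge, topology),
                    params$epsilon, params$bond_k, params$bond_r0,
                    params$debye_length, COULOMB_KCAL / params$dielectric,
                    params$pair_cutoff, params$coulomb_cutoff,
                    TRUE, nb)
  res
}

potential_energy <- function(positions, box, topology, params) {
  cpp_forces(positions, box, topology$chain_id,
             per_bead(params$sigma, topology),
             per_bead(params$lambda, topology),
             per_bead(params$charge, topology),
             params$epsilon, params$bond_k, params$bond_r0,
             params$debye_length, COULOMB_KCAL / params$dielectric,
             params$pair_cutoff, params$coulomb_cutoff,
             FALSE, 0L)$energy
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
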