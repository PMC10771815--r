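# Synthetic droplet configurations with planted statistical structure.
#
# The generator builds non-interacting Gaussian chains whose centre-of-mass
# radii follow a prescribed tanh density profile, with optional planted
# radial compactness modulation, end-segment enrichment at the interface and
# segment orientation modes. Every planted value is recorded in the
# trajectory metadata, so each analysis stage has a known ground truth to
# recover.

#' Sample an ideal (Gaussian) chain
#'
#' Chain with i.i.d. Gaussian bond vectors of root-mean-square length `b`.
#' The mean squared radius of gyration of such a chain is
#' `b^2 (n^2 - 1) / (6 n)`.
#'
#' @param n number of beads (>= 2)
#' @param b RMS bond length
#' @param seed optional seed (restores the caller's RNG state)
#' @return n x 3 coordinate matrix (first bead at the origin)
#' @export
sample_gaussian_chain <- function(n, b, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  gen <- function() {
    steps <- matrix(stats::rnorm((n - 1) * 3, sd = b / sqrt(3)), ncol = 3)
    rbind(0, apply(steps, 2, cumsum))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Specification for a synthetic droplet
#'
#' @param chain_length beads per chain
#' @param b RMS bond length
#' @param c_dense,c_dilute,d_mid,delta planted tanh density profile (mM, mM,
#'   length, length); `c_dense > c_dilute >= 0`, `delta > 0`
#' @param n_chains chains per frame; `NULL` (default) derives the count that
#'   realizes the requested concentrations exactly (recommended — with an
#'   explicit count the planted concentrations are rescaled accordingly and
#'   the rescaled values are what the truth metadata records)
#' @param rg_scale_profile optional piecewise-linear compactness modulation:
#'   a list with knots `d` (radii, increasing) and `s` (scale factors);
#'   chains at radius r are scaled by the interpolated s(r). `NULL` = 1
#'   everywhere
#' @param end_enrichment strength (>= 0) of the bias that turns a chain end
#'   radially outward for chains inside the interface band, enriching
#'   terminal segments there while leaving the density profile unchanged
#' @param orientation_mode `"isotropic"`, `"tangential"` or `"radial"`
#'   planted chain end-to-end orientation relative to the droplet radius
#' @param seed RNG seed
#' @return object of class `synthetic_droplet_spec`
#' @export
synthetic_droplet_spec <- function(chain_length = 20, b = 1.5,
                                   c_dense = 500, c_dilute = 0,
                                   d_mid = 60, delta = 12,
                                   n_chains = NULL,
                                   rg_scale_profile = NULL,
                                   end_enrichment = 0,
                                   orientation_mode = c("isotropic",
                                                        "tangential", "radial"),
                                   seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  if (c_dense <= c_dilute || c_dilute < 0) stop("need c_dense > c_dilute >= 0")
  if (delta <= 0 || d_mid <= 0 || b <= 0) stop("lengths must be positive")
  if (end_enrichment < 0) stop("end_enrichment must be >= 0")
  if (!is.null(rg_scale_profile)) {
    if (is.unsorted(rg_scale_profile$d, strictly = TRUE))
      stop("rg_scale_profile$d knots must be increasing")
    if (any(rg_scale_profile$s <= 0)) stop("rg_scale factors must be positive")
  }
  structure(list(chain_length = as.integer(chain_length), b = b,
                 c_dense = c_dense, c_dilute = c_dilute,
                 d_mid = d_mid, delta = delta, n_chains = n_chains,
                 rg_scale_profile = rg_scale_profile,
                 end_enrichment = end_enrichment,
                 orientation_mode = orientation_mode,
                 seed = as.integer(seed)),
            class = "synthetic_droplet_spec")
}

tanh_profile_fun <- function(c_dense, c_dilute, d_mid, delta) {
  function(d) (c_dense + c_dilute) / 2 -
    (c_dense - c_dilute) / 2 * tanh((d - d_mid) / delta)
}

# Rodrigues rotation taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {     # antiparallel: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Generate a synthetic droplet trajectory
#'
#' Draws, per frame, chain centre-of-mass radii from the density
#' `p(r) dr \propto r^2 c(r) dr` with `c` the planted tanh profile, attaches
#' independently sampled Gaussian chains (scaled by the planted compactness
#' profile, oriented per the planted mode, optionally end-enriched at the
#' interface), and returns a trajectory whose metadata records every planted
#' value under `$metadata$truth`.
#'
#' @param spec a [synthetic_droplet_spec()]
#' @param n_frames number of independent frames
#' @return `md_trajectory` (reduced length units); metadata field `truth`
#'   holds the planted parameters actually realized (concentrations rescaled
#'   if an explicit `n_chains` was forced)
#' @export
generate_synthetic_droplet <- function(spec, n_frames = 1) {
  stopifnot(inherits(spec, "synthetic_droplet_spec"))
  r_max <- spec$d_mid + 6 * spec$delta
  cfun <- tanh_profile_fun(spec$c_dense, spec$c_dilute, spec$d_mid, spec$delta)
  # beads implied by the requested absolute concentrations
  n_req <- stats::integrate(function(r) cfun(r) / MM_PER_BEAD_A3 * 4 * pi * r^2,
                            0, r_max, rel.tol = 1e-8)$value
  n_chains <- spec$n_chains %||% max(1L, round(n_req / spec$chain_length))
  scale_c <- n_chains * spec$chain_length / n_req
  topo <- build_linear_topology(n_chains, spec$chain_length)
  box <- rep(2 * (r_max + 6 * spec$b * sqrt(spec$chain_length)), 3)
  centre <- box / 2
  band <- interface_bounds(list(d_mid = spec$d_mid, delta = spec$delta), 0.8)
  p_flip <- spec$end_enrichment / (1 + spec$end_enrichment)
  # a radially aligned chain's terminal segments sit about 0.4 Re outward of
  # its COM, so chains eligible for the end-outward rotation are selected
  # from the shell just below the interface band (displaced inward by that
  # offset and capped at the inner bound): their rotated outward ends reach
  # into the band while their middles stay below it, and since rotation
  # about the chain COM moves no centre of mass the density profile is
  # untouched
  re_off <- 0.4 * spec$b * sqrt(spec$chain_length - 1)
  sel_lo <- band[1] - re_off
  sel_hi <- min(band[2] - re_off, band[1])
  sfun <- if (is.null(spec$rg_scale_profile)) function(r) rep(1, length(r))
  else function(r) stats::approx(spec$rg_scale_profile$d, spec$rg_scale_profile$s,
                                 xout = r, rule = 2)$y
  cmax <- cfun(0)

  frames <- with_seed(spec$seed, {
    lapply(seq_len(n_frames), function(f) {
      pos <- matrix(NA_real_, topo$n_beads, 3)
      for (ch in seq_len(n_chains)) {
        # rejection-sample the COM radius from r^2 c(r)
        repeat {
          r <- r_max * stats::runif(1)^(1 / 3)
          if (stats::runif(1) < cfun(r) / cmax) break
        }
        dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
        p <- sample_gaussian_chain(spec$chain_length, spec$b)
        p <- sweep(p, 2, colMeans(p))          # COM at origin
        p <- p * sfun(r)                       # planted compactness
        ev <- p[nrow(p), ] - p[1, ]
        evn <- sqrt(sum(ev^2))
        target <- NULL
        if (r >= sel_lo && r <= sel_hi && stats::runif(1) < p_flip) {
          # turn a random chain end radially outward
          target <- dirv * sample(c(-1, 1), 1)
        } else if (spec$orientation_mode == "radial") {
          target <- dirv * sample(c(-1, 1), 1)
        } else if (spec$orientation_mode == "tangential") {
          w <- stats::rnorm(3)
          w <- w - sum(w * dirv) * dirv
          target <- w / sqrt(sum(w^2))
        }
        if (!is.null(target) && evn > 1e-10)
          p <- p %*% t(rotation_between(ev / evn, target))
        rows <- (ch - 1) * spec$chain_length + seq_len(spec$chain_length)
        pos[rows, ] <- sweep(p, 2, centre + r * dirv, `+`)
      }
      md_frame(pos, box, time = f)
    })
  })
  traj <- md_trajectory(topo, frames, units = "reduced", wrapped = TRUE)
  traj$metadata$truth <- list(
    c_dense = spec$c_dense * scale_c, c_dilute = spec$c_dilute * scale_c,
    d_mid = spec$d_mid, delta = spec$delta, r_max = r_max,
    n_chains = n_chains, chain_length = spec$chain_length, b = spec$b,
    rg_scale_profile = spec$rg_scale_profile,
    end_enrichment = spec$end_enrichment,
    orientation_mode = spec$orientation_mode,
    interface_band = band, seed = spec$seed)
  traj
}

#' Synthetic noisy tanh density profile
#'
#' Evaluates the tanh profile at bin centres and applies multiplicative
#' Gaussian noise of relative standard deviation `noise_frac`. Negative
#' concentrations after noise are clipped to 0 (flagged in attribute
#' `"clipped"`). The returned object is a regular `density_profile`, so it
#' feeds straight into [fit_tanh_profile()] for recovery tests.
#'
#' @param c_dense,c_dilute,d_mid,delta tanh parameters
#' @param noise_frac relative noise SD (0 = exact curve)
#' @param n_bins number of radial bins
#' @param r_max profile extent (default `d_mid + 5 delta`)
#' @param seed optional seed
#' @return `density_profile`
#' @export
generate_noisy_profile <- function(c_dense, c_dilute, d_mid, delta,
                                   noise_frac = 0.02, n_bins = 60,
                                   r_max = NULL, seed = NULL) {
  if (c_dense <= c_dilute || c_dilute < 0) stop("need c_dense > c_dilute >= 0")
  if (delta <= 0) stop("delta must be positive")
  if (is.null(r_max)) r_max <- d_mid + 5 * delta
  edges <- seq(0, r_max, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  cfun <- tanh_profile_fun(c_dense, c_dilute, d_mid, delta)
  vals <- cfun(mids)
  if (noise_frac > 0) {
    noise <- if (is.null(seed)) stats::rnorm(n_bins) else
      with_seed(seed, stats::rnorm(n_bins))
    vals <- vals * (1 + noise_frac * noise)
  }
  clipped <- vals < 0
  vals[clipped] <- 0
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(n_bins + 1)]^3)
  prof <- structure(list(bin_edges = edges,
                         counts = vals / MM_PER_BEAD_A3 * shell_vol,
                         concentration = vals, n_frames = 1,
                         beads_in_scope = NA_real_, n_outside = 0),
                    class = "density_profile")
  attr(prof, "clipped") <- any(clipped)
  prof
}
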