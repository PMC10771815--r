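# Droplet location, radial concentration profile, hyperbolic-tangent
# interface fit, and sphericity diagnostics.

#' Largest connected cluster of chains
#'
#' Chains are nodes; an edge joins two chains when any inter-chain bead pair
#' lies within `cluster_cutoff` under the minimum-image convention. Returns
#' the chain ids of the largest connected component; among equally sized
#' components the one containing the lowest chain id wins, so the result is
#' deterministic.
#'
#' @param frame `md_frame`
#' @param topology `chain_topology`
#' @param cluster_cutoff contact distance defining chain-chain adjacency
#' @return sorted integer vector of chain ids
#' @export
find_largest_cluster <- function(frame, topology, cluster_cutoff) {
  if (cluster_cutoff <= 0) stop("cluster_cutoff must be positive")
  validate_topology(topology)
  method <- if (topology$n_beads > 256 && all(frame$box >= 3 * cluster_cutoff))
    "cell" else "brute"
  prs <- cpp_pair_list(frame$positions, frame$box, cluster_cutoff, method)
  ci <- topology$chain_id[prs[, 1]]
  cj <- topology$chain_id[prs[, 2]]
  keep <- ci != cj
  comp <- union_find(topology$n_chains, cbind(ci[keep], cj[keep]))
  sizes <- tabulate(comp, nbins = topology$n_chains)
  best <- which(sizes == max(sizes))
  # tie rule: component containing the smallest chain id
  if (length(best) > 1) {
    firsts <- vapply(best, function(b) min(which(comp == b)), integer(1))
    best <- best[which.min(firsts)]
  }
  sort(which(comp == best))
}

# union-find over n nodes given an edge matrix; returns component labels
union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Periodicity-safe droplet centre of mass
#'
#' Computes the (mass-weighted) centre of a bead set under periodic
#' boundaries: a circular mean per axis locates the cluster even when it
#' straddles the box boundary, followed by a minimum-image refinement about
#' that estimate. Translation-equivariant modulo the box.
#'
#' @param frame `md_frame`
#' @param beads integer indices of the beads in scope (e.g. the largest
#'   cluster); default all
#' @param weights optional per-bead masses
#' @return length-3 centre, inside the box
#' @export
droplet_center <- function(frame, beads = NULL, weights = NULL) {
  pos <- frame$positions
  if (!is.null(beads)) {
    if (length(beads) == 0) stop("empty bead set")
    pos <- pos[beads, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[beads]
  }
  if (nrow(pos) == 0) stop("empty bead set")
  w <- if (is.null(weights)) rep(1, nrow(pos)) else weights / sum(weights) * nrow(pos)
  box <- frame$box
  ctr <- numeric(3)
  for (k in 1:3) {
    th <- 2 * pi * pos[, k] / box[k]
    ang <- atan2(sum(w * sin(th)), sum(w * cos(th)))
    ctr[k] <- (ang / (2 * pi)) * box[k]
  }
  # refine twice with minimum-image displacements about the current estimate
  for (it in 1:2) {
    d <- sweep(pos, 2, ctr)
    d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
    ctr <- ctr + colSums(d * w) / sum(w)
  }
  ctr - floor(ctr / box) * box
}

min_image_disp <- function(pos, centre, box) {
  d <- sweep(pos, 2, centre)
  d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
}

#' Radial concentration profile of a droplet
#'
#' Accumulates, over frames, a histogram of bead distances from the
#' (per-frame, recomputed) droplet centre, and converts shell counts to
#' molar concentrations: 1 bead/Angstrom^3 = 1.66054e6 mM. When
#' `cluster_cutoff` is given, only beads of the largest chain cluster define
#' the centre, while all beads are binned (so a dilute phase contributes to
#' the outer bins).
#'
#' @param traj `md_trajectory`
#' @param bin_width radial bin width (default 5)
#' @param r_max outer edge of the profile; default half the smallest box edge
#' @param cluster_cutoff optional chain-cluster cutoff for droplet detection
#' @param center optional fixed droplet centre (length 3) overriding the
#'   per-frame estimate
#' @return object of class `density_profile`: `bin_edges`, `counts`
#'   (time-accumulated), `concentration` (mM), `n_frames`, `beads_in_scope`,
#'   `n_outside` (beads beyond `r_max`, kept for the count-conservation
#'   invariant)
#' @export
radial_concentration_profile <- function(traj, bin_width = 5, r_max = NULL,
                                         cluster_cutoff = NULL,
                                         center = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (bin_width <= 0) stop("bin_width must be positive")
  box0 <- traj$frames[[1]]$box
  if (is.null(r_max)) r_max <- min(box0) / 2
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  n_outside <- 0
  total_in_scope <- 0
  for (fr in traj$frames) {
    beads <- seq_len(nrow(fr$positions))
    if (is.null(center)) {
      cl_beads <- beads
      if (!is.null(cluster_cutoff)) {
        cl <- find_largest_cluster(fr, traj$topology, cluster_cutoff)
        cl_beads <- which(traj$topology$chain_id %in% cl)
      }
      ctr <- droplet_center(fr, cl_beads)
    } else {
      ctr <- as.numeric(center)
    }
    d <- sqrt(rowSums(min_image_disp(fr$positions, ctr, fr$box)^2))
    idx <- findInterval(d, edges, rightmost.closed = FALSE)
    ok <- idx >= 1 & idx <= nb
    counts <- counts + tabulate(idx[ok], nbins = nb)
    n_outside <- n_outside + sum(!ok)
    total_in_scope <- total_in_scope + length(beads)
  }
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  conc <- counts / (length(traj$frames) * shell_vol) * MM_PER_BEAD_A3
  structure(list(bin_edges = edges, counts = counts, concentration = conc,
                 n_frames = length(traj$frames),
                 beads_in_scope = total_in_scope, n_outside = n_outside),
            class = "density_profile")
}

bin_centers <- function(profile) {
  e <- profile$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Fit the hyperbolic-tangent interface profile
#'
#' Fits the radial concentration profile to
#' \deqn{c(d) = \frac{c_{dense}+c_{dilute}}{2} -
#'       \frac{c_{dense}-c_{dilute}}{2}\tanh\!\big((d-d_{mid})/\delta\big)}
#' by Levenberg-Marquardt least squares. `c_dense` and `c_dilute` are the
#' dense- and dilute-phase concentrations, `d_mid` the interface midpoint and
#' `delta` its width; the radius at which the concentration falls to half its
#' central value (`r_half`) equals `d_mid` by the functional form. Start
#' values come from profile quantiles (inner 20% of bins for `c_dense`,
#' outer 10% for `c_dilute`, first bin below the midpoint concentration for
#' `d_mid`, a tenth of that for `delta`). A fitted `c_dilute` below zero is
#' clipped to 0 and flagged.
#'
#' @param profile a `density_profile` (at least 8 bins spanning a decline)
#' @param coverage passed to [interface_bounds()] for the derived bounds
#' @param weighting `"poisson"` (default) weights each bin by the inverse
#'   count variance — appropriate for profiles accumulated from bead counts,
#'   where the tiny innermost shells hold few beads and would otherwise
#'   dominate the residuals; `"none"` gives ordinary unweighted least squares
#'   (appropriate when bin noise is multiplicative)
#' @return object of class `interface_fit`: parameters, standard
#'   uncertainties, `r_half`, `inner_bound`, `outer_bound`, `residual_norm`,
#'   `clipped_dilute` flag and the underlying `nls` fit
#' @export
fit_tanh_profile <- function(profile, coverage = 0.8,
                             weighting = c("poisson", "none")) {
  stopifnot(inherits(profile, "density_profile"))
  weighting <- match.arg(weighting)
  d <- bin_centers(profile)
  y <- profile$concentration
  w <- rep(1, length(d))
  if (weighting == "poisson" && !is.null(profile$counts) &&
      !anyNA(profile$counts)) {
    shell_vol <- 4 / 3 * pi * diff(profile$bin_edges^3)
    # concentration contributed by a single bead-count in each shell
    u <- MM_PER_BEAD_A3 / (profile$n_frames * shell_vol)
    w <- 1 / (u^2 * pmax(profile$counts, 1))
    # normalize and floor the relative weight so the tiny innermost shells
    # are strongly but not infinitely downweighted (keeps the weighted
    # Jacobian well conditioned)
    w <- pmax(w / max(w), 1e-6)
  }
  if (length(d) < 8) stop("profile must have at least 8 bins")
  n <- length(d)
  c_dense0 <- mean(y[seq_len(max(1, floor(0.2 * n)))])
  c_dilute0 <- mean(y[seq(ceiling(0.9 * n), n)])
  midc <- (c_dense0 + c_dilute0) / 2
  below <- which(y < midc)
  d_mid0 <- if (length(below) > 0) d[below[1]] else stats::median(d)
  delta0 <- max(0.1 * d_mid0, diff(d[1:2]))
  if (c_dense0 <= c_dilute0)
    stop("profile does not decline: cannot initialize interface fit")
  dat <- data.frame(d = d, y = y, w = w)
  start <- list(c_dense = c_dense0, c_dilute = c_dilute0,
                d_mid = d_mid0, delta = delta0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (c_dense + c_dilute) / 2 - (c_dense - c_dilute) / 2 *
        tanh((d - d_mid) / delta),
      data = dat, start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("interface fit did not converge (", conditionMessage(e),
           "); start values were c_dense=", signif(c_dense0, 4),
           " c_dilute=", signif(c_dilute0, 4), " d_mid=", signif(d_mid0, 4),
           " delta=", signif(delta0, 4)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  clipped <- FALSE
  if (cf[["c_dilute"]] < 0) {
    warning("fitted c_dilute < 0; clipped to 0")
    cf[["c_dilute"]] <- 0
    clipped <- TRUE
  }
  if (cf[["delta"]] < 0) cf[["delta"]] <- abs(cf[["delta"]])  # tanh symmetry
  bounds <- c(cf[["d_mid"]] - cf[["delta"]] * atanh(coverage),
              cf[["d_mid"]] + cf[["delta"]] * atanh(coverage))
  structure(list(
    c_dense = cf[["c_dense"]], c_dilute = cf[["c_dilute"]],
    d_mid = cf[["d_mid"]], delta = cf[["delta"]],
    param_uncertainties = se,
    r_half = cf[["d_mid"]],
    inner_bound = bounds[1], outer_bound = bounds[2],
    coverage = coverage,
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    clipped_dilute = clipped,
    nls = fit
  ), class = "interface_fit")
}

#' @export
print.interface_fit <- function(x, ...) {
  cat(sprintf(paste0("interface_fit: c_dense=%.4g  c_dilute=%.4g  ",
                     "d_mid=%.4g  delta=%.4g\n  interface region [%.4g, %.4g]",
                     " (coverage %.2f)%s\n"),
              x$c_dense, x$c_dilute, x$d_mid, x$delta,
              x$inner_bound, x$outer_bound, x$coverage,
              if (x$clipped_dilute) "  [c_dilute clipped to 0]" else ""))
  invisible(x)
}

#' Interface region bounds
#'
#' The interface region is where the tanh profile traverses the central
#' `coverage` fraction of the dense-dilute concentration difference:
#' `d_mid -/+ delta * atanh(coverage)`. The default 0.8 corresponds to the
#' common 10-90 convention.
#'
#' @param fit an `interface_fit` (or any list with `d_mid`, `delta`)
#' @param coverage fraction in (0, 1)
#' @return named vector `c(inner, outer)`
#' @export
interface_bounds <- function(fit, coverage = 0.8) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  h <- fit$delta * atanh(coverage)
  c(inner = fit$d_mid - h, outer = fit$d_mid + h)
}

#' Asphericity of a bead cloud
#'
#' From the ordered gyration-tensor eigenvalues l1 >= l2 >= l3:
#' `b = ((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / (2 (l1+l2+l3)^2)`,
#' which is 0 for a sphere and 1 for a rod.
#'
#' @param frame `md_frame` (or an n x 3 matrix)
#' @param beads optional bead subset (>= 4 beads)
#' @return asphericity in \[0, 1\]; attribute `"degenerate"` flags
#'   (near-)collinear input
#' @export
asphericity <- function(frame, beads = NULL) {
  pos <- if (inherits(frame, "md_frame")) frame$positions else as.matrix(frame)
  if (!is.null(beads)) pos <- pos[beads, , drop = FALSE]
  if (nrow(pos) < 4) stop("asphericity needs at least 4 beads")
  cen <- colMeans(pos)
  x <- sweep(pos, 2, cen)
  gt <- crossprod(x) / nrow(x)
  l <- sort(eigen(gt, symmetric = TRUE, only.values = TRUE)$values,
            decreasing = TRUE)
  b <- ((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) /
    (2 * sum(l)^2)
  b <- min(max(b, 0), 1)
  attr(b, "degenerate") <- l[2] / l[1] < 1e-8
  b
}
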