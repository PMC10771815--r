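# Segment orientation relative to the droplet radius.
#
# theta is the angle between the segment-to-droplet-centre vector and the
# segment end-to-end vector, folded into [pi/2, pi]: pi/2 means the segment
# lies tangential to the droplet surface, pi means perpendicular to it. For
# randomly oriented segments the mean folded angle is pi - 1.

#' Folded angle between two vectors
#'
#' Raw angle in \[0, pi\], folded as `max(theta, pi - theta)` so the result
#' lies in \[pi/2, pi\]. The fold makes the angle insensitive to the sign of
#' either vector, as required when a segment has no head or tail.
#'
#' @param u,v nonzero 3-vectors
#' @return angle in radians in \[pi/2, pi\]
#' @export
folded_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("folded_angle: zero vector")
  th <- acos(max(-1, min(1, sum(u * v) / (nu * nv))))
  max(th, pi - th)
}

# vectorized fold for row-matrices of u and v
folded_angle_rows <- function(u, v) {
  cosd <- rowSums(u * v) /
    (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  th <- acos(pmax(-1, pmin(1, cosd)))
  pmax(th, pi - th)
}

#' Mean folded angle of isotropically oriented segments
#'
#' Closed form of the sin-weighted mean over the folded range,
#' `int_{pi/2}^{pi} theta sin(theta) dtheta / int_{pi/2}^{pi} sin(theta)
#' dtheta`, which evaluates to `pi - 1` (about 2.1416 rad). This is the
#' reference line against which measured angle profiles are compared.
#'
#' @return radians
#' @export
isotropic_mean_angle <- function() {
  num <- (sin(pi) - pi * cos(pi)) - (sin(pi / 2) - (pi / 2) * cos(pi / 2))
  den <- cos(pi / 2) - cos(pi)
  num / den
}

#' Geometric lower bound on the folded segment angle
#'
#' A segment with end-to-end distance `re` whose terminal bead sits at
#' distance `R` from the droplet centre, with the whole segment confined to
#' the ball of radius `R`, cannot make a folded angle (measured at that
#' terminal bead) smaller than `pi/2 + asin(re / (2 R))` — the chord
#' geometry of a sphere. The bound decreases toward pi/2 (tangential) as
#' `R/re` grows and reaches pi for a diametral chord (`re = 2R`).
#'
#' @param R distance from the terminal bead to the droplet centre (> 0);
#'   vectorized
#' @param re segment end-to-end distance, `0 <= re <= 2 R`
#' @return radians in \[pi/2, pi\]
#' @export
theta_min <- function(R, re) {
  if (any(R <= 0)) stop("R must be positive")
  if (any(re < 0)) stop("re must be non-negative")
  if (any(re > 2 * R)) stop("re > 2R: chord longer than the sphere diameter")
  pi / 2 + asin(re / (2 * R))
}

#' Per-segment orientation records
#'
#' For every contiguous segment of length `n_seg` in every chain and frame:
#' the folded angle between the segment-to-droplet-centre vector and the
#' segment end-to-end vector, together with the segment's radial position and
#' position class. Segments with a degenerate (near-zero) end-to-end vector
#' are skipped and counted in the `"skipped"` attribute rather than assigned
#' an arbitrary angle.
#'
#' @param traj `md_trajectory`
#' @param n_seg segment length (>= 2)
#' @param fit optional `interface_fit` for region labels
#' @param cluster_cutoff optional cluster cutoff for droplet detection
#' @param origin `"com"`: the centre vector originates at the segment COM
#'   (default); `"terminal"`: at the segment's outermost terminal bead (the
#'   construction used by the [theta_min()] estimate)
#' @param re_floor minimum end-to-end distance below which a record is
#'   skipped
#' @param center optional fixed droplet centre overriding the estimate
#' @return data frame `frame_id`, `chain_id`, `n_seg`, `start`,
#'   `segment_index`, `d_com`, `theta`, `position_class` (plus `region` with
#'   a fit); attribute `"skipped"` counts dropped degenerate segments
#' @export
orientation_records <- function(traj, n_seg, fit = NULL, cluster_cutoff = NULL,
                                origin = c("com", "terminal"),
                                re_floor = 1e-8, center = NULL) {
  origin <- match.arg(origin)
  if (n_seg < 2) stop("orientation needs n_seg >= 2")
  topo <- traj$topology
  if (any(n_seg > topo$chain_lengths)) stop("n_seg exceeds chain length")
  ctr <- frame_centers(traj, cluster_cutoff, center)
  recs <- vector("list", length(traj$frames) * topo$n_chains)
  k <- 0L
  skipped <- 0L
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    up <- unwrap_chains(fr, topo)
    idx <- 0L
    for (ch in seq_len(topo$n_chains)) {
      len <- topo$chain_lengths[ch]
      rows <- idx + seq_len(len)
      p <- up[rows, , drop = FALSE]
      ws <- window_stats(p, n_seg)
      seg <- enumerate_segments(len, n_seg)
      # displacement of segment COM from the centre, minimum image
      disp <- min_image_disp(ws$com, ctr[[i]]$center, fr$box)
      d_com <- sqrt(rowSums(disp^2))
      if (origin == "com") {
        u <- -disp                       # segment COM -> droplet centre
      } else {
        i0 <- seg$start; i1 <- seg$start + n_seg - 1
        d0 <- min_image_disp(p[i0, , drop = FALSE], ctr[[i]]$center, fr$box)
        d1 <- min_image_disp(p[i1, , drop = FALSE], ctr[[i]]$center, fr$box)
        outer_is_last <- rowSums(d1^2) >= rowSums(d0^2)
        u <- -ifelse(matrix(outer_is_last, nrow(d1), 3), d1, d0)
      }
      keep <- ws$re > re_floor & d_com > re_floor
      skipped <- skipped + sum(!keep)
      if (any(keep)) {
        k <- k + 1L
        recs[[k]] <- data.frame(
          frame_id = i, chain_id = ch, n_seg = n_seg,
          start = seg$start[keep], segment_index = seg$segment_index[keep],
          d_com = d_com[keep],
          theta = folded_angle_rows(u[keep, , drop = FALSE],
                                    ws$re_vec[keep, , drop = FALSE]),
          position_class = position_class(seg$start, seg$segment_index,
                                          len, n_seg)[keep])
      }
      idx <- idx + len
    }
  }
  out <- do.call(rbind, recs[seq_len(k)])
  if (!is.null(fit)) out$region <- assign_region(out$d_com, fit)
  attr(out, "skipped") <- skipped
  out
}

#' Mean segment angle versus radial position
#'
#' Per-bin mean folded angle with standard errors, for all segments or the
#' end/middle subsets; the isotropic reference `pi - 1` is attached as the
#' `"isotropic_reference"` attribute. Bins with fewer than `min_count`
#' records are absent.
#'
#' @param records data frame from [orientation_records()]
#' @param bin_edges radial bin edges
#' @param subset `"all"`, `"end"` or `"middle"`
#' @param min_count minimum records per reported bin
#' @return data frame `bin_lo`, `bin_hi`, `d_mid_bin`, `count`, `mean_theta`,
#'   `se_theta`
#' @export
angle_profile <- function(records, bin_edges, subset = c("all", "end", "middle"),
                          min_count = 1) {
  subset <- match.arg(subset)
  r <- if (subset == "all") records else
    records[records$position_class == subset, ]
  idx <- findInterval(r$d_com, bin_edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx < length(bin_edges)
  r <- r[ok, ]; idx <- idx[ok]
  bins <- sort(unique(idx))
  out <- data.frame(
    bin_lo = bin_edges[bins], bin_hi = bin_edges[bins + 1],
    d_mid_bin = (bin_edges[bins] + bin_edges[bins + 1]) / 2,
    count = vapply(bins, function(b) sum(idx == b), numeric(1)),
    mean_theta = vapply(bins, function(b) mean(r$theta[idx == b]), numeric(1)),
    se_theta = vapply(bins, function(b) stats::sd(r$theta[idx == b]) /
                        sqrt(sum(idx == b)), numeric(1)))
  out <- out[out$count >= min_count, ]
  attr(out, "isotropic_reference") <- isotropic_mean_angle()
  out
}
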