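# Chain- and segment-level conformational statistics as a function of the
# distance from the droplet centre of mass (d_com).

#' Unwrap chains across periodic boundaries
#'
#' Rebuilds each chain by walking its bonds and applying the minimum-image
#' convention to every bond vector, so that chain geometry (Rg, Re, segment
#' statistics) can be computed without periodic artefacts. Assumes every bond
#' is shorter than half the box.
#'
#' @param frame `md_frame`
#' @param topology `chain_topology`
#' @return n x 3 matrix of unwrapped coordinates (chains are contiguous in
#'   space; absolute positions keep each chain's first bead fixed)
#' @export
unwrap_chains <- function(frame, topology) {
  pos <- frame$positions
  box <- frame$box
  out <- pos
  idx <- 0L
  for (ch in seq_len(topology$n_chains)) {
    len <- topology$chain_lengths[ch]
    rows <- idx + seq_len(len)
    p <- pos[rows, , drop = FALSE]
    if (len > 1) {
      d <- diff(p)
      d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
      out[rows, ] <- rbind(p[1, ], p[rep(1, len - 1), , drop = FALSE] +
                             apply(d, 2, cumsum))
    }
    idx <- idx + len
  }
  out
}

#' Radius of gyration of one chain
#'
#' `Rg^2 = (1/N) sum_i |r_i - r_com|^2` over the N beads of the chain
#' (equal masses). The chain must be unwrapped first; if a box is supplied,
#' any bond longer than half the box raises an error instructing to unwrap.
#'
#' @param positions n x 3 matrix of one chain's bead coordinates
#' @param box optional box edges used only for the wrapped-chain check
#' @return Rg (same length unit as the input)
#' @export
chain_rg <- function(positions, box = NULL) {
  positions <- as.matrix(positions)
  if (!is.null(box) && nrow(positions) > 1) {
    bl <- sqrt(rowSums(diff(positions)^2))
    if (any(bl > min(box) / 2))
      stop("chain appears wrapped across the periodic boundary ",
           "(a bond exceeds box/2); unwrap with unwrap_chains() first")
  }
  cen <- colMeans(positions)
  sqrt(mean(rowSums(sweep(positions, 2, cen)^2)))
}

#' End-to-end distance of a chain (first to last bead)
#' @param positions n x 3 matrix of one (unwrapped) chain
#' @export
chain_re <- function(positions) {
  positions <- as.matrix(positions)
  sqrt(sum((positions[nrow(positions), ] - positions[1, ])^2))
}

# per-frame droplet centres (and cluster memberships); shared by the
# record builders
frame_centers <- function(traj, cluster_cutoff = NULL, center = NULL) {
  lapply(traj$frames, function(fr) {
    chains <- seq_len(traj$topology$n_chains)
    if (!is.null(center))
      return(list(center = as.numeric(center), chains = chains))
    beads <- NULL
    if (!is.null(cluster_cutoff)) {
      chains <- find_largest_cluster(fr, traj$topology, cluster_cutoff)
      beads <- which(traj$topology$chain_id %in% chains)
    }
    list(center = droplet_center(fr, beads), chains = chains)
  })
}

#' Per-chain conformation records
#'
#' One row per (frame, chain): radial position of the chain centre of mass
#' (`d_com`), radius of gyration, end-to-end distance, and (when a fit is
#' given) the region label from [assign_region()].
#'
#' @param traj `md_trajectory`
#' @param fit optional `interface_fit` for region labels
#' @param cluster_cutoff optional cluster cutoff for droplet detection (all
#'   chains are still reported; the cutoff only affects the centre)
#' @param center optional fixed droplet centre (length 3) overriding the
#'   per-frame estimate (useful when the true centre is known)
#' @return data frame with columns `frame_id`, `chain_id`, `d_com`, `rg`,
#'   `re`, and `region` if `fit` is supplied
#' @export
chain_records <- function(traj, fit = NULL, cluster_cutoff = NULL,
                          center = NULL) {
  topo <- traj$topology
  ctr <- frame_centers(traj, cluster_cutoff, center)
  recs <- vector("list", length(traj$frames))
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    up <- unwrap_chains(fr, topo)
    coms <- rowsum(up, topo$chain_id) / topo$chain_lengths
    # wrap chain COM displacement to the droplet centre
    disp <- min_image_disp(coms, ctr[[i]]$center, fr$box)
    d_com <- sqrt(rowSums(disp^2))
    rg <- re <- numeric(topo$n_chains)
    idx <- 0L
    for (ch in seq_len(topo$n_chains)) {
      rows <- idx + seq_len(topo$chain_lengths[ch])
      rg[ch] <- chain_rg(up[rows, , drop = FALSE])
      re[ch] <- chain_re(up[rows, , drop = FALSE])
      idx <- idx + topo$chain_lengths[ch]
    }
    recs[[i]] <- data.frame(frame_id = i, chain_id = seq_len(topo$n_chains),
                            d_com = d_com, rg = rg, re = re)
  }
  out <- do.call(rbind, recs)
  if (!is.null(fit)) out$region <- assign_region(out$d_com, fit)
  out
}

#' Assign a radial position to interior / interface / exterior
#'
#' Interior: `d < inner_bound`; interface: `inner_bound <= d <= outer_bound`
#' (closed on both ends); exterior otherwise.
#'
#' @param d_com radial distance(s)
#' @param fit `interface_fit` (or list with `inner_bound`, `outer_bound`)
#' @return character vector of region labels
#' @export
assign_region <- function(d_com, fit) {
  ifelse(d_com < fit$inner_bound, "interior",
         ifelse(d_com <= fit$outer_bound, "interface", "exterior"))
}

#' Rg distributions by radial bin
#'
#' Splits chain records into `d_com` bins and returns, per bin, a normalized
#' Rg histogram (density integrating to 1) plus mean, mode (midpoint of the
#' densest histogram bin) and count. Empty radial bins are absent from the
#' output, not reported as zero.
#'
#' @param records data frame from [chain_records()]
#' @param bin_edges radial bin edges for `d_com`
#' @param rg_breaks number of histogram cells (or explicit break vector) for
#'   the Rg axis
#' @return list with `summary` (data frame: bin_lo, bin_hi, count, mean_rg,
#'   mode_rg) and `histograms` (named list of `hist` objects)
#' @export
rg_distribution_by_bin <- function(records, bin_edges, rg_breaks = 30) {
  idx <- findInterval(records$d_com, bin_edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx < length(bin_edges)
  hists <- list()
  rows <- list()
  for (b in sort(unique(idx[ok]))) {
    rg <- records$rg[ok & idx == b]
    h <- graphics::hist(rg, breaks = rg_breaks, plot = FALSE)
    key <- sprintf("[%g,%g)", bin_edges[b], bin_edges[b + 1])
    hists[[key]] <- h
    # degenerate (all-equal) samples: the mode is the common value itself
    mode_rg <- if (diff(range(rg)) < sqrt(.Machine$double.eps)) rg[1] else
      h$mids[which.max(h$density)]
    rows[[key]] <- data.frame(bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1],
                              count = length(rg), mean_rg = mean(rg),
                              mode_rg = mode_rg)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       histograms = hists)
}

#' Enumerate contiguous segments of a chain
#'
#' A chain of `chain_length` beads has `chain_length - n_seg + 1` contiguous
#' segments of length `n_seg`. Each segment is identified by the 1-based
#' index of its middle bead (the segment index); for even `n_seg` the larger
#' of the two middle beads is used.
#'
#' @param chain_length beads per chain
#' @param n_seg segment length, `1 <= n_seg <= chain_length`
#' @return data frame with `start` and `segment_index`
#' @export
enumerate_segments <- function(chain_length, n_seg) {
  if (n_seg < 1 || n_seg > chain_length)
    stop("n_seg must lie in [1, chain_length]")
  start <- seq_len(chain_length - n_seg + 1)
  off <- if (n_seg %% 2 == 0) n_seg %/% 2 else (n_seg - 1) %/% 2
  data.frame(start = start, segment_index = start + off)
}

# classify segments by within-chain position:
# "end" = the two terminal segments; "middle" = the segment whose index is
# nearest the chain midpoint (ties -> lower index); everything else "other"
position_class <- function(starts, seg_index, chain_length, n_seg) {
  cls <- rep("other", length(starts))
  cls[starts == 1 | starts == chain_length - n_seg + 1] <- "end"
  mid_target <- (chain_length + 1) / 2
  dmid <- abs(seg_index - mid_target)
  mid_idx <- which(dmid == min(dmid))
  cls[mid_idx[1]] <- "middle"
  cls
}

# COM, Rg and Re of every contiguous window of length n via prefix sums
window_stats <- function(p, n_seg) {
  n <- nrow(p)
  cs <- apply(rbind(0, p), 2, cumsum)
  cs2 <- cumsum(c(0, rowSums(p^2)))
  i0 <- seq_len(n - n_seg + 1)
  com <- (cs[i0 + n_seg, , drop = FALSE] - cs[i0, , drop = FALSE]) / n_seg
  msq <- (cs2[i0 + n_seg] - cs2[i0]) / n_seg
  rg <- sqrt(pmax(msq - rowSums(com^2), 0))
  rev_ <- p[i0 + n_seg - 1, , drop = FALSE] - p[i0, , drop = FALSE]
  list(com = com, rg = rg, re = sqrt(rowSums(rev_^2)), re_vec = rev_)
}

#' Per-segment conformation records
#'
#' One row per (frame, chain, segment) for a given segment length: segment
#' index, radial position of the segment COM, segmental Rg and Re, and the
#' end/middle/other position class.
#'
#' @param traj `md_trajectory`
#' @param n_seg segment length
#' @param fit optional `interface_fit` for region labels
#' @param cluster_cutoff optional cluster cutoff for droplet detection
#' @param center optional fixed droplet centre overriding the estimate
#' @return data frame with columns `frame_id`, `chain_id`, `n_seg`, `start`,
#'   `segment_index`, `d_com`, `rg_seg`, `re_seg`, `position_class` (and
#'   `region` if `fit` given)
#' @export
segment_records <- function(traj, n_seg, fit = NULL, cluster_cutoff = NULL,
                            center = NULL) {
  topo <- traj$topology
  if (any(n_seg > topo$chain_lengths))
    stop("n_seg exceeds chain length")
  ctr <- frame_centers(traj, cluster_cutoff, center)
  recs <- vector("list", length(traj$frames) * topo$n_chains)
  k <- 0L
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    up <- unwrap_chains(fr, topo)
    idx <- 0L
    for (ch in seq_len(topo$n_chains)) {
      len <- topo$chain_lengths[ch]
      rows <- idx + seq_len(len)
      ws <- window_stats(up[rows, , drop = FALSE], n_seg)
      seg <- enumerate_segments(len, n_seg)
      disp <- min_image_disp(ws$com, ctr[[i]]$center, fr$box)
      k <- k + 1L
      recs[[k]] <- data.frame(
        frame_id = i, chain_id = ch, n_seg = n_seg,
        start = seg$start, segment_index = seg$segment_index,
        d_com = sqrt(rowSums(disp^2)),
        rg_seg = ws$rg, re_seg = ws$re,
        position_class = position_class(seg$start, seg$segment_index,
                                        len, n_seg))
      idx <- idx + len
    }
  }
  out <- do.call(rbind, recs[seq_len(k)])
  if (!is.null(fit)) out$region <- assign_region(out$d_com, fit)
  out
}

#' Segment-index occupancy within a region
#'
#' Probability distribution of the segment index among segments whose COM
#' lies in the stated region — the enrichment signal of chain termini at the
#' droplet interface.
#'
#' @param records data frame from [segment_records()] carrying a `region`
#'   column (i.e. built with a fit)
#' @param region `"interior"`, `"interface"` or `"exterior"`
#' @return data frame `segment_index`, `count`, `probability` (sums to 1)
#' @export
segment_occupancy <- function(records, region) {
  if (!"region" %in% names(records))
    stop("records lack a region column; build them with a fit")
  r <- records[records$region == region, ]
  if (nrow(r) == 0)
    stop("no segments in region '", region, "'")
  # every occurring index of this n_seg, so structural zeros are visible
  all_idx <- sort(unique(records$segment_index))
  cnt <- vapply(all_idx, function(i) sum(r$segment_index == i), numeric(1))
  data.frame(segment_index = all_idx, count = cnt,
             probability = cnt / sum(cnt))
}

#' Segmental Rg versus radial position
#'
#' Mean segmental Rg in `d_com` bins, for all segments or restricted to the
#' terminal (`"end"`) or central (`"middle"`) segments. When a fit is given,
#' a normalized column divides by the mean over interior bins
#' (`d_com < inner_bound`), making profiles of different `n_seg` comparable.
#'
#' @param records data frame from [segment_records()]
#' @param bin_edges radial bin edges
#' @param subset `"all"`, `"end"` or `"middle"`
#' @param fit optional `interface_fit` used for the interior normalizer
#' @return data frame: `bin_lo`, `bin_hi`, `d_mid_bin`, `count`, `mean_rg`,
#'   `se_rg`, and `norm_rg` when a fit is supplied; empty bins are absent
#' @export
segmental_rg_profile <- function(records, bin_edges,
                                 subset = c("all", "end", "middle"),
                                 fit = NULL) {
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
    mean_rg = vapply(bins, function(b) mean(r$rg_seg[idx == b]), numeric(1)),
    se_rg = vapply(bins, function(b) stats::sd(r$rg_seg[idx == b]) /
                     sqrt(sum(idx == b)), numeric(1)))
  if (!is.null(fit)) {
    interior <- out$d_mid_bin < fit$inner_bound
    if (any(interior)) {
      norm <- sum(out$mean_rg[interior] * out$count[interior]) /
        sum(out$count[interior])
      out$norm_rg <- out$mean_rg / norm
    }
  }
  out
}

#' Inter- and intrachain contact profile
#'
#' A contact is an unordered bead pair within `contact_cutoff` (minimum
#' image). Pairs on the same chain separated by `intra_exclusion` bonds or
#' fewer are excluded from the intrachain count. Each monomer's inter- and
#' intrachain contact counts are attributed to the radial bin of that
#' monomer's own distance from the droplet centre, and averaged per monomer.
#'
#' @param traj `md_trajectory`
#' @param contact_cutoff contact distance
#' @param intra_exclusion minimum bond separation for intrachain contacts
#'   (default 2: nearest and next-nearest bonded neighbours excluded)
#' @param bin_width radial bin width
#' @param r_max outer edge (default half the smallest box edge)
#' @param cluster_cutoff optional cluster cutoff for droplet detection
#' @param center optional fixed droplet centre overriding the estimate
#' @return data frame: `bin_lo`, `bin_hi`, `d_mid_bin`, `n_monomers`,
#'   `mean_interchain`, `mean_intrachain`
#' @export
contact_profile <- function(traj, contact_cutoff, intra_exclusion = 2,
                            bin_width = 5, r_max = NULL,
                            cluster_cutoff = NULL, center = NULL) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")
  topo <- traj$topology
  box0 <- traj$frames[[1]]$box
  if (is.null(r_max)) r_max <- min(box0) / 2
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1
  ctr <- frame_centers(traj, cluster_cutoff, center)
  inter_sum <- intra_sum <- mono_cnt <- numeric(nb)
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    method <- if (topo$n_beads > 256 && all(fr$box >= 3 * contact_cutoff))
      "cell" else "brute"
    prs <- cpp_pair_list(fr$positions, fr$box, contact_cutoff, method)
    ci <- topo$chain_id[prs[, 1]]; cj <- topo$chain_id[prs[, 2]]
    same <- ci == cj
    sep <- abs(topo$within_pos[prs[, 1]] - topo$within_pos[prs[, 2]])
    intra_keep <- same & sep > intra_exclusion
    inter_keep <- !same
    n_inter <- tabulate(c(prs[inter_keep, 1], prs[inter_keep, 2]),
                        nbins = topo$n_beads)
    n_intra <- tabulate(c(prs[intra_keep, 1], prs[intra_keep, 2]),
                        nbins = topo$n_beads)
    d <- sqrt(rowSums(min_image_disp(fr$positions, ctr[[i]]$center, fr$box)^2))
    bidx <- findInterval(d, edges, rightmost.closed = FALSE)
    ok <- bidx >= 1 & bidx <= nb
    inter_sum <- inter_sum + unname(tapply(n_inter[ok], factor(bidx[ok], levels = 1:nb),
                                           sum, default = 0))
    intra_sum <- intra_sum + unname(tapply(n_intra[ok], factor(bidx[ok], levels = 1:nb),
                                           sum, default = 0))
    mono_cnt <- mono_cnt + tabulate(bidx[ok], nbins = nb)
  }
  keep <- mono_cnt > 0
  data.frame(bin_lo = edges[-(nb + 1)][keep], bin_hi = edges[-1][keep],
             d_mid_bin = ((edges[-1] + edges[-(nb + 1)]) / 2)[keep],
             n_monomers = mono_cnt[keep],
             mean_interchain = inter_sum[keep] / mono_cnt[keep],
             mean_intrachain = intra_sum[keep] / mono_cnt[keep])
}
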