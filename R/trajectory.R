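#' Construct a single trajectory frame
#'
#' @param positions n x 3 numeric matrix of bead coordinates (Angstrom in
#'   real units, sigma in reduced units)
#' @param box length-3 vector of orthogonal periodic box edge lengths
#' @param time time stamp (simulation step or ps); default 0
#' @return object of class `md_frame`
#' @export
md_frame <- function(positions, box, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || !is.numeric(positions))
    stop("positions must be an n x 3 numeric matrix")
  if (anyNA(positions)) stop("positions contain NA")
  box <- as.numeric(box)
  if (length(box) == 1) box <- rep(box, 3)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive edge lengths")
  structure(list(positions = unname(positions), box = box, time = time),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' A trajectory bundles a [build_linear_topology()] topology with a
#' time-ordered list of frames, plus metadata (unit system, whether the
#' stored coordinates are wrapped into the periodic box).
#'
#' @param topology a `chain_topology`
#' @param frames list of `md_frame` objects with strictly increasing times
#' @param units `"real"` (Angstrom, kcal/mol) or `"reduced"` (sigma, epsilon)
#' @param wrapped logical: are coordinates wrapped into the box?
#' @return object of class `md_trajectory`
#' @export
md_trajectory <- function(topology, frames, units = "real", wrapped = TRUE) {
  validate_topology(topology)
  if (length(frames) == 0) stop("trajectory must contain at least one frame")
  nb <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (any(nb != topology$n_beads))
    stop("all frames must have the topology's bead count (", topology$n_beads, ")")
  times <- vapply(frames, function(f) as.numeric(f$time), numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  units <- match.arg(units, c("real", "reduced"))
  structure(list(topology = topology, frames = frames,
                 metadata = list(units = units, wrapped = wrapped)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames, %d beads (%d chains), units=%s\n",
              length(x$frames), x$topology$n_beads, x$topology$n_chains,
              x$metadata$units))
  invisible(x)
}

#' @export
length.md_trajectory <- function(x) length(x$frames)

n_frames <- function(traj) length(traj$frames)
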