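#' Build a linear bead-spring topology
#'
#' Constructs the topology of a melt of linear homopolymer-style chains:
#' `n_chains` chains of `chain_length` beads each, bonded consecutively
#' within a chain (no inter-chain bonds). Beads are numbered contiguously,
#' chain by chain; within-chain positions are 1-based.
#'
#' @param n_chains number of chains (>= 1)
#' @param chain_length beads per chain (>= 2)
#' @param bead_type symbolic bead type, recycled to all beads (single type
#'   for a homopolymer), or a vector of length `chain_length` giving the
#'   per-position type of every chain
#' @return an object of class `chain_topology` with elements
#'   `n_chains`, `chain_lengths`, `n_beads`, `bead_types`, `chain_id`
#'   (per-bead chain index), `within_pos` (per-bead 1-based position in its
#'   chain) and `bonds` (two-column matrix of bonded bead indices)
#' @export
build_linear_topology <- function(n_chains, chain_length, bead_type = "H") {
  if (!is.numeric(n_chains) || length(n_chains) != 1L || n_chains < 1 ||
      n_chains != round(n_chains))
    stop("n_chains must be a positive integer")
  if (!is.numeric(chain_length) || length(chain_length) != 1L ||
      chain_length < 2 || chain_length != round(chain_length))
    stop("chain_length must be an integer >= 2")
  n_chains <- as.integer(n_chains)
  chain_length <- as.integer(chain_length)
  if (length(bead_type) == 1L) {
    types <- rep(as.character(bead_type), n_chains * chain_length)
  } else if (length(bead_type) == chain_length) {
    types <- rep(as.character(bead_type), times = n_chains)
  } else {
    stop("bead_type must have length 1 or chain_length")
  }
  chain_id <- rep(seq_len(n_chains), each = chain_length)
  within_pos <- rep(seq_len(chain_length), times = n_chains)
  first <- which(within_pos < chain_length)
  bonds <- cbind(first, first + 1L)
  structure(list(
    n_chains = n_chains,
    chain_lengths = rep(chain_length, n_chains),
    n_beads = n_chains * chain_length,
    bead_types = types,
    chain_id = chain_id,
    within_pos = within_pos,
    bonds = bonds
  ), class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("chain_topology: %d chains x %d beads (%d beads, %d bonds)\n",
              x$n_chains, x$chain_lengths[1], x$n_beads, nrow(x$bonds)))
  invisible(x)
}

# internal: placeholder topology for trajectories read without chain info
# (every bead its own "chain", no bonds); analyses that need connectivity
# refuse it.
topology_unbonded <- function(n_beads, bead_type = "X") {
  structure(list(
    n_chains = n_beads,
    chain_lengths = rep(1L, n_beads),
    n_beads = as.integer(n_beads),
    bead_types = rep(bead_type, n_beads),
    chain_id = seq_len(n_beads),
    within_pos = rep(1L, n_beads),
    bonds = matrix(integer(0), ncol = 2)
  ), class = "chain_topology")
}

validate_topology <- function(topology) {
  stopifnot(inherits(topology, "chain_topology"))
  if (topology$n_beads != sum(topology$chain_lengths))
    stop("topology invariant violated: n_beads != sum(chain_lengths)")
  invisible(topology)
}
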