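#' Spin configurations of the three-state cascade model
#'
#' Each node carries a spin in {-1, 0, +1}: +1 is the activated ("red",
#' fibrosis) state, -1 the repairing ("blue", healthy) state and 0 the
#' neutral ("white") state that can still be converted by its neighbours.
#' Nodes in the panel's fixed sets are pinned: their spins never change.
#'
#' @param panel an [node_panel()].
#' @param N node count.
#' @param initial_blues integer indices started at spin -1 (variable, may
#'   flip later — only the panel blues are pinned).
#' @param initial_sign spin value given to `initial_blues`; -1 by default,
#'   +1 yields the mirrored (initial red) experiment.
#' @return an object of class `infi_spins` with fields `spins`, `fixed_red`,
#'   `fixed_blue`.
#' @export
spin_configuration <- function(panel, N, initial_blues = integer(0),
                               initial_sign = -1L) {
  stopifnot(inherits(panel, "infi_panel"))
  initial_blues <- as.integer(initial_blues)
  if (any(initial_blues %in% c(panel$fixed_red, panel$fixed_blue))) {
    stop("initial blue nodes must be disjoint from the pinned sets")
  }
  s <- integer(N)
  s[panel$fixed_red] <- 1L
  s[panel$fixed_blue] <- -1L
  s[initial_blues] <- as.integer(initial_sign)
  structure(list(spins = s, fixed_red = panel$fixed_red,
                 fixed_blue = panel$fixed_blue),
            class = "infi_spins")
}

is_pinned <- function(state, i) {
  i %in% state$fixed_red || i %in% state$fixed_blue
}

variable_nodes <- function(state) {
  setdiff(seq_along(state$spins), c(state$fixed_red, state$fixed_blue))
}

#' Local field of a node
#'
#' `Z_i = sum_{j != i} (S~_ij + S~_ji) sigma_j`, the coupling-weighted sum
#' of all neighbour spins (pinned and variable alike). Cost is proportional
#' to the degree of `i` thanks to the sparse coupling matrix.
#'
#' @param W symmetric sparse coupling matrix `S_tilde + t(S_tilde)`.
#' @param spins integer spin vector.
#' @param i node index.
#' @return the signed field value.
#' @export
local_field <- function(W, spins, i) {
  sum(W[, i] * spins)
}

#' Update a single variable node (reference implementation)
#'
#' Sets `sigma_i <- sign(Z_i)` when the local field is nonzero and leaves
#' the spin unchanged when `Z_i = 0`. This is the pure-R reference for the
#' compiled sweep engine; the two paths are cross-checked in the tests.
#'
#' @param state an [spin_configuration()].
#' @param W symmetric sparse coupling matrix.
#' @param i a non-pinned node index.
#' @return the updated `infi_spins`.
#' @export
update_node <- function(state, W, i) {
  if (is_pinned(state, i)) stop("update_node called on pinned node ", i)
  z <- local_field(W, state$spins, i)
  if (z != 0) state$spins[i] <- as.integer(sign(z))
  state
}

#' One asynchronous sweep along a given update order (reference)
#'
#' Updates every node in `order` once; each new spin value is immediately
#' visible to the later updates of the same sweep, so the outcome depends
#' on the order.
#'
#' @param state an [spin_configuration()].
#' @param W symmetric sparse coupling matrix.
#' @param order a permutation of exactly the non-pinned node indices.
#' @return list with elements `state` and `n_changed`.
#' @export
sweep_spins <- function(state, W, order) {
  vn <- variable_nodes(state)
  if (!setequal(order, vn) || length(order) != length(vn)) {
    stop("`order` must be a permutation of exactly the non-pinned nodes")
  }
  n_changed <- 0L
  for (i in order) {
    old <- state$spins[i]
    state <- update_node(state, W, i)
    if (state$spins[i] != old) n_changed <- n_changed + 1L
  }
  list(state = state, n_changed = n_changed)
}
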