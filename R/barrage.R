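#' Erdös-1 candidate set around a hub
#'
#' Returns the nodes at symmetrized-graph distance one from the hub: all
#' nodes outside the hub with a direct or inverse link (a positive entry of
#' `W = S_tilde + t(S_tilde)`) to at least one hub node. These are the
#' candidate locations for blue barrage nodes.
#'
#' @param mats an [build_transition_matrices()] result.
#' @param hub integer node indices of the pinned red hub.
#' @param panel optional [node_panel()]; when given and
#'   `exclude_blue = TRUE` (default) the pinned blue nodes are excluded
#'   from the candidate set.
#' @param exclude_blue drop panel-blue neighbours of the hub.
#' @return sorted integer vector of candidate node indices.
#' @export
erdos_set <- function(mats, hub, panel = NULL, exclude_blue = TRUE) {
  stopifnot(inherits(mats, "infi_matrices"), length(hub) > 0L)
  hub <- as.integer(hub)
  touch <- Matrix::rowSums(abs(mats$W[, hub, drop = FALSE])) > 0
  cand <- setdiff(which(touch), hub)
  if (!is.null(panel) && exclude_blue) {
    cand <- setdiff(cand, panel$fixed_blue)
  }
  sort(cand)
}

#' Rank candidate nodes as single initial blue barrages
#'
#' For each candidate `i`, runs the ensemble with the fixed configuration
#' `[i]` as the single initial blue node and records the network-mean red
#' outcome `frc(i)`. Candidates are ordered by increasing `frc` (ties by
#' ascending node index), giving the barrage rank `Kfr`: the top of the
#' list is the most suppressive single-node intervention.
#'
#' @param mats an [build_transition_matrices()] result.
#' @param panel an [node_panel()].
#' @param candidates integer node indices, disjoint from the pinned sets.
#' @param R realizations per candidate.
#' @param tau_max sweep cap.
#' @param seed master seed; candidate `i` uses substream `seed + position`.
#' @return an object of class `infi_barrage`: tibble with columns
#'   `candidate`, `name`, `frc`, `se`, `support`, `Kfr`, sorted by `Kfr`.
#' @export
rank_single_blue <- function(mats, panel, candidates, R = 1000L,
                             tau_max = 100L, seed = 1L) {
  candidates <- as.integer(candidates)
  if (length(candidates) == 0L) stop("empty candidate set")
  if (any(candidates %in% c(panel$fixed_red, panel$fixed_blue))) {
    stop("candidates must be disjoint from the pinned sets")
  }
  rows <- purrr::map2_dfr(candidates, seq_along(candidates), function(i, k) {
    sim <- simulate_infi(mats, panel, sim_config(
      R = R, tau_max = tau_max, placement = "fixed_configuration",
      configuration = i, seed = seed + k
    ))
    tibble::tibble(candidate = i, frc = sim$fr_mean, se = fr_mean_se(sim),
                   support = R)
  })
  rows <- dplyr::arrange(rows, .data$frc, .data$candidate)
  rows$Kfr <- seq_len(nrow(rows))
  rows$name <- mats$node_names[rows$candidate]
  out <- dplyr::select(rows, "Kfr", "candidate", "name", "frc", "se",
                       "support")
  class(out) <- c("infi_barrage", class(out))
  out
}

#' Conditional red outcome of a node or configuration in a stored ensemble
#'
#' Given an ensemble simulated with `store_realizations = TRUE` and random
#' initial-blue placement, estimates the conditional network-mean red
#' fraction over the realizations whose initial-blue draw contains the
#' query node(s) (`mode = "contains"`) or exactly equals the query
#' configuration (`mode = "exact"`). Estimates supported by fewer than
#' `min_support` realizations are flagged undefined (`frc = NA`).
#'
#' @param sim an `infi_sim` run with `store_realizations = TRUE`.
#' @param query integer node index or vector (a configuration).
#' @param mode `"contains"` or `"exact"`.
#' @param min_support minimum realizations behind a reported value (default
#'   100).
#' @return tibble of class `infi_config_outcome` with columns `n_ib`,
#'   `frc`, `se`, `support`, `defined` and a `configuration` list-column.
#' @export
conditional_frc <- function(sim, query, mode = c("contains", "exact"),
                            min_support = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "infi_sim"))
  if (is.null(sim$initial_blues)) {
    stop("ensemble was not run with store_realizations = TRUE")
  }
  query <- sort(as.integer(query))
  ib <- sim$initial_blues # n_ib x R matrix
  sel <- if (mode == "contains") {
    colSums(matrix(ib %in% query, nrow = nrow(ib))) == length(query)
  } else {
    if (length(query) != nrow(ib)) {
      rep(FALSE, ncol(ib))
    } else {
      apply(ib, 2L, function(col) identical(sort(col), query))
    }
  }
  support <- sum(sel)
  defined <- support >= min_support
  vals <- sim$fr_real[sel]
  out <- tibble::tibble(
    configuration = list(query), n_ib = length(query),
    frc = if (defined) mean(vals) else NA_real_,
    se = if (defined) stats::sd(vals) / sqrt(support) else NA_real_,
    support = support, defined = defined
  )
  class(out) <- c("infi_config_outcome", class(out))
  out
}

#' Evaluate every subset of a small node group as a fixed barrage
#'
#' Runs the ensemble once per subset of `nodes` (including the empty
#' baseline) with the subset as fixed initial-blue configuration, and
#' reports the network-mean red outcome per configuration, grouped by size.
#'
#' @param mats an [build_transition_matrices()] result.
#' @param panel an [node_panel()].
#' @param nodes integer node vector, at most 12 nodes (2^k runs).
#' @param R realizations per configuration.
#' @param tau_max sweep cap.
#' @param seed master seed.
#' @return tibble of class `infi_config_outcome` with one row per subset:
#'   `configuration` (list-column), `n_ib`, `frc`, `se`, `support`.
#' @export
evaluate_all_subsets <- function(mats, panel, nodes, R = 1000L,
                                 tau_max = 100L, seed = 1L) {
  nodes <- as.integer(nodes)
  k <- length(nodes)
  if (k > 12L) stop("at most 12 nodes (2^k configurations)")
  subsets <- purrr::map(0:(2^k - 1L), function(m) {
    nodes[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
  })
  rows <- purrr::imap_dfr(subsets, function(cfg, idx) {
    sim <- simulate_infi(mats, panel, sim_config(
      R = R, tau_max = tau_max, placement = "fixed_configuration",
      configuration = cfg, seed = seed + idx
    ))
    tibble::tibble(configuration = list(cfg), n_ib = length(cfg),
                   frc = sim$fr_mean, se = fr_mean_se(sim), support = R)
  })
  rows <- dplyr::arrange(rows, .data$n_ib, .data$frc)
  class(rows) <- c("infi_config_outcome", class(rows))
  rows
}

#' Select a jointly optimal barrage group across rankings
#'
#' Given barrage rankings obtained at several `n_ib` values over a shared
#' candidate set, returns the `k` candidates with the smallest summed rank
#' positions — a rank-sum heuristic for a group that is uniformly near the
#' top of every ranking. Ties break by ascending node index.
#'
#' @param rankings list of `infi_barrage` tibbles sharing one candidate set.
#' @param k group size.
#' @return integer vector of `k` node indices.
#' @export
select_optimal_group <- function(rankings, k) {
  if (inherits(rankings, "infi_barrage")) rankings <- list(rankings)
  cand <- sort(rankings[[1L]]$candidate)
  for (r in rankings) {
    if (!identical(sort(r$candidate), cand)) {
      stop("all rankings must share the same candidate set")
    }
  }
  if (k > length(cand)) stop("k exceeds the candidate count")
  score <- purrr::reduce(
    purrr::map(rankings, function(r) {
      setNames(r$Kfr, r$candidate)[as.character(cand)]
    }),
    `+`
  )
  ord <- order(score, cand)
  sort(cand[ord[seq_len(k)]])
}
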