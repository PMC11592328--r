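#' Simulation configuration for the cascade ensemble
#'
#' @param R realization count (the paper-scale default is 100,000; tests and
#'   examples use far less).
#' @param tau_max sweep cap per realization, default 100.
#' @param n_ib number of initial (non-pinned) blue nodes per realization.
#' @param candidate_set integer node indices from which initial blues are
#'   drawn when `placement = "random_in_set"`; `NULL` means all variable
#'   nodes.
#' @param placement `"random_in_set"` (fresh uniform draw of `n_ib` distinct
#'   candidates per realization) or `"fixed_configuration"` (the explicit
#'   `configuration` in every realization).
#' @param configuration explicit node indices, required when
#'   `placement = "fixed_configuration"`.
#' @param initial_sign spin given to the placed nodes; -1 (blue) by default.
#' @param seed master RNG seed; every realization r derives an independent
#'   substream from (seed, r), so results do not depend on execution order.
#' @param store_realizations keep per-realization initial-blue sets and
#'   network-mean red fractions (needed by [conditional_frc()]).
#' @return a list of class `infi_config`.
#' @export
sim_config <- function(R = 100L, tau_max = 100L, n_ib = 0L,
                       candidate_set = NULL,
                       placement = c("random_in_set", "fixed_configuration"),
                       configuration = NULL, initial_sign = -1L,
                       seed = 1L, store_realizations = FALSE) {
  placement <- match.arg(placement)
  if (placement == "fixed_configuration" && is.null(configuration)) {
    stop("placement = 'fixed_configuration' requires `configuration`")
  }
  structure(list(R = as.integer(R), tau_max = as.integer(tau_max),
                 n_ib = as.integer(n_ib),
                 candidate_set = if (is.null(candidate_set)) NULL
                                 else as.integer(candidate_set),
                 placement = placement,
                 configuration = if (is.null(configuration)) integer(0)
                                 else as.integer(configuration),
                 initial_sign = as.integer(initial_sign),
                 seed = as.integer(seed),
                 store_realizations = isTRUE(store_realizations)),
            class = "infi_config")
}

engine_inputs <- function(mats, panel) {
  stopifnot(inherits(mats, "infi_matrices"), inherits(panel, "infi_panel"))
  N <- mats$N
  pinned <- integer(N)
  pinned[panel$fixed_red] <- 1L
  pinned[panel$fixed_blue] <- -1L
  variable <- which(pinned == 0L)
  W <- mats$W
  list(wp = W@p, wi = W@i, wx = W@x, pinned = pinned, variable = variable)
}

#' Run one pathway realization
#'
#' Starts from the pinned panel values, spin -1 on `initial_blues` and 0
#' (white) elsewhere, then performs asynchronous sweeps with a fresh random
#' update permutation per sweep until no spin changes or `tau_max` sweeps
#' have run. Deterministic given `seed`.
#'
#' @param mats an [build_transition_matrices()] result.
#' @param panel an [node_panel()].
#' @param initial_blues integer node indices, disjoint from the pinned sets.
#' @param tau_max sweep cap.
#' @param seed RNG stream seed for this realization.
#' @param initial_sign spin given to `initial_blues` (-1 default).
#' @return list of class `infi_realization`: `final_spins`, `tau_last`
#'   (first sweep index after which no spin changed), `converged`,
#'   `initial_blues`.
#' @export
run_realization <- function(mats, panel, initial_blues = integer(0),
                            tau_max = 100L, seed = 1L, initial_sign = -1L) {
  ei <- engine_inputs(mats, panel)
  initial_blues <- as.integer(initial_blues)
  if (any(ei$pinned[initial_blues] != 0L)) {
    stop("initial blue nodes must be disjoint from the pinned sets")
  }
  out <- run_engine_cpp(ei$wp, ei$wi, ei$wx, ei$pinned, ei$variable - 1L,
                        integer(0), length(initial_blues), TRUE,
                        initial_blues - 1L, as.integer(initial_sign),
                        as.integer(tau_max), 1L, as.integer(seed),
                        FALSE, TRUE)
  structure(list(final_spins = as.integer(out$final_spins[, 1L]),
                 tau_last = out$tau_last[1L],
                 converged = out$converged[1L],
                 initial_blues = initial_blues),
            class = "infi_realization")
}

#' Simulate the cascade ensemble and collect outcome statistics
#'
#' Runs `config$R` independent realizations of the asynchronous spin
#' dynamics and aggregates, per node, the fraction of realizations ending
#' red (`fr`), blue and white, plus the network-averaged trajectory
#' `fr(tau)` and convergence times.
#'
#' @param mats an [build_transition_matrices()] result (dynamics use the
#'   coupling `W = S_tilde + t(S_tilde)`; dangling columns stay zero).
#' @param panel an [node_panel()].
#' @param config an [sim_config()].
#' @return an object of class `infi_sim`: per-node vectors `fr_per_node`,
#'   `fb_per_node`, scalars `fr_mean` (average of `fr` over the `Nv`
#'   variable nodes), `Nv`, `white_stable_count` (nodes never red and never
#'   blue), `fr_trajectory` (length `tau_max`), `tau_last` (per
#'   realization), `fr_real` (per-realization mean red fraction) and, when
#'   requested, the per-realization initial-blue matrix.
#' @export
simulate_infi <- function(mats, panel, config = sim_config()) {
  stopifnot(inherits(config, "infi_config"))
  ei <- engine_inputs(mats, panel)
  cand <- config$candidate_set
  if (is.null(cand)) cand <- ei$variable
  if (any(ei$pinned[cand] != 0L)) {
    stop("candidate set must not contain pinned nodes")
  }
  fixed <- config$placement == "fixed_configuration"
  if (fixed) {
    if (any(ei$pinned[config$configuration] != 0L)) {
      stop("configuration must not contain pinned nodes")
    }
  } else if (config$n_ib > length(cand)) {
    stop("n_ib exceeds the candidate set size (", length(cand), ")")
  }
  out <- run_engine_cpp(ei$wp, ei$wi, ei$wx, ei$pinned, ei$variable - 1L,
                        cand - 1L, config$n_ib, fixed,
                        config$configuration - 1L, config$initial_sign,
                        config$tau_max, config$R, config$seed,
                        config$store_realizations, FALSE)
  R <- config$R
  fr <- out$red_count / R
  fb <- out$blue_count / R
  Nv <- length(ei$variable)
  structure(
    list(fr_per_node = fr, fb_per_node = fb,
         fr_mean = if (Nv > 0) sum(fr[ei$variable]) / Nv else 0,
         Nv = Nv, variable = ei$variable,
         white_stable_count = sum(fr == 0 & fb == 0),
         fr_trajectory = out$fr_trajectory,
         tau_last = out$tau_last, converged = out$converged,
         fr_real = out$fr_real,
         initial_blues = if (config$store_realizations)
           out$initial_blues + 1L else NULL,
         config = config, panel = panel, node_names = mats$node_names,
         R = R),
    class = "infi_sim"
  )
}

#' @export
print.infi_sim <- function(x, ...) {
  cat("<infi_sim> R = ", x$R, ", Nv = ", x$Nv,
      ", fr_mean = ", signif(x$fr_mean, 6),
      ", stable white = ", x$white_stable_count, "\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_infi per-node outcome tibble.
#' @param x an `infi_sim`.
#' @param ... unused.
#' @export
tidy.infi_sim <- function(x, ...) {
  N <- length(x$fr_per_node)
  tibble::tibble(
    node = seq_len(N), name = x$node_names,
    fr = x$fr_per_node, blue_fraction = x$fb_per_node,
    white_fraction = 1 - x$fr_per_node - x$fb_per_node,
    pinned = dplyr::case_when(
      seq_len(N) %in% x$panel$fixed_red ~ "red",
      seq_len(N) %in% x$panel$fixed_blue ~ "blue",
      TRUE ~ "variable"
    )
  )
}

#' @describeIn simulate_infi one-row run summary.
#' @export
glance.infi_sim <- function(x, ...) {
  tibble::tibble(
    fr_mean = x$fr_mean, Nv = x$Nv, R = x$R,
    white_stable_count = x$white_stable_count,
    white_stable_fraction = x$white_stable_count / length(x$fr_per_node),
    tau_last_median = stats::median(x$tau_last),
    tau_last_max = max(x$tau_last),
    all_converged = all(x$converged),
    n_ib = x$config$n_ib, tau_max = x$config$tau_max, seed = x$config$seed
  )
}

#' Monte Carlo standard error of the network-mean red fraction
#'
#' @param sim an `infi_sim`.
#' @return `sd(fr_real)/sqrt(R)`.
#' @export
fr_mean_se <- function(sim) {
  stopifnot(inherits(sim, "infi_sim"))
  stats::sd(sim$fr_real) / sqrt(sim$R)
}
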