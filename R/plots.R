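#' Plot methods for simulation, distribution and barrage results
#'
#' `autoplot.infi_sim` shows the per-node red-outcome histogram and the
#' convergence of the network-mean red fraction with sweep time;
#' `autoplot.infi_dist` the normalised density and log-log CCDF;
#' `autoplot.infi_barrage` the conditional red outcome along the barrage
#' rank.
#'
#' @param object the result object.
#' @param which for `infi_sim`: `"histogram"` or `"trajectory"`; for
#'   `infi_dist`: `"density"` or `"ccdf"`.
#' @param ... unused.
#' @return a ggplot.
#' @name infinet-plots
NULL

#' @rdname infinet-plots
#' @export
autoplot.infi_sim <- function(object, which = c("histogram", "trajectory"),
                              ...) {
  which <- match.arg(which)
  if (which == "histogram") {
    vals <- object$fr_per_node[object$variable]
    h <- histogram_density(vals, 0.01)
    ggplot2::ggplot(h[h$count > 0, ],
                    ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
      ggplot2::geom_col(width = 0.01, fill = "firebrick") +
      ggplot2::labs(x = "red-outcome fraction fr(i)", y = "density p(fr)",
                    title = "Distribution of per-node red outcomes") +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(tau = seq_along(object$fr_trajectory),
                         fr = object$fr_trajectory)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$fr)) +
      ggplot2::geom_line(colour = "firebrick") +
      ggplot2::labs(x = "sweep", y = "mean red fraction",
                    title = "Convergence of the cascade") +
      ggplot2::theme_minimal()
  }
}

#' @rdname infinet-plots
#' @export
autoplot.infi_dist <- function(object, which = c("density", "ccdf"), ...) {
  which <- match.arg(which)
  if (which == "density") {
    h <- object$density
    ggplot2::ggplot(h[h$count > 0, ],
                    ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
      ggplot2::geom_col(width = object$bin_width, fill = "grey30") +
      ggplot2::labs(x = "fr", y = "p(fr)") +
      ggplot2::theme_minimal()
  } else {
    cc <- object$ccdf[object$ccdf$ccdf > 0 & object$ccdf$fr > 0, ]
    ggplot2::ggplot(cc, ggplot2::aes(x = .data$fr, y = .data$ccdf)) +
      ggplot2::geom_step(colour = "steelblue") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "fr", y = "P(fr(i) > fr)") +
      ggplot2::theme_minimal()
  }
}

#' @rdname infinet-plots
#' @export
autoplot.infi_barrage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$Kfr, y = .data$frc)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$frc - 2 * .data$se,
                                          ymax = .data$frc + 2 * .data$se),
                             colour = "steelblue", size = 0.3) +
    ggplot2::labs(x = "barrage rank Kfr",
                  y = "conditional red outcome frc",
                  title = "Single-node blue barrage ranking") +
    ggplot2::theme_minimal()
}

#' Decay of the mean red outcome with barrage size
#'
#' Convenience runner for decay curves: simulates the ensemble at each
#' `n_ib` on the grid with initial blues drawn from `candidate_set` and
#' plots (or returns) mean red fraction versus `n_ib`.
#'
#' @param mats an [build_transition_matrices()] result.
#' @param panel an [node_panel()].
#' @param n_ib_grid integer vector of barrage sizes (see [ng_grid()]).
#' @param candidate_set candidate node indices (`NULL`: all variable nodes).
#' @param R realizations per grid point.
#' @param tau_max sweep cap.
#' @param seed master seed.
#' @return tibble with columns `n_ib`, `fr_mean`, `se`.
#' @export
barrage_decay <- function(mats, panel, n_ib_grid, candidate_set = NULL,
                          R = 1000L, tau_max = 100L, seed = 1L) {
  purrr::imap_dfr(n_ib_grid, function(nib, k) {
    sim <- simulate_infi(mats, panel, sim_config(
      R = R, tau_max = tau_max, n_ib = nib, candidate_set = candidate_set,
      seed = seed + k
    ))
    tibble::tibble(n_ib = nib, fr_mean = sim$fr_mean, se = fr_mean_se(sim))
  })
}

#' @rdname barrage_decay
#' @param decay a [barrage_decay()] tibble (or several row-bound with a
#'   `set` column).
#' @export
plot_decay <- function(decay) {
  aes <- if ("set" %in% names(decay)) {
    ggplot2::aes(x = .data$n_ib + 0.5, y = .data$fr_mean,
                 colour = .data$set)
  } else {
    ggplot2::aes(x = .data$n_ib + 0.5, y = .data$fr_mean)
  }
  ggplot2::ggplot(decay, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "initial blue nodes n_ib (+0.5 offset)",
                  y = "mean red fraction") +
    ggplot2::theme_minimal()
}
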