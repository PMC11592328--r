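#' Normalised histogram density of per-node outcome fractions
#'
#' Bins are half-open `[k*bw, (k+1)*bw)` with the last bin closed at 1, and
#' the density is normalised so that `sum(density * bw) = 1`. Each bin also
#' records the mean of the values that fell into it, so that the
#' histogram-weighted mean reproduces the arithmetic mean of the input
#' exactly (used by the ensemble consistency identity).
#'
#' @param values numeric vector in \[0, 1\].
#' @param bin_width positive bin width, typically 0.01, 0.001 or 0.0001.
#' @return tibble with columns `bin_lo`, `bin_mid`, `bin_hi`, `count`,
#'   `density`, `bin_mean`.
#' @export
histogram_density <- function(values, bin_width = 0.01) {
  if (length(values) == 0L) stop("empty input")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  if (bin_width <= 0) stop("bin_width must be positive")
  nb <- ceiling(1 / bin_width - 1e-9)
  bin <- pmin(floor(values / bin_width) + 1L, nb) # last bin closed at 1
  count <- tabulate(bin, nbins = nb)
  bin_mean <- rep(NA_real_, nb)
  means <- tapply(values, factor(bin, levels = seq_len(nb)), mean)
  bin_mean[!is.na(means)] <- means[!is.na(means)]
  tibble::tibble(
    bin_lo = (seq_len(nb) - 1) * bin_width,
    bin_mid = (seq_len(nb) - 0.5) * bin_width,
    bin_hi = seq_len(nb) * bin_width,
    count = count,
    density = count / (length(values) * bin_width),
    bin_mean = bin_mean
  )
}

#' Mean of a histogram (exact, via per-bin value means)
#'
#' @param h a [histogram_density()] tibble.
#' @return the histogram-weighted mean, equal to the arithmetic mean of the
#'   binned values to machine precision.
#' @export
histogram_mean <- function(h) {
  w <- h$count / sum(h$count)
  sum(w[h$count > 0] * h$bin_mean[h$count > 0])
}

#' Empirical complementary CDF
#'
#' `P(x) = fraction of values strictly greater than x`, evaluated at the
#' sorted unique values (a right-continuous step function).
#'
#' @param values numeric vector.
#' @return tibble with columns `fr` (sorted unique support) and `ccdf`.
#' @export
tail_ccdf <- function(values) {
  if (length(values) == 0L) stop("empty input")
  xs <- sort(unique(values))
  n <- length(values)
  cnt_le <- cumsum(tabulate(match(sort(values), xs), nbins = length(xs)))
  tibble::tibble(fr = xs, ccdf = (n - cnt_le) / n)
}

#' Evaluate an empirical CCDF at arbitrary probe points
#'
#' @param values numeric sample.
#' @param probes probe points.
#' @return `P(value > probe)` for each probe.
#' @export
ccdf_at <- function(values, probes) {
  vapply(probes, function(p) mean(values > p), numeric(1))
}

#' Fit the algebraic tail exponent of a CCDF
#'
#' Ordinary least squares of `log P` against `log fr` over the support
#' points with `fr >= fr_min` and `P > 0`, returning the slope (the tail
#' exponent of `P(fr) ~ fr^slope`), its standard error and the residual
#' standard deviation as a goodness-of-fit flag.
#'
#' @param ccdf a [tail_ccdf()] tibble (columns `fr`, `ccdf`).
#' @param fr_min lower cutoff of the fit range, default 5e-3.
#' @return list with `exponent`, `se`, `resid_sd`, `n_points`.
#' @export
fit_tail_exponent <- function(ccdf, fr_min = 5e-3) {
  pts <- ccdf[ccdf$fr >= fr_min & ccdf$ccdf > 0, ]
  if (nrow(pts) < 10L) {
    stop("need at least 10 support points with fr >= fr_min and P > 0 (have ",
         nrow(pts), ")")
  }
  fit <- lm(log(ccdf) ~ log(fr), data = pts)
  sm <- suppressWarnings(summary(fit)) # perfect fits warn harmlessly
  list(exponent = unname(coef(fit)[2L]),
       se = unname(sm$coefficients[2L, 2L]),
       resid_sd = sm$sigma,
       n_points = nrow(pts))
}

#' Full distributional summary of per-node outcome fractions
#'
#' @param values per-node red-outcome fractions in \[0, 1\].
#' @param bin_width histogram bin width.
#' @param fr_min tail-fit cutoff; the tail fit is skipped (NA) when fewer
#'   than 10 support points remain above it.
#' @return object of class `infi_dist` with fields `density` (tibble),
#'   `ccdf` (tibble), `median` (smallest observed value with CCDF <= 0.5),
#'   `peak` (density-maximising bin midpoint), `mean`, `tail` (fit or NULL).
#' @export
outcome_distribution <- function(values, bin_width = 0.01, fr_min = 5e-3) {
  h <- histogram_density(values, bin_width)
  cc <- tail_ccdf(values)
  med <- cc$fr[which(cc$ccdf <= 0.5)[1L]]
  peak <- h$bin_mid[which.max(h$density)]
  tail_fit <- tryCatch(fit_tail_exponent(cc, fr_min), error = function(e) NULL)
  structure(list(density = h, ccdf = cc, median = med, peak = peak,
                 mean = histogram_mean(h), bin_width = bin_width,
                 tail = tail_fit),
            class = "infi_dist")
}

#' @export
print.infi_dist <- function(x, ...) {
  cat("<infi_dist> mean = ", signif(x$mean, 6), ", median = ",
      signif(x$median, 6), ", peak = ", signif(x$peak, 4), sep = "")
  if (!is.null(x$tail)) {
    cat(", tail exponent = ", signif(x$tail$exponent, 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Coarse-grained grid of initial-blue counts
#'
#' A mixed linear/geometric grid: `n_ib = ng` for `ng <= 10` and
#' `n_ib = round(10 * 1.2^(ng - 10))` for `ng > 10`, deduplicated and
#' capped at `n_max`. Useful for decay curves of the mean red outcome over
#' several orders of magnitude of barrage size.
#'
#' @param n_max largest `n_ib` to include.
#' @return strictly increasing integer vector starting at 0.
#' @export
ng_grid <- function(n_max) {
  ng <- 0L
  vals <- integer(0)
  repeat {
    v <- if (ng <= 10L) ng else as.integer(round(10 * 1.2^(ng - 10)))
    if (v > n_max) break
    vals <- c(vals, v)
    ng <- ng + 1L
  }
  unique(vals)
}
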