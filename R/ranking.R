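#' Apply the Google matrix to a probability vector, matrix-free
#'
#' Computes `G v = alpha * S v + (1 - alpha)/N` without ever materialising
#' the dense `N x N` Google matrix: the sparse `S_tilde` part is applied
#' directly and the uniform dangling-column and teleportation contributions
#' are added as rank-one corrections.
#'
#' @param mats an [build_transition_matrices()] result.
#' @param v nonnegative numeric vector summing to 1.
#' @param alpha damping factor in (0, 1], default 0.85: the probability of
#'   following the network rather than teleporting to a uniformly random node.
#' @return the image probability vector (sum preserved to 1e-12).
#' @export
apply_google <- function(mats, v, alpha = 0.85) {
  stopifnot(inherits(mats, "infi_matrices"))
  if (length(v) != mats$N) stop("dimension mismatch: length(v) != N")
  if (any(v < 0)) stop("v must be nonnegative")
  sv <- as.numeric(mats$S_tilde %*% v) + sum(v[mats$dangling]) / mats$N
  alpha * sv + (1 - alpha) / mats$N
}

#' PageRank by power iteration on the Google matrix
#'
#' Iterates `v <- G v` from the uniform vector until the L1 change falls
#' below `tol`. The result is the stationary distribution of the damped
#' random walk; the rank index `K` orders nodes by decreasing probability
#' (K = 1 is the most central node), with ties broken by ascending node
#' index.
#'
#' @param x an [infi_network] or [build_transition_matrices()] result.
#' @param alpha damping factor, default 0.85.
#' @param tol L1 convergence threshold, default 1e-12.
#' @param max_iter iteration cap, default 10000; non-convergence is an error.
#' @return an object of class `infi_rank` with fields `probabilities`,
#'   `rank_index` (per-node rank position), `kind`, `residual`, `iterations`.
#' @export
pagerank <- function(x, alpha = 0.85, tol = 1e-12, max_iter = 10000L) {
  mats <- if (inherits(x, "infi_network")) build_transition_matrices(x) else x
  stopifnot(inherits(mats, "infi_matrices"), tol > 0)
  N <- mats$N
  v <- rep(1 / N, N)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    v_new <- apply_google(mats, v, alpha)
    res <- sum(abs(v_new - v))
    v <- v_new
    if (res < tol) break
  }
  if (res >= tol) {
    stop("pagerank did not converge in ", max_iter,
         " iterations (last L1 residual ", format(res), ")")
  }
  structure(
    list(probabilities = v, rank_index = rank_index(v), kind = "pagerank",
         residual = res, iterations = it, node_names = mats$node_names),
    class = "infi_rank"
  )
}

#' CheiRank: PageRank of the link-inverted network
#'
#' A node with small CheiRank index `K*` is highly communicative: it has
#' important outgoing links in the original network.
#'
#' @inheritParams pagerank
#' @param net an [infi_network].
#' @return an `infi_rank` with `kind = "cheirank"`.
#' @export
cheirank <- function(net, alpha = 0.85, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(net, "infi_network"))
  out <- pagerank(invert_network(net), alpha = alpha, tol = tol,
                  max_iter = max_iter)
  out$kind <- "cheirank"
  out
}

#' Rank positions of a probability vector
#'
#' Rank 1 is the largest value; ties are broken by ascending node index.
#' Invariant under multiplication of `p` by a positive constant.
#'
#' @param p finite numeric vector.
#' @return integer vector of rank positions, a bijection onto `1..length(p)`.
#' @export
rank_index <- function(p) {
  if (!all(is.finite(p))) stop("rank_index requires finite values")
  ord <- order(-p, seq_along(p))
  r <- integer(length(p))
  r[ord] <- seq_along(p)
  r
}

#' @export
print.infi_rank <- function(x, ...) {
  cat("<infi_rank> ", x$kind, ", N = ", length(x$probabilities),
      ", residual = ", format(x$residual), " after ", x$iterations,
      " iterations\n", sep = "")
  invisible(x)
}

#' @describeIn pagerank per-node tibble (node, name, probability, rank).
#' @export
tidy.infi_rank <- function(x, ...) {
  tibble::tibble(node = seq_along(x$probabilities),
                 name = x$node_names,
                 probability = x$probabilities,
                 rank = x$rank_index,
                 kind = x$kind)
}

#' Combined PageRank/CheiRank table of a network
#'
#' @param net an [infi_network].
#' @inheritParams pagerank
#' @return tibble with columns name, P, K, P_star, K_star.
#' @export
rank_table <- function(net, alpha = 0.85, tol = 1e-12) {
  pr <- pagerank(net, alpha = alpha, tol = tol)
  cr <- cheirank(net, alpha = alpha, tol = tol)
  tibble::tibble(node = seq_len(net$N), name = net$node_names,
                 P = pr$probabilities, K = pr$rank_index,
                 P_star = cr$probabilities, K_star = cr$rank_index)
}
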