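# Independent oracles used across the suite. These deliberately share no
# code with the package: dense matrices, double loops and explicit
# enumeration only.

# Dense coupling matrix built straight from the edge list.
oracle_W <- function(net) {
  N <- net$N
  A <- matrix(0, N, N)
  A[cbind(net$edges[, 2L], net$edges[, 1L])] <- 1
  out_deg <- colSums(A)
  St <- sweep(A, 2L, ifelse(out_deg == 0, 1, out_deg), "/")
  St[, out_deg == 0] <- 0
  St + t(St)
}

# Dense Google matrix and its leading right eigenvector.
oracle_google <- function(net, alpha = 0.85) {
  N <- net$N
  A <- matrix(0, N, N)
  A[cbind(net$edges[, 2L], net$edges[, 1L])] <- 1
  out_deg <- colSums(A)
  S <- sweep(A, 2L, ifelse(out_deg == 0, 1, out_deg), "/")
  S[, out_deg == 0] <- 1 / N
  alpha * S + (1 - alpha) / N
}

oracle_pagerank <- function(net, alpha = 0.85) {
  G <- oracle_google(net, alpha)
  ev <- eigen(G)
  k <- which.max(Re(ev$values))
  v <- Re(ev$vectors[, k])
  v / sum(v)
}

# One asynchronous sweep with dense arithmetic (no early exit, no RNG).
oracle_sweep <- function(spins, Wd, order) {
  for (i in order) {
    z <- sum(Wd[i, ] * spins)
    if (z > 0) spins[i] <- 1L else if (z < 0) spins[i] <- -1L
  }
  spins
}

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    out <- c(out, lapply(oracle_perms(v[-k]), function(p) c(v[k], p)))
  }
  out
}

# Exact distribution over final spin configurations after `tau` sweeps,
# averaging uniformly over ALL (Nv!)^tau update-order sequences. Distinct
# intermediate configurations are collapsed, which keeps the enumeration
# exact but tractable.
oracle_enumerate <- function(Wd, init_spins, variable, tau) {
  perms <- oracle_perms(variable)
  np <- length(perms)
  states <- list()
  key <- function(s) paste(s, collapse = ",")
  states[[key(init_spins)]] <- list(s = init_spins, p = 1)
  for (t in seq_len(tau)) {
    nxt <- list()
    for (st in states) {
      for (pm in perms) {
        s2 <- oracle_sweep(st$s, Wd, pm)
        k2 <- key(s2)
        if (is.null(nxt[[k2]])) nxt[[k2]] <- list(s = s2, p = 0)
        nxt[[k2]]$p <- nxt[[k2]]$p + st$p / np
      }
    }
    states <- nxt
  }
  states
}

# Exact per-node probability of a red outcome from an enumeration result.
oracle_fr <- function(states, N) {
  fr <- numeric(N)
  for (st in states) fr <- fr + st$p * (st$s == 1L)
  pmin(pmax(fr, 0), 1) # clamp float-accumulation noise
}
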