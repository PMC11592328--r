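fx <- fixture_catalog()

test_that("erdos_set finds symmetrized distance-1 neighbours of the hub", {
  star <- fx$out_star
  ms <- build_transition_matrices(star$network)
  hub <- which(star$network$node_names == "h")
  expect_equal(erdos_set(ms, hub), setdiff(1:5, hub))

  # hub with no links at all
  net <- infi_network(data.frame("a", "b"), node_names = c("a", "b", "z"),
                      quiet = TRUE)
  mz <- build_transition_matrices(net)
  expect_equal(erdos_set(mz, 3L), integer(0))

  # brute-force dense scan on random 30-node fixtures
  for (seed in c(61, 62)) {
    net30 <- random_net(30, 90, seed = seed)
    m30 <- build_transition_matrices(net30)
    hub <- 1:3
    Wd <- oracle_W(net30)
    brute <- sort(setdiff(which(rowSums(Wd[, hub, drop = FALSE] > 0) > 0), hub))
    expect_equal(erdos_set(m30, hub), brute)
  }

  # pinned blue neighbours excluded by default, kept on request
  b <- bench()
  with_blue <- erdos_set(b$mats, b$panel$fixed_red, b$panel,
                         exclude_blue = FALSE)
  expect_true(all(b$erdos %in% with_blue))
  expect_equal(setdiff(with_blue, b$erdos),
               intersect(with_blue, b$panel$fixed_blue))
})

test_that("rank_single_blue orders candidates by conditional red outcome", {
  # an isolated candidate cannot influence the cascade: frc = baseline
  nm <- c("h", paste0("l", 1:4), "z")
  net <- infi_network(data.frame(rep("h", 4), paste0("l", 1:4)),
                      node_names = nm, quiet = TRUE)
  m <- build_transition_matrices(net)
  panel <- node_panel(net, red = "h", blue = character(0))
  base <- simulate_infi(m, panel, sim_config(R = 50, tau_max = 5, seed = 1))
  br <- rank_single_blue(m, panel, candidates = match("z", nm), R = 50,
                         tau_max = 5, seed = 2)
  expect_equal(br$frc, base$fr_mean) # deterministic dynamics on this fixture

  # the bottleneck bridge suppresses the community
  bt <- fx$bottleneck
  mb <- build_transition_matrices(bt$network)
  cand <- match(c("bridge", "leaf", "c4"), bt$network$node_names)
  br2 <- rank_single_blue(mb, bt$panel, cand, R = 400, tau_max = 20, seed = 3)
  base2 <- simulate_infi(mb, bt$panel, sim_config(R = 400, tau_max = 20, seed = 4))
  bridge_row <- br2[br2$name == "bridge", ]
  expect_lt(bridge_row$frc, base2$fr_mean)
  expect_equal(br2$Kfr, 1:3)
  expect_true(all(diff(br2$frc) >= 0))

  expect_error(rank_single_blue(m, panel, integer(0)), "empty")
  expect_error(rank_single_blue(m, panel, panel$fixed_red), "disjoint")
})

test_that("bridge-blue realizations never turn the community red", {
  bt <- fx$bottleneck
  mb <- build_transition_matrices(bt$network)
  bridge <- match("bridge", bt$network$node_names)
  community <- match(paste0("c", 1:7), bt$network$node_names)
  blue_seen <- 0L
  for (s in 1:200) {
    r <- run_realization(mb, bt$panel, initial_blues = bridge,
                         tau_max = 20, seed = s)
    if (r$final_spins[bridge] == -1L) {
      blue_seen <- blue_seen + 1L
      expect_true(all(r$final_spins[community] != 1L))
    }
  }
  expect_gt(blue_seen, 0L) # the blue branch actually occurs
})

test_that("conditional_frc is consistent with direct fixed-configuration runs", {
  b <- bench()
  R <- 12000
  ens <- simulate_infi(b$mats, b$panel, sim_config(
    R = R, tau_max = 30, n_ib = 1, candidate_set = b$erdos, seed = 42,
    store_realizations = TRUE
  ))
  probes <- b$erdos[seq(1, length(b$erdos), length.out = 5)]
  for (q in probes) {
    cond <- conditional_frc(ens, q, min_support = 10)
    expect_true(cond$defined)
    direct <- simulate_infi(b$mats, b$panel, sim_config(
      R = 600, tau_max = 30, placement = "fixed_configuration",
      configuration = q, seed = 1000 + q
    ))
    # binomial-scale standard errors of both estimates
    p_hat <- (cond$frc * cond$support + direct$fr_mean * direct$R) /
      (cond$support + direct$R)
    tol <- 3 * sqrt(p_hat * (1 - p_hat) *
                      (1 / cond$support + 1 / direct$R))
    expect_lt(abs(cond$frc - direct$fr_mean), max(tol, 1e-10))
  }

  # a node outside the candidate set is never drawn: flagged undefined
  outside <- setdiff(seq_len(b$net$N),
                     c(b$erdos, b$panel$fixed_red, b$panel$fixed_blue))[1]
  und <- conditional_frc(ens, outside)
  expect_false(und$defined)
  expect_true(is.na(und$frc))
  expect_equal(und$support, 0L)
})

test_that("conditional support follows the hypergeometric sizing rule", {
  b <- bench()
  R <- 8000
  n_ib <- 4
  ens <- simulate_infi(b$mats, b$panel, sim_config(
    R = R, tau_max = 20, n_ib = n_ib, candidate_set = b$erdos, seed = 7,
    store_realizations = TRUE
  ))
  Nr <- length(b$erdos)
  p <- n_ib / Nr
  expected <- R * p
  sdv <- sqrt(R * p * (1 - p))
  for (q in b$erdos[c(2, 20, 100)]) {
    supp <- conditional_frc(ens, q, min_support = 1)$support
    expect_lt(abs(supp - expected), 5 * sdv)
  }
})

test_that("evaluate_all_subsets enumerates the full configuration lattice", {
  bt <- fx$bottleneck
  mb <- build_transition_matrices(bt$network)
  nodes <- match(c("bridge", "c1"), bt$network$node_names)
  res2 <- evaluate_all_subsets(mb, bt$panel, nodes, R = 100, tau_max = 15,
                               seed = 5)
  expect_equal(nrow(res2), 4L)
  expect_equal(sort(table(res2$n_ib)), sort(c(`0` = 1, `1` = 2, `2` = 1)),
               ignore_attr = TRUE)

  nodes4 <- match(c("bridge", "c1", "c4", "leaf"), bt$network$node_names)
  res4 <- evaluate_all_subsets(mb, bt$panel, nodes4, R = 60, tau_max = 15,
                               seed = 6)
  expect_equal(nrow(res4), 16L)
  expect_equal(as.integer(table(res4$n_ib)), c(1L, 4L, 6L, 4L, 1L))
  expect_error(evaluate_all_subsets(mb, bt$panel, 1:13), "12")

  # on the bottleneck, adding the bridge to any configuration does not
  # increase the red outcome beyond Monte Carlo error
  base <- res2[res2$n_ib == 0, ]
  with_bridge <- res2[vapply(res2$configuration,
                             function(cf) nodes[1] %in% cf, logical(1)), ]
  for (k in seq_len(nrow(with_bridge))) {
    expect_lt(with_bridge$frc[k],
              base$frc + 3 * sqrt(base$se^2 + with_bridge$se[k]^2) + 1e-12)
  }
})

test_that("select_optimal_group minimises summed rank positions", {
  mk_rank <- function(cand, kfr) {
    out <- tibble::tibble(Kfr = kfr, candidate = cand,
                          name = as.character(cand),
                          frc = kfr / 10, se = 0, support = 1)
    class(out) <- c("infi_barrage", class(out))
    out
  }
  r1 <- mk_rank(1:6, c(1L, 2L, 3L, 4L, 5L, 6L))
  expect_equal(select_optimal_group(r1, 3), 1:3)
  expect_equal(select_optimal_group(list(r1, r1), 3), 1:3)

  # brute-force oracle over all k-subsets with discordant rankings
  set.seed(15)
  ranks <- lapply(1:3, function(i) mk_rank(1:8, sample(1:8)))
  score <- Reduce(`+`, lapply(ranks, function(r) {
    setNames(r$Kfr, r$candidate)[as.character(1:8)]
  }))
  combs <- utils::combn(1:8, 3)
  best <- combs[, which.min(colSums(matrix(score[combs], nrow = 3)))]
  expect_equal(select_optimal_group(ranks, 3), sort(best))

  expect_error(select_optimal_group(r1, 10), "exceeds")
})
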