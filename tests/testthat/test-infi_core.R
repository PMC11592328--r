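fx <- fixture_catalog()

test_that("local_field sums coupling-weighted neighbour spins", {
  # single in-neighbour with full weight
  net <- infi_network(data.frame("j", "i"), quiet = TRUE)
  m <- build_transition_matrices(net)
  i <- which(net$node_names == "i")
  j <- which(net$node_names == "j")
  expect_equal(local_field(m$W, c(`j` = 1L, `i` = 0L)[net$node_names], i), 1)

  # all-white neighbourhood
  expect_equal(local_field(m$W, c(0L, 0L), i), 0)

  # dense double-loop oracle on a random 6-node fixture
  net6 <- random_net(6, 12, seed = 21)
  m6 <- build_transition_matrices(net6)
  Wd <- oracle_W(net6)
  set.seed(22)
  spins <- sample(c(-1L, 0L, 1L), 6, replace = TRUE)
  for (i in 1:6) {
    z_oracle <- sum(vapply(seq_len(6), function(j) {
      if (j == i) 0 else Wd[i, j] * spins[j]
    }, numeric(1)))
    expect_equal(local_field(m6$W, spins, i), z_oracle, tolerance = 1e-14)
  }
})

test_that("update_node applies the sign rule and refuses pinned nodes", {
  net <- fx$out_star$network
  m <- build_transition_matrices(net)
  panel <- fx$out_star$panel
  st <- spin_configuration(panel, net$N)
  leaf <- which(net$node_names == "l1")
  st2 <- update_node(st, m$W, leaf) # field from pinned red hub is positive
  expect_equal(st2$spins[leaf], 1L)

  # zero field leaves the spin unchanged
  iso_net <- infi_network(data.frame("a", "b"), node_names = c("a", "b", "z"),
                          quiet = TRUE)
  mz <- build_transition_matrices(iso_net)
  pz <- node_panel(iso_net, red = "a", blue = character(0))
  stz <- spin_configuration(pz, 3, initial_blues = 3L)
  expect_equal(update_node(stz, mz$W, 3L)$spins[3], -1L)

  hub <- which(net$node_names == "h")
  expect_error(update_node(st, m$W, hub), "pinned")
})

test_that("asynchronous order matters: red-white-white chain hand trace", {
  nm <- c("r", "w1", "w2")
  net <- infi_network(data.frame(c("r", "w1"), c("w1", "w2")),
                      node_names = nm, quiet = TRUE)
  m <- build_transition_matrices(net)
  panel <- node_panel(net, red = "r", blue = character(0))

  left_right <- sweep_spins(spin_configuration(panel, 3), m$W, c(2L, 3L))
  expect_equal(left_right$state$spins, c(1L, 1L, 1L))
  expect_equal(left_right$n_changed, 2L)

  right_left <- sweep_spins(spin_configuration(panel, 3), m$W, c(3L, 2L))
  expect_equal(right_left$state$spins, c(1L, 1L, 0L))
  expect_equal(right_left$n_changed, 1L)
})

test_that("sweep counts changes and validates the update order", {
  net <- random_net(5, 8, seed = 31)
  m <- build_transition_matrices(net)
  panel <- node_panel(net, red = character(0), blue = character(0))
  allwhite <- sweep_spins(spin_configuration(panel, 5), m$W, 1:5)
  expect_equal(allwhite$n_changed, 0L)
  expect_equal(allwhite$state$spins, rep(0L, 5))

  star <- fx$out_star
  ms <- build_transition_matrices(star$network)
  sts <- spin_configuration(star$panel, 5)
  vn <- setdiff(1:5, star$panel$fixed_red)
  out <- sweep_spins(sts, ms$W, vn)
  expect_equal(out$n_changed, 4L)
  expect_true(all(out$state$spins == 1L))
  expect_error(sweep_spins(sts, ms$W, 1:5), "permutation")
  expect_error(sweep_spins(sts, ms$W, vn[-1]), "permutation")
})

test_that("run_realization converges, stops early and is seed-deterministic", {
  # nothing pinned, nothing blue: stays white, converged after sweep 1
  net <- random_net(6, 10, seed = 51)
  m <- build_transition_matrices(net)
  p0 <- node_panel(net, red = character(0), blue = character(0))
  r0 <- run_realization(m, p0, tau_max = 10, seed = 4)
  expect_equal(r0$final_spins, rep(0L, 6))
  expect_equal(r0$tau_last, 1L)
  expect_true(r0$converged)

  star <- fx$out_star
  ms <- build_transition_matrices(star$network)
  rs <- run_realization(ms, star$panel, tau_max = 10, seed = 4)
  expect_true(all(rs$final_spins == 1L))
  expect_equal(rs$tau_last, 2L)

  b <- bench()
  ra <- run_realization(b$mats, b$panel, initial_blues = b$erdos[1:5],
                        tau_max = 30, seed = 77)
  rb <- run_realization(b$mats, b$panel, initial_blues = b$erdos[1:5],
                        tau_max = 30, seed = 77)
  expect_identical(ra$final_spins, rb$final_spins)
  expect_identical(ra$tau_last, rb$tau_last)

  expect_error(
    run_realization(ms, star$panel,
                    initial_blues = star$panel$fixed_red, seed = 1),
    "disjoint"
  )
})

test_that("simulate matches trivial ensembles and flags the white-stable set", {
  star <- fx$out_star
  ms <- build_transition_matrices(star$network)
  sim <- simulate_infi(ms, star$panel, sim_config(R = 30, tau_max = 5, seed = 2))
  expect_equal(sim$fr_per_node, rep(1, 5)) # hub pinned red, all leaves red
  expect_equal(sim$fr_mean, 1)

  two <- fx$two_component
  mt <- build_transition_matrices(two$network)
  sim2 <- simulate_infi(mt, two$panel, sim_config(R = 100, tau_max = 10, seed = 3))
  far <- match(c("x1", "x2", "x3"), two$network$node_names)
  expect_equal(sim2$fr_per_node[far], rep(0, 3))
  expect_equal(sim2$fb_per_node[far], rep(0, 3))
  expect_gte(sim2$white_stable_count, 3L)

  # pinned nodes keep their colour in every realization
  rr <- match("r", two$network$node_names)
  bb <- match("b", two$network$node_names)
  expect_equal(sim2$fr_per_node[rr], 1)
  expect_equal(sim2$fr_per_node[bb], 0)
  expect_equal(sim2$fb_per_node[bb], 1)
})

test_that("nodes with no symmetrized path to a pinned node stay white", {
  b <- bench()
  pinned <- c(b$panel$fixed_red, b$panel$fixed_blue)
  reach <- infinet:::reachable_set(b$mats$W, pinned)
  unreach <- setdiff(seq_len(b$net$N), reach)
  expect_gt(length(unreach), 0)
  sim <- simulate_infi(b$mats, b$panel,
                       sim_config(R = 300, tau_max = 30, n_ib = 5,
                                  candidate_set = b$erdos, seed = 8))
  expect_equal(sim$fr_per_node[unreach], rep(0, length(unreach)))
  expect_equal(sim$fb_per_node[unreach], rep(0, length(unreach)))
})

test_that("simulator fr matches the exhaustive order-enumeration oracle", {
  two <- fx$two_component
  mt <- build_transition_matrices(two$network)
  Wd <- oracle_W(two$network)
  st0 <- spin_configuration(two$panel, two$network$N)
  vn <- setdiff(seq_len(8), c(two$panel$fixed_red, two$panel$fixed_blue))
  exact <- oracle_fr(oracle_enumerate(Wd, st0$spins, vn, tau = 2), 8)

  R <- 4000
  sim <- simulate_infi(mt, two$panel, sim_config(R = R, tau_max = 2, seed = 12))
  se <- sqrt(exact * (1 - exact) / R)
  expect_true(all(abs(sim$fr_per_node - exact) <= pmax(3 * se, 1e-12)))
  # the fixture is genuinely stochastic: some node has 0 < fr < 1
  expect_true(any(exact > 0 & exact < 1))
})

test_that("ensemble trajectories converge and hold after convergence", {
  b <- bench()
  sim <- simulate_infi(b$mats, b$panel, sim_config(R = 100, tau_max = 40, seed = 5))
  traj <- sim$fr_trajectory
  expect_equal(length(traj), 40L)
  expect_equal(traj[40], sim$fr_mean, tolerance = 1e-12)
  tmax <- max(sim$tau_last)
  expect_true(all(abs(diff(traj[tmax:40])) == 0))
  expect_true(all(sim$tau_last <= 40L))
})
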