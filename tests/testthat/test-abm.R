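test_that("network initialisation honours exact counts, feasibility and seeds", {
  # complete intra graphs when the counts saturate
  pars4 <- coevo_params(n1 = 4, n2 = 4, l1 = 6, l2 = 6, l12 = 0)
  net4 <- init_network(pars4, 0.5, seed = 1)
  ed <- network_edges(net4)
  expect_equal(nrow(ed), 12L)
  expect_equal(sum(ed$from_group == 1 & ed$to_group == 1), 6L)
  expect_equal(sum(ed$from_group == 2 & ed$to_group == 2), 6L)
  # all-D at fraction 0
  pars <- ref_params()
  net0 <- init_network(pars, 0, seed = 2)
  expect_true(all(net0$strategy == "D"))
  # exact cooperator counts per group
  net <- init_network(pars, c(0.37, 0.62), seed = 3)
  expect_equal(sum(net$strategy == "C" & net$group == 1), floor(0.37 * 100))
  expect_equal(sum(net$strategy == "C" & net$group == 2), floor(0.62 * 100))
  # simple graph with the prescribed compartment counts
  e <- network_edges(net)
  expect_equal(as.integer(table(e$from_group * 10 + e$to_group)[c("11", "22", "12")]),
               c(500L, 500L, 200L))
  expect_false(any(e$from == e$to))
  expect_equal(anyDuplicated(cbind(pmin(e$from, e$to), pmax(e$from, e$to))), 0L)
  # same seed, same network; different seed, different network
  expect_identical(init_network(pars, 0.5, seed = 9),
                   init_network(pars, 0.5, seed = 9))
  expect_false(identical(init_network(pars, 0.5, seed = 9)$edges,
                         init_network(pars, 0.5, seed = 10)$edges))
  expect_error(init_network(coevo_params(n1 = 4, l1 = 10)), "infeasible")
})

test_that("accumulated payoff sums the donation game over all current neighbours", {
  pars <- coevo_params(b = 2, c = 1, n1 = 4, n2 = 4, l1 = 0, l2 = 0, l12 = 0)
  net <- init_network(pars, 0, seed = 1)
  # hand-built: node 1 (C) linked to three Cs (2,3,5); node 4 (D) linked
  # to two Cs (2,3) and one D (8)
  net$strategy <- c("C", "C", "C", "D", "C", "D", "D", "D")
  net$edges <- rbind(c(1, 2), c(1, 3), c(1, 5), c(4, 2), c(4, 3), c(4, 8))
  pay <- accumulated_payoff(net, pars)
  expect_equal(pay[1], 3 * (2 - 1))          # C with 3 C-neighbours
  expect_equal(pay[4], 2 * 2)                # D with 2 C-, 1 D-neighbour
  expect_equal(pay[6], 0)                    # isolated node
  expect_equal(pay[2], (2 - 1) + (-1))       # C meeting one C and one D
})

test_that("single strategy events follow the Fermi rule in both degenerate regimes", {
  pars <- ref_params(w = 0)
  net <- init_network(pars, 0.5, seed = 4)
  # monomorphic network is absorbing under strategy updates
  netC <- net; netC$strategy[] <- "C"
  set.seed(1)
  for (i in 1:20) netC <- strategy_update_event(netC, pars)
  expect_true(all(netC$strategy == "C"))
  # at w = 0 acceptance is exactly 1/2: over many single events from the
  # same state, about half of the C-D encounters flip the neighbour
  set.seed(2)
  flips <- replicate(400, {
    n2 <- strategy_update_event(net, pars)
    any(n2$strategy != net$strategy)
  })
  enc <- mean(flips)
  # expected flip rate = P(discordant pair) / 2; estimate the pair rate
  # from the link composition
  ed <- network_edges(net)
  disc <- mean(ed$from_strategy != ed$to_strategy)
  expect_lt(abs(enc - disc / 2), 3 * sqrt(disc / 2 * (1 - disc / 2) / 400))
})

test_that("link events conserve the edge count and freeze when nothing breaks", {
  pars0 <- coevo_params(schedule = breaking_schedule(0, 0, 0))
  net <- init_network(pars0, 0.5, seed = 5)
  set.seed(3)
  frozen <- net
  for (i in 1:10) frozen <- link_update_event(frozen, pars0)
  expect_identical(frozen$edges, net$edges)
  # with breaking on, the edge count stays constant and the graph simple
  pars <- ref_params()
  sim <- simulate_coevolution(pars, 0.5, horizon = 1e5, seed = 6,
                              events = "link", sample_every = 1e4)
  counts <- rowSums(as.matrix(sim$series[, link_types()$type]))
  expect_true(all(counts == 1200))
  expect_silent(coevonet:::.validate_network(sim$network))
})

test_that("cached link-type counters equal a full recount after many events", {
  pars <- ref_params()
  sim <- simulate_coevolution(pars, 0.5, horizon = 1e5, seed = 7,
                              sample_every = 0)
  last <- sim$series[nrow(sim$series), link_types()$type]
  expect_equal(unname(unlist(last)), link_type_counts(sim$network)$count)
})

test_that("simulation runs are bit-reproducible and respect the event mix", {
  pars <- ref_params()
  s1 <- simulate_coevolution(pars, 0.5, horizon = 5e4, seed = 8)
  s2 <- simulate_coevolution(pars, 0.5, horizon = 5e4, seed = 8)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$network, s2$network)
  # W = 0: frequencies never move
  sW0 <- simulate_coevolution(update_params(pars, W = 0), c(0.4, 0.6),
                              horizon = 5e4, seed = 9, sample_every = 1e4)
  expect_true(all(sW0$series$x1 == 0.4))
  expect_true(all(sW0$series$x2 == 0.6))
  # W = 1: network static, only strategies move
  sW1 <- simulate_coevolution(update_params(pars, W = 1), 0.5,
                              horizon = 5e3, seed = 10)
  net0 <- init_network(pars, 0.5, seed = 10)
  expect_equal(sort(paste(pmin(sW1$network$edges[, 1], sW1$network$edges[, 2]),
                          pmax(sW1$network$edges[, 1], sW1$network$edges[, 2]))),
               sort(paste(pmin(net0$edges[, 1], net0$edges[, 2]),
                          pmax(net0$edges[, 1], net0$edges[, 2]))))
})

test_that("frozen-strategy link-type frequencies converge to the chain's stationary law", {
  # sparse regime (mean degree 2.5 against groups of 100); snapshots are
  # separated by far more events than a full link turnover, so they are
  # effectively independent draws of the stationary network
  pars <- sparse_params()
  L <- 250
  x1 <- 0.6; x2 <- 0.4
  pi_pred <- link_stationary(pars, x1, x2)
  sim <- simulate_coevolution(pars, coop_frac = c(x1, x2), horizon = 5e5,
                              seed = 11, events = "link", sample_every = 5e4)
  snaps <- as.matrix(sim$series[sim$series$event >= 1e5, pi_pred$type]) / L
  emp <- colMeans(snaps)
  se <- sqrt(pi_pred$pi * (1 - pi_pred$pi) / (nrow(snaps) * L))
  z <- abs(emp - pi_pred$pi) / pmax(se, 1e-12)
  expect_true(all(z < 3))
})

test_that("absorbing initialisations and the final-cooperation summary behave", {
  pars <- ref_params()
  fcC <- final_cooperation(pars, coop_frac = 1, replicates = 3, horizon = 1e4)
  expect_equal(fcC$mean, 1)
  fcD <- final_cooperation(pars, coop_frac = 0, replicates = 3, horizon = 1e4)
  expect_equal(fcD$mean, 0)
  expect_equal(fcD$stderr, 0)
  # replicates are independent and seeded: same base seed reproduces
  f1 <- final_cooperation(pars, 0.5, replicates = 4, horizon = 2e4, seed = 5)
  f2 <- final_cooperation(pars, 0.5, replicates = 4, horizon = 2e4, seed = 5)
  expect_identical(attr(f1, "finals"), attr(f2, "finals"))
})

test_that("far from the basin boundary, fixation follows the mean-field prediction", {
  # fast rewiring, weak selection: deep in each basin the stochastic runs
  # agree with the deterministic attractor in a clear majority
  pars <- ref_params()
  lo <- attr(final_cooperation(pars, 0.1, replicates = 10, horizon = 3e7,
                               seed = 31), "finals")
  hi <- attr(final_cooperation(pars, 0.9, replicates = 10, horizon = 3e7,
                               seed = 31), "finals")
  expect_gt(sum(lo < 0.5), 5)
  expect_gt(sum(hi > 0.5), 5)
})

test_that("node-uniform pair sampling hands low-degree defectors an imitation advantage", {
  # with k_CD > k_CC defectors sit on fewer links; sampling the focal
  # player uniformly then a neighbour overweights defector-focal pairs and
  # defection sweeps even from a cooperator-heavy start, while link-based
  # sampling preserves the bistable basin structure
  pars <- ref_params()
  node <- final_cooperation(pars, 0.8, replicates = 5, horizon = 5e6,
                            seed = 21, pair_sampling = "node")
  link <- final_cooperation(pars, 0.8, replicates = 5, horizon = 5e6,
                            seed = 21, pair_sampling = "link")
  expect_equal(node$mean, 0)
  expect_gt(link$mean, 0.5)
})
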