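test_that("average fitness matches boundary, symmetry and well-mixed oracles", {
  pars <- ref_params()
  Mr <- rescale_payoff(pars$payoff, pars$schedule)
  # all-defector population: C earns the rescaled S entry per unit weight,
  # D earns the rescaled P entry
  f0 <- mean_fitness(pars, 0, 0)
  expect_equal(f0$fitness[f0$strategy == "C"], rep(Mr["C", "D"], 2))
  expect_equal(f0$fitness[f0$strategy == "D"], rep(Mr["D", "D"], 2))
  # symmetric parameters and equal frequencies: groups indistinguishable
  fs <- mean_fitness(pars, 0.42, 0.42)
  expect_equal(fs$fitness[fs$group == 1], fs$fitness[fs$group == 2])
  # all k = 1 and x1 = x2: the well-mixed donation game, by direct
  # expectation over a random opponent
  pars1 <- coevo_params(k_cc = 1, k_cd = 1, k_dd = 1, p = 0.37)
  x <- 0.63
  fw <- mean_fitness(pars1, x, x)
  M <- pars1$payoff
  expect_equal(fw$fitness[fw$strategy == "C"][1],
               x * M["C", "C"] + (1 - x) * M["C", "D"])
  expect_equal(fw$fitness[fw$strategy == "D"][1],
               x * M["D", "C"] + (1 - x) * M["D", "D"])
})

test_that("Fermi transition probabilities are neutral at w = 0 and respect missing strategies", {
  pars0 <- ref_params(w = 0)
  r <- imitation_rates(pars0, 0.35, 0.62)
  # at w = 0 acceptance is exactly 1/2; the only asymmetry is the neutral
  # cross-group exchange
  p <- pars0$p
  expect_equal(r$t_plus[1] - r$t_minus[1],
               unname((1 - p) * (0.62 - 0.35) / 2 *
                        (1 / 0.8) / sum_pair_mass(pars0, 0.35, 0.62)),
               tolerance = 1e-12)
  # x1 = 0: no intra-group cooperator to imitate; gain channel is purely
  # cross-group
  r0 <- imitation_rates(ref_params(), 0, 0.5)
  expect_gt(r0$t_plus[1], 0)
  r00 <- imitation_rates(ref_params(), 0, 0)
  expect_equal(r00$t_plus, c(0, 0))
  expect_equal(r00$t_minus, c(0, 0))
})

test_that("Fermi drift matches a direct Monte-Carlo of the pairwise process", {
  pars <- ref_params(w = 0.1)
  x1 <- 0.55; x2 <- 0.3
  r <- imitation_rates(pars, x1, x2)
  # oracle: draw ordered linked pairs from the stationary pair law (built
  # from the numeric eigen-solve, not the closed form), apply the Fermi
  # acceptance by coin flip, tally the change in each group's C count
  set.seed(11)
  P <- link_transition_matrix(pars, x1, x2)
  pi_n <- link_stationary_numeric(P)
  lt <- link_types()
  k <- as.numeric(pars$schedule)
  # ordered pair law: split each unordered type's breaking-flux-free mass
  # evenly over its two orientations
  labs <- c("C1", "D1", "C2", "D2")
  prob <- matrix(0, 4, 4, dimnames = list(labs, labs))
  for (i in seq_len(10)) {
    a <- paste0(lt$a_strategy[i], lt$a_group[i])
    b <- paste0(lt$b_strategy[i], lt$b_group[i])
    prob[a, b] <- prob[a, b] + pi_n$pi[i] / 2
    prob[b, a] <- prob[b, a] + pi_n$pi[i] / 2
  }
  fit <- setNames(mean_fitness(pars, x1, x2)$fitness, c("C1", "D1", "C2", "D2"))
  n <- 4e5
  draws <- sample(16, n, replace = TRUE, prob = as.numeric(prob))
  focal <- labs[(draws - 1) %% 4 + 1]
  nb <- labs[(draws - 1) %/% 4 + 1]
  acc <- stats::runif(n) < 1 / (1 + exp(-pars$w * (fit[focal] - fit[nb])))
  dx1 <- sum(acc & focal %in% c("C1", "C2") & nb == "D1") -
    sum(acc & focal %in% c("D1", "D2") & nb == "C1")
  drift_mc <- dx1 / n
  drift_an <- r$t_plus[1] - r$t_minus[1]
  se <- sqrt(2 * sum(prob[c("C1", "C2"), "D1"], prob[c("D1", "D2"), "C1"]) / n)
  expect_lt(abs(drift_mc - drift_an), 4 * se)
})

test_that("replicator field vanishes at the corners and keeps the diagonal invariant", {
  set.seed(21)
  for (i in 1:10) {
    pars <- random_params()
    expect_equal(unname(replicator_field(pars, 0, 0)), c(0, 0))
    expect_equal(unname(replicator_field(pars, 1, 1)), c(0, 0))
    expect_equal(unname(replicator_field(pars, 0, 0, limit = "fermi")), c(0, 0))
    expect_equal(unname(replicator_field(pars, 1, 1, limit = "fermi")), c(0, 0))
    x <- runif(1)
    f <- replicator_field(pars, x, x)
    expect_equal(f[["dx1"]], f[["dx2"]], tolerance = 1e-14)
  }
})

test_that("weak-selection field is the w -> 0 limit of the Fermi drift up to a fixed rescaling", {
  pars <- ref_params()
  state <- c(0.45, 0.7)
  ratios <- vapply(c(1e-2, 1e-3, 1e-4), function(w) {
    p <- update_params(pars, w = w)
    f7 <- replicator_field(p, state[1], state[2], limit = "fermi")
    f8 <- replicator_field(p, state[1], state[2], limit = "weak")
    f7[["dx1"]] / f8[["dx1"]]
  }, numeric(1))
  # ratio converges (to the dropped state-dependent normalisation)
  expect_lt(abs(ratios[2] - ratios[3]), abs(ratios[1] - ratios[2]))
  expect_lt(abs(ratios[2] - ratios[3]) / abs(ratios[3]), 5e-3)
})

test_that("unit square is forward-invariant for the weak-selection field", {
  pars <- ref_params()
  g <- seq(0, 1, length.out = 100)
  for (xx in g) {
    expect_gte(replicator_field(pars, 0, xx)[["dx1"]], 0)
    expect_lte(replicator_field(pars, 1, xx)[["dx1"]], 0)
    expect_gte(replicator_field(pars, xx, 0)[["dx2"]], 0)
    expect_lte(replicator_field(pars, xx, 1)[["dx2"]], 0)
  }
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(31)
  for (i in 1:20) {
    pars <- random_params()
    x1 <- runif(1, 0.05, 0.95); x2 <- runif(1, 0.05, 0.95)
    J <- replicator_jacobian(pars, x1, x2)
    h <- 1e-6
    fd <- cbind(
      (replicator_field(pars, x1 + h, x2) - replicator_field(pars, x1 - h, x2)) / (2 * h),
      (replicator_field(pars, x1, x2 + h) - replicator_field(pars, x1, x2 - h)) / (2 * h)
    )
    expect_equal(unname(J), unname(fd), tolerance = 1e-6)
  }
})

test_that("Jacobian commutes with the coordinate swap on the diagonal", {
  S <- matrix(c(0, 1, 1, 0), 2)
  set.seed(41)
  for (i in 1:5) {
    pars <- random_params()
    x <- runif(1)
    J <- unname(replicator_jacobian(pars, x, x))
    expect_equal(J %*% S, S %*% J, tolerance = 1e-12)
  }
})

test_that("closed-form equilibrium eigenvalues equal the numeric eigen-decomposition", {
  set.seed(51)
  for (i in 1:20) {
    pars <- random_params()
    ev <- equilibrium_eigenvalues(pars)
    for (j in seq_len(nrow(ev))) {
      J <- replicator_jacobian(pars, ev$x1[j], ev$x2[j])
      expect_equal(sort(eigen(J, only.values = TRUE)$values),
                   unname(sort(c(ev$lambda_diag[j], ev$lambda_off[j]))),
                   tolerance = 1e-8)
    }
  }
})

test_that("critical benefit-to-cost ratio marks the stability change of all-C", {
  pars <- coevo_params(k_cc = 0.3, k_cd = 0.9)
  thr <- critical_benefit_cost(pars)
  expect_equal(thr, 0.9 / 0.6)
  # monotone: more fragile mixed links lower the threshold, more fragile
  # C-C links raise it
  expect_lt(critical_benefit_cost(coevo_params(k_cc = 0.3, k_cd = 0.95)), thr)
  expect_gt(critical_benefit_cost(coevo_params(k_cc = 0.4, k_cd = 0.9)), thr)
  expect_equal(critical_benefit_cost(coevo_params(k_cc = 0.5, k_cd = 0.5)), Inf)
  # eigenvalue oracle: just above the threshold all-C is stable, just
  # below it is not (c chosen so b/c straddles thr)
  for (eps in c(-0.02, 0.02)) {
    bc <- thr * (1 + eps)
    p2 <- coevo_params(b = bc, c = 1, k_cc = 0.3, k_cd = 0.9)
    ev <- equilibrium_eigenvalues(p2)
    stable <- all(unlist(ev[ev$equilibrium == "allc", c("lambda_diag", "lambda_off")]) < 0)
    expect_equal(stable, eps > 0)
  }
  # sign-change bisection in b/c agrees with the closed form to 1e-6
  f <- function(bc) {
    p2 <- coevo_params(b = bc, c = 1, k_cc = 0.3, k_cd = 0.9)
    max(unlist(equilibrium_eigenvalues(p2)[2, c("lambda_diag", "lambda_off")]))
  }
  root <- uniroot(f, c(1.01, 10), tol = 1e-9)$root
  expect_equal(root, thr, tolerance = 1e-6)
})

test_that("interior fixed point matches the diagonal root and the caption monotonicities", {
  pars <- ref_params()
  xs <- interior_fixed_point(pars)
  expect_equal(xs, 1 / 3, tolerance = 1e-12)
  # root-finding oracle on the diagonal field
  g <- function(x) replicator_field(pars, x, x)[["dx1"]]
  root <- uniroot(g, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  expect_equal(xs, root, tolerance = 1e-8)
  # basin boundary from trajectory bisection sits at x*
  expect_equal(basin_threshold(pars, tol = 1e-6), xs, tolerance = 1e-5)
  # x* grows with the fragility ratio k_cc / k_cd (smaller basin of
  # cooperation) and shrinks as the benefit grows (larger basin)
  kappa <- seq(0.1, 0.4, by = 0.1)
  xs_k <- vapply(kappa, function(k)
    interior_fixed_point(coevo_params(k_cc = k * 0.8, k_cd = 0.8)), numeric(1))
  expect_true(all(diff(xs_k) > 0))
  bs <- seq(1.5, 3, by = 0.5)
  xs_b <- vapply(bs, function(b)
    interior_fixed_point(coevo_params(b = b, c = 0.75)), numeric(1))
  expect_true(all(diff(xs_b) < 0))
  # absent when the threshold condition fails
  expect_true(is.na(interior_fixed_point(coevo_params(k_cc = 0.8, k_cd = 0.2))))
})

test_that("critical intra-group bias separates saddle from unstable interior node", {
  pars <- ref_params(w = 0.2)
  pc <- critical_intra_bias(pars)
  expect_true(!is.na(pc) && pc > 0.5 && pc < 1)
  # below p_c the interior point is a saddle, above an unstable node
  lab <- function(p) {
    rep <- classify_equilibria(update_params(pars, p = p))
    rep$equilibria$label[rep$equilibria$equilibrium == "interior"]
  }
  expect_equal(lab(pc - 1e-3), "saddle")
  expect_equal(lab(pc + 1e-3), "unstable")
  # bisection is stable under tolerance refinement
  expect_lt(abs(critical_intra_bias(pars, tol = 1e-6) -
                  critical_intra_bias(pars, tol = 1e-9)), 1e-5)
  # closed-form oracle: the transverse eigenvalue is a quadratic in p
  cf <- coevonet:::.mf_coefs(pars)
  xs <- interior_fixed_point(pars)
  q <- (pars$w / 2) * xs * (1 - xs) * cf$D
  pc_quad <- (-(1 - q) + sqrt((1 - q)^2 + 8 * q)) / (4 * q)
  expect_equal(pc, pc_quad, tolerance = 1e-8)
})

test_that("equilibrium classification reports bistability with stable corners", {
  rep <- classify_equilibria(ref_params())
  td <- tidy(rep)
  expect_equal(td$label[td$equilibrium == "origin"], "stable")
  expect_equal(td$label[td$equilibrium == "allc"], "stable")
  expect_equal(td$label[td$equilibrium == "interior"], "saddle")
  gl <- glance(rep)
  expect_true(gl$bistable)
  expect_equal(gl$x_star, 1 / 3, tolerance = 1e-12)
  expect_equal(gl$bc_critical, 4 / 3, tolerance = 1e-12)
  # defection-dominant game: all-C unstable, no interior point
  rep2 <- classify_equilibria(coevo_params(b = 1.2, c = 1))
  td2 <- tidy(rep2)
  expect_false("interior" %in% td2$equilibrium)
  expect_false(rep2$bistable)
})

test_that("trajectories converge to the basin-predicted corner and respect tolerances", {
  pars <- ref_params()
  # constant at a fixed point
  tr0 <- integrate_replicator(pars, c(0, 0), horizon = 10)
  expect_equal(unname(attr(tr0, "terminal")), c(0, 0))
  # above the diagonal boundary -> all-C; below -> all-D
  hi <- integrate_replicator(pars, c(0.5, 0.5))
  lo <- integrate_replicator(pars, c(0.2, 0.2))
  expect_true(attr(hi, "converged") && mean(attr(hi, "terminal")) > 0.99)
  expect_true(attr(lo, "converged") && mean(attr(lo, "terminal")) < 0.01)
  # off-diagonal start still lands on a corner
  od <- integrate_replicator(pars, c(0.9, 0.35))
  expect_true(attr(od, "converged"))
  # halving the tolerance does not move the terminal state
  t1 <- attr(integrate_replicator(pars, c(0.41, 0.52), rtol = 1e-8), "terminal")
  t2 <- attr(integrate_replicator(pars, c(0.41, 0.52), rtol = 5e-9), "terminal")
  expect_equal(t1, t2, tolerance = 1e-6)
  # trajectories stay in the unit square
  expect_unit_square_state(c(hi$x1, hi$x2, lo$x1, lo$x2, od$x1, od$x2))
})
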