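# Shared fixtures: the bistable reference world and a sparse variant whose
# mean degree is small against the group size (the regime in which the
# link-type chain's mean-field partner sampling is accurate).

ref_params <- function(...) coevo_params(...)

sparse_params <- function(...) {
  coevo_params(n1 = 100, n2 = 100, l1 = 90, l2 = 90, l12 = 70, ...)
}

# random parameter draw for property-style loops
random_params <- function() {
  b <- runif(1, 1, 4)
  coevo_params(
    b = b, c = runif(1, 0.2, 0.9) * b,
    k_cc = runif(1, 0.05, 1), k_cd = runif(1, 0.05, 1),
    k_dd = runif(1, 0.05, 1),
    p = runif(1, 0.05, 0.95), w = runif(1, 0.01, 0.2)
  )
}

expect_unit_square_state <- function(x) {
  expect_true(all(x >= 0 & x <= 1))
}

# total unnormalised mass of the stationary ordered-pair law, the
# normalisation the Fermi transition probabilities divide by
sum_pair_mass <- function(pars, x1, x2) {
  f <- c(C1 = x1, D1 = 1 - x1, C2 = x2, D2 = 1 - x2)
  grp <- c(1, 1, 2, 2)
  str <- c("C", "D", "C", "D")
  kp <- c(CC = pars$k_cc, CD = pars$k_cd, DD = pars$k_dd)
  Z <- 0
  for (u in 1:4) for (v in 1:4) {
    wgt <- if (grp[u] == grp[v]) pars$p else 1 - pars$p
    pr <- paste0(min(str[u], str[v]), max(str[u], str[v]))
    Z <- Z + wgt * f[u] * f[v] / kp[[pr]]
  }
  Z
}
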