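# Deterministic population-level dynamics under fast rewiring: average
# fitness from the stationary link structure, Fermi pairwise-comparison
# transition rates, the extended replicator field and its weak-selection
# limit, Jacobians, equilibrium classification and the two thresholds
# (critical benefit-to-cost ratio, critical intra-group bias).

# Rescaled-entry shorthands.  R' = (b-c)/k_CC, S' = -c/k_CD, T' = b/k_CD,
# P' = 0/k_DD; the analysis layer works with
#   A = R' - T'   (stability margin of all-C),
#   B = S' - P'   (invasion margin at all-D, always negative),
#   D = A - B = (b-c)(1/k_CC - 1/k_CD).
.mf_coefs <- function(params) {
  Mr <- rescale_payoff(params$payoff, params$schedule)
  Rp <- Mr["C", "C"]; Sp <- Mr["C", "D"]; Tp <- Mr["D", "C"]; Pp <- Mr["D", "D"]
  list(Rp = Rp, Sp = Sp, Tp = Tp, Pp = Pp,
       A = Rp - Tp, B = Sp - Pp, D = (Rp - Sp) - (Tp - Pp),
       u = Rp - Sp, v = Tp - Pp)
}

.check_state <- function(x1, x2) {
  stopifnot(is.numeric(x1), is.numeric(x2), length(x1) == 1L, length(x2) == 1L)
  if (x1 < 0 || x1 > 1 || x2 < 0 || x2 > 1)
    stop("state (x1, x2) must lie in the unit square")
}

#' Average fitness of each strategy in each group
#'
#' Under fast rewiring the link structure sits in the stationary
#' distribution of the link-type chain, so a player's expected payoff per
#' unit link mass is an average over the rescaled payoff matrix: a weight
#' `p` on opponents of its own group and `1 - p` on opponents of the other
#' group, each opponent cooperating with its group's frequency.  Writing
#' `m_g = p x_g + (1-p) x_h` for the opponent-cooperator mix seen from
#' group g, the fitnesses are `f_Cg = m_g R' + (1 - m_g) S'` and
#' `f_Dg = m_g T' + (1 - m_g) P'` with `R', S', T', P'` the entries of
#' [rescale_payoff()].  A common positive factor (total links over group
#' size, normalisation of the stationary distribution) is dropped; it only
#' rescales the selection intensity.
#'
#' @param params A [coevo_params()] object.
#' @param x1,x2 Cooperator frequencies of the two groups, in `[0, 1]`.
#' @return A tibble with columns `group`, `strategy`, `fitness` (4 rows).
#' @examples
#' mean_fitness(coevo_params(), 0.5, 0.5)
#' @export
mean_fitness <- function(params, x1, x2) {
  stopifnot(inherits(params, "coevo_params"))
  .check_state(x1, x2)
  cf <- .mf_coefs(params)
  p <- params$p
  m1 <- p * x1 + (1 - p) * x2
  m2 <- p * x2 + (1 - p) * x1
  tibble::tibble(
    group    = c(1L, 1L, 2L, 2L),
    strategy = c("C", "D", "C", "D"),
    fitness  = c(m1 * cf$Rp + (1 - m1) * cf$Sp,
                 m1 * cf$Tp + (1 - m1) * cf$Pp,
                 m2 * cf$Rp + (1 - m2) * cf$Sp,
                 m2 * cf$Tp + (1 - m2) * cf$Pp)
  )
}

.fitness_vec <- function(params, x1, x2) {
  f <- mean_fitness(params, x1, x2)
  setNames(f$fitness, paste0(f$strategy, f$group))
}

.fermi <- function(delta, w) 1 / (1 + exp(-w * delta))

#' Fermi pairwise-comparison transition probabilities
#'
#' Probability per event that the number of cooperators in each group rises
#' (`t_plus`) or falls (`t_minus`).  A focal-neighbour pair is drawn from
#' the stationary link structure (an ordered pair of labels (strategy,
#' group) has probability proportional to `w(g, g') f f' / k`, the
#' stationary pair law of the link-type chain), and the focal player's
#' strategy replaces the neighbour's with the Fermi probability
#' `1 / (1 + exp(-w (f_focal - f_neighbour)))`.  `t_plus` for group g sums
#' the channels where a cooperator of either group converts a defector of
#' group g; `t_minus` the reverse channels.
#'
#' At `w = 0` every acceptance probability is exactly 1/2 and the only
#' remaining drift is the neutral cross-group exchange proportional to
#' `x_h - x_g`.
#'
#' @inheritParams mean_fitness
#' @return A tibble with columns `group`, `t_plus`, `t_minus`.
#' @export
imitation_rates <- function(params, x1, x2) {
  stopifnot(inherits(params, "coevo_params"))
  .check_state(x1, x2)
  k <- .schedule_pair(params$schedule)
  if (any(k <= 0)) stop("imitation rates require all k > 0")
  p <- params$p
  f <- c(C1 = x1, D1 = 1 - x1, C2 = x2, D2 = 1 - x2)
  grp <- c(C1 = 1L, D1 = 1L, C2 = 2L, D2 = 2L)
  str <- c(C1 = "C", D1 = "D", C2 = "C", D2 = "D")
  labs <- names(f)
  wgt <- function(u, v) if (grp[u] == grp[v]) p else 1 - p
  kpair <- function(u, v) {
    pr <- paste0(min(str[u], str[v]), max(str[u], str[v]))
    k[[pr]]
  }
  # ordered-pair stationary law
  vmat <- outer(labs, labs, Vectorize(function(u, v)
    wgt(u, v) * f[[u]] * f[[v]] / kpair(u, v)))
  dimnames(vmat) <- list(labs, labs)
  Z <- sum(vmat)
  fit <- .fitness_vec(params, x1, x2)
  pair_prob <- function(focal, nb) vmat[focal, nb] / Z
  acc <- function(focal, nb) .fermi(fit[[focal]] - fit[[nb]], params$w)
  t_pm <- function(g) {
    dg <- paste0("D", g); cg <- paste0("C", g)
    tp <- sum(vapply(c("C1", "C2"), function(ch)
      pair_prob(ch, dg) * acc(ch, dg), numeric(1)))
    tm <- sum(vapply(c("D1", "D2"), function(dh)
      pair_prob(dh, cg) * acc(dh, cg), numeric(1)))
    c(tp, tm)
  }
  r1 <- t_pm(1L); r2 <- t_pm(2L)
  tibble::tibble(group = c(1L, 2L),
                 t_plus = c(r1[1], r2[1]),
                 t_minus = c(r1[2], r2[2]))
}

# Weak-selection (order-w) polynomial drift for group 1; group 2 follows by
# exchanging the arguments.  The state-dependent positive normalisation of
# the pair law and the common 1/k_CD factor are dropped (time
# reparameterisation; orbits and stability are unaffected).
.weak_field_1 <- function(params, x1, x2) {
  cf <- .mf_coefs(params)
  p <- params$p; w <- params$w
  m1 <- p * x1 + (1 - p) * x2
  m2 <- p * x2 + (1 - p) * x1
  df1 <- cf$B + m1 * cf$D                    # f_C1 - f_D1
  g21 <- cf$B + m2 * cf$u - m1 * cf$v        # f_C2 - f_D1
  h21 <- -cf$B + m2 * cf$v - m1 * cf$u       # f_D2 - f_C1
  (1 - p) * (x2 - x1) / 2 +
    (w / 2) * p * x1 * (1 - x1) * df1 +
    (w / 4) * (1 - p) * (x2 * (1 - x1) * g21 - x1 * (1 - x2) * h21)
}

#' Replicator field of the co-evolutionary dynamics
#'
#' The deterministic drift of the cooperator frequencies `(x1, x2)`.  Two
#' forms are available:
#'
#' * `limit = "weak"` (default): the weak-selection extension of the
#'   replicator dynamics -- the order-w expansion of the Fermi drift.  Each
#'   group g feels a standard intra-group replicator term
#'   `(w/2) p x_g (1 - x_g) (f_Cg - f_Dg)`, a neutral cross-group exchange
#'   `(1 - p)(x_h - x_g)/2` that equalises the groups, and an order-w
#'   cross-group selection correction.  A state-dependent positive time
#'   rescaling is dropped, so the field is polynomial; all of the analysis
#'   layer (equilibria, eigenvalues, thresholds) refers to this form.
#' * `limit = "fermi"`: the full finite-w drift `t_plus - t_minus` from
#'   [imitation_rates()], kept as genuine probabilities.
#'
#' Both forms vanish identically at (0,0) and (1,1), and the unit square is
#' forward-invariant.
#'
#' @inheritParams mean_fitness
#' @param limit `"weak"` for the order-w replicator extension, `"fermi"`
#'   for the full Fermi drift.
#' @return A named numeric vector `c(dx1 = , dx2 = )`.
#' @examples
#' replicator_field(coevo_params(), 0.5, 0.4)
#' @export
replicator_field <- function(params, x1, x2, limit = c("weak", "fermi")) {
  limit <- match.arg(limit)
  stopifnot(inherits(params, "coevo_params"))
  .check_state(x1, x2)
  if (limit == "weak") {
    c(dx1 = .weak_field_1(params, x1, x2),
      dx2 = .weak_field_1(params, x2, x1))
  } else {
    r <- imitation_rates(params, x1, x2)
    c(dx1 = r$t_plus[1] - r$t_minus[1],
      dx2 = r$t_plus[2] - r$t_minus[2])
  }
}

# Analytic partials of the weak-selection field for group 1.
.weak_grad_1 <- function(params, x1, x2) {
  cf <- .mf_coefs(params)
  p <- params$p; w <- params$w
  m1 <- p * x1 + (1 - p) * x2
  m2 <- p * x2 + (1 - p) * x1
  df1 <- cf$B + m1 * cf$D
  g21 <- cf$B + m2 * cf$u - m1 * cf$v
  h21 <- -cf$B + m2 * cf$v - m1 * cf$u
  dg21_d1 <- (1 - p) * cf$u - p * cf$v
  dg21_d2 <- p * cf$u - (1 - p) * cf$v
  dh21_d1 <- (1 - p) * cf$v - p * cf$u
  dh21_d2 <- p * cf$v - (1 - p) * cf$u
  d1 <- -(1 - p) / 2 +
    (w / 2) * p * ((1 - 2 * x1) * df1 + x1 * (1 - x1) * p * cf$D) +
    (w / 4) * (1 - p) *
      (-x2 * g21 + x2 * (1 - x1) * dg21_d1 -
         (1 - x2) * h21 - x1 * (1 - x2) * dh21_d1)
  d2 <- (1 - p) / 2 +
    (w / 2) * p * x1 * (1 - x1) * (1 - p) * cf$D +
    (w / 4) * (1 - p) *
      ((1 - x1) * g21 + x2 * (1 - x1) * dg21_d2 +
         x1 * h21 - x1 * (1 - x2) * dh21_d2)
  c(d1, d2)
}

#' Jacobian of the weak-selection replicator field
#'
#' Analytic 2x2 Jacobian of the `limit = "weak"` field of
#' [replicator_field()].  By the group exchange symmetry of the field the
#' second row is the first row of the swapped state with its entries
#' exchanged.
#'
#' @inheritParams mean_fitness
#' @return A 2x2 numeric matrix.
#' @export
replicator_jacobian <- function(params, x1, x2) {
  stopifnot(inherits(params, "coevo_params"))
  .check_state(x1, x2)
  r1 <- .weak_grad_1(params, x1, x2)
  r2 <- .weak_grad_1(params, x2, x1)
  matrix(c(r1[1], r2[2], r1[2], r2[1]), nrow = 2L,
         dimnames = list(c("dx1", "dx2"), c("x1", "x2")))
}

#' Critical benefit-to-cost ratio for stable cooperation
#'
#' All-cooperate is a stable equilibrium of the weak-selection dynamics iff
#' the rescaled stability margin `A = (b-c)/k_CC - b/k_CD` is positive,
#' i.e. iff \deqn{b/c > \frac{k_{CD}}{k_{CD} - k_{CC}}.}
#' The threshold is finite only when C-D links are more fragile than C-C
#' links (`k_cd > k_cc`); otherwise `Inf` is returned (cooperation is never
#' stable).  It decreases in `k_cd` and increases in `k_cc`: robust
#' cooperator pairs and fragile mixed pairs promote cooperation.  In the
#' degenerate case `k_cc = k_cd` the threshold is infinite.
#'
#' @param params A [coevo_params()] object (only the fragilities are used).
#' @return A scalar threshold for `b/c` (possibly `Inf`).
#' @examples
#' critical_benefit_cost(coevo_params(k_cc = 0.2, k_cd = 0.8))  # 4/3
#' @export
critical_benefit_cost <- function(params) {
  stopifnot(inherits(params, "coevo_params"))
  if (params$k_cd <= params$k_cc) return(Inf)
  params$k_cd / (params$k_cd - params$k_cc)
}

#' Unstable interior fixed point of the symmetric dynamics
#'
#' On the diagonal `x1 = x2 = x` the weak-selection field reduces to
#' `(w/2) x (1-x) (f_C - f_D)` with `f_C - f_D = B + D x`, giving the
#' interior root \deqn{x^* = \frac{c\,k_{CC}}{(b - c)(k_{CD} - k_{CC})}.}
#' The point exists in (0,1) exactly when the benefit-to-cost ratio exceeds
#' the critical value of [critical_benefit_cost()]; it is the basin
#' boundary of cooperation along the diagonal (initial frequencies above
#' `x*` flow to all-C, below to all-D).  `x*` rises with the fragility
#' ratio `k_cc / k_cd` (a more robust mixed link shrinks the basin of
#' cooperation) and falls as `b` grows (a better game enlarges it); it does
#' not depend on `p`.
#'
#' @param params A [coevo_params()] object.
#' @return The interior fixed point in (0,1), or `NA_real_` when absent.
#' @examples
#' interior_fixed_point(coevo_params())  # 1/3
#' @export
interior_fixed_point <- function(params) {
  stopifnot(inherits(params, "coevo_params"))
  if (params$k_cd <= params$k_cc) return(NA_real_)
  xs <- params$c * params$k_cc /
    ((params$b - params$c) * (params$k_cd - params$k_cc))
  if (xs <= 0 || xs >= 1) NA_real_ else xs
}

# Closed-form eigenvalues of the Jacobian at the three candidate
# equilibria.  Eigenvectors are (1,1) ("diag") and (1,-1) ("off") by the
# exchange symmetry.
.equilibrium_eigvals <- function(params) {
  cf <- .mf_coefs(params)
  p <- params$p; w <- params$w
  xs <- interior_fixed_point(params)
  out <- list(
    origin = c(diag = w * cf$B / 2,
               off  = -(1 - p) + w * p * cf$B / 2),
    allc   = c(diag = -w * cf$A / 2,
               off  = -(1 - p) - w * p * cf$A / 2)
  )
  if (!is.na(xs)) {
    q <- (w / 2) * xs * (1 - xs) * cf$D
    out$interior <- c(diag = q, off = -(1 - p) + q * p * (2 * p - 1))
  }
  out
}

#' Closed-form Jacobian eigenvalues at the equilibria
#'
#' The weak-selection field always has the corner equilibria (0,0) and
#' (1,1), plus the interior point `(x*, x*)` when it exists.  The exchange
#' symmetry makes every Jacobian there of the form `[[a, b], [b, a]]`, so
#' the eigenvalues are `a + b` along the diagonal direction (1,1) and
#' `a - b` along (1,-1).  In terms of `A`, `B`, `D` (see
#' [critical_benefit_cost()] and [interior_fixed_point()]):
#'
#' * at (0,0): `wB/2` and `-(1-p) + wpB/2` (both negative: all-D is always
#'   stable);
#' * at (1,1): `-wA/2` and `-(1-p) - wpA/2` (both negative iff the
#'   benefit-to-cost condition holds);
#' * at `(x*, x*)`: `q` and `-(1-p) + q p (2p - 1)` with
#'   `q = (w/2) x*(1-x*) D > 0` -- repelling along the diagonal, and a
#'   saddle or unstable node according to the sign of the second value
#'   (see [critical_intra_bias()]).
#'
#' @param params A [coevo_params()] object.
#' @return A tibble with columns `equilibrium` (`"origin"`, `"allc"`,
#'   `"interior"`), `x1`, `x2`, `lambda_diag`, `lambda_off`.
#' @export
equilibrium_eigenvalues <- function(params) {
  stopifnot(inherits(params, "coevo_params"))
  ev <- .equilibrium_eigvals(params)
  xs <- interior_fixed_point(params)
  pts <- list(origin = c(0, 0), allc = c(1, 1), interior = c(xs, xs))
  nm <- names(ev)
  tibble::tibble(
    equilibrium = nm,
    x1 = vapply(nm, function(n) pts[[n]][1], numeric(1)),
    x2 = vapply(nm, function(n) pts[[n]][2], numeric(1)),
    lambda_diag = vapply(ev, `[[`, numeric(1), "diag"),
    lambda_off = vapply(ev, `[[`, numeric(1), "off")
  )
}

#' Critical intra-group bias
#'
#' At the interior equilibrium the diagonal eigenvalue `q` is always
#' positive, while the transverse eigenvalue `-(1-p) + q p (2p-1)` changes
#' sign at a critical bias `p_c`: below it the interior point is a saddle
#' (the neutral cross-group exchange pins the dynamics to the diagonal),
#' above it an unstable node and the phase portrait is the coordination
#' picture with two stable corners and a repelling interior point.  The
#' root is found by bisection of the closed-form eigenvalue on (0, 1); it
#' is unique because the eigenvalue is increasing in `p` on the relevant
#' range.
#'
#' @param params A [coevo_params()] object.
#' @param tol Bisection tolerance on `p` (default `1e-9`).
#' @return The critical bias in (0, 1), or `NA_real_` when the interior
#'   point is absent or no sign change exists (e.g. `w = 0`).
#' @export
critical_intra_bias <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "coevo_params"))
  xs <- interior_fixed_point(params)
  if (is.na(xs) || params$w <= 0) return(NA_real_)
  cf <- .mf_coefs(params)
  q <- (params$w / 2) * xs * (1 - xs) * cf$D
  g <- function(p) -(1 - p) + q * p * (2 * p - 1)
  if (g(1) <= 0) return(NA_real_)   # never an unstable node below p = 1
  uniroot(g, c(0, 1), tol = tol)$root
}

.label_eigvals <- function(l1, l2) {
  if (l1 < 0 && l2 < 0) "stable"
  else if (l1 > 0 && l2 > 0) "unstable"
  else if (l1 * l2 < 0) "saddle"
  else "non-hyperbolic"
}

#' Classify the equilibria of the weak-selection dynamics
#'
#' Evaluates the closed-form eigenvalues at (0,0), (1,1) and (when present)
#' `(x*, x*)`, labels each point stable / unstable / saddle, and collects
#' the two thresholds of the model: the critical benefit-to-cost ratio and
#' the critical intra-group bias.  The report prints a summary and has
#' [tidy()] / [glance()] methods; `tidy()` returns the per-equilibrium
#' table, `glance()` a one-row tibble with `bc_ratio`, `bc_critical`,
#' `x_star`, `p_critical` and the logical `bistable` (both corners stable
#' with a repelling interior point).
#'
#' @param params A [coevo_params()] object.
#' @return An object of class `"equilibrium_report"`.
#' @examples
#' classify_equilibria(coevo_params())
#' @export
classify_equilibria <- function(params) {
  stopifnot(inherits(params, "coevo_params"))
  tab <- equilibrium_eigenvalues(params)
  tab$label <- unname(mapply(.label_eigvals, tab$lambda_diag,
                             tab$lambda_off, USE.NAMES = FALSE))
  xs <- interior_fixed_point(params)
  bistable <- all(tab$label[tab$equilibrium %in% c("origin", "allc")] ==
                    "stable") && !is.na(xs)
  structure(list(
    equilibria = tab,
    x_star = xs,
    bc_ratio = params$b / params$c,
    bc_critical = critical_benefit_cost(params),
    p_critical = critical_intra_bias(params),
    bistable = bistable,
    params = params
  ), class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("<equilibrium_report>\n")
  print(as.data.frame(x$equilibria), row.names = FALSE)
  cat(sprintf("  b/c = %.4g (critical %.4g); x* = %s; p_c = %s; bistable: %s\n",
              x$bc_ratio, x$bc_critical,
              ifelse(is.na(x$x_star), "absent", sprintf("%.6g", x$x_star)),
              ifelse(is.na(x$p_critical), "absent", sprintf("%.6g", x$p_critical)),
              x$bistable))
  invisible(x)
}

#' @rdname classify_equilibria
#' @param x An `equilibrium_report`.
#' @param ... Unused.
#' @export
tidy.equilibrium_report <- function(x, ...) x$equilibria

#' @rdname classify_equilibria
#' @export
glance.equilibrium_report <- function(x, ...) {
  tibble::tibble(bc_ratio = x$bc_ratio, bc_critical = x$bc_critical,
                 x_star = x$x_star, p_critical = x$p_critical,
                 bistable = x$bistable)
}

#' Integrate the replicator dynamics
#'
#' Adaptive Cash-Karp Runge-Kutta (order 4/5) integration of the
#' weak-selection field from a given start.  Steps that would leave the
#' unit square are rejected and halved (the exact field is inward or
#' tangent on the boundary, so only roundoff can push outside).
#' Integration stops early once the state is within `ptol` of (0,0) or
#' (1,1) or the field norm falls below machine-level; otherwise it runs to
#' `horizon` and the trajectory is flagged unconverged.
#'
#' @param params A [coevo_params()] object.
#' @param x0 Numeric length-2 start `(x1, x2)` inside the unit square.
#' @param horizon Maximum integration time (the timescale is that of the
#'   polynomial field of [replicator_field()]).
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param ptol Fixed-point arrival tolerance (distance to a corner).
#' @param limit Passed to [replicator_field()].
#' @return A tibble with columns `time`, `x1`, `x2`; attributes
#'   `converged` (logical) and `terminal` (final state).
#' @examples
#' tr <- integrate_replicator(coevo_params(), c(0.6, 0.5), horizon = 2000)
#' attr(tr, "terminal")
#' @export
integrate_replicator <- function(params, x0, horizon = 1e4,
                                 rtol = 1e-8, atol = 1e-10, ptol = 1e-6,
                                 limit = "weak") {
  stopifnot(inherits(params, "coevo_params"), length(x0) == 2L)
  .check_state(x0[1], x0[2])
  fld <- function(s) unname(replicator_field(params, s[1], s[2], limit = limit))
  # Cash-Karp tableau
  a <- list(c(), 1/5, c(3/40, 9/40), c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  b5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  b4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  t <- 0; s <- as.numeric(x0); h <- 1
  times <- t; xs1 <- s[1]; xs2 <- s[2]
  converged <- FALSE
  corners <- list(c(0, 0), c(1, 1))
  max_steps <- 200000L
  for (step in seq_len(max_steps)) {
    if (t >= horizon) break
    near <- vapply(corners, function(cc) sqrt(sum((s - cc)^2)), numeric(1))
    kf <- fld(s)
    if (min(near) < ptol || max(abs(kf)) < 1e-14) { converged <- TRUE; break }
    h <- min(h, horizon - t)
    # one adaptive step
    repeat {
      ks <- matrix(0, 6L, 2L)
      ks[1, ] <- kf
      ok <- TRUE
      for (i in 2:6) {
        si <- s + h * colSums(ks[seq_len(i - 1), , drop = FALSE] * a[[i]])
        if (any(si < -1e-9) || any(si > 1 + 1e-9)) { ok <- FALSE; break }
        si <- pmin(pmax(si, 0), 1)
        ks[i, ] <- fld(si)
      }
      if (ok) {
        s5 <- s + h * colSums(ks * b5)
        s4 <- s + h * colSums(ks * b4)
        if (any(s5 < -1e-12) || any(s5 > 1 + 1e-12)) ok <- FALSE
      }
      if (ok) {
        sc <- atol + rtol * pmax(abs(s), abs(s5))
        err <- max(abs(s5 - s4) / sc)
        if (err <= 1) {
          t <- t + h
          s <- pmin(pmax(s5, 0), 1)
          h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
          break
        }
        h <- h * max(0.2, 0.9 * err^(-0.25))
      } else {
        h <- h / 2
      }
      if (h < 1e-12) stop("step size underflow in integrate_replicator()")
    }
    times <- c(times, t); xs1 <- c(xs1, s[1]); xs2 <- c(xs2, s[2])
  }
  structure(tibble::tibble(time = times, x1 = xs1, x2 = xs2),
            converged = converged, terminal = s)
}

#' Locate the diagonal basin boundary by bisection
#'
#' Integrates the symmetric dynamics from diagonal starts `(x0, x0)` and
#' bisects on the terminal corner (all-C above the boundary, all-D below).
#' In the symmetric bistable regime the boundary is the unstable interior
#' fixed point, so this is the numerical-integration oracle for
#' [interior_fixed_point()].
#'
#' @param params A [coevo_params()] object in a bistable regime.
#' @param tol Bisection tolerance on the initial frequency.
#' @param horizon Passed to [integrate_replicator()].
#' @return The boundary initial frequency in (0, 1), or `NA_real_` when
#'   both probe starts reach the same corner.
#' @export
basin_threshold <- function(params, tol = 1e-6, horizon = 1e5) {
  stopifnot(inherits(params, "coevo_params"))
  endpoint <- function(x0) {
    tr <- integrate_replicator(params, c(x0, x0), horizon = horizon)
    term <- attr(tr, "terminal")
    mean(term) > 0.5
  }
  lo <- 1e-4; hi <- 1 - 1e-4
  if (endpoint(lo) || !endpoint(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (endpoint(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
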