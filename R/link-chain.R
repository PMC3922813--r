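# Embedded Markov chain over the 10 link types under frozen strategy
# frequencies: transition matrix, stationary distribution (closed form and
# eigen-solve) and expected link counts.

# Partner-label distribution seen by a retained endpoint in group g:
# with probability p a uniform same-group node, else a uniform other-group
# node; strategies mean-field Bernoulli(x of the target group).
.partner_dist <- function(g, p, x1, x2) {
  x_own <- if (g == 1L) x1 else x2
  x_oth <- if (g == 1L) x2 else x1
  g_oth <- if (g == 1L) 2L else 1L
  tibble::tibble(
    strategy = c("C", "D", "C", "D"),
    group    = c(g, g, g_oth, g_oth),
    prob     = c(p * x_own, p * (1 - x_own),
                 (1 - p) * x_oth, (1 - p) * (1 - x_oth))
  )
}

#' Transition matrix of the embedded link-type chain
#'
#' One linking event acts on a single link: a link of type e survives with
#' probability `1 - k_e`; otherwise it breaks, one endpoint is retained
#' uniformly at random, and the retained endpoint rewires -- with
#' probability `p` to a uniform node of its own group, else to a uniform
#' node of the other group -- so the new type is set by the retained
#' endpoint's label and the new partner's label.  The new partner's strategy
#' is mean-field: Bernoulli with the cooperator frequency of the target
#' group (`x1` or `x2`), neglecting the O(1/N) exclusion of current
#' neighbours, which is valid in the sparse regime (degree much smaller
#' than group size).
#'
#' @param params A [coevo_params()] object (`p` and the breaking schedule
#'   are used).
#' @param x1,x2 Frozen cooperator frequencies in Group-1 and Group-2, in
#'   `[0, 1]`.
#' @return A row-stochastic 10x10 matrix in canonical [link_types()] order.
#' @examples
#' P <- link_transition_matrix(coevo_params(), x1 = 0.6, x2 = 0.4)
#' rowSums(P)
#' @export
link_transition_matrix <- function(params, x1, x2) {
  stopifnot(inherits(params, "coevo_params"),
            x1 >= 0, x1 <= 1, x2 >= 0, x2 <= 1)
  types <- link_types()
  k <- as.numeric(params$schedule)
  P <- matrix(0, 10L, 10L, dimnames = list(types$type, types$type))
  for (i in seq_len(10L)) {
    P[i, i] <- 1 - k[i]
    if (k[i] == 0) next
    for (side in c("a", "b")) {
      s_keep <- types[[paste0(side, "_strategy")]][i]
      g_keep <- types[[paste0(side, "_group")]][i]
      pd <- .partner_dist(g_keep, params$p, x1, x2)
      new_type <- link_type_of(s_keep, g_keep, pd$strategy, pd$group)
      for (j in seq_len(nrow(pd))) {
        P[i, new_type[j]] <- P[i, new_type[j]] + k[i] * 0.5 * pd$prob[j]
      }
    }
  }
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("internal error: transition matrix rows do not sum to one")
  P
}

# Closed classes of the chain (on the support graph of positive entries).
.closed_classes <- function(P) {
  n <- nrow(P)
  reach <- (P > 0) | diag(n) > 0
  # transitive closure (n is 10; repeated squaring is plenty)
  for (i in seq_len(5L)) reach <- (reach %*% reach) > 0
  classes <- list()
  assigned <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    comm <- which(reach[i, ] & reach[, i])
    assigned[comm] <- TRUE
    # closed iff nothing escapes the class
    if (all(!reach[comm, -comm, drop = FALSE])) classes <- c(classes, list(comm))
  }
  classes
}

#' Stationary distribution of the link-type chain (numeric solve)
#'
#' Left fixed vector of the transition matrix, found by eigen-decomposition
#' of its transpose.  When the chain is reducible (frequencies on the
#' boundary, or `p` in `{0, 1}` collapsing compartments) the distribution is
#' computed on the unique closed communicating class and flagged via the
#' `"restricted"` attribute plus a warning; several closed classes (e.g. the
#' identity matrix) are an error, since no unique stationary distribution
#' exists.
#'
#' @param P A row-stochastic 10x10 matrix from [link_transition_matrix()].
#' @return A tibble with columns `type` and `pi` (summing to 1), with
#'   attribute `restricted` (logical).
#' @export
link_stationary_numeric <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(abs(rowSums(P) - 1) > 1e-10)) stop("`P` must be row-stochastic")
  classes <- .closed_classes(P)
  if (length(classes) == 0L) stop("internal error: no closed class found")
  if (length(classes) > 1L)
    stop("chain is reducible with several closed classes; ",
         "no unique stationary distribution")
  cls <- classes[[1L]]
  restricted <- length(cls) < nrow(P)
  if (restricted)
    warning("chain is reducible; returning the stationary distribution of ",
            "its unique closed class (", length(cls), " types)")
  sub <- P[cls, cls, drop = FALSE]
  e <- eigen(t(sub))
  idx <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, idx])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("eigen-solve produced a negative stationary mass")
  v[v < 0] <- 0
  pi <- setNames(rep(0, nrow(P)), rownames(P))
  pi[cls] <- v / sum(v)
  structure(tibble::tibble(type = rownames(P), pi = unname(pi)),
            restricted = restricted)
}

#' Stationary distribution of the link-type chain (closed form)
#'
#' The unique stationary distribution has a product form: the probability of
#' the type with endpoint labels a, b is proportional to
#' \deqn{\pi_{ab} \propto \frac{(2 - \delta_{ab})\, w(g_a, g_b)\, f_a f_b}{k_{ab}},}
#' where \eqn{\delta_{ab}} is the Kronecker delta of the two endpoint labels
#' (like-labelled pairs are counted once, unlike pairs twice), the group
#' weight \eqn{w} is `p` for intra-group pairs and `1 - p` for inter-group
#' pairs, \eqn{f} is the frequency of the endpoint's strategy in its group
#' (`x` or `1 - x`), and \eqn{k_{ab}} is the breaking probability of the
#' type.  Division by the normalisation factor Z gives the distribution.
#' Doubling every `k` leaves the distribution unchanged (only relative
#' fragilities matter).  The form follows from flux balance: the breaking
#' flux `pi * k` out of each type must equal the rebuild flux into it, and
#' the rebuild kernel's stationary pair law factorises over endpoint labels
#' with equal mass on the two groups.
#'
#' Requires `p < 1` (at `p = 1` links never change compartment and the chain
#' splits into two closed intra-group classes) and all `k > 0`.  Boundary
#' frequencies (`x` equal to 0 or 1) are allowed: mass simply vanishes on
#' the unreachable types, matching the numeric solve's restricted class.
#'
#' @inheritParams link_transition_matrix
#' @return A tibble with columns `type` and `pi`.
#' @examples
#' link_stationary(coevo_params(), x1 = 0.6, x2 = 0.4)
#' @export
link_stationary <- function(params, x1, x2) {
  stopifnot(inherits(params, "coevo_params"),
            x1 >= 0, x1 <= 1, x2 >= 0, x2 <= 1)
  k <- as.numeric(params$schedule)
  if (any(k <= 0))
    stop("closed-form stationary distribution requires all k > 0")
  if (params$p >= 1)
    stop("closed-form stationary distribution requires p < 1 ",
         "(at p = 1 the chain splits into two closed intra-group classes)")
  types <- link_types()
  f <- function(s, g) {
    x <- ifelse(g == 1L, x1, x2)
    ifelse(s == "C", x, 1 - x)
  }
  mult <- ifelse(types$a_strategy == types$b_strategy &
                   types$a_group == types$b_group, 1, 2)
  wgt <- ifelse(types$compartment == "inter", 1 - params$p, params$p)
  v <- mult * wgt * f(types$a_strategy, types$a_group) *
    f(types$b_strategy, types$b_group) / k
  tibble::tibble(type = types$type, pi = v / sum(v))
}

#' Expected link counts from a stationary distribution
#'
#' Multiplies the stationary type probabilities by the conserved total
#' number of links, `L = l1 + l2 + l12`.
#'
#' @param pi A tibble from [link_stationary()] or
#'   [link_stationary_numeric()] (columns `type`, `pi`).
#' @param L Total number of links (a nonnegative scalar), e.g.
#'   `params$l1 + params$l2 + params$l12`.
#' @return A tibble with columns `type` and `count`; counts sum to `L`.
#' @export
expected_link_counts <- function(pi, L) {
  stopifnot(is.data.frame(pi), all(c("type", "pi") %in% names(pi)), L >= 0)
  if (abs(sum(pi$pi) - 1) > 1e-8) stop("`pi` must be normalised")
  tibble::tibble(type = pi$type, count = L * pi$pi)
}

#' Simulate the single-link embedded chain
#'
#' Monte-Carlo sampler of the link-type chain under frozen frequencies,
#' used to validate the stationary distribution.  Counts visits over
#' `n_events` transitions after `burnin` discarded ones.
#'
#' @inheritParams link_transition_matrix
#' @param n_events Number of recorded transitions.
#' @param burnin Discarded initial transitions.
#' @param init Starting type index (default 1).
#' @return A tibble with columns `type`, `freq` (visit frequencies).
#' @export
simulate_link_chain <- function(params, x1, x2, n_events = 1e5,
                                burnin = 1e3, init = 1L) {
  P <- link_transition_matrix(params, x1, x2)
  states <- cpp_simulate_chain(P, as.integer(init) - 1L,
                               as.integer(burnin), as.integer(n_events))
  counts <- tabulate(states + 1L, nbins = nrow(P))
  tibble::tibble(type = rownames(P), freq = counts / sum(counts))
}
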