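# Agent-based simulation of the co-evolution process on an explicit
# two-group network: Fermi strategy updates with probability W, link
# breaking/rewiring with probability 1 - W.  The event loop is compiled
# (src/abm.cpp) and draws from R's RNG, so runs are seed-exact.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# decode pair index in 1..choose(n,2) to (i, j), i < j, both 1-based
.decode_intra_pair <- function(idx, n) {
  # j is the larger endpoint: pairs with larger endpoint j are preceded by
  # choose(j - 1, 2) pairs
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  cbind(as.integer(i), as.integer(j))
}

#' Initialise a random interdependent network
#'
#' Draws uniformly random simple graphs with the exact prescribed link
#' counts in each compartment (within Group-1, within Group-2, between
#' groups) and assigns strategies by exact-count random placement:
#' `floor(coop_frac * N)` cooperators per group, at uniformly random
#' positions.  Node ids are `1..n1` for Group-1 and `n1+1..n1+n2` for
#' Group-2.
#'
#' @param params A [coevo_params()] object (sizes and link counts are used).
#' @param coop_frac Initial cooperator fraction per group; a scalar or a
#'   length-2 vector `(group 1, group 2)`.
#' @param seed Optional integer seed; when given the global RNG state is
#'   restored afterwards, so the same seed always yields the same network.
#' @return An object of class `"interdependent_network"`: a list with
#'   `group` (integer 1/2 per node), `strategy` (`"C"`/`"D"` per node) and
#'   `edges` (an L x 2 integer matrix of node ids).
#' @examples
#' net <- init_network(coevo_params(), coop_frac = 0.5, seed = 1)
#' net
#' @export
init_network <- function(params, coop_frac = 0.5, seed = NULL) {
  stopifnot(inherits(params, "coevo_params"))
  coop_frac <- rep_len(coop_frac, 2L)
  stopifnot(all(coop_frac >= 0), all(coop_frac <= 1))
  n1 <- params$n1; n2 <- params$n2
  .with_seed(seed, {
    strat <- c(rep("D", n1), rep("D", n2))
    nc1 <- floor(coop_frac[1] * n1); nc2 <- floor(coop_frac[2] * n2)
    if (nc1 > 0) strat[sample.int(n1, nc1)] <- "C"
    if (nc2 > 0) strat[n1 + sample.int(n2, nc2)] <- "C"
    e1 <- if (params$l1 > 0)
      .decode_intra_pair(sample.int(choose(n1, 2), params$l1), n1)
    else matrix(integer(0), 0, 2)
    e2 <- if (params$l2 > 0)
      n1 + .decode_intra_pair(sample.int(choose(n2, 2), params$l2), n2)
    else matrix(integer(0), 0, 2)
    e12 <- if (params$l12 > 0) {
      idx <- sample.int(n1 * n2, params$l12) - 1L
      cbind(idx %/% n2 + 1L, idx %% n2 + n1 + 1L)
    } else matrix(integer(0), 0, 2)
    structure(list(
      group = rep(c(1L, 2L), c(n1, n2)),
      strategy = strat,
      edges = rbind(e1, e2, e12)
    ), class = "interdependent_network")
  })
}

#' @export
print.interdependent_network <- function(x, ...) {
  n1 <- sum(x$group == 1L)
  cat(sprintf("<interdependent_network> %d + %d nodes, %d links\n",
              n1, sum(x$group == 2L), nrow(x$edges)))
  cat(sprintf("  cooperators: %d | %d\n",
              sum(x$strategy == "C" & x$group == 1L),
              sum(x$strategy == "C" & x$group == 2L)))
  invisible(x)
}

.validate_network <- function(net) {
  stopifnot(inherits(net, "interdependent_network"))
  e <- net$edges
  if (nrow(e) > 0) {
    if (any(e[, 1] == e[, 2])) stop("network has self-loops")
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (anyDuplicated(key)) stop("network has duplicate edges")
  }
  invisible(net)
}

#' Count links of each type in a network
#'
#' A full recount from the edge list, keyed by canonical type labels; used
#' to cross-check the simulator's incremental counters.
#'
#' @param net An [init_network()] object.
#' @return A tibble with columns `type` and `count`, in canonical order.
#' @export
link_type_counts <- function(net) {
  stopifnot(inherits(net, "interdependent_network"))
  types <- link_types()$type
  e <- net$edges
  lab <- link_type_of(net$strategy[e[, 1]], net$group[e[, 1]],
                      net$strategy[e[, 2]], net$group[e[, 2]])
  tibble::tibble(type = types,
                 count = as.numeric(table(factor(lab, levels = types))))
}

#' Accumulated payoff of each player
#'
#' Every player plays the donation game with all of its current neighbours
#' -- in its own group and in the other group alike -- and collects the sum
#' of payoffs.  Isolated nodes score 0.
#'
#' @param net An [init_network()] object.
#' @param params A [coevo_params()] object (its payoff matrix is used).
#' @return A numeric vector of length `n1 + n2`.
#' @examples
#' net <- init_network(coevo_params(), 0.5, seed = 1)
#' head(accumulated_payoff(net, coevo_params()))
#' @export
accumulated_payoff <- function(net, params) {
  stopifnot(inherits(net, "interdependent_network"),
            inherits(params, "coevo_params"))
  M <- params$payoff
  n <- length(net$group)
  pay <- numeric(n)
  e <- net$edges
  if (nrow(e) > 0) {
    sa <- net$strategy[e[, 1]]; sb <- net$strategy[e[, 2]]
    pa <- M[cbind(sa, sb)]; pb <- M[cbind(sb, sa)]
    acc <- vapply(split(c(pa, pb), c(e[, 1], e[, 2])), sum, numeric(1))
    pay[as.integer(names(acc))] <- acc
  }
  pay
}

.net_to_cpp <- function(net) {
  list(group = net$group - 1L,
       strat = as.integer(net$strategy == "D"),
       edges = net$edges - 1L)
}

.cpp_to_net <- function(res, net) {
  net$strategy <- c("C", "D")[res$strategy + 1L]
  net$edges <- res$edges + 1L
  net
}

.run_cpp <- function(net, params, n_events, sample_every = 0L,
                     event_mode = 0L, focal_adopts = FALSE,
                     pair_by_link = TRUE, stop_on_absorb = FALSE) {
  st <- .net_to_cpp(net)
  cpp_run_abm(st$group, st$strat, st$edges, params$n1, params$n2,
              params$payoff, as.numeric(params$schedule),
              params$p, params$W, params$w,
              as.double(n_events), as.integer(sample_every),
              as.integer(event_mode), focal_adopts, pair_by_link,
              stop_on_absorb)
}

#' Single strategy-update event
#'
#' Performs one Fermi imitation event: a (focal, neighbour) pair of linked
#' players is drawn, and the focal player's strategy replaces the
#' neighbour's with probability
#' `1 / (1 + exp(-w * (P_focal - P_neighbour)))` on accumulated payoffs
#' (`focal_adopts = TRUE` flips the direction: the focal player adopts the
#' neighbour's strategy, the convention used by part of the literature).
#' Uses R's RNG.
#'
#' Pair choice (`pair_sampling`): the default `"link"` draws a uniform
#' link with a uniform orientation, so every linked ordered pair is
#' equally likely -- the sampling assumed by the mean-field transition
#' probabilities, and the one under which the simulation reproduces the
#' analytical bistability.  `"node"` draws a uniform focal player and then
#' a uniform neighbour; that variant weights pairs by the inverse focal
#' degree, which under heterogeneous fragilities hands low-degree
#' defectors a selection-independent imitation advantage strong enough to
#' destroy cooperation at weak selection (see the methods vignette); a
#' focal player without neighbours then makes the event a no-op.
#'
#' @param net An [init_network()] object.
#' @param params A [coevo_params()] object.
#' @param focal_adopts Direction switch, see above.
#' @param pair_sampling `"link"` (default) or `"node"`, see above.
#' @return The updated network.
#' @export
strategy_update_event <- function(net, params, focal_adopts = FALSE,
                                  pair_sampling = c("link", "node")) {
  pair_sampling <- match.arg(pair_sampling)
  res <- .run_cpp(net, params, 1, event_mode = 1L, focal_adopts = focal_adopts,
                  pair_by_link = pair_sampling == "link")
  .cpp_to_net(res, net)
}

#' Single linking event
#'
#' Performs one link-adjustment event: a link is drawn uniformly, survives
#' with probability `1 - k` of its type, otherwise breaks; one endpoint is
#' retained uniformly and rewires -- with probability `p` to a uniform
#' non-neighbour of its own group, else of the other group.  The total link
#' count is conserved; reconnection to the just-broken partner is allowed
#' (after deletion it is no longer a neighbour).  If the chosen side offers
#' no eligible partner the event is consumed as a no-op.
#'
#' @inheritParams strategy_update_event
#' @return The updated network.
#' @export
link_update_event <- function(net, params) {
  res <- .run_cpp(net, params, 1, event_mode = 2L)
  .cpp_to_net(res, net)
}

#' Run the co-evolutionary agent-based simulation
#'
#' Per event, a strategy update occurs with probability `W`, otherwise a
#' link adjustment (see [strategy_update_event()] and
#' [link_update_event()]).  Time is counted in events.  The cooperator
#' frequencies and the ten link-type counts are recorded every
#' `sample_every` events.  A fixed seed makes the whole record
#' reproducible bit for bit.
#'
#' @param params A [coevo_params()] object.
#' @param coop_frac Initial cooperator fraction per group (scalar or
#'   length 2), used when `net` is not supplied.
#' @param horizon Number of events to run.
#' @param seed Optional integer seed (network initialisation and dynamics).
#' @param sample_every Recording stride in events.
#' @param net Optional starting network (overrides `coop_frac`).
#' @param events `"auto"` (mixed by `W`), `"strategy"` or `"link"` to force
#'   a single event type (e.g. frozen strategies for linking-dynamics
#'   studies).
#' @param focal_adopts Fermi direction switch, see [strategy_update_event()].
#' @param pair_sampling Pair-selection rule for strategy updates, see
#'   [strategy_update_event()].
#' @param stop_on_absorb Stop early once the population is monomorphic
#'   (all-C or all-D); link dynamics cannot change strategies afterwards.
#' @return An object of class `"coevo_sim"`: a list with `series` (a tibble
#'   with `event`, `x1`, `x2` and one column per link type), `network`
#'   (final state), `final` (named vector `x1`, `x2`, `x`), `absorbed`,
#'   `params`, `seed`.  Has [tidy()] and [autoplot()] methods.
#' @examples
#' sim <- simulate_coevolution(coevo_params(), 0.5, horizon = 2e4, seed = 1)
#' sim$final
#' @export
simulate_coevolution <- function(params, coop_frac = 0.5, horizon = 1e5,
                                 seed = NULL, sample_every = 1000,
                                 net = NULL,
                                 events = c("auto", "strategy", "link"),
                                 focal_adopts = FALSE,
                                 pair_sampling = c("link", "node"),
                                 stop_on_absorb = FALSE) {
  stopifnot(inherits(params, "coevo_params"), horizon > 0)
  events <- match.arg(events)
  pair_sampling <- match.arg(pair_sampling)
  mode <- match(events, c("auto", "strategy", "link")) - 1L
  .with_seed(seed, {
    if (is.null(net)) net <- init_network(params, coop_frac)
    .validate_network(net)
    res <- .run_cpp(net, params, horizon, sample_every = sample_every,
                    event_mode = mode, focal_adopts = focal_adopts,
                    pair_by_link = pair_sampling == "link",
                    stop_on_absorb = stop_on_absorb)
    counts <- res$type_counts
    colnames(counts) <- link_types()$type
    series <- tibble::as_tibble(cbind(
      tibble::tibble(event = res$event, x1 = res$x1, x2 = res$x2),
      tibble::as_tibble(counts)))
    final_net <- .cpp_to_net(res, net)
    n <- length(net$group)
    xfin <- sum(final_net$strategy == "C") / n
    structure(list(
      series = series,
      network = final_net,
      final = c(x1 = res$x1[length(res$x1)], x2 = res$x2[length(res$x2)],
                x = xfin),
      absorbed = res$absorbed,
      events_run = res$events_run,
      params = params, seed = seed
    ), class = "coevo_sim")
  })
}

#' @export
print.coevo_sim <- function(x, ...) {
  cat(sprintf("<coevo_sim> %s events; final x1 = %.3f, x2 = %.3f%s\n",
              format(x$events_run, big.mark = ","),
              x$final["x1"], x$final["x2"],
              if (isTRUE(x$absorbed)) " (absorbed)" else ""))
  invisible(x)
}

#' @rdname simulate_coevolution
#' @param x A `coevo_sim` object.
#' @param ... Unused.
#' @export
tidy.coevo_sim <- function(x, ...) x$series

#' @rdname simulate_coevolution
#' @param object A `coevo_sim` object.
#' @export
autoplot.coevo_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$series[, c("event", "x1", "x2")],
                            c("x1", "x2"),
                            names_to = "group", values_to = "frequency")
  ggplot2::ggplot(df, ggplot2::aes(.data$event, .data$frequency,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "event", y = "cooperator frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Final cooperation level over independent runs
#'
#' Runs `replicates` independent seeded simulations (replicate r uses
#' `seed + r`) and summarises the terminal cooperator fraction of the whole
#' population.
#'
#' @inheritParams simulate_coevolution
#' @param replicates Number of independent runs.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A one-row tibble with `mean`, `stderr`, `replicates`; the
#'   per-replicate terminal fractions are kept in the `"finals"` attribute.
#' @export
final_cooperation <- function(params, coop_frac = 0.5, replicates = 10,
                              horizon = 1e5, seed = 1,
                              stop_on_absorb = TRUE, ...) {
  stopifnot(replicates >= 1)
  finals <- vapply(seq_len(replicates), function(r) {
    sim <- simulate_coevolution(params, coop_frac, horizon = horizon,
                                seed = seed + r,
                                sample_every = 0,
                                stop_on_absorb = stop_on_absorb, ...)
    unname(sim$final["x"])
  }, numeric(1))
  structure(
    tibble::tibble(mean = mean(finals),
                   stderr = if (replicates > 1)
                     sd(finals) / sqrt(replicates) else 0,
                   replicates = replicates),
    finals = finals)
}

#' Export a network as a tidy edge table
#'
#' @param net An [init_network()] object.
#' @return A tibble with `from`, `to`, node attributes of both endpoints
#'   and the canonical link `type`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "interdependent_network"))
  e <- net$edges
  tibble::tibble(
    from = e[, 1], to = e[, 2],
    from_group = net$group[e[, 1]], to_group = net$group[e[, 2]],
    from_strategy = net$strategy[e[, 1]], to_strategy = net$strategy[e[, 2]],
    type = link_type_of(net$strategy[e[, 1]], net$group[e[, 1]],
                        net$strategy[e[, 2]], net$group[e[, 2]])
  )
}
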