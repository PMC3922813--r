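# Game parameters, link-type algebra and payoff-matrix construction.

STRATS <- c("C", "D")

.link_type_table <- function() {
  tibble::tibble(
    type        = c("C1C1", "C1D1", "D1D1",
                    "C2C2", "C2D2", "D2D2",
                    "C1C2", "C1D2", "D1C2", "D1D2"),
    a_strategy  = c("C", "C", "D", "C", "C", "D", "C", "C", "D", "D"),
    a_group     = c(1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L, 1L),
    b_strategy  = c("C", "D", "D", "C", "D", "D", "C", "D", "C", "D"),
    b_group     = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
    compartment = rep(c("intra1", "intra2", "inter"), times = c(3L, 3L, 4L))
  )
}

#' Enumerate the ten link types of the interdependent-population model
#'
#' A link carries the unordered pair of its endpoints' (strategy, group)
#' labels.  With two strategies (C, D) and two groups there are exactly ten
#' distinct types: three within Group-1, three within Group-2 and four
#' between the groups.  The canonical ordering used everywhere in the
#' package (transition-matrix rows, stationary vectors, simulator counters)
#' is intra-1 (CC, CD, DD), intra-2 (CC, CD, DD), then inter with the
#' Group-1 endpoint first (C1C2, C1D2, D1C2, D1D2).
#'
#' @return A tibble with one row per link type, in canonical order, with
#'   columns `type` (label such as `"C1D2"`), `a_strategy`, `a_group`,
#'   `b_strategy`, `b_group` (the canonical endpoints), `strategy_pair`
#'   (`"CC"`, `"CD"` or `"DD"`) and `compartment` (`"intra1"`, `"intra2"`,
#'   `"inter"`).
#' @examples
#' link_types()
#' @export
link_types <- function() {
  tab <- .link_type_table()
  tab$strategy_pair <- paste0(
    pmin(tab$a_strategy, tab$b_strategy),
    pmax(tab$a_strategy, tab$b_strategy)
  )
  tab[, c("type", "a_strategy", "a_group", "b_strategy", "b_group",
          "strategy_pair", "compartment")]
}

#' Canonical label of a link from its two endpoint labels
#'
#' Maps an unordered pair of (strategy, group) endpoint labels to the
#' canonical type label of [link_types()].  Canonicalisation is idempotent:
#' swapping the endpoints yields the same label.
#'
#' @param s1,s2 Strategies of the two endpoints, `"C"` or `"D"`.
#' @param g1,g2 Groups of the two endpoints, `1` or `2`.
#' @return A character vector of canonical type labels.
#' @examples
#' link_type_of("D", 2, "C", 1)  # "C1D2"
#' @export
link_type_of <- function(s1, g1, s2, g2) {
  stopifnot(all(s1 %in% STRATS), all(s2 %in% STRATS),
            all(g1 %in% 1:2), all(g2 %in% 1:2))
  n <- max(length(s1), length(s2), length(g1), length(g2))
  s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  g1 <- rep_len(as.integer(g1), n); g2 <- rep_len(as.integer(g2), n)
  # order endpoints: group first, then strategy (C before D)
  swap <- (g1 > g2) | (g1 == g2 & s1 > s2)
  a_s <- ifelse(swap, s2, s1); a_g <- ifelse(swap, g2, g1)
  b_s <- ifelse(swap, s1, s2); b_g <- ifelse(swap, g1, g2)
  paste0(a_s, a_g, b_s, b_g)
}

#' Donation-game payoff matrix
#'
#' Builds the 2x2 prisoner's dilemma payoff matrix of the donation game in
#' which a cooperator pays a cost `c` to confer a benefit `b` on its
#' opponent while a defector pays and gives nothing.  Rows and columns are
#' ordered (C, D), so the entries are `b - c` (C meets C), `-c` (C meets D),
#' `b` (D meets C) and `0` (D meets D).  The PD ordering T > R > P > S holds
#' for every valid `b > c > 0`.
#'
#' @param b Benefit conferred by a cooperator; must exceed `c`.
#' @param c Cost paid by a cooperator; must be positive.
#' @return A 2x2 numeric matrix with dimnames `c("C","D")`.
#' @examples
#' donation_payoff(2, 1)
#' @export
donation_payoff <- function(b, c) {
  stopifnot(is.numeric(b), is.numeric(c), length(b) == 1L, length(c) == 1L)
  if (!(c > 0)) stop("`c` must be positive (donation game requires b > c > 0)")
  if (!(b > c)) stop("`b` must exceed `c` (donation game requires b > c > 0)")
  matrix(c(b - c, b, -c, 0), nrow = 2L,
         dimnames = list(STRATS, STRATS))
}

#' Breaking-probability schedule over link types
#'
#' Each link type e is assigned a probability `k_e` of being severed when it
#' is selected during the linking dynamics; `1/k_e` is the mean lifetime of
#' an e-link (geometric duration), i.e. the average interaction rate across
#' it.  The model keys fragility by the strategy pair of the endpoints --
#' `k_cc`, `k_cd`, `k_dd` -- applied identically to intra- and inter-group
#' links, but a full 10-type map can be supplied through `by_type` for
#' group-dependent variants.
#'
#' @param k_cc,k_cd,k_dd Breaking probabilities for CC, CD and DD links, each
#'   in `[0, 1]`.  (`k = 0` describes an unbreakable link; operations that
#'   divide by `k`, such as payoff rescaling and the closed-form stationary
#'   distribution, reject zero values.)
#' @param by_type Optional named numeric vector over the canonical type
#'   labels of [link_types()]; overrides the strategy-pair values for the
#'   named types.
#' @return An object of class `"breaking_schedule"`: a named numeric vector
#'   of length 10 in canonical order, with the strategy-pair parameters kept
#'   as attributes.
#' @examples
#' breaking_schedule(k_cc = 0.2, k_cd = 0.8)
#' @export
breaking_schedule <- function(k_cc = 0.2, k_cd = 0.8, k_dd = k_cd,
                              by_type = NULL) {
  for (k in c(k_cc, k_cd, k_dd)) {
    stopifnot(is.numeric(k), length(k) == 1L)
    if (k < 0 || k > 1) stop("breaking probabilities must lie in [0, 1]")
  }
  types <- link_types()
  k <- c(CC = k_cc, CD = k_cd, DD = k_dd)[types$strategy_pair]
  names(k) <- types$type
  if (!is.null(by_type)) {
    if (is.null(names(by_type)) || !all(names(by_type) %in% types$type))
      stop("`by_type` must be named by canonical link-type labels")
    if (any(by_type < 0 | by_type > 1))
      stop("breaking probabilities must lie in [0, 1]")
    k[names(by_type)] <- by_type
  }
  structure(k, class = "breaking_schedule",
            k_cc = k_cc, k_cd = k_cd, k_dd = k_dd)
}

#' @export
print.breaking_schedule <- function(x, ...) {
  cat("<breaking_schedule>\n")
  print(unclass(x)[])
  invisible(x)
}

.schedule_pair <- function(schedule) {
  c(CC = attr(schedule, "k_cc"), CD = attr(schedule, "k_cd"),
    DD = attr(schedule, "k_dd"))
}

#' Rescale a payoff matrix by inverse breaking probabilities
#'
#' Under fast rewiring a link of type e lives for `1/k_e` selections on
#' average, so the effective game is the original matrix with each entry
#' divided by the breaking probability of its strategy pair: the C-C entry
#' by `k_CC`, both mixed entries by `k_CD` and the D-D entry by `k_DD`.
#' With the donation game's zero D-D payoff the rescaled D-D entry remains
#' zero.
#'
#' @param M 2x2 payoff matrix in (C, D) order, e.g. from [donation_payoff()].
#' @param schedule A [breaking_schedule()] (only its strategy-pair values are
#'   used: rescaling acts on strategy pairs, not on groups).
#' @return A 2x2 numeric matrix.
#' @examples
#' rescale_payoff(donation_payoff(2, 1), breaking_schedule(0.5, 1, 1))
#' @export
rescale_payoff <- function(M, schedule) {
  stopifnot(is.matrix(M), identical(dim(M), c(2L, 2L)))
  kp <- .schedule_pair(schedule)
  if (any(kp <= 0))
    stop("rescaling requires strictly positive breaking probabilities")
  out <- M / matrix(c(kp["CC"], kp["CD"], kp["CD"], kp["DD"]), 2L, 2L)
  dimnames(out) <- list(STRATS, STRATS)
  out
}

#' Parameters of the co-evolutionary model
#'
#' Bundles every tunable of the model: the donation game (`b`, `c`), the
#' link fragilities (`k_cc`, `k_cd`, `k_dd`), the intra-group attaching bias
#' `p` (probability that a rewiring player reconnects within its own group),
#' the strategy-update event probability `W` (events are strategy updates
#' with probability `W`, link adjustments otherwise; small `W` is the
#' fast-rewiring regime), the selection intensity `w` of the Fermi rule, the
#' group sizes and the three link-count compartments.  Defaults describe a
#' sparse, bistable reference world: mean intra-group degree 10 with group
#' size 100, fragile C-D links (`k_cd = 0.8`) and robust C-C links
#' (`k_cc = 0.2`), benefit-to-cost ratio 2 against a critical ratio of 4/3,
#' which places the unstable interior fixed point at x* = 1/3.
#'
#' @param b,c Donation-game benefit and cost, `b > c > 0`.
#' @param k_cc,k_cd,k_dd Breaking probabilities by strategy pair, in `[0,1]`.
#' @param p Intra-group attaching bias in `[0, 1]`.
#' @param W Strategy-update event probability in `[0, 1]`.
#' @param w Selection (imitation) intensity, `>= 0`.
#' @param n1,n2 Group sizes (positive integers).
#' @param l1,l2,l12 Initial link counts within Group-1, within Group-2 and
#'   between the groups; the total `l1 + l2 + l12` is conserved by the
#'   dynamics.
#' @param schedule Optional [breaking_schedule()] overriding the three `k_*`
#'   scalars (e.g. a 10-type map).
#' @return An object of class `"coevo_params"` (a validated named list, with
#'   `$payoff` and `$schedule` precomputed).
#' @examples
#' pars <- coevo_params(b = 1, c = 0.5, k_cc = 0.2, k_cd = 0.8)
#' pars$payoff
#' @export
coevo_params <- function(b = 1, c = 0.5,
                         k_cc = 0.2, k_cd = 0.8, k_dd = k_cd,
                         p = 0.8, W = 0.01, w = 0.05,
                         n1 = 100, n2 = 100,
                         l1 = 500, l2 = 500, l12 = 200,
                         schedule = NULL) {
  if (is.null(schedule)) {
    schedule <- breaking_schedule(k_cc, k_cd, k_dd)
  } else {
    stopifnot(inherits(schedule, "breaking_schedule"))
    k_cc <- attr(schedule, "k_cc"); k_cd <- attr(schedule, "k_cd")
    k_dd <- attr(schedule, "k_dd")
  }
  stopifnot(p >= 0, p <= 1, W >= 0, W <= 1, w >= 0)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  l1 <- as.integer(l1); l2 <- as.integer(l2); l12 <- as.integer(l12)
  stopifnot(n1 >= 2, n2 >= 2, l1 >= 0, l2 >= 0, l12 >= 0)
  if (l1 > choose(n1, 2) || l2 > choose(n2, 2) || l12 > n1 * n2)
    stop("infeasible link counts for the given group sizes")
  structure(list(
    b = b, c = c, k_cc = k_cc, k_cd = k_cd, k_dd = k_dd,
    p = p, W = W, w = w, n1 = n1, n2 = n2, l1 = l1, l2 = l2, l12 = l12,
    payoff = donation_payoff(b, c), schedule = schedule
  ), class = "coevo_params")
}

#' @export
print.coevo_params <- function(x, ...) {
  cat("<coevo_params>\n")
  cat(sprintf("  donation game : b = %g, c = %g (b/c = %g)\n", x$b, x$c, x$b / x$c))
  cat(sprintf("  fragilities   : k_CC = %g, k_CD = %g, k_DD = %g\n",
              x$k_cc, x$k_cd, x$k_dd))
  cat(sprintf("  bias/rates    : p = %g, W = %g, w = %g\n", x$p, x$W, x$w))
  cat(sprintf("  groups        : N1 = %d, N2 = %d; L1 = %d, L2 = %d, L12 = %d\n",
              x$n1, x$n2, x$l1, x$l2, x$l12))
  invisible(x)
}

#' Update a parameter object
#'
#' Convenience wrapper that re-validates after replacing named fields.
#'
#' @param object A [coevo_params()] object.  (Named `object`, not `params`,
#'   so that short replacement names such as `p = ` cannot partially match
#'   the first argument.)
#' @param ... Named fields to replace (any argument of [coevo_params()]).
#' @return A new `coevo_params` object.
#' @export
update_params <- function(object, ...) {
  stopifnot(inherits(object, "coevo_params"))
  args <- object[c("b", "c", "k_cc", "k_cd", "k_dd", "p", "W", "w",
                   "n1", "n2", "l1", "l2", "l12")]
  do.call(coevo_params, modifyList(unclass(args), list(...)))
}

#' Read model parameters from a flat configuration file
#'
#' Accepts either JSON (a flat object of name/value pairs) or `key = value`
#' lines.  Unknown keys are rejected with a message naming them.
#'
#' @param path Path to the configuration file.
#' @return A [coevo_params()] object.
#' @export
read_params <- function(path) {
  txt <- readLines(path, warn = FALSE)
  trimmed <- trimws(paste(txt, collapse = "\n"))
  if (startsWith(trimmed, "{")) {
    vals <- jsonlite::fromJSON(trimmed, simplifyVector = TRUE)
  } else {
    lines <- trimws(txt)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed line(s): ", paste(lines[bad], collapse = "; "))
    vals <- lapply(kv, function(x) as.numeric(trimws(x[2])))
    names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  }
  allowed <- c("b", "c", "k_cc", "k_cd", "k_dd", "p", "W", "w",
               "n1", "n2", "l1", "l2", "l12")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  do.call(coevo_params, vals)
}
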