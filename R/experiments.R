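# Experiment drivers: phase portraits, intra-group-bias sweeps,
# initial-fraction sweeps and timeseries runs, each deterministic given
# (configuration, seed), with analytic overlays taken from the mean-field
# layer (never re-derived here).

#' Phase portrait of the weak-selection dynamics
#'
#' Evaluates the replicator field on a regular grid over the unit square
#' and integrates a trajectory from every grid start, classifying each
#' endpoint as all-D, all-C or (exceptionally) unconverged.
#'
#' @param params A [coevo_params()] object.
#' @param n_grid Number of grid points per axis.
#' @param horizon Integration horizon per start.
#' @return An object of class `"coevo_phase"`: a tibble with columns `x1`,
#'   `x2`, `dx1`, `dx2` (the field) and `endpoint` (`"all-D"`, `"all-C"`,
#'   `"none"`); the [classify_equilibria()] report is attached as the
#'   `"report"` attribute.  Has an [autoplot()] method.
#' @examples
#' pp <- phase_portrait(coevo_params(), n_grid = 5, horizon = 2000)
#' table(pp$endpoint)
#' @export
phase_portrait <- function(params, n_grid = 11, horizon = 1e4) {
  stopifnot(inherits(params, "coevo_params"), n_grid >= 2)
  g <- seq(0, 1, length.out = n_grid)
  grid <- tidyr::expand_grid(x1 = g, x2 = g)
  res <- purrr::pmap(grid, function(x1, x2) {
    f <- replicator_field(params, x1, x2)
    tr <- integrate_replicator(params, c(x1, x2), horizon = horizon)
    term <- attr(tr, "terminal")
    endpoint <- if (!attr(tr, "converged")) "none"
    else if (mean(term) > 0.5) "all-C" else "all-D"
    tibble::tibble(dx1 = f[["dx1"]], dx2 = f[["dx2"]], endpoint = endpoint)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  structure(out, class = c("coevo_phase", class(out)),
            report = classify_equilibria(params))
}

#' @rdname phase_portrait
#' @param object A `coevo_phase` tibble.
#' @param ... Unused.
#' @export
autoplot.coevo_phase <- function(object, ...) {
  rep <- attr(object, "report")
  sc <- 0.08 / max(sqrt(object$dx1^2 + object$dx2^2) + 1e-300)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x1, .data$x2)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x1 + sc * .data$dx1,
                                       yend = .data$x2 + sc * .data$dx2,
                                       colour = .data$endpoint),
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "pt"))) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "x1 (cooperators, Group-1)",
                  y = "x2 (cooperators, Group-2)", colour = "basin") +
    ggplot2::theme_minimal()
  if (!is.na(rep$x_star))
    p <- p + ggplot2::annotate("point", x = rep$x_star, y = rep$x_star,
                               shape = 21, size = 3, fill = "white")
  p
}

.sweep_tibble <- function(grid_name, grid, params, coop_frac, replicates,
                          horizon, seed, mutate_params) {
  rows <- purrr::imap(grid, function(val, i) {
    pars_i <- mutate_params(params, val)
    cf <- if (is.function(coop_frac)) coop_frac(val) else coop_frac
    fc <- final_cooperation(pars_i, coop_frac = cf, replicates = replicates,
                            horizon = horizon,
                            seed = seed + (i - 1L) * replicates)
    tibble::tibble(!!grid_name := val, mean = fc$mean, stderr = fc$stderr)
  })
  dplyr::bind_rows(rows)
}

#' Sweep the intra-group attaching bias
#'
#' Runs the agent-based model over a grid of `p` values and records the
#' mean and standard error of the final cooperation level.  Under bistable
#' parameters the curve is non-monotone: moderate intra-group bias
#' maximises cooperation, while both very mixed rewiring (small `p`) and
#' near-complete group closure (`p` near 1) suppress it.  The analytic
#' critical bias [critical_intra_bias()] of the base parameters is attached
#' as an overlay.
#'
#' @param params A [coevo_params()] object (its `p` is overridden by the
#'   grid).
#' @param p_grid Grid of bias values in `[0, 1]`.
#' @param coop_frac Initial cooperator fraction per group.
#' @param replicates Independent runs per grid point.
#' @param horizon Events per run.
#' @param seed Base seed; grid point i, replicate r uses
#'   `seed + (i-1) * replicates + r`.
#' @return An object of class `"coevo_sweep"`: a tibble with columns `p`,
#'   `mean`, `stderr`, with attributes `overlay` (named analytic values)
#'   and `sweep` (`"bias"`).  Has an [autoplot()] method.
#' @export
bias_sweep <- function(params, p_grid = seq(0, 1, by = 0.1),
                       coop_frac = 0.5, replicates = 10,
                       horizon = 1e5, seed = 1) {
  stopifnot(inherits(params, "coevo_params"),
            length(p_grid) >= 1, all(p_grid >= 0), all(p_grid <= 1))
  out <- .sweep_tibble("p", p_grid, params, coop_frac, replicates, horizon,
                       seed, function(par, v) update_params(par, p = v))
  structure(out, class = c("coevo_sweep", class(out)),
            overlay = c(p_critical = critical_intra_bias(params)),
            sweep = "bias")
}

#' Sweep the initial cooperator fraction
#'
#' Runs the agent-based model over a grid of initial cooperator fractions
#' (the same in both groups) and records the final cooperation level.  In
#' the bistable regime the response is a step around the unstable interior
#' fixed point `x*` of the mean-field dynamics, which is attached as the
#' analytic overlay.
#'
#' @inheritParams bias_sweep
#' @param x0_grid Grid of initial fractions in `[0, 1]`.
#' @return A `"coevo_sweep"` tibble with columns `x0`, `mean`, `stderr`;
#'   attribute `overlay` carries `x_star`.
#' @export
initial_fraction_sweep <- function(params, x0_grid = seq(0, 1, by = 0.1),
                                   replicates = 10, horizon = 1e5, seed = 1) {
  stopifnot(inherits(params, "coevo_params"),
            length(x0_grid) >= 1, all(x0_grid >= 0), all(x0_grid <= 1))
  out <- .sweep_tibble("x0", x0_grid, params, coop_frac = identity,
                       replicates, horizon, seed,
                       function(par, v) par)
  structure(out, class = c("coevo_sweep", class(out)),
            overlay = c(x_star = interior_fixed_point(params)),
            sweep = "initial")
}

#' @rdname bias_sweep
#' @param object A `coevo_sweep` tibble.
#' @param ... Unused.
#' @export
autoplot.coevo_sweep <- function(object, ...) {
  xvar <- names(object)[1]
  ov <- attr(object, "overlay")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data[[xvar]], .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$stderr,
                                          ymax = .data$mean + .data$stderr)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = if (xvar == "p") "intra-group bias p"
                  else "initial cooperator fraction",
                  y = "final cooperation level") +
    ggplot2::theme_minimal()
  if (length(ov) && !is.na(ov[[1]]))
    p <- p + ggplot2::geom_vline(xintercept = ov[[1]], linetype = "dashed")
  p
}

#' Reference parameter presets
#'
#' `"reduced"` is the CI-scale world used throughout the tests (groups of
#' 100, mean intra-group degree 10, 10 replicates' worth of runtime);
#' `"full"` is a larger production preset (groups of 500, same densities
#' and rates) for standalone experiments.  Both share the bistable game:
#' `b = 1`, `c = 0.5`, `k_CC = 0.2`, `k_CD = k_DD = 0.8`, so the critical
#' benefit-to-cost ratio is 4/3 and `x* = 1/3`.
#'
#' @param scale `"reduced"` or `"full"`.
#' @return A [coevo_params()] object.
#' @export
coevo_preset <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (scale == "reduced") coevo_params()
  else coevo_params(n1 = 500, n2 = 500, l1 = 2500, l2 = 2500, l12 = 1000)
}

#' Run an experiment from a configuration file
#'
#' The configuration is a JSON object with fields `experiment` (one of
#' `"phase_portrait"`, `"timeseries"`, `"bias_sweep"`, `"initial_sweep"`),
#' `params` (any fields of [coevo_params()]), `seed`, and the grid /
#' replicate / horizon settings of the chosen experiment (`p_grid`,
#' `x0_grid`, `n_grid`, `coop_frac`, `replicates`, `horizon`,
#' `sample_every`).  Results are written to `out_dir` as a CSV
#' (`result.csv`), the equilibrium report as JSON (`equilibria.json`) and a
#' provenance record (`provenance.json`: full configuration, seed and
#' package version).  Identical configurations yield byte-identical result
#' files.
#'
#' @param path Path to a JSON configuration file, or an equivalent named
#'   list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the result object of the dispatched experiment.
#' @export
run_config <- function(path, out_dir = ".") {
  cfg <- if (is.character(path)) jsonlite::fromJSON(path) else path
  if (!is.list(cfg)) stop("configuration must be a JSON object")
  valid <- c("phase_portrait", "timeseries", "bias_sweep", "initial_sweep")
  if (is.null(cfg$experiment) || !cfg$experiment %in% valid)
    stop("field `experiment` must be one of: ", paste(valid, collapse = ", "))
  known <- c("experiment", "params", "seed", "p_grid", "x0_grid", "n_grid",
             "coop_frac", "replicates", "horizon", "sample_every")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  params <- do.call(coevo_params, as.list(cfg$params %||% list()))
  seed <- cfg$seed %||% 1L
  grab <- function(name, default) cfg[[name]] %||% default
  res <- switch(cfg$experiment,
    phase_portrait = phase_portrait(params,
                                    n_grid = grab("n_grid", 11),
                                    horizon = grab("horizon", 1e4)),
    timeseries = simulate_coevolution(params,
                                      coop_frac = grab("coop_frac", 0.5),
                                      horizon = grab("horizon", 1e5),
                                      seed = seed,
                                      sample_every = grab("sample_every", 1000)),
    bias_sweep = bias_sweep(params,
                            p_grid = grab("p_grid", seq(0, 1, by = 0.1)),
                            coop_frac = grab("coop_frac", 0.5),
                            replicates = grab("replicates", 10),
                            horizon = grab("horizon", 1e5), seed = seed),
    initial_sweep = initial_fraction_sweep(params,
                                           x0_grid = grab("x0_grid", seq(0, 1, by = 0.1)),
                                           replicates = grab("replicates", 10),
                                           horizon = grab("horizon", 1e5),
                                           seed = seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- if (inherits(res, "coevo_sim")) res$series else as.data.frame(res)
  utils::write.csv(tab, file.path(out_dir, "result.csv"), row.names = FALSE)
  rep <- classify_equilibria(params)
  jsonlite::write_json(list(equilibria = rep$equilibria,
                            x_star = rep$x_star,
                            bc_ratio = rep$bc_ratio,
                            bc_critical = rep$bc_critical,
                            p_critical = rep$p_critical,
                            bistable = rep$bistable),
                       file.path(out_dir, "equilibria.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(list(config = cfg, seed = seed,
                            package = "coevonet",
                            version = as.character(utils::packageVersion("coevonet"))),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
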