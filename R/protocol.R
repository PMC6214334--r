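# Experimental protocol: many random seed sets, repeated runs, iteration-wise
# averaging, and summary statistics of the final infected percentage.

#' Protocol configuration
#'
#' Defaults mirror the study conditions: 100 random seed sets each covering 5%
#' of the nodes, 30 iterations per run, and the parameter grids tau in
#' 0.1..0.8, gamma in \{0.05, 0.1, ..., 0.8\}, blocking probability p in
#' \{0, 0.1, 0.2, 0.3\}, spontaneous rate a in \{0, 0.001, 0.005, 0.01\}.
#' `n_seed_sets` scales down for desk-size experiments without changing any
#' other condition.
#'
#' @param seed_fraction fraction of nodes in each seed set, in `(0, 1]`.
#' @param n_seed_sets number of independent seed sets (runs) per configuration.
#' @param iterations iterations per run.
#' @param tau,gamma,blocking_p,spontaneous_a numeric vectors of grid values
#'   for [run_grid()]; scalars are fine for [run_protocol()].
#' @param rng_seed root seed; every run's seed is derived from it.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(seed_fraction = 0.05, n_seed_sets = 100,
                            iterations = 30,
                            tau = seq(0.1, 0.8, by = 0.1),
                            gamma = c(0.05, seq(0.1, 0.8, by = 0.1)),
                            blocking_p = c(0, 0.1, 0.2, 0.3),
                            spontaneous_a = c(0, 0.001, 0.005, 0.01),
                            rng_seed = 1L) {
  if (!is.numeric(seed_fraction) || seed_fraction <= 0 || seed_fraction > 1)
    param_error("`seed_fraction` must be in (0, 1]")
  if (!is_count(n_seed_sets) || n_seed_sets < 1)
    param_error("`n_seed_sets` must be a positive integer")
  if (!is_count(iterations) || iterations < 1)
    param_error("`iterations` must be a positive integer")
  for (nm in c("tau", "gamma", "blocking_p", "spontaneous_a"))
    check_prob(get(nm), nm)
  structure(list(seed_fraction = seed_fraction, n_seed_sets = n_seed_sets,
                 iterations = iterations, tau = tau, gamma = gamma,
                 blocking_p = blocking_p, spontaneous_a = spontaneous_a,
                 rng_seed = as.integer(rng_seed)),
            class = "protocol_config")
}

#' Sample random seed sets
#'
#' Draws `count` node sets, each of size `round(fraction * n)` (half-up),
#' uniformly without replacement within each set and independently across
#' sets. Reproducible from `rng_seed`.
#'
#' @param g an `igraph` graph or [adjacency_index()].
#' @param fraction fraction of nodes per set, in `(0, 1]`.
#' @param count number of sets.
#' @param rng_seed integer seed.
#' @return A list of `count` integer vectors.
#' @export
sample_seed_sets <- function(g, fraction, count, rng_seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    param_error("`fraction` must be in (0, 1]")
  if (!is_count(count) || count < 1)
    param_error("`count` must be a positive integer")
  n <- if (inherits(g, "adj_index")) g$n else igraph::vcount(g)
  size <- as.integer(floor(fraction * n + 0.5))  # round half up
  if (size < 1) param_error("seed-set size rounds to 0; increase `fraction`")
  set.seed(rng_seed)
  lapply(seq_len(count), function(i) sort(sample.int(n, size)))
}

#' Iteration-wise average of diffusion trends
#'
#' @param trends list of equal-length numeric trend vectors (or of
#'   `diffusion_run` objects, whose `$trend` is taken).
#' @return Data frame `iteration` (0-based), `mean_infected_fraction`,
#'   `std_infected_fraction` (sample standard deviation).
#' @export
average_trend <- function(trends) {
  trends <- lapply(trends, function(t)
    if (inherits(t, "diffusion_run")) t$trend else t)
  lens <- lengths(trends)
  if (length(unique(lens)) != 1)
    param_error("all trends must have the same length")
  m <- do.call(rbind, trends)
  data.frame(iteration = seq_len(ncol(m)) - 1L,
             mean_infected_fraction = colMeans(m),
             std_infected_fraction = apply(m, 2, stats::sd))
}

#' Final infected percentage of a trend
#'
#' @param trend numeric trend vector, a `diffusion_run`, or an
#'   [average_trend()] data frame (its mean column is used).
#' @return `100 *` the last infected fraction.
#' @export
final_infected_percentage <- function(trend) {
  if (inherits(trend, "diffusion_run")) trend <- trend$trend
  if (is.data.frame(trend)) trend <- trend$mean_infected_fraction
  if (length(trend) == 0) param_error("empty trend")
  100 * trend[length(trend)]
}

#' First iteration reaching a coverage level
#'
#' @param trend numeric trend vector or a `diffusion_run`.
#' @param coverage target infected fraction in `(0, 1]`.
#' @return The smallest iteration index `t` (0-based) with
#'   `trend[t] >= coverage`, or `NA` if never reached.
#' @export
iterations_to_coverage <- function(trend, coverage) {
  if (inherits(trend, "diffusion_run")) trend <- trend$trend
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
    param_error("`coverage` must be in (0, 1]")
  hit <- which(trend >= coverage)
  if (length(hit) == 0) NA_integer_ else hit[1] - 1L
}

#' Run the full multi-seed-set protocol for one configuration
#'
#' Samples `config$n_seed_sets` random seed sets, runs the model once per
#' seed set, and aggregates: the iteration-wise mean/sd trend and the mean and
#' sd of the final infected percentage across seed sets. Per-run RNG seeds are
#' derived from `config$rng_seed`, so the whole protocol is reproducible.
#'
#' @param g an `igraph` graph or a prebuilt [adjacency_index()].
#' @param params a [model_params()] (scalar `tau`/`gamma` for this run).
#' @param config a [protocol_config()].
#' @param seed_sets optional pre-sampled list of seed sets (e.g. to share one
#'   sample across grid rows); defaults to sampling from the config.
#' @param seed_stream index offsetting the derived per-run seeds, used by
#'   [run_grid()] to give every grid row an independent stream.
#' @return An object of class `protocol_result`: list with `trend` (the
#'   [average_trend()] data frame), `final_mean_pct`, `final_std_pct`,
#'   `final_pct` (per seed set), `n_runs`, and the `params` echo.
#' @export
run_protocol <- function(g, params, config, seed_sets = NULL,
                         seed_stream = 0L) {
  if (!inherits(config, "protocol_config"))
    param_error("`config` must be created with protocol_config()")
  idx <- as_adj_index(g)
  if (is.null(seed_sets))
    seed_sets <- sample_seed_sets(idx, config$seed_fraction,
                                  config$n_seed_sets,
                                  derive_seed(config$rng_seed, 0))
  runs <- lapply(seq_along(seed_sets), function(i)
    run_diffusion(idx, params, seed_sets[[i]], config$iterations,
                  rng_seed = derive_seed(config$rng_seed,
                                         seed_stream * 100003 + i)))
  finals <- vapply(runs, final_infected_percentage, numeric(1))
  structure(list(trend = average_trend(runs),
                 final_mean_pct = mean(finals),
                 final_std_pct = stats::sd(finals),
                 final_pct = finals,
                 n_runs = length(runs),
                 params = params,
                 config = config),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s | %d runs x %d iterations | final infected %.2f%% (sd %.2f)\n",
              x$params$kind, x$n_runs, nrow(x$trend) - 1L,
              x$final_mean_pct, x$final_std_pct))
  invisible(x)
}

#' Write an averaged trend as CSV
#'
#' Columns `iteration,mean_infected_fraction,std_infected_fraction`.
#'
#' @param result a `protocol_result` or an [average_trend()] data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trend <- function(result, path) {
  df <- if (inherits(result, "protocol_result")) result$trend else result
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
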