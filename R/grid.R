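# Parameter-grid sweeps: one protocol execution per valid parameter
# combination per model kind, yielding the heatmap table of mean final
# infected percentages.

# Enumerate valid combinations: parameters a model ignores are not swept for
# it (threshold: tau x a; profile: gamma x p x a; mixed: tau x gamma x p x a).
grid_rows <- function(config, models = c("threshold", "profile",
                                         "profile_threshold")) {
  rows <- list()
  if ("threshold" %in% models)
    rows$threshold <- expand.grid(model = "threshold", tau = config$tau,
                                  gamma = NA_real_, blocking_p = NA_real_,
                                  spontaneous_a = config$spontaneous_a,
                                  stringsAsFactors = FALSE)
  if ("profile" %in% models)
    rows$profile <- expand.grid(model = "profile", tau = NA_real_,
                                gamma = config$gamma,
                                blocking_p = config$blocking_p,
                                spontaneous_a = config$spontaneous_a,
                                stringsAsFactors = FALSE)
  if ("profile_threshold" %in% models)
    rows$profile_threshold <- expand.grid(model = "profile_threshold",
                                          tau = config$tau,
                                          gamma = config$gamma,
                                          blocking_p = config$blocking_p,
                                          spontaneous_a = config$spontaneous_a,
                                          stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

row_key <- function(df) {
  num <- function(x) sprintf("%.10g", as.numeric(x)) # element-wise, NA-safe
  paste(df$model, num(df$tau), num(df$gamma), num(df$blocking_p),
        num(df$spontaneous_a), sep = "|")
}

#' Sweep a parameter grid over the three models
#'
#' For every valid parameter combination of every requested model kind, runs
#' the full multi-seed-set protocol and records the mean and standard
#' deviation of the final infected percentage. One set of seed sets is sampled
#' once and shared across all rows, and each row's RNG stream is derived from
#' its position in the full enumeration — so a sweep is reproducible from the
#' root seed, and an interrupted sweep resumed via `out_csv` completes the
#' remaining rows with the results an uninterrupted sweep would have
#' produced.
#'
#' @param g an `igraph` graph or [adjacency_index()].
#' @param config a [protocol_config()]; its `tau`, `gamma`, `blocking_p`,
#'   `spontaneous_a` vectors define the grid.
#' @param models model kinds to include.
#' @param out_csv optional path: rows are appended (flushed) there as they
#'   finish; if the file already holds rows from an earlier interrupted sweep
#'   with the same grid, those rows are kept and skipped.
#' @param progress print one line per completed row.
#' @return Data frame with columns `model, tau, gamma, blocking_p,
#'   spontaneous_a, mean_final_pct, std_final_pct, n_runs` (parameters a model
#'   ignores are `NA`).
#' @export
run_grid <- function(g, config,
                     models = c("threshold", "profile", "profile_threshold"),
                     out_csv = NULL, progress = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  if (length(config$tau) == 0 || length(config$gamma) == 0 ||
      length(config$blocking_p) == 0 || length(config$spontaneous_a) == 0)
    param_error("grid lists must be non-empty")
  rows <- grid_rows(config, models)
  idx <- as_adj_index(g)
  seed_sets <- sample_seed_sets(idx, config$seed_fraction, config$n_seed_sets,
                                derive_seed(config$rng_seed, 0))
  done <- character(0)
  results <- list()
  if (!is.null(out_csv) && file.exists(out_csv)) {
    prev <- utils::read.csv(out_csv, stringsAsFactors = FALSE)
    if (nrow(prev) > 0) {
      done <- row_key(prev)
      results <- list(prev)
      message(sprintf("run_grid: resuming, %d of %d rows already present",
                      sum(row_key(rows) %in% done), nrow(rows)))
    }
  }
  keys <- row_key(rows)
  for (i in seq_len(nrow(rows))) {
    if (keys[i] %in% done) next
    r <- rows[i, ]
    params <- model_params(r$model,
                           tau = if (is.na(r$tau)) 0 else r$tau,
                           gamma = if (is.na(r$gamma)) 0 else r$gamma,
                           blocking_p = if (is.na(r$blocking_p)) 0 else r$blocking_p,
                           spontaneous_a = r$spontaneous_a)
    res <- run_protocol(idx, params, config, seed_sets = seed_sets,
                        seed_stream = i)
    out <- data.frame(model = r$model, tau = r$tau, gamma = r$gamma,
                      blocking_p = r$blocking_p,
                      spontaneous_a = r$spontaneous_a,
                      mean_final_pct = res$final_mean_pct,
                      std_final_pct = res$final_std_pct,
                      n_runs = res$n_runs)
    results[[length(results) + 1]] <- out
    if (!is.null(out_csv))
      utils::write.table(out, out_csv, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out_csv), append = file.exists(out_csv))
    if (progress)
      message(sprintf("[%d/%d] %s tau=%s gamma=%s p=%s a=%s -> %.2f%%",
                      i, nrow(rows), r$model, format(r$tau), format(r$gamma),
                      format(r$blocking_p), format(r$spontaneous_a),
                      out$mean_final_pct))
  }
  res <- do.call(rbind, results)
  # return in enumeration order regardless of resume history
  res <- res[order(match(row_key(res), keys)), , drop = FALSE]
  rownames(res) <- NULL
  res
}
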