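# Orchestration and I/O. Times are stored in seconds, frequencies in Hz,
# levels in dB SPL; unit names are embedded in the column headers.

#' Write / read spike tables
#'
#' Canonical text format: CSV with columns `neuron_id`,
#' `condition_value`, `trial`, `spike_time_s` (times written at 1 us
#' resolution). An Arrow (feather) backend is available for bulk runs
#' via `backend = "arrow"`.
#'
#' @param spikes data.frame with the four canonical columns.
#' @param path Output path.
#' @param backend `"csv"` or `"arrow"`.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(spikes, path, backend = c("csv", "arrow")) {
  backend <- match.arg(backend)
  need <- c("neuron_id", "condition_value", "trial", "spike_time_s")
  missing_cols <- setdiff(need, names(spikes))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  spikes <- spikes[, need]
  spikes$spike_time_s <- round(spikes$spike_time_s, 6)
  if (backend == "csv") {
    utils::write.csv(spikes, path, row.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for backend = 'arrow'")
    arrow::write_feather(spikes, path)
  }
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path, backend = c("csv", "arrow")) {
  backend <- match.arg(backend)
  spikes <- if (backend == "csv") {
    utils::read.csv(path)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for backend = 'arrow'")
    as.data.frame(arrow::read_feather(path))
  }
  need <- c("neuron_id", "condition_value", "trial", "spike_time_s")
  missing_cols <- setdiff(need, names(spikes))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(spikes$spike_time_s))
  if (length(bad))
    stop("malformed spike time at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  spikes
}

#' Convert a spike_train_set to/from the canonical table
#' @param trains A `spike_train_set`.
#' @param neuron_id Identifier to attach.
#' @return data.frame with the canonical spike-table columns.
#' @export
spike_table <- function(trains, neuron_id = "n1") {
  data.frame(neuron_id = neuron_id,
             condition_value = trains$spikes$condition,
             trial = trains$spikes$trial,
             spike_time_s = trains$spikes$time_s)
}

#' @rdname spike_table
#' @param tab Canonical spike table (one neuron).
#' @param conditions Full condition axis (defaults to observed values).
#' @param n_reps Trials per condition.
#' @param duration Stimulus duration, s.
#' @param condition_type Condition axis label.
#' @export
spike_train_set_from_table <- function(tab,
                                       conditions =
                                         sort(unique(tab$condition_value)),
                                       n_reps = max(tab$trial),
                                       duration = 0.3,
                                       condition_type = "peak_freq_hz") {
  new_spike_train_set(
    data.frame(condition = tab$condition_value, trial = tab$trial,
               time_s = tab$spike_time_s),
    conditions = conditions, n_reps = n_reps, duration = duration,
    condition_type = condition_type)
}

#' Write neuron metadata / rate profiles as CSV
#' @param meta data.frame with `neuron_id`, `cf_hz`, `spont_sps`,
#'   `mtf_type`.
#' @param path Output path.
#' @export
write_neuron_metadata <- function(meta, path) {
  need <- c("neuron_id", "cf_hz", "spont_sps", "mtf_type")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(meta[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_neuron_metadata
#' @param profile A `rate_profile`.
#' @export
write_rate_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Full-run configuration
#'
#' @param n_neurons Number of synthetic neurons.
#' @param cf_range CF range, Hz.
#' @param levels Sound levels analyzed, dB SPL.
#' @param n_reps Trials per condition.
#' @param duration Stimulus duration, s.
#' @param increment Shift increment, Hz.
#' @param seed Master seed.
#' @param fit_rfs Also fit Gaussian/DoG receptive fields?
#' @param shape_probs,mtf_probs Population proportions.
#' @return A `run_config`.
#' @export
run_config <- function(n_neurons = 20, cf_range = c(320, 9236),
                       levels = c(43, 63, 83), n_reps = 30,
                       duration = 0.3, increment = 40, seed = 1,
                       fit_rfs = FALSE,
                       shape_probs = c(peak = 0.81, dip = 0.10,
                                       sloping = 0.09),
                       mtf_probs = c(BE = 0.239, BS = 0.548,
                                     hybrid = 0.128, flat = 0.085)) {
  structure(list(n_neurons = n_neurons, cf_range = cf_range,
                 levels = levels, n_reps = n_reps, duration = duration,
                 increment = increment, seed = seed, fit_rfs = fit_rfs,
                 shape_probs = shape_probs, mtf_probs = mtf_probs),
            class = "run_config")
}

#' Run the full seeded analysis pipeline on a synthetic population
#'
#' Generates a seeded neuron population, simulates shift-series spike
#' trains per neuron, and runs the rate-profile, classification,
#' salience, and threshold pipelines, optionally plus receptive-field
#' fits. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return A `run_result`: `neurons` (per-neuron summary data.frame),
#'   `summary` (population proportions), `config`, `log`.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- c(sprintf("run_full seed=%d n_neurons=%d levels=%s",
                   config$seed, config$n_neurons,
                   paste(config$levels, collapse = "/")),
           sprintf("n_reps=%d duration=%g increment=%g fit_rfs=%s",
                   config$n_reps, config$duration, config$increment,
                   config$fit_rfs))
  if (config$n_neurons == 0) {
    warning("empty neuron list; nothing to do")
    return(structure(list(neurons = NULL, summary = NULL,
                          config = config, log = log),
                     class = "run_result"))
  }
  pop <- synthetic_population(config$n_neurons, config$cf_range,
                              config$shape_probs, config$mtf_probs,
                              seed = config$seed)
  rows <- vector("list", length(pop))
  for (i in seq_along(pop)) {
    nrn <- pop[[i]]
    row <- tryCatch({
      series <- make_shift_series(nrn$cf, increment = config$increment)
      trains <- simulate_spike_trains(nrn, series,
                                      n_reps = config$n_reps,
                                      duration = config$duration,
                                      seed = config$seed + i)
      an <- analyze_rate_profile(trains, cf = nrn$cf, spont = nrn$spont)
      thr <- rate_threshold(an$profile)
      out <- data.frame(
        neuron_id = sprintf("n%03d", i), cf_hz = nrn$cf,
        spont_sps = nrn$spont, true_shape = nrn$profile_shape,
        mtf_type = nrn$mtf_type,
        category = an$classification$category,
        q = ifelse(is.null(an$salience), NA, an$salience$q),
        theta_pct = thr$theta, threshold_found = thr$found)
      if (config$fit_rfs) {
        fg <- fit_rf(an$profile, series, "gaussian")
        fd <- fit_rf(an$profile, series, "dog")
        cmpr <- compare_models(fg, fd)
        out$gauss_adj_r2 <- fg$adj_r2
        out$dog_adj_r2 <- fd$adj_r2
        out$f_test_p <- cmpr$p
      }
      out
    }, error = function(e) {
      log <<- c(log, sprintf("neuron %d failed: %s", i,
                             conditionMessage(e)))
      NULL
    })
    rows[[i]] <- row
  }
  neurons <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  summary <- as.data.frame(table(category = neurons$category))
  summary$proportion <- summary$Freq / sum(summary$Freq)
  structure(list(neurons = neurons, summary = summary, config = config,
                 log = log), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  if (is.null(x$neurons)) {
    cat("run_result: empty\n")
    return(invisible(x))
  }
  cat(sprintf("run_result: %d neurons analyzed\n", nrow(x$neurons)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
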