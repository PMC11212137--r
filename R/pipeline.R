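#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file; format chosen by extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return The configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
}

resolve_condition <- function(spec, seed) {
  if (inherits(spec, "sim_config")) return(spec)
  if (is.list(spec) && !is.null(spec$preset)) {
    return(avp_sim_config(spec$preset, duration = spec$duration, seed = seed))
  }
  stop("condition must be a sim_config or list(preset=, duration=)", call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - simulate, detect, filter, fit,
#' classify, evaluate - for each configured condition, with one derived
#' seed per stage so the whole run is reproducible from the master
#' seed. Configuration sections:
#'
#' * `conditions`: named list; each entry a [sim_config()] or
#'   `list(preset = <avp condition>, duration = <s>)`.
#' * `detection`: `k`, `min_dwell`, `min_sigma`, `min_norm_blockade`.
#' * `fits`: list of `list(condition, what = "blockade"|"dwell"|
#'   "frequency", model, window)`; `window` a preset name or
#'   `c(lower, upper)`.
#' * `classification` (optional): `list(reference =, bands = list(D =,
#'   L =), mixture = <condition or NULL>)`. Bands are fitted per
#'   single-peptide condition in the reference model's PC plane; the
#'   combined single-peptide data are Monte Carlo classified and scored
#'   against their true condition of origin, and the mixture (if any)
#'   is classified and its L/D ratio estimated.
#' * `seed`: master seed; `out_dir` (optional): directory for event
#'   CSVs, fit summaries and the JSON report.
#'
#' @param config Configuration list (see above) or a path readable by
#'   [read_run_config()].
#' @return A `run_report` list: `conditions` (event counts, baselines),
#'   `fits`, `classification` (bands, confusion matrix, mixture ratio),
#'   `seeds`, `timing_s`, `package_version`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config), !is.null(config$conditions))
  t_start <- Sys.time()
  master <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  det <- utils::modifyList(list(k = 7, min_dwell = 200, min_sigma = 1,
                                min_norm_blockade = 0.2),
                           if (is.null(config$detection)) list() else config$detection)

  cond_names <- names(config$conditions)
  seeds <- stats::setNames(master + seq_along(cond_names), cond_names)
  events <- list()
  cond_report <- list()
  for (nm in cond_names) {
    cfg <- resolve_condition(config$conditions[[nm]], seeds[[nm]])
    trace <- simulate_trace(cfg)
    tab <- detect_events(trace, k = det$k)
    tab <- filter_events(tab, det$min_dwell, det$min_sigma,
                         det$min_norm_blockade)
    events[[nm]] <- tab
    bl <- attr(tab, "baseline")
    cond_report[[nm]] <- list(
      n_true_events = nrow(trace$ledger),
      n_detected = attr(tab, "filter_log")$n_in,
      n_retained = nrow(tab),
      i0_pA = bl$i0, sigma_pA = bl$sigma,
      filter_log = attr(tab, "filter_log"))
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_event_table(tab, file.path(config$out_dir,
                                       paste0("events_", nm, ".csv")))
      write_ledger(trace, file.path(config$out_dir,
                                    paste0("ledger_", nm, ".csv")))
    }
  }

  as_window <- function(w) {
    if (inherits(w, "population_window")) w
    else if (is.character(w)) population_window(w)
    else population_window(lower = w[[1]], upper = w[[2]])
  }
  fit_report <- list()
  if (!is.null(config$fits)) {
    for (i in seq_along(config$fits)) {
      f <- config$fits[[i]]
      tab <- events[[f$condition]]
      res <- switch(f$what,
        blockade = {
          h <- blockade_histogram(tab)
          fit <- fit_blockade_peaks(h, model = if (is.null(f$model)) "gaussian" else f$model,
                                    window = as_window(f$window),
                                    seed = master + 1000L + i)
          list(kind = "blockade", model = fit$model,
               window = c(fit$window$lower, fit$window$upper),
               components = fit$components, dominant = fit$dominant,
               dominant_mean = fit$components$mean[fit$dominant])
        },
        dwell = {
          fit <- fit_dwell_time(tab, window = if (is.null(f$window)) NULL else as_window(f$window),
                                seed = master + 1000L + i)
          list(kind = "dwell", tau_us = fit$tau, tau_sd = fit$tau_repeat_sd,
               n_events = fit$n_events)
        },
        frequency = {
          fit <- event_frequency(tab, seed = master + 1000L + i)
          list(kind = "frequency", rate_hz = fit$rate,
               rate_sd = fit$rate_repeat_sd, n_events = fit$n_events)
        },
        stop("unknown fit kind: ", f$what, call. = FALSE))
      nm <- paste0(f$condition, "_", f$what,
                   if (!is.null(f$label)) paste0("_", f$label) else "")
      fit_report[[nm]] <- res
    }
  }

  class_report <- NULL
  if (!is.null(config$classification)) {
    cl <- config$classification
    model <- fit_pca_model(events[[cl$reference]])
    band_conditions <- cl$bands
    bands <- list()
    proj <- list()
    for (lbl in names(band_conditions)) {
      pr <- project_events(events[[band_conditions[[lbl]]]], model)
      proj[[lbl]] <- pr
      bands[[lbl]] <- fit_pc2_band(pr, lbl)
    }
    combined <- do.call(rbind, proj)
    truth <- rep(names(proj), vapply(proj, nrow, integer(1)))
    combined <- structure(combined, class = c("labeled_events", "data.frame"))
    labeled <- monte_carlo_classify(combined, bands[[1]], bands[[2]],
                                    seed = master + 2000L)
    cm <- evaluate_confusion(labeled, truth)
    mix <- NULL
    if (!is.null(cl$mixture)) {
      mp <- project_events(events[[cl$mixture]], model)
      ml <- monte_carlo_classify(mp, bands[[1]], bands[[2]],
                                 seed = master + 2001L)
      rat <- estimate_mixture_ratio(ml)
      mix <- list(condition = cl$mixture, ratio = rat$ratio,
                  conf_int = rat$conf_int, n_L = rat$n_L, n_D = rat$n_D)
    }
    class_report <- list(
      reference = cl$reference,
      eigenvalues = model$eigenvalues,
      bands = lapply(bands, function(b) list(label = b$label, mean = b$mean,
                                             sd = b$sd)),
      confusion_counts = as.data.frame(cm$counts),
      success = cm$success, false_positive = cm$false_positive,
      overall_success = cm$overall_success,
      mixture = mix)
  }

  report <- structure(list(
    conditions = cond_report, fits = fit_report,
    classification = class_report,
    seeds = list(master = master, conditions = as.list(seeds)),
    detection = det,
    timing_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    package_version = as.character(utils::packageVersion("enantiopore"))),
    class = "run_report")
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$conditions)) {
    c <- x$conditions[[nm]]
    cat(sprintf("  %s: %d detected, %d retained (I0 = %.2f pA)\n",
                nm, c$n_detected, c$n_retained, c$i0_pA))
  }
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  fit %s: %s\n", nm, switch(f$kind,
      blockade = sprintf("dominant mean %.3f", f$dominant_mean),
      dwell = sprintf("tau %.0f us", f$tau_us),
      frequency = sprintf("rate %.2f Hz", f$rate_hz))))
  }
  if (!is.null(x$classification)) {
    cat(sprintf("  classification: overall success %.1f%%\n",
                100 * x$classification$overall_success))
    if (!is.null(x$classification$mixture)) {
      cat(sprintf("  mixture %s: L/D = %.2f\n",
                  x$classification$mixture$condition,
                  x$classification$mixture$ratio))
    }
  }
  cat(sprintf("  completed in %.1f s\n", x$timing_s))
  invisible(x)
}
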