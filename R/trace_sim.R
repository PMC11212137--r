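#' Describe one blockade-event population
#'
#' A population groups events with a common normalized blockade level
#' (Gaussian), dwell-time scale (exponential) and Poisson arrival rate.
#' Populations correspond to the event types seen with vasopressin on
#' aerolysin: Type I (deep, short), Type IIa/IIb (medium, long) and the
#' single population seen after disulfide reduction with TCEP.
#'
#' @param name Text label, e.g. `"TypeIIa_L"`.
#' @param norm_blockade_mean Mean normalized blockade level
#'   \eqn{\Delta I_b / I_0}, a fraction strictly between 0 and 1.
#' @param norm_blockade_sd Standard deviation of the normalized blockade
#'   level across events (dimensionless, > 0).
#' @param dwell_tau Mean of the exponential dwell-time distribution, in
#'   microseconds.
#' @param rate Poisson arrival rate in Hz (may be 0 to silence a
#'   population).
#' @param intra_event_noise_sd Within-event current noise as measured on
#'   the filtered trace, pA (the generator injects white noise scaled by
#'   the filter's noise-bandwidth ratio so the filtered trace shows this
#'   amplitude). The default 3 pA keeps simulated in-event noise above
#'   the 1 pA bumping-rejection floor.
#' @return A `population_spec` list.
#' @export
#' @examples
#' population_spec("TypeIIa_L", 0.43, 0.015, 820, 11.4)
population_spec <- function(name, norm_blockade_mean, norm_blockade_sd,
                            dwell_tau, rate, intra_event_noise_sd = 3) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot_scalar_pos(norm_blockade_mean, "norm_blockade_mean")
  if (norm_blockade_mean >= 1) {
    stop("`norm_blockade_mean` must be < 1 (a blockade cannot exceed the open-pore current)",
         call. = FALSE)
  }
  stopifnot_scalar_pos(norm_blockade_sd, "norm_blockade_sd")
  stopifnot_scalar_pos(dwell_tau, "dwell_tau")
  stopifnot_scalar_pos(rate, "rate", strict = FALSE)
  stopifnot_scalar_pos(intra_event_noise_sd, "intra_event_noise_sd", strict = FALSE)
  structure(list(name = name,
                 norm_blockade_mean = norm_blockade_mean,
                 norm_blockade_sd = norm_blockade_sd,
                 dwell_tau = dwell_tau,
                 rate = rate,
                 intra_event_noise_sd = intra_event_noise_sd),
            class = "population_spec")
}

#' Simulation configuration for a single-channel recording
#'
#' Defaults mirror typical aerolysin recordings in 4 M KCl: open-pore
#' current near 250 pA at 110 mV, 250 kHz sampling (4 us per sample) and a
#' 5 kHz low-pass filter.
#'
#' @param duration Recording length in seconds.
#' @param populations List of [population_spec()] objects (may be empty).
#' @param i0 Open-pore current, pA.
#' @param baseline_noise_sd Open-pore current noise as measured on the
#'   filtered trace, pA (matching how recording noise like
#'   "I0 = 243.82 +/- 1.77 pA" is reported; the injected white noise is
#'   pre-amplified by the filter's noise-bandwidth ratio).
#' @param sampling_rate Samples per second, Hz.
#' @param filter_cutoff Low-pass cutoff, Hz (-3 dB, Gaussian response);
#'   `NA` disables filtering.
#' @param seed Integer seed controlling every random draw of the
#'   simulation.
#' @param voltage_mV Applied potential recorded as metadata.
#' @param condition Free-text condition label recorded as metadata.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration, populations = list(), i0 = 250,
                       baseline_noise_sd = 2, sampling_rate = 250e3,
                       filter_cutoff = 5e3, seed = 1L, voltage_mV = 110,
                       condition = "") {
  stopifnot_scalar_pos(duration, "duration")
  stopifnot_scalar_pos(i0, "i0")
  stopifnot_scalar_pos(baseline_noise_sd, "baseline_noise_sd", strict = FALSE)
  stopifnot_scalar_pos(sampling_rate, "sampling_rate")
  if (!is.na(filter_cutoff)) {
    stopifnot_scalar_pos(filter_cutoff, "filter_cutoff")
    if (sampling_rate <= 2 * filter_cutoff) {
      stop("`sampling_rate` must exceed twice `filter_cutoff`", call. = FALSE)
    }
  }
  if (!is.list(populations) || (length(populations) &&
      !all(vapply(populations, inherits, logical(1), "population_spec")))) {
    stop("`populations` must be a list of population_spec objects", call. = FALSE)
  }
  structure(list(duration = duration, populations = populations, i0 = i0,
                 baseline_noise_sd = baseline_noise_sd,
                 sampling_rate = sampling_rate, filter_cutoff = filter_cutoff,
                 seed = seed, voltage_mV = voltage_mV, condition = condition),
            class = "sim_config")
}

#' Gaussian low-pass filter for current traces
#'
#' Finite-impulse-response filter with a Gaussian frequency response whose
#' -3 dB point sits at `cutoff`. The acquisition chain the simulator
#' emulates reports only a 5 kHz low-pass; a Gaussian response is the
#' conventional stand-in and is swappable (any function with this
#' signature can replace it in [simulate_trace()] post-processing).
#' Edges are padded by replicating the first/last sample.
#'
#' @param x Numeric vector of current samples, pA.
#' @param sampling_rate Hz.
#' @param cutoff -3 dB cutoff frequency, Hz; `NA` returns `x` unchanged.
#' @return Filtered numeric vector, same length as `x`.
#' @export
lowpass_filter <- function(x, sampling_rate, cutoff) {
  if (is.null(cutoff) || is.na(cutoff)) return(x)
  # time-domain sigma (in samples) for a Gaussian with -3 dB at `cutoff`
  sigma <- sqrt(log(2)) / (2 * pi * cutoff) * sampling_rate
  k <- ceiling(4 * sigma)
  h <- stats::dnorm(seq(-k, k), 0, sigma)
  h <- h / sum(h)
  n <- length(x)
  if (n == 0L) return(x)
  padded <- c(rep(x[1L], k), x, rep(x[n], k))
  y <- stats::filter(padded, h, sides = 2)
  as.numeric(y[(k + 1L):(k + n)])
}

# standard-deviation attenuation of white noise through the Gaussian FIR
filter_noise_ratio <- function(sampling_rate, cutoff) {
  if (is.null(cutoff) || is.na(cutoff)) return(1)
  sigma <- sqrt(log(2)) / (2 * pi * cutoff) * sampling_rate
  k <- ceiling(4 * sigma)
  h <- stats::dnorm(seq(-k, k), 0, sigma)
  h <- h / sum(h)
  sqrt(sum(h^2))
}

#' Simulate a nanopore current trace
#'
#' Generates an open-pore baseline with Gaussian current noise, inserts
#' blockade events for each population (Poisson arrivals, exponential
#' dwell, per-event Gaussian normalized blockade depth, within-event
#' noise), and passes the whole trace through the configured low-pass
#' filter. Event arrivals that would overlap an existing event are
#' redrawn, and events are placed on sample boundaries. A ground-truth
#' ledger (one row per inserted event) is attached for downstream
#' recovery tests.
#'
#' @param config A [sim_config()] object.
#' @param apply_filter Set `FALSE` to skip the low-pass stage (the
#'   unfiltered trace can be filtered later with [lowpass_filter()];
#'   the two routes are identical).
#' @return A `nanopore_trace`: list with `current` (pA), `sampling_rate`,
#'   `metadata` and the ground-truth `ledger` data frame (columns
#'   `population`, `onset_index`, `dwell_us`, `true_norm_blockade`).
#' @export
#' @examples
#' cfg <- sim_config(duration = 0.2, populations = list(
#'   population_spec("TypeIIa_L", 0.43, 0.015, 820, 50)), seed = 7)
#' tr <- simulate_trace(cfg)
#' tr
simulate_trace <- function(config, apply_filter = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  for (p in config$populations) {
    if (p$norm_blockade_mean >= 1) {
      stop("population mean blockade must be < 1", call. = FALSE)
    }
  }
  duty <- sum(vapply(config$populations,
                     function(p) p$rate * p$dwell_tau * 1e-6, numeric(1)))
  if (duty > 0.5) {
    stop(sprintf(
      "expected event duty cycle %.2f exceeds 50%%: events would merge pervasively",
      duty), call. = FALSE)
  }
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  dt_us <- 1e6 / fs
  # noise sds are specified as measured on the filtered trace; the white
  # noise injected here is scaled up by the filter's noise-bandwidth
  # ratio (independent of `apply_filter`, which only defers the filter,
  # so that deferred filtering yields the identical trace)
  gain <- 1 / filter_noise_ratio(fs, config$filter_cutoff)

  with_seed(config$seed, {
    current <- stats::rnorm(n, config$i0, gain * config$baseline_noise_sd)

    led <- list()
    occupied_start <- integer(0)
    occupied_end <- integer(0)
    for (p in config$populations) {
      if (p$rate <= 0) next
      n_ev <- stats::rpois(1L, p$rate * config$duration)
      if (n_ev == 0L) next
      dwell_us <- stats::rexp(n_ev, 1 / p$dwell_tau)
      g <- stats::rnorm(n_ev, p$norm_blockade_mean, p$norm_blockade_sd)
      onset <- integer(n_ev)
      span <- pmax(1L, as.integer(round(dwell_us / dt_us)))
      for (j in seq_len(n_ev)) {
        placed <- FALSE
        if (span[j] >= n - 2L) {
          onset[j] <- NA_integer_
          next
        }
        for (try in 1:200) {
          s <- sample.int(n - span[j] - 1L, 1L) + 1L
          e <- s + span[j] - 1L
          if (!any(s <= occupied_end & e >= occupied_start)) {
            occupied_start <- c(occupied_start, s)
            occupied_end <- c(occupied_end, e)
            onset[j] <- s
            placed <- TRUE
            break
          }
        }
        if (!placed) onset[j] <- NA_integer_
      }
      keep <- !is.na(onset)
      if (!all(keep)) {
        onset <- onset[keep]; span <- span[keep]
        dwell_us <- dwell_us[keep]; g <- g[keep]
      }
      for (j in seq_along(onset)) {
        idx <- onset[j]:(onset[j] + span[j] - 1L)
        level <- config$i0 * (1 - g[j])
        current[idx] <- level +
          stats::rnorm(length(idx), 0, gain * p$intra_event_noise_sd)
      }
      if (length(onset)) {
        led[[p$name]] <- data.frame(population = p$name,
                                    onset_index = onset,
                                    dwell_us = dwell_us,
                                    true_norm_blockade = g,
                                    stringsAsFactors = FALSE)
      }
    }
    ledger <- if (length(led)) do.call(rbind, led) else {
      data.frame(population = character(0), onset_index = integer(0),
                 dwell_us = numeric(0), true_norm_blockade = numeric(0))
    }
    rownames(ledger) <- NULL
    ledger <- ledger[order(ledger$onset_index), , drop = FALSE]

    if (apply_filter) {
      current <- lowpass_filter(current, fs, config$filter_cutoff)
    }

    structure(list(
      current = current,
      sampling_rate = fs,
      metadata = list(i0_nominal = config$i0,
                      baseline_noise_sd = config$baseline_noise_sd,
                      voltage_mV = config$voltage_mV,
                      condition = config$condition,
                      seed = config$seed,
                      filter_cutoff = if (apply_filter) config$filter_cutoff else NA_real_,
                      duration = config$duration),
      ledger = ledger,
      config = config), class = "nanopore_trace")
  })
}

#' @export
print.nanopore_trace <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<nanopore_trace> %s samples at %g kHz (%.3g s)\n",
              format(length(x$current), big.mark = ","),
              x$sampling_rate / 1e3, md$duration))
  cat(sprintf("  I0 nominal %.2f pA, %g mV%s, filter %s\n",
              md$i0_nominal, md$voltage_mV,
              if (nzchar(md$condition)) paste0(", ", md$condition) else "",
              if (is.na(md$filter_cutoff)) "off"
              else sprintf("%g kHz", md$filter_cutoff / 1e3)))
  cat(sprintf("  ground-truth events: %d (%s)\n", nrow(x$ledger),
              if (nrow(x$ledger)) paste(names(table(x$ledger$population)),
                                        table(x$ledger$population),
                                        sep = ":", collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
plot.nanopore_trace <- function(x, from = 1, to = min(length(x$current), 250000), ...) {
  idx <- from:to
  t_s <- (idx - 1) / x$sampling_rate
  graphics::plot(t_s, x$current[idx], type = "l", xlab = "time (s)",
                 ylab = "current (pA)", ...)
  invisible(x)
}

#' Draw PC2 values from a fitted enantiomer band
#'
#' Samples independent values from the Gaussian underlying a PC2 band,
#' standing in for the per-peptide PC2 populations observed in
#' single-peptide experiments.
#'
#' @param band A [pc2_band()] object (or any list with `mean` and `sd`).
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; same seed and band give identical draws.
#' @return Numeric vector of `n` dimensionless PC2 values.
#' @export
simulate_pc2_samples <- function(band, n, seed = NULL) {
  stopifnot(is.numeric(band$mean), is.numeric(band$sd))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  if (!is.finite(band$sd) || band$sd <= 0) {
    stop("band `sd` must be positive", call. = FALSE)
  }
  with_seed(seed, stats::rnorm(n, band$mean, band$sd))
}
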