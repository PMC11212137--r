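# Shared fixtures: small simulated traces and synthetic event tables.
# Everything is generated in code under fixed seeds; nothing is stored.

# single-population trace short enough for fast unit tests
quick_trace <- function(duration = 2, rate = 60, level = 0.43, sd = 0.015,
                        tau = 820, seed = 101, i0 = 250, noise = 2,
                        filter_cutoff = 5e3, intra = 3) {
  cfg <- sim_config(duration = duration,
                    populations = list(population_spec("pop", level, sd, tau,
                                                       rate,
                                                       intra_event_noise_sd = intra)),
                    i0 = i0, baseline_noise_sd = noise,
                    filter_cutoff = filter_cutoff, seed = seed)
  simulate_trace(cfg)
}

# a noiseless, unfiltered trace with rectangular events at known spots
rect_trace <- function(i0 = 250, depth = 100, starts = c(5001, 12001),
                       len = 250, n = 30000, fs = 250e3) {
  x <- rep(i0, n)
  for (s in starts) x[s:(s + len - 1L)] <- i0 - depth
  structure(list(current = x, sampling_rate = fs,
                 metadata = list(i0_nominal = i0, filter_cutoff = NA_real_,
                                 duration = n / fs, voltage_mV = 110,
                                 condition = "rect", seed = NA),
                 ledger = NULL, config = NULL),
            class = "nanopore_trace")
}

# synthetic featurized event table drawn from given population stats
synth_events <- function(n, mean_block = 0.43, sd_block = 0.015, tau = 820,
                         i0 = 250, i_bs = 3, seed = 1, rate = 20,
                         min_dwell = 0) {
  withr::with_seed(seed, {
    dwell <- stats::rexp(n * 3, 1 / tau)
    dwell <- dwell[dwell >= min_dwell][seq_len(n)]
    nb <- stats::rnorm(n, mean_block, sd_block)
    gaps <- stats::rexp(n, rate) * 250e3
    df <- data.frame(t_t_us = dwell, norm_di_b = nb,
                     i_bs_pA = rep(i_bs, n),
                     start_index = cumsum(gaps + dwell / 4))
    df$start_index <- as.integer(round(df$start_index))
    event_table(df, i0 = i0)
  })
}
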