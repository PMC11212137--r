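test_that("blockade histograms conserve counts and bin deterministically", {
  tab <- synth_events(1000, mean_block = 0.4025, sd_block = 1e-9, seed = 2)
  h <- blockade_histogram(tab)
  expect_equal(sum(h$counts), 1000)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$counts[h$mids == 0.4025], 1000)

  # values 0.401 and 0.404 share the [0.400, 0.405) bin
  tab2 <- event_table(data.frame(t_t_us = c(300, 300),
                                 norm_di_b = c(0.401, 0.404),
                                 i_bs_pA = c(3, 3)), i0 = 250)
  h2 <- blockade_histogram(tab2)
  expect_equal(sum(h2$counts > 0), 1)

  tab3 <- synth_events(5000, sd_block = 0.02, seed = 3)
  h3a <- blockade_histogram(tab3)
  h3b <- blockade_histogram(tab3)
  expect_identical(h3a$counts, h3b$counts)
  expect_equal(sum(h3a$counts), 5000)

  empty <- event_table(data.frame(t_t_us = numeric(0),
                                  norm_di_b = numeric(0),
                                  i_bs_pA = numeric(0)), i0 = 250)
  expect_equal(sum(blockade_histogram(empty)$counts), 0)
})

test_that("Gaussian peak fitting recovers a synthetic population", {
  tab <- synth_events(3000, mean_block = 0.43, sd_block = 0.02, seed = 4)
  h <- blockade_histogram(tab)
  fit <- fit_blockade_peaks(h, "gaussian", population_window("TypeII"),
                            seed = 1)
  expect_equal(fit$components$mean[1], 0.43, tolerance = 0.01 / 0.43)
  expect_equal(fit$components$sd[1], 0.02, tolerance = 0.15)
  expect_equal(fit$n_converged, 3)

  # symmetric unimodal histogram: fitted mean within one bin of the mode
  mode_bin <- h$mids[which.max(h$counts)]
  expect_lt(abs(fit$components$mean[1] - mode_bin), h$bin_width)
})

test_that("bi-Gaussian fitting resolves the equimolar-mixture modes", {
  t1 <- synth_events(2800, mean_block = 0.39, sd_block = 0.015, seed = 5)
  t2 <- synth_events(1200, mean_block = 0.43, sd_block = 0.015, seed = 6)
  both <- event_table(rbind(as.data.frame(t1)[c("t_t_us", "norm_di_b", "i_bs_pA")],
                            as.data.frame(t2)[c("t_t_us", "norm_di_b", "i_bs_pA")]),
                      i0 = 250)
  h <- blockade_histogram(both)
  fit <- fit_blockade_peaks(h, "bigaussian", population_window("TypeII"),
                            seed = 2)
  expect_equal(nrow(fit$components), 2)
  expect_equal(fit$components$mean[1], 0.39, tolerance = 0.01 / 0.39)
  expect_equal(fit$components$mean[2], 0.43, tolerance = 0.01 / 0.43)
  # components ordered by mean, dominant is the 70% one
  expect_true(fit$components$mean[1] < fit$components$mean[2])
  expect_equal(fit$dominant, 1L)
})

test_that("a collapsed bi-Gaussian is flagged and refitted as Gaussian", {
  tab <- synth_events(4000, mean_block = 0.45, sd_block = 0.015, seed = 7)
  h <- blockade_histogram(tab)
  fit <- fit_blockade_peaks(h, "bigaussian", population_window("TypeII"),
                            seed = 3)
  if (fit$collapsed) {
    expect_equal(nrow(fit$components), 1)
    expect_equal(fit$components$mean[1], 0.45, tolerance = 0.01)
  } else {
    # the dominant component carries the single peak; any minor
    # component can only soak up shoulder noise
    expect_equal(fit$components$mean[fit$dominant], 0.45, tolerance = 0.01)
    expect_gt(fit$components$amplitude[fit$dominant],
              2 * min(fit$components$amplitude))
  }
})

test_that("dwell-time fits recover a truncated exponential scale", {
  tab <- synth_events(3000, tau = 440, seed = 8, min_dwell = 200)
  fit <- fit_dwell_time(tab, seed = 1)
  expect_equal(fit$tau, 440, tolerance = 0.1)

  # scale equivariance: doubling dwell doubles tau
  tab2 <- tab
  tab2$t_t_us <- tab$t_t_us * 2
  fit2 <- fit_dwell_time(tab2, min_dwell = 400, seed = 1)
  expect_equal(fit2$tau / fit$tau, 2, tolerance = 0.1)

  # estimates at different n agree within combined uncertainty
  big <- synth_events(2e4, tau = 440, seed = 9, min_dwell = 200)
  fit3 <- fit_dwell_time(big, seed = 1)
  expect_equal(fit3$tau, fit$tau, tolerance = 0.12)

  # agreement with the closed-form truncated-exponential MLE
  expect_equal(fit$tau, dwell_mle(tab$t_t_us, 200), tolerance = 0.1)
})

test_that("event-frequency fits recover Poisson arrival rates", {
  # synthetic tables have unconditional exponential gaps, so the decay
  # rate is the arrival rate directly and no dead-time correction applies
  # (the correction is exercised on simulated traces in the acceptance
  # tests, where arrivals are conditioned on the pore being free)
  tab <- synth_events(3000, tau = 820, rate = 19.1, seed = 10)
  fit <- event_frequency(tab, correct_dead_time = FALSE, seed = 1)
  expect_equal(fit$rate, 19.1, tolerance = 1.5 / 19.1)

  # thinning every second event halves the rate
  thin <- tab[seq(1, nrow(tab), by = 2), ]
  thin <- event_table(as.data.frame(thin), i0 = 250)
  fit_thin <- event_frequency(thin, correct_dead_time = FALSE, seed = 1)
  expect_equal(fit_thin$rate / fit$rate, 0.5, tolerance = 0.15)

  fast <- synth_events(5000, tau = 900, rate = 153.3, seed = 11)
  fit_fast <- event_frequency(fast, correct_dead_time = FALSE, seed = 1)
  expect_equal(fit_fast$rate, 153.3, tolerance = 0.05)
})

test_that("population windows select inclusively and compose as sets", {
  df <- data.frame(t_t_us = rep(500, 5),
                   norm_di_b = c(0.72, 0.60, 0.43, 0.35, 0.55),
                   i_bs_pA = rep(3, 5))
  tab <- event_table(df, i0 = 250)
  tI <- select_population(tab, population_window("TypeI"))
  tII <- select_population(tab, population_window("TypeII"))
  expect_equal(tI$norm_di_b, 0.72)
  # 0.60 excluded by both windows; window bounds are inclusive
  expect_false(0.60 %in% c(tI$norm_di_b, tII$norm_di_b))
  expect_setequal(tII$norm_di_b, c(0.43, 0.35, 0.55))
  # union of disjoint windows selects the union of selections
  expect_setequal(c(tI$norm_di_b, tII$norm_di_b),
                  df$norm_di_b[df$norm_di_b != 0.60])
})

test_that("repeat-fit uncertainty is finite and fits are reproducible", {
  tab <- synth_events(2000, sd_block = 0.02, seed = 12)
  h <- blockade_histogram(tab)
  f1 <- fit_blockade_peaks(h, "gaussian", population_window("TypeII"), seed = 5)
  f2 <- fit_blockade_peaks(h, "gaussian", population_window("TypeII"), seed = 5)
  expect_identical(f1$components, f2$components)
  expect_true(is.finite(f1$components$mean_repeat_sd[1]))
})
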