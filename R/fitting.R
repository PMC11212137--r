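#' Histogram of normalized blockade levels
#'
#' Fixed-width binning of `norm_di_b` over `[0, 1]` (0.005 by default,
#' the convention for these recordings). The total count equals the
#' number of input events.
#'
#' @param events A featurized `event_table`.
#' @param bin_width Bin width on the normalized blockade axis.
#' @return A `blockade_histogram`: list with `mids`, `counts`, `breaks`,
#'   `bin_width`, `n_events`.
#' @export
blockade_histogram <- function(events, bin_width = 0.005) {
  stopifnot(inherits(events, "event_table"))
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  x <- events$norm_di_b
  x <- x[!is.na(x) & x >= 0 & x <= 1]
  # right-open bins except the last, so 1.0 lands in the final bin
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(mids = (breaks[-length(breaks)] + breaks[-1]) / 2,
                 counts = counts, breaks = breaks, bin_width = bin_width,
                 n_events = length(x)),
            class = "blockade_histogram")
}

#' @export
print.blockade_histogram <- function(x, ...) {
  cat(sprintf("<blockade_histogram> %d events in %d bins of width %g\n",
              x$n_events, length(x$counts), x$bin_width))
  invisible(x)
}

#' @export
plot.blockade_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h",
                 xlab = expression(Delta * I[b] / I[0]),
                 ylab = "events", ...)
  invisible(x)
}

gauss_fun <- function(x, A, m, s) A * exp(-((x - m)^2) / (2 * s^2))

# one randomized-start Levenberg-Marquardt fit; returns coef or NULL
nls_try <- function(formula, data, start, lower, upper, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(data))
  # do.call so the weights vector is passed by value (nlsLM would
  # otherwise resolve the name `weights` in the wrong environment)
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM,
            list(formula, data = data, start = start,
                 lower = lower, upper = upper, weights = weights,
                 control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(coef = stats::coef(fit),
       rss = sum(weights * stats::residuals(fit)^2))
}

perturb <- function(start, frac = 0.2) {
  lapply(start, function(v) v * stats::runif(1, 1 - frac, 1 + frac))
}

repeat_fit <- function(formula, data, start, lower, upper, repeats, seed,
                       weights = NULL) {
  fits <- with_seed(seed, {
    out <- list()
    for (r in seq_len(repeats)) {
      st <- if (r == 1L) start else perturb(start)
      cf <- nls_try(formula, data, st, lower, upper, weights)
      if (!is.null(cf)) out[[length(out) + 1L]] <- cf
    }
    out
  })
  if (!length(fits)) return(list())
  # repeats that stalled in a clearly worse local minimum are not
  # independent fits of the same optimum; drop them before averaging
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  keep <- rss <= min(rss) * 1.5 + 1e-12
  lapply(fits[keep], `[[`, "coef")
}

summarize_repeats <- function(coefs) {
  m <- do.call(rbind, coefs)
  list(estimate = colMeans(m),
       repeat_sd = if (nrow(m) > 1) apply(m, 2, stats::sd) else
         stats::setNames(rep(NA_real_, ncol(m)), colnames(m)),
       n_converged = nrow(m))
}

#' Fit Gaussian or bi-Gaussian peaks to a blockade-level histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) of one or two Gaussian
#' components to the histogram counts inside a population window.
#' Following the 3-independent-fits convention, the fit is repeated
#' `repeats` times from randomized initial parameters (moment-based
#' starts perturbed by +/-20%); the reported value of each parameter is
#' the mean over converged repeats and its uncertainty the standard
#' deviation across them. A bi-Gaussian whose component means collapse
#' to within one bin is flagged and refitted as a single Gaussian.
#'
#' @param hist A [blockade_histogram()].
#' @param model `"gaussian"` or `"bigaussian"`.
#' @param window A [population_window()] bounding the fit region.
#' @param repeats Number of randomized-start fits (default 3).
#' @param seed Optional seed for the start randomization.
#' @return A `blockade_fit`: `components` data frame (`mean`, `sd`,
#'   `amplitude`, ordered by mean, with repeat-sd columns), `dominant`
#'   (row index of the largest-amplitude component), `model`, `window`,
#'   `n_converged`, `collapsed`.
#' @export
fit_blockade_peaks <- function(hist, model = c("gaussian", "bigaussian"),
                               window, repeats = 3, seed = NULL) {
  stopifnot(inherits(hist, "blockade_histogram"),
            inherits(window, "population_window"))
  model <- match.arg(model)
  sel <- hist$mids >= window$lower & hist$mids <= window$upper
  d <- data.frame(x = hist$mids[sel], y = hist$counts[sel])
  nz <- sum(d$y > 0)
  need <- if (model == "gaussian") 10L else 15L
  if (nz < need) {
    stop(sprintf("window [%g, %g] has %d nonzero bins; need >= %d for a %s fit",
                 window$lower, window$upper, nz, need, model), call. = FALSE)
  }
  w_mean <- sum(d$x * d$y) / sum(d$y)
  w_sd <- sqrt(pmax(sum(d$y * (d$x - w_mean)^2) / sum(d$y), hist$bin_width^2))
  bw <- hist$bin_width

  # per-bin Poisson shot-noise weights stabilize fits in sparse or
  # truncated windows without biasing symmetric peak positions
  w <- 1 / pmax(d$y, 1)

  if (model == "gaussian") {
    start <- list(A = max(d$y), m = w_mean, s = min(w_sd, (window$upper - window$lower) / 4))
    ww <- window$upper - window$lower
    form <- y ~ gauss_fun(x, A, m, s)
    coefs <- repeat_fit(form, d, start,
                        lower = c(A = 0, m = window$lower, s = bw / 2),
                        upper = c(A = Inf, m = window$upper, s = ww),
                        repeats, seed, weights = w)
    if (!length(coefs)) stop("no Gaussian fit converged in the window", call. = FALSE)
    sm <- summarize_repeats(coefs)
    comps <- data.frame(mean = sm$estimate[["m"]], sd = sm$estimate[["s"]],
                        amplitude = sm$estimate[["A"]],
                        mean_repeat_sd = sm$repeat_sd[["m"]],
                        sd_repeat_sd = sm$repeat_sd[["s"]],
                        amplitude_repeat_sd = sm$repeat_sd[["A"]])
    out <- list(components = comps, dominant = 1L, model = "gaussian",
                window = window, n_converged = sm$n_converged,
                collapsed = FALSE, n_events = sum(d$y))
    return(structure(out, class = "blockade_fit"))
  }

  # bi-Gaussian starts: two strongest local maxima of the lightly
  # smoothed windowed histogram at least four bins apart; otherwise a
  # moment split of the windowed mass at its weighted mean
  ys <- as.numeric(stats::filter(d$y, c(1, 2, 1) / 4, sides = 2))
  ys[is.na(ys)] <- d$y[is.na(ys)]
  pk <- which(diff(sign(diff(c(-Inf, ys, -Inf)))) < 0)
  pk <- pk[order(ys[pk], decreasing = TRUE)]
  sep <- pk[1]
  for (cand in pk[-1]) {
    if (all(abs(d$x[cand] - d$x[sep]) >= 4 * bw) &&
        ys[cand] >= 0.15 * ys[pk[1]]) {
      sep <- c(sep, cand)
      if (length(sep) == 2L) break
    }
  }
  if (length(sep) >= 2L) {
    m1 <- d$x[sep[1]]; m2 <- d$x[sep[2]]
  } else {
    lo_half <- d$x <= w_mean
    m1 <- sum(d$x[lo_half] * d$y[lo_half]) / max(sum(d$y[lo_half]), 1)
    m2 <- sum(d$x[!lo_half] * d$y[!lo_half]) / max(sum(d$y[!lo_half]), 1)
    if (!is.finite(m1) || !is.finite(m2) || m1 == m2) {
      m1 <- w_mean - w_sd; m2 <- w_mean + w_sd
    }
  }
  start <- list(A1 = max(d$y), m1 = min(m1, m2), s1 = w_sd / 2,
                A2 = max(d$y) / 2, m2 = max(m1, m2), s2 = w_sd / 2)
  form <- y ~ gauss_fun(x, A1, m1, s1) + gauss_fun(x, A2, m2, s2)
  ww <- window$upper - window$lower
  lower <- c(A1 = 0, m1 = window$lower, s1 = bw / 2,
             A2 = 0, m2 = window$lower, s2 = bw / 2)
  upper <- c(A1 = Inf, m1 = window$upper, s1 = ww,
             A2 = Inf, m2 = window$upper, s2 = ww)
  coefs <- repeat_fit(form, d, start, lower, upper, repeats, seed, weights = w)
  if (!length(coefs)) {
    # a unimodal window gives the 6-parameter model a degenerate surface;
    # treat total non-convergence as component collapse
    g <- fit_blockade_peaks(hist, "gaussian", window, repeats, seed)
    g$collapsed <- TRUE
    g$model <- "bigaussian"
    return(g)
  }
  # order each repeat's components by mean before averaging
  coefs <- lapply(coefs, function(cf) {
    if (cf[["m1"]] > cf[["m2"]]) {
      cf <- cf[c("A2", "m2", "s2", "A1", "m1", "s1")]
      names(cf) <- c("A1", "m1", "s1", "A2", "m2", "s2")
    }
    cf
  })
  sm <- summarize_repeats(coefs)
  est <- sm$estimate
  if (abs(est[["m2"]] - est[["m1"]]) < bw) {
    g <- fit_blockade_peaks(hist, "gaussian", window, repeats, seed)
    g$collapsed <- TRUE
    g$model <- "bigaussian"
    return(g)
  }
  comps <- data.frame(
    mean = c(est[["m1"]], est[["m2"]]),
    sd = c(est[["s1"]], est[["s2"]]),
    amplitude = c(est[["A1"]], est[["A2"]]),
    mean_repeat_sd = c(sm$repeat_sd[["m1"]], sm$repeat_sd[["m2"]]),
    sd_repeat_sd = c(sm$repeat_sd[["s1"]], sm$repeat_sd[["s2"]]),
    amplitude_repeat_sd = c(sm$repeat_sd[["A1"]], sm$repeat_sd[["A2"]]))
  structure(list(components = comps, dominant = which.max(comps$amplitude),
                 model = "bigaussian", window = window,
                 n_converged = sm$n_converged, collapsed = FALSE,
                 n_events = sum(d$y)),
            class = "blockade_fit")
}

#' @export
print.blockade_fit <- function(x, ...) {
  cat(sprintf("<blockade_fit> %s in window [%g, %g] (%s)\n", x$model,
              x$window$lower, x$window$upper, x$window$label))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  component %d%s: mean %.3f +/- %.3f, sd %.3f, amplitude %.1f\n",
                i, if (i == x$dominant) " (dominant)" else "",
                x$components$mean[i], x$components$mean_repeat_sd[i],
                x$components$sd[i], x$components$amplitude[i]))
  }
  if (x$collapsed) cat("  note: bi-Gaussian collapsed; refit as single Gaussian\n")
  invisible(x)
}

#' @export
coef.blockade_fit <- function(object, ...) {
  stats::setNames(object$components$mean,
                  paste0("mean", seq_len(nrow(object$components))))
}

#' Fit the dwell-time distribution of a population
#'
#' Dwell times of the events inside a blockade-level window are binned
#' logarithmically (30 bins per decade by default, the semilog-histogram
#' convention) and the per-bin density (count / bin width) is fitted
#' with a single exponential decay `A exp(-t/tau)` over bins at or above
#' `min_dwell`, so `tau` is the decay constant of the surviving tail of
#' the left-truncated distribution. Randomized-start repeats as in
#' [fit_blockade_peaks()].
#'
#' @param events A featurized `event_table` (>= 100 events in window).
#' @param window Optional [population_window()]; `NULL` uses all events.
#' @param bins_per_decade Log-histogram resolution (default 30).
#' @param min_dwell Lower fit bound, us (default 200; the upstream
#'   event filter).
#' @param repeats,seed Repeat-fit controls.
#' @return An `exp_fit` with `tau` (us), `tau_repeat_sd`, `n_events`.
#' @export
fit_dwell_time <- function(events, window = NULL, bins_per_decade = 30,
                           min_dwell = 200, repeats = 3, seed = NULL) {
  stopifnot(inherits(events, "event_table"))
  if (!is.null(window)) events <- select_population(events, window)
  t_us <- events$t_t_us
  t_us <- t_us[is.finite(t_us) & t_us > 0]
  if (length(t_us) < 100) {
    stop("need >= 100 events in the window for a dwell-time fit", call. = FALSE)
  }
  if (stats::sd(t_us) == 0) stop("degenerate dwell distribution (all equal)",
                                 call. = FALSE)
  lo <- floor(log10(min(t_us)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(t_us)) * bins_per_decade) / bins_per_decade
  breaks <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  counts <- tabulate(findInterval(t_us, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  widths <- diff(breaks)
  mids <- sqrt(breaks[-length(breaks)] * breaks[-1])  # geometric bin centers
  # keep empty bins up to the last occupied one: dropping zeros would
  # censor the tail and bias tau upward
  last_occ <- max(which(counts > 0))
  sel <- mids >= min_dwell & seq_along(mids) <= last_occ
  d <- data.frame(x = mids[sel], y = counts[sel] / widths[sel])
  if (nrow(d) < 5) stop("too few occupied dwell bins above min_dwell", call. = FALSE)
  tau0 <- max(mean(t_us) - min_dwell, mean(t_us) / 4)
  start <- list(A = max(d$y), tau = tau0)
  # Poisson counting errors: inverse-variance weights on the densities
  w_inv_var <- widths[sel]^2 / pmax(counts[sel], 1)
  coefs <- repeat_fit(y ~ A * exp(-x / tau), d, start,
                      lower = c(A = 0, tau = 1),
                      upper = c(A = Inf, tau = Inf), repeats, seed,
                      weights = w_inv_var)
  if (!length(coefs)) stop("dwell-time exponential fit did not converge", call. = FALSE)
  sm <- summarize_repeats(coefs)
  structure(list(tau = sm$estimate[["tau"]],
                 tau_repeat_sd = sm$repeat_sd[["tau"]],
                 rate = NA_real_, rate_repeat_sd = NA_real_,
                 units = "us", kind = "dwell",
                 n_events = length(t_us), n_converged = sm$n_converged),
            class = "exp_fit")
}

#' Maximum-likelihood dwell-time estimate (cross-check)
#'
#' For a left-truncated exponential the maximum-likelihood decay
#' constant is the mean excess over the truncation point. Provided as an
#' independent cross-check of [fit_dwell_time()].
#'
#' @param t_us Dwell times, us.
#' @param min_dwell Truncation point, us.
#' @return Decay constant in us.
#' @export
dwell_mle <- function(t_us, min_dwell = 200) {
  t_us <- t_us[t_us >= min_dwell]
  mean(t_us) - min_dwell
}

#' Fit the event frequency from interevent times
#'
#' Interevent times are the differences between consecutive event start
#' times. They are binned linearly (2 ms by default for the global
#' frequency; 4 ms is the per-population convention) and fitted with a
#' single exponential `A exp(-t/tau)`. The first bin is excluded from
#' the fit: it is depleted by the event dead time (no new event can
#' start while one is in progress).
#'
#' The exponential decay of the interevent distribution measures the
#' conditional capture intensity while the pore is free, which exceeds
#' the wall-clock event frequency by the factor `1/(1 - duty cycle)`.
#' With `correct_dead_time = TRUE` (default) the reported rate is
#' corrected to the wall-clock frequency,
#' `rate = decay / (1 + decay * mean_dwell)`; at the low duty cycles of
#' typical native recordings the correction is below 2%.
#'
#' @param events A time-ordered `event_table` (>= 100 interevent
#'   intervals).
#' @param bin_width_ms Interevent-time bin width, ms (default 2).
#' @param correct_dead_time Correct the fitted decay rate for the event
#'   dead time (default `TRUE`).
#' @param repeats,seed Repeat-fit controls.
#' @return An `exp_fit` with `rate` (Hz), `rate_repeat_sd`, `tau` (ms).
#' @export
event_frequency <- function(events, bin_width_ms = 2, correct_dead_time = TRUE,
                            repeats = 3, seed = NULL) {
  stopifnot(inherits(events, "event_table"))
  starts <- events$start_index
  if (is.unsorted(starts)) stop("events must be time-ordered", call. = FALSE)
  fs <- attr(events, "sampling_rate")
  iet_ms <- diff(starts) / fs * 1e3
  if (length(iet_ms) < 100) {
    stop("need >= 100 interevent intervals", call. = FALSE)
  }
  breaks <- seq(0, max(iet_ms) + bin_width_ms, by = bin_width_ms)
  counts <- tabulate(findInterval(iet_ms, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  last_occ <- max(which(counts > 0))
  sel <- seq_along(mids) > 1L & seq_along(mids) <= last_occ
  d <- data.frame(x = mids[sel], y = counts[sel])
  tau0 <- mean(iet_ms)
  start <- list(A = max(d$y), tau = tau0)
  # two-pass Poisson weighting: variance taken from the first-pass fit,
  # not the observed counts, so empty tail bins are weighted sensibly
  pass1 <- nls_try(y ~ A * exp(-x / tau), d, start,
                   lower = c(A = 0, tau = 1e-6), upper = c(A = Inf, tau = Inf))
  w <- if (is.null(pass1)) NULL else {
    cf1 <- pass1$coef
    1 / pmax(cf1[["A"]] * exp(-d$x / cf1[["tau"]]), 0.25)
  }
  coefs <- repeat_fit(y ~ A * exp(-x / tau), d, start,
                      lower = c(A = 0, tau = 1e-6),
                      upper = c(A = Inf, tau = Inf), repeats, seed,
                      weights = w)
  if (!length(coefs)) stop("interevent-time exponential fit did not converge",
                           call. = FALSE)
  sm <- summarize_repeats(coefs)
  tau_ms <- sm$estimate[["tau"]]
  tau_sd <- sm$repeat_sd[["tau"]]
  decay_hz <- 1e3 / tau_ms
  rate <- decay_hz
  if (correct_dead_time && !is.null(events$t_t_us) && nrow(events) > 0) {
    mean_dwell_s <- mean(events$t_t_us) * 1e-6
    rate <- decay_hz / (1 + decay_hz * mean_dwell_s)
  }
  structure(list(tau = tau_ms, tau_repeat_sd = tau_sd,
                 rate = rate,
                 rate_repeat_sd = if (is.na(tau_sd)) NA_real_ else 1e3 * tau_sd / tau_ms^2,
                 units = "ms", kind = "frequency",
                 n_events = length(iet_ms) + 1L, n_converged = sm$n_converged),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$kind == "dwell") {
    cat(sprintf("<exp_fit> dwell-time tau = %.1f +/- %.1f us (n = %d, %d fits)\n",
                x$tau, x$tau_repeat_sd, x$n_events, x$n_converged))
  } else {
    cat(sprintf("<exp_fit> event frequency = %.2f +/- %.2f Hz (tau = %.2f ms, n = %d)\n",
                x$rate, x$rate_repeat_sd, x$tau, x$n_events))
  }
  invisible(x)
}

#' Select events inside a blockade-level window
#'
#' @param events A featurized `event_table`.
#' @param window A [population_window()]; bounds are inclusive.
#' @return The `event_table` restricted to
#'   `lower <= norm_di_b <= upper`.
#' @export
select_population <- function(events, window) {
  stopifnot(inherits(events, "event_table"),
            inherits(window, "population_window"))
  keep <- !is.na(events$norm_di_b) &
    events$norm_di_b >= window$lower & events$norm_di_b <= window$upper
  out <- events[keep, , drop = FALSE]
  out <- new_event_table(as.data.frame(out), attr(events, "baseline"),
                         attr(events, "sampling_rate"), attr(events, "metadata"),
                         attr(events, "filter_log"))
  rownames(out) <- NULL
  out
}
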