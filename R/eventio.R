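#' Estimate the open-pore baseline of a recording
#'
#' The open-pore current I0 and its standard deviation sigma are
#' estimated robustly against event contamination by iterative
#' sigma-clipping around the dominant current mode (start at the median,
#' repeatedly keep samples within `clip` sigma of the running mean).
#' The detection threshold is `I0 - k * sigma`.
#'
#' @param trace A `nanopore_trace` with at least 1e4 samples.
#' @param k Threshold depth in units of sigma (default 7).
#' @param clip Clipping half-width in sigma for the iteration.
#' @param max_iter Maximum clipping iterations.
#' @return A `baseline_stats` list: `i0`, `sigma`, `threshold`, `k`,
#'   `fraction_retained`.
#' @export
estimate_baseline <- function(trace, k = 7, clip = 3, max_iter = 25) {
  stopifnot(inherits(trace, "nanopore_trace"))
  x <- trace$current
  if (length(x) < 1e4) {
    stop("trace too short for baseline estimation (need >= 1e4 samples)",
         call. = FALSE)
  }
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  # start the clipping at the dominant density mode, not the median:
  # with heavy event contamination the median can fall between the
  # open-pore and blocked levels
  dens <- stats::density(x, n = 512)
  center <- dens$x[which.max(dens$y)]
  spread <- stats::mad(x[abs(x - center) <= stats::mad(x)], center = center)
  if (!is.finite(spread) || spread <= 0) spread <- stats::mad(x)
  if (!is.finite(spread) || spread <= 0) spread <- stats::sd(x)
  if (!is.finite(spread) || spread <= 0) {
    stop("trace has no measurable noise (constant current); supply I0 manually",
         call. = FALSE)
  }
  keep_prev <- rep(TRUE, length(x))
  for (i in seq_len(max_iter)) {
    keep <- abs(x - center) <= clip * spread
    if (!any(keep)) break
    center <- mean(x[keep])
    spread <- stats::sd(x[keep])
    if (!is.finite(spread) || spread <= 0) {
      stop("degenerate baseline (zero variance after clipping)", call. = FALSE)
    }
    if (identical(keep, keep_prev)) break
    keep_prev <- keep
  }
  frac <- mean(keep_prev)
  if (frac < 0.55) {
    stop(sprintf(paste0("no dominant current level (only %.0f%% of samples near ",
                        "the candidate baseline); the trace looks bimodal - ",
                        "supply I0 manually"), 100 * frac), call. = FALSE)
  }
  structure(list(i0 = center, sigma = spread, threshold = center - k * spread,
                 k = k, fraction_retained = frac),
            class = "baseline_stats")
}

#' Construct baseline statistics manually
#'
#' For recordings where the automatic estimate fails (or synthetic
#' fixtures), supply the open-pore current and noise directly.
#'
#' @param i0 Open-pore current, pA.
#' @param sigma Open-pore noise sd, pA.
#' @param k Threshold multiplier (default 7).
#' @return A `baseline_stats`.
#' @export
baseline_stats <- function(i0, sigma, k = 7) {
  stopifnot_scalar_pos(i0, "i0")
  stopifnot_scalar_pos(sigma, "sigma")
  stopifnot_scalar_pos(k, "k")
  structure(list(i0 = i0, sigma = sigma, threshold = i0 - k * sigma, k = k,
                 fraction_retained = NA_real_),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> I0 = %.2f pA, sigma = %.3f pA, threshold = I0 - %g sigma = %.2f pA\n",
              x$i0, x$sigma, x$k, x$threshold))
  invisible(x)
}

new_event_table <- function(df, baseline, sampling_rate, metadata = list(),
                            filter_log = list()) {
  structure(df, baseline = baseline, sampling_rate = sampling_rate,
            metadata = metadata, filter_log = filter_log,
            class = c("event_table", "data.frame"))
}

#' Build an event table from a plain data frame
#'
#' Mostly used to assemble synthetic event tables for the fitting and
#' classification layers without going through a trace. Missing derived
#' columns (`di_b_pA`, `norm_di_b`, ...) are computed from `i0` when the
#' base current columns are present.
#'
#' @param df Data frame with at least `t_t_us` and either `norm_di_b` or
#'   `i_b_pA`.
#' @param i0 Open-pore current, pA.
#' @param sigma Baseline noise, pA (metadata only).
#' @param sampling_rate Hz.
#' @return An `event_table`.
#' @export
event_table <- function(df, i0, sigma = 2, sampling_rate = 250e3) {
  df <- as.data.frame(df)
  if (is.null(df$i_b_pA) && !is.null(df$norm_di_b)) {
    df$i_b_pA <- i0 * (1 - df$norm_di_b)
  }
  if (is.null(df$di_b_pA) && !is.null(df$i_b_pA)) df$di_b_pA <- i0 - df$i_b_pA
  if (is.null(df$norm_di_b)) df$norm_di_b <- df$di_b_pA / i0
  if (is.null(df$i_bmax_pA)) df$i_bmax_pA <- df$i_b_pA
  if (is.null(df$i_bmin_pA)) df$i_bmin_pA <- df$i_b_pA
  if (is.null(df$di_bmin_pA)) df$di_bmin_pA <- i0 - df$i_bmax_pA
  if (is.null(df$di_bmax_pA)) df$di_bmax_pA <- i0 - df$i_bmin_pA
  if (is.null(df$i_bs_pA)) df$i_bs_pA <- rep(NA_real_, nrow(df))
  if (is.null(df$start_index)) {
    df$start_index <- seq_len(nrow(df))
  }
  if (is.null(df$flags)) df$flags <- rep("", nrow(df))
  bl <- structure(list(i0 = i0, sigma = sigma, threshold = i0 - 7 * sigma,
                       k = 7, fraction_retained = NA_real_),
                  class = "baseline_stats")
  new_event_table(df, bl, sampling_rate)
}

#' Detect blockade events by baseline thresholding
#'
#' An event spans from the first sample below `I0 - k sigma` to the last
#' sample below it before the current re-crosses the threshold; events
#' separated by at least one above-threshold sample are distinct. Events
#' touching either end of the trace are discarded (their true span is
#' unknown). By default the five event parameters are extracted
#' immediately (see [extract_features()]).
#'
#' @param trace A `nanopore_trace`.
#' @param baseline A `baseline_stats`, or `NULL` to estimate it from the
#'   trace.
#' @param k Threshold multiplier (used when `baseline` is `NULL`, or to
#'   re-threshold an existing baseline).
#' @param features Extract event features right away (default `TRUE`).
#' @return An `event_table`, time-ordered and non-overlapping.
#' @export
detect_events <- function(trace, baseline = NULL, k = 7, features = TRUE) {
  stopifnot(inherits(trace, "nanopore_trace"))
  if (length(trace$current) == 0L) stop("empty trace", call. = FALSE)
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  if (is.null(baseline)) {
    baseline <- estimate_baseline(trace, k = k)
  } else if (!isTRUE(all.equal(baseline$k, k))) {
    baseline$k <- k
    baseline$threshold <- baseline$i0 - k * baseline$sigma
  }
  x <- trace$current
  below <- x < baseline$threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- r$values
  s <- starts[ev]; e <- ends[ev]
  # unknown true span if the event touches the trace edges
  keep <- s > 1L & e < length(x)
  s <- s[keep]; e <- e[keep]
  dt_us <- 1e6 / trace$sampling_rate
  df <- data.frame(start_index = s, end_index = e,
                   t_t_us = (e - s + 1L) * dt_us)
  tab <- new_event_table(df, baseline, trace$sampling_rate, trace$metadata)
  if (features && nrow(df)) tab <- extract_features(trace, tab)
  tab
}

#' Extract the five event parameters
#'
#' For each detected event the mean (`i_b`), maximum (`i_bmax`), minimum
#' (`i_bmin`) and standard deviation (`i_bs`) of the in-event current are
#' computed, and the blockade depths derived against the recording's I0:
#' `di_b = I0 - i_b`, `di_bmin = I0 - i_bmax`, `di_bmax = I0 - i_bmin`,
#' `norm_di_b = di_b / I0`. The dwell time `t_t_us` is the full
#' threshold-to-threshold span.
#'
#' The detected span starts where the filtered current crosses the
#' deep detection threshold, early on the smoothed falling edge, so the
#' raw span includes the filter's rise and fall. To keep those
#' transition samples out of the level statistics, the level estimators
#' use a settled core: the event edges are relocated to the
#' half-amplitude crossings (which sit at the true edges of a filtered
#' step) and `edge_trim` further samples - three filter time-constants
#' by default - are dropped inside each relocated edge. The trim
#' shrinks automatically for short events (their residual shallow bias
#' is documented in the methods vignette). Events shorter than 2 usable
#' samples get `i_bs = NA` and a `"short"` flag.
#'
#' The operation is idempotent: re-extracting features of an already
#' featurized table recomputes the same values.
#'
#' @param trace The `nanopore_trace` the events were detected in.
#' @param table An `event_table` from [detect_events()].
#' @param edge_trim Samples to drop at each event edge, or `NULL` for the
#'   filter-derived default.
#' @return The featurized `event_table`.
#' @export
extract_features <- function(trace, table, edge_trim = NULL) {
  stopifnot(inherits(trace, "nanopore_trace"), inherits(table, "event_table"))
  bl <- attr(table, "baseline")
  x <- trace$current
  if (is.null(edge_trim)) {
    fc <- trace$metadata$filter_cutoff
    if (is.null(fc) || is.na(fc)) {
      edge_trim <- 0L
    } else {
      sigma_t <- sqrt(log(2)) / (2 * pi * fc) * trace$sampling_rate
      edge_trim <- as.integer(ceiling(3 * sigma_t))
    }
  }
  i0 <- bl$i0
  n_ev <- nrow(table)
  i_b <- i_bmax <- i_bmin <- i_bs <- numeric(n_ev)
  flags <- character(n_ev)
  for (j in seq_len(n_ev)) {
    s <- table$start_index[j]; e <- table$end_index[j]
    seg_full <- x[s:e]
    # relocate edges to the half-amplitude crossings: for a low-pass
    # filtered step these sit at the true event boundaries
    level0 <- stats::median(seg_full)
    half_thr <- i0 - 0.5 * (i0 - level0)
    idx <- which(seg_full < half_thr)
    s2 <- min(idx); e2 <- max(idx)
    len <- e2 - s2 + 1L
    trim <- min(edge_trim, max(0L, (len - 4L) %/% 3L))
    seg <- seg_full[(s2 + trim):(e2 - trim)]
    i_b[j] <- mean(seg)
    i_bmax[j] <- max(seg)
    i_bmin[j] <- min(seg)
    if (length(seg) >= 2L) {
      i_bs[j] <- stats::sd(seg)
      flags[j] <- ""
    } else {
      i_bs[j] <- NA_real_
      flags[j] <- "short"
    }
  }
  table$i_b_pA <- i_b
  table$i_bmax_pA <- i_bmax
  table$i_bmin_pA <- i_bmin
  table$i_bs_pA <- i_bs
  table$di_b_pA <- bl$i0 - i_b
  table$di_bmin_pA <- bl$i0 - i_bmax
  table$di_bmax_pA <- bl$i0 - i_bmin
  table$norm_di_b <- table$di_b_pA / bl$i0
  table$flags <- flags
  table
}

#' Apply the standard event filters
#'
#' Removes bumping-like and unresolvable events: dwell time below
#' `min_dwell` microseconds (comparison is inclusive: an event exactly at
#' 200 us is kept), in-event noise below `min_sigma` pA, and normalized
#' blockade level below `min_norm_blockade`. Per-criterion removal
#' counts are recorded in the table's `filter_log` attribute; retained
#' events keep their time order.
#'
#' @param table A featurized `event_table`.
#' @param min_dwell Minimum dwell time, us (default 200).
#' @param min_sigma Minimum in-event standard deviation, pA (default 1).
#' @param min_norm_blockade Minimum normalized blockade level
#'   (default 0.2).
#' @return The filtered `event_table` (possibly empty).
#' @export
filter_events <- function(table, min_dwell = 200, min_sigma = 1,
                          min_norm_blockade = 0.2) {
  stopifnot(inherits(table, "event_table"))
  n_in <- nrow(table)
  if (n_in == 0L) {
    attr(table, "filter_log") <- list(n_in = 0L, removed_dwell = 0L,
                                      removed_sigma = 0L, removed_blockade = 0L,
                                      n_removed = 0L, n_retained = 0L,
                                      min_dwell = min_dwell, min_sigma = min_sigma,
                                      min_norm_blockade = min_norm_blockade)
    return(table)
  }
  fail_dwell <- table$t_t_us < min_dwell
  fail_sigma <- is.na(table$i_bs_pA) | table$i_bs_pA < min_sigma
  fail_block <- table$norm_di_b < min_norm_blockade
  keep <- !(fail_dwell | fail_sigma | fail_block)
  log <- list(n_in = n_in,
              removed_dwell = sum(fail_dwell),
              removed_sigma = sum(fail_sigma),
              removed_blockade = sum(fail_block),
              n_removed = sum(!keep),
              n_retained = sum(keep),
              min_dwell = min_dwell, min_sigma = min_sigma,
              min_norm_blockade = min_norm_blockade)
  out <- table[keep, , drop = FALSE]
  attributes_to_keep <- attributes(table)[c("baseline", "sampling_rate", "metadata")]
  out <- new_event_table(as.data.frame(out),
                         attributes_to_keep$baseline,
                         attributes_to_keep$sampling_rate,
                         attributes_to_keep$metadata,
                         filter_log = log)
  rownames(out) <- NULL
  out
}

#' @export
print.event_table <- function(x, ...) {
  bl <- attr(x, "baseline")
  cat(sprintf("<event_table> %d events", nrow(x)))
  if (!is.null(bl)) cat(sprintf(" (I0 = %.2f pA, sigma = %.3f pA)", bl$i0, bl$sigma))
  cat("\n")
  log <- attr(x, "filter_log")
  if (length(log)) {
    cat(sprintf("  filtered: %d of %d removed (dwell %d, sigma %d, blockade %d)\n",
                log$n_removed, log$n_in, log$removed_dwell, log$removed_sigma,
                log$removed_blockade))
  }
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
summary.event_table <- function(object, ...) {
  cat(sprintf("event_table with %d events\n", nrow(object)))
  if (nrow(object) && !is.null(object$norm_di_b)) {
    cat(sprintf("  norm blockade: median %.3f [%.3f, %.3f]\n",
                stats::median(object$norm_di_b),
                stats::quantile(object$norm_di_b, 0.05),
                stats::quantile(object$norm_di_b, 0.95)))
    cat(sprintf("  dwell (us):    median %.0f [%.0f, %.0f]\n",
                stats::median(object$t_t_us),
                stats::quantile(object$t_t_us, 0.05),
                stats::quantile(object$t_t_us, 0.95)))
  }
  invisible(object)
}

#' Event-table CSV round trip
#'
#' Columns: `start_index`, `t_t_us`, `i0_pA`, `i_b_pA`, `i_bmax_pA`,
#' `i_bmin_pA`, `i_bs_pA`, `di_b_pA`, `di_bmin_pA`, `di_bmax_pA`,
#' `norm_di_b`, `flags`. Integer columns round-trip bit-exactly.
#'
#' @param table A featurized `event_table`.
#' @param path CSV file path.
#' @return `write_event_table()`: `path` invisibly;
#'   `read_event_table()`: an `event_table`.
#' @export
write_event_table <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  bl <- attr(table, "baseline")
  df <- data.frame(start_index = as.integer(table$start_index),
                   t_t_us = table$t_t_us,
                   i0_pA = bl$i0,
                   i_b_pA = table$i_b_pA,
                   i_bmax_pA = table$i_bmax_pA,
                   i_bmin_pA = table$i_bmin_pA,
                   i_bs_pA = table$i_bs_pA,
                   di_b_pA = table$di_b_pA,
                   di_bmin_pA = table$di_bmin_pA,
                   di_bmax_pA = table$di_bmax_pA,
                   norm_di_b = table$norm_di_b,
                   flags = table$flags)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @param sigma Baseline sigma to record (metadata only; not stored in
#'   the CSV).
#' @param sampling_rate Hz.
#' @export
read_event_table <- function(path, sigma = NA_real_, sampling_rate = 250e3) {
  df <- utils::read.csv(path, colClasses = c(start_index = "integer"))
  if (!"i0_pA" %in% names(df)) stop("not an event-table CSV", call. = FALSE)
  i0 <- df$i0_pA[1]
  df$i0_pA <- NULL
  df$flags[is.na(df$flags)] <- ""
  event_table(df, i0 = i0, sigma = sigma, sampling_rate = sampling_rate)
}
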