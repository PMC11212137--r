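#' Write a current trace to disk
#'
#' Binary format: raw little-endian IEEE-754 float samples (pA) in
#' `path`, plus a JSON sidecar `<path>.json` holding `sampling_rate`,
#' `n_samples`, `dtype` and the trace metadata. `dtype = "float32"` is
#' the compact exchange default; use `"float64"` for lossless
#' round-trips of simulated traces.
#'
#' @param trace A `nanopore_trace`.
#' @param path Output file for the raw samples.
#' @param dtype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @seealso [read_trace()], [write_trace_csv()]
#' @export
write_trace <- function(trace, path, dtype = c("float32", "float64")) {
  stopifnot(inherits(trace, "nanopore_trace"))
  dtype <- match.arg(dtype)
  size <- if (dtype == "float32") 4L else 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$current), con, size = size, endian = "little")
  sidecar <- c(list(sampling_rate = trace$sampling_rate,
                    n_samples = length(trace$current),
                    dtype = dtype),
               trace$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a current trace written by [write_trace()]
#'
#' Validates the sample stream against the sidecar: a file shorter than
#' the declared `n_samples` is an error, never a silent truncation.
#'
#' @param path File written by [write_trace()] (sidecar `<path>.json`
#'   must be present).
#' @return A `nanopore_trace` (without ground-truth ledger).
#' @export
read_trace <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar metadata file: ", sidecar_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate) || is.null(meta$n_samples)) {
    stop("sidecar lacks sampling_rate/n_samples", call. = FALSE)
  }
  size <- if (identical(meta$dtype, "float64")) 8L else 4L
  n_declared <- as.integer(meta$n_samples)
  avail <- file.info(path)$size %/% size
  if (avail < n_declared) {
    stop(sprintf("truncated sample stream: %d samples on disk, %d declared",
                 avail, n_declared), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n_declared, size = size, endian = "little")
  structure(list(current = x,
                 sampling_rate = meta$sampling_rate,
                 metadata = meta[setdiff(names(meta),
                                         c("sampling_rate", "n_samples", "dtype"))],
                 ledger = NULL, config = NULL),
            class = "nanopore_trace")
}

#' Export / import a trace as CSV
#'
#' Two columns, `time_s` and `current_pA`. On import the sampling rate is
#' taken from the time column spacing unless given; a non-uniform time
#' grid (beyond float formatting noise) is an error.
#'
#' @param trace A `nanopore_trace`.
#' @param path CSV file path.
#' @return `write_trace_csv()`: `path` invisibly; `read_trace_csv()`: a
#'   `nanopore_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "nanopore_trace"))
  df <- data.frame(time_s = (seq_along(trace$current) - 1) / trace$sampling_rate,
                   current_pA = trace$current)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param sampling_rate Override for the sampling rate, Hz.
#' @export
read_trace_csv <- function(path, sampling_rate = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(df))) {
    stop("CSV must have columns time_s and current_pA", call. = FALSE)
  }
  if (is.null(sampling_rate)) {
    dts <- diff(df$time_s)
    if (length(dts) < 1L) stop("trace CSV has fewer than 2 samples", call. = FALSE)
    if (max(dts) - min(dts) > 1e-3 * stats::median(dts)) {
      stop("non-uniform time grid; pass `sampling_rate` explicitly", call. = FALSE)
    }
    sampling_rate <- 1 / stats::median(dts)
  }
  structure(list(current = df$current_pA, sampling_rate = sampling_rate,
                 metadata = list(), ledger = NULL, config = NULL),
            class = "nanopore_trace")
}

#' Write a simulation ground-truth ledger as CSV
#'
#' @param trace A simulated `nanopore_trace`.
#' @param path CSV path; columns `population`, `onset_index`, `dwell_us`,
#'   `true_norm_blockade`.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(trace, path) {
  stopifnot(inherits(trace, "nanopore_trace"), !is.null(trace$ledger))
  utils::write.csv(trace$ledger, path, row.names = FALSE)
  invisible(path)
}
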