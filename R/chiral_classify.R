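#' Gaussian band on the second principal component
#'
#' A per-enantiomer band `[mean - 3 sd, mean + 3 sd]` on PC2. Under the
#' Gaussian model the band retains 99.7% of that peptide's events.
#'
#' @param mean Band center (dimensionless PC2).
#' @param sd Band Gaussian standard deviation (> 0).
#' @param label Enantiomer identity, e.g. `"D"` or `"L"`.
#' @param multiplier Half-width in units of `sd` (default 3).
#' @return A `pc2_band` with `lower`/`upper` bounds (closed interval).
#' @export
#' @examples
#' pc2_band(-0.039, 0.043, "D")
pc2_band <- function(mean, sd, label, multiplier = 3) {
  stopifnot_scalar_pos(sd, "sd")
  structure(list(mean = mean, sd = sd, label = label,
                 multiplier = multiplier,
                 lower = mean - multiplier * sd,
                 upper = mean + multiplier * sd),
            class = "pc2_band")
}

#' @export
print.pc2_band <- function(x, ...) {
  cat(sprintf("<pc2_band> %s: mu = %.4f, sigma = %.4f, band [%.4f, %.4f] (mu +/- %g sigma)\n",
              x$label, x$mean, x$sd, x$lower, x$upper, x$multiplier))
  invisible(x)
}

pca_features <- c("t_t_us", "di_bmin_pA", "di_bmax_pA", "di_b_pA", "i_bs_pA")

feature_matrix <- function(events, features) {
  missing <- setdiff(features, names(events))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(as.data.frame(events)[features])
  storage.mode(m) <- "double"
  m
}

robust_mode <- function(x) {
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Fit the reference PCA model on the five event parameters
#'
#' Standardizes the five parameters (dwell time, minimum / maximum /
#' mean blockade, in-event noise) with the reference dataset's mean and
#' standard deviation, eigen-decomposes the resulting correlation
#' matrix, and keeps the two leading eigenvectors (PC1, PC2).
#'
#' Sign conventions fix the eigenvector ambiguity: PC1's largest-loading
#' entry is positive, and PC2 is oriented so the reference population's
#' main PC2 peak (density mode region) has a negative mean. By the
#' reference-matrix convention of the method, every later dataset
#' (other peptide, mixtures) is standardized and projected with this
#' model, typically the one fitted on the d-peptide data.
#'
#' @param reference A filtered, featurized `event_table` (>= 100
#'   events; in-event noise >= 1 pA and blockade >= 0.2 applied
#'   upstream).
#' @param features Feature column names (default the five parameters).
#' @return A `pca_model`: `feature_names`, `center`, `scale`,
#'   `correlation`, `eigenvalues`, `rotation` (5 x 2).
#' @export
fit_pca_model <- function(reference, features = pca_features) {
  stopifnot(inherits(reference, "event_table"))
  if (nrow(reference) < 100) {
    stop("need >= 100 reference events to fit the PCA model", call. = FALSE)
  }
  m <- feature_matrix(reference, features)
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero)) {
    stop("constant feature(s): ", paste(features[zero], collapse = ", "),
         call. = FALSE)
  }
  z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  C <- stats::cor(z)
  eig <- eigen(C, symmetric = TRUE)
  rot <- eig$vectors[, 1:2, drop = FALSE]
  dimnames(rot) <- list(features, c("PC1", "PC2"))
  # PC1 sign: dominant loading positive
  i1 <- which.max(abs(rot[, 1]))
  if (rot[i1, 1] < 0) rot[, 1] <- -rot[, 1]
  model <- structure(list(feature_names = features, center = ctr, scale = scl,
                          correlation = C, eigenvalues = eig$values,
                          rotation = rot, n_reference = nrow(reference)),
                     class = "pca_model")
  # PC2 sign: reference main-peak mean negative
  pc2 <- predict(model, reference)$PC2
  mode2 <- robust_mode(pc2)
  core <- pc2[abs(pc2 - mode2) <= 2 * stats::mad(pc2)]
  if (mean(core) > 0) model$rotation[, 2] <- -model$rotation[, 2]
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> fitted on %d reference events\n", x$n_reference))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  cat(sprintf("  variance in PC1+PC2: %.1f%%\n",
              100 * sum(x$eigenvalues[1:2]) / sum(x$eigenvalues)))
  invisible(x)
}

#' Project events into the reference PC1/PC2 plane
#'
#' Events are standardized with the *model's* reference normalization
#' (not their own statistics) and projected onto the stored
#' eigenvectors, as required for reusing the reference correlation
#' matrix across peptides and mixtures.
#'
#' @param object A `pca_model`.
#' @param newdata An `event_table` (or data frame with the feature
#'   columns).
#' @param ... Unused.
#' @return Data frame with `PC1` and `PC2`.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  m <- feature_matrix(newdata, object$feature_names)
  z <- sweep(sweep(m, 2, object$center), 2, object$scale, "/")
  s <- z %*% object$rotation
  data.frame(PC1 = s[, 1], PC2 = s[, 2])
}

#' @rdname predict.pca_model
#' @param events An `event_table`.
#' @param model A `pca_model`.
#' @return `project_events()`: a `labeled_events` data frame with
#'   `event`, `PC1`, `PC2` and an `unlabeled` label column (low-noise
#'   events flagged `"short"`/excluded upstream keep `low_sigma`).
#' @export
project_events <- function(events, model) {
  sc <- predict(model, events)
  lab <- factor(rep("unlabeled", nrow(sc)),
                levels = c("D", "L", "unlabeled", "low_sigma"))
  if (!is.null(events$i_bs_pA)) {
    lab[!is.na(events$i_bs_pA) & events$i_bs_pA < 1] <- "low_sigma"
  }
  structure(data.frame(event = seq_len(nrow(sc)), PC1 = sc$PC1, PC2 = sc$PC2,
                       label = lab, p_D = NA_real_),
            class = c("labeled_events", "data.frame"))
}

as_labeled_events <- function(x) {
  if (inherits(x, "labeled_events")) return(x)
  if (is.numeric(x)) {
    return(structure(data.frame(event = seq_along(x), PC1 = NA_real_, PC2 = x,
                                label = factor(rep("unlabeled", length(x)),
                                               levels = c("D", "L", "unlabeled",
                                                          "low_sigma")),
                                p_D = NA_real_),
                     class = c("labeled_events", "data.frame")))
  }
  stop("expected labeled_events or a numeric PC2 vector", call. = FALSE)
}

#' Fit a Gaussian band to a PC2 distribution
#'
#' Fits the dominant PC2 peak of a single-peptide dataset with a
#' Gaussian. The fit window is the density mode +/- 2 robust standard
#' deviations (MAD), which excludes the minor shoulder contributed by
#' the secondary event cluster; the histogram inside the window is
#' fitted by nonlinear least squares. A clearly bimodal distribution
#' (two comparable density peaks) is an error: fit per population
#' instead.
#'
#' @param pc2 Numeric PC2 values (>= 100) or a `labeled_events`.
#' @param label Band label, e.g. `"D"` or `"L"`.
#' @param multiplier Band half-width in sd units (default 3).
#' @return A [pc2_band()].
#' @export
fit_pc2_band <- function(pc2, label, multiplier = 3) {
  if (inherits(pc2, "labeled_events")) pc2 <- pc2$PC2
  pc2 <- pc2[is.finite(pc2)]
  if (length(pc2) < 100) stop("need >= 100 PC2 values", call. = FALSE)
  d <- stats::density(pc2, n = 512)
  pk <- which(diff(sign(diff(c(-Inf, d$y, -Inf)))) < 0)
  pk <- pk[order(d$y[pk], decreasing = TRUE)]
  rsd <- stats::mad(pc2)
  if (length(pk) >= 2L) {
    if (d$y[pk[2]] > 0.5 * d$y[pk[1]] &&
        abs(d$x[pk[2]] - d$x[pk[1]]) > rsd) {
      stop(paste0("PC2 distribution is bimodal with comparable masses; ",
                  "fit each population separately"), call. = FALSE)
    }
  }
  mode <- d$x[pk[1]]
  win <- c(mode - 2 * rsd, mode + 2 * rsd)
  xin <- pc2[pc2 >= win[1] & pc2 <= win[2]]
  nb <- max(25L, min(80L, floor(length(xin) / 20)))
  h <- graphics::hist(xin, breaks = seq(win[1], win[2], length.out = nb + 1),
                      plot = FALSE)
  dd <- data.frame(x = h$mids, y = h$counts)
  start <- list(A = max(dd$y), m = mode, s = stats::sd(xin))
  fit <- nls_try(y ~ gauss_fun(x, A, m, s), dd, start,
                 lower = c(A = 0, m = win[1], s = diff(win) / 200),
                 upper = c(A = Inf, m = win[2], s = Inf))
  cf <- if (is.null(fit)) {
    # histogram fit failed; fall back to moments of the windowed sample
    c(A = max(dd$y), m = mean(xin), s = stats::sd(xin))
  } else {
    fit$coef
  }
  pc2_band(cf[["m"]], cf[["s"]], label, multiplier)
}

#' Label events against a single enantiomer band
#'
#' Events whose PC2 lies in the closed band interval get the band's
#' label; all others stay unlabeled (`low_sigma` rows are untouched).
#'
#' @param events A `labeled_events` (or numeric PC2 vector).
#' @param band A [pc2_band()].
#' @return The relabeled `labeled_events`.
#' @export
label_single <- function(events, band) {
  events <- as_labeled_events(events)
  events$label <- factor(as.character(events$label),
                         levels = union(levels(events$label), band$label))
  eligible <- events$label != "low_sigma"
  inside <- eligible & events$PC2 >= band$lower & events$PC2 <= band$upper
  events$label[eligible] <- "unlabeled"
  events$label[inside] <- band$label
  events
}

#' Monte Carlo enantiomer classification with two PC2 bands
#'
#' Events outside both 3-sigma bands stay unlabeled; events inside
#' exactly one band take that band's label; events inside both bands
#' are assigned stochastically, drawing the label with probability
#' proportional to the two band Gaussians' densities at the event's PC2
#' (class priors equal by default, since the mixture composition is the
#' unknown being estimated). The draw probability for the first band's
#' label is stored in `p_D`.
#'
#' @param events A `labeled_events` or numeric PC2 vector.
#' @param band_D,band_L The two [pc2_band()]s (labels are taken from the
#'   bands).
#' @param seed Integer seed; fixed seed gives identical labelings.
#' @param priors Two class priors, summing to 1.
#' @return The labeled `labeled_events`.
#' @export
monte_carlo_classify <- function(events, band_D, band_L, seed = NULL,
                                 priors = c(0.5, 0.5)) {
  events <- as_labeled_events(events)
  if (band_D$sd <= 0 || band_L$sd <= 0) {
    stop("bands must have positive sd", call. = FALSE)
  }
  stopifnot(length(priors) == 2, all(priors > 0))
  priors <- priors / sum(priors)
  events$label <- factor(as.character(events$label),
                         levels = union(levels(events$label),
                                        c(band_D$label, band_L$label)))
  x <- events$PC2
  eligible <- events$label != "low_sigma"
  in_D <- x >= band_D$lower & x <= band_D$upper
  in_L <- x >= band_L$lower & x <= band_L$upper
  lab <- rep("unlabeled", length(x))
  lab[in_D & !in_L] <- band_D$label
  lab[in_L & !in_D] <- band_L$label
  both <- which(in_D & in_L & eligible)
  p_D <- rep(NA_real_, length(x))
  if (length(both)) {
    fD <- priors[1] * stats::dnorm(x[both], band_D$mean, band_D$sd)
    fL <- priors[2] * stats::dnorm(x[both], band_L$mean, band_L$sd)
    p <- fD / (fD + fL)
    draw <- with_seed(seed, stats::runif(length(both)) < p)
    lab[both] <- ifelse(draw, band_D$label, band_L$label)
    p_D[both] <- p
  }
  events$label[eligible] <- lab[eligible]
  events$p_D <- p_D
  events
}

#' Confusion matrix for enantiomer predictions
#'
#' Counts of true versus predicted labels over `{D, L, unlabeled}`.
#' Per-class success is the fraction of that class's events labeled
#' correctly; the per-class false-positive rate is the fraction of the
#' *other* class's events labeled as this class; overall success is the
#' fraction of all evaluated events labeled correctly.
#'
#' @param pred A `labeled_events` or factor/character of predictions.
#' @param truth True labels (`"D"`/`"L"`), same length.
#' @return A `confusion_matrix`: `counts`, `success` (per class),
#'   `false_positive` (per class), `overall_success`, `n`.
#' @export
evaluate_confusion <- function(pred, truth) {
  if (inherits(pred, "labeled_events")) pred <- pred$label
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` lengths differ", call. = FALSE)
  }
  classes <- c("D", "L")
  keep <- truth %in% classes
  pred <- pred[keep]; truth <- truth[keep]
  pred[!(pred %in% classes)] <- "unlabeled"
  counts <- table(true = factor(truth, classes),
                  predicted = factor(pred, c(classes, "unlabeled")))
  success <- vapply(classes, function(cl) {
    tot <- sum(counts[cl, ])
    if (tot == 0) NA_real_ else counts[cl, cl] / tot
  }, numeric(1))
  false_positive <- vapply(classes, function(cl) {
    other <- setdiff(classes, cl)
    tot <- sum(counts[other, ])
    if (tot == 0) NA_real_ else counts[other, cl] / tot
  }, numeric(1))
  overall <- sum(diag(counts[, classes])) / sum(counts)
  structure(list(counts = counts, success = success,
                 false_positive = false_positive,
                 overall_success = overall, n = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(x$counts)
  cat(sprintf("  success: D %.1f%%, L %.1f%%; overall %.1f%%\n",
              100 * x$success["D"], 100 * x$success["L"],
              100 * x$overall_success))
  cat(sprintf("  false positives: D %.1f%%, L %.1f%%\n",
              100 * x$false_positive["D"], 100 * x$false_positive["L"]))
  invisible(x)
}

#' Estimate the mixture ratio from labeled events
#'
#' Ratio of l-labeled to d-labeled events with a confidence interval
#' obtained by transforming the exact binomial interval for the
#' l-fraction among labeled events. Unlabeled events are excluded.
#'
#' @param labels A `labeled_events` or factor of labels.
#' @param conf_level Confidence level (default 0.95).
#' @return A `mixture_ratio`: `ratio` (L/D), `conf_int`, `n_L`, `n_D`,
#'   `flag` (`"no_D_events"` when the ratio is undefined).
#' @export
estimate_mixture_ratio <- function(labels, conf_level = 0.95) {
  if (inherits(labels, "labeled_events")) labels <- labels$label
  labels <- as.character(labels)
  n_L <- sum(labels == "L")
  n_D <- sum(labels == "D")
  if (n_L + n_D == 0) stop("no labeled events", call. = FALSE)
  if (n_D == 0) {
    return(structure(list(ratio = NA_real_, conf_int = c(NA_real_, NA_real_),
                          n_L = n_L, n_D = n_D, flag = "no_D_events",
                          conf_level = conf_level),
                     class = "mixture_ratio"))
  }
  ci_p <- stats::binom.test(n_L, n_L + n_D, conf.level = conf_level)$conf.int
  structure(list(ratio = n_L / n_D, conf_int = ci_p / (1 - ci_p),
                 n_L = n_L, n_D = n_D, flag = "",
                 conf_level = conf_level),
            class = "mixture_ratio")
}

#' @export
print.mixture_ratio <- function(x, ...) {
  if (nzchar(x$flag)) {
    cat(sprintf("<mixture_ratio> undefined (%s): n_L = %d, n_D = %d\n",
                x$flag, x$n_L, x$n_D))
  } else {
    cat(sprintf("<mixture_ratio> L/D = %.3f [%.3f, %.3f] (%d L, %d D; %g%% CI)\n",
                x$ratio, x$conf_int[1], x$conf_int[2], x$n_L, x$n_D,
                100 * x$conf_level))
  }
  invisible(x)
}

#' Logistic-regression baseline classifier on PC1/PC2
#'
#' The rejected baseline of the band method: a linear logistic
#' classifier on the two principal components, trained on a 20% split
#' of the combined two-peptide data and evaluated on the remainder. A
#' training split that happens to contain a single class is resampled.
#'
#' @param events A `labeled_events` (PC1/PC2 present).
#' @param truth True labels (`"D"`/`"L"`).
#' @param train_fraction Training fraction (default 0.2).
#' @param seed Integer seed for the split.
#' @return A `logistic_baseline`: `accuracy`, per-class recall,
#'   `confusion` (a `confusion_matrix`), `model` (the `glm`).
#' @export
logistic_baseline <- function(events, truth, train_fraction = 0.2, seed = NULL) {
  events <- as_labeled_events(events)
  truth <- factor(as.character(truth), c("D", "L"))
  stopifnot(nrow(events) == length(truth))
  df <- data.frame(PC1 = events$PC1, PC2 = events$PC2, y = truth)
  df <- df[stats::complete.cases(df$PC2, df$y), ]
  if (nlevels(droplevels(df$y)) < 2) stop("need both classes", call. = FALSE)
  if (all(is.na(df$PC1))) df$PC1 <- 0
  n <- nrow(df)
  with_seed(seed, {
    for (attempt in 1:100) {
      idx <- sample.int(n, max(2L, round(train_fraction * n)))
      if (length(unique(df$y[idx])) == 2L) break
    }
    # perfectly separable training data triggers harmless convergence
    # warnings; separation is an expected regime for this baseline
    fit <- suppressWarnings(
      stats::glm(y ~ PC1 + PC2, family = stats::binomial(), data = df[idx, ]))
    test <- df[-idx, ]
    p <- stats::predict(fit, newdata = test, type = "response")
    pred <- ifelse(p > 0.5, "L", "D")
    cm <- evaluate_confusion(pred, test$y)
    structure(list(accuracy = mean(pred == as.character(test$y)),
                   recall = cm$success, confusion = cm, model = fit,
                   n_train = length(idx), n_test = nrow(test)),
              class = "logistic_baseline")
  })
}

#' @export
print.logistic_baseline <- function(x, ...) {
  cat(sprintf("<logistic_baseline> test accuracy %.1f%% (train %d, test %d)\n",
              100 * x$accuracy, x$n_train, x$n_test))
  invisible(x)
}
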