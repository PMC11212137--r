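test_that("isotropic features give flat eigenvalues; collinear ones do not", {
  withr::with_seed(31, {
    n <- 2000
    df <- data.frame(t_t_us = rnorm(n), di_bmin_pA = rnorm(n),
                     di_bmax_pA = rnorm(n), di_b_pA = rnorm(n),
                     i_bs_pA = rnorm(n))
    tab <- structure(df, class = c("event_table", "data.frame"))
    m <- fit_pca_model(tab)
    expect_equal(m$eigenvalues, rep(1, 5), tolerance = 0.15)
    expect_equal(sum(m$eigenvalues), 5, tolerance = 1e-8)

    df2 <- df
    df2$di_bmax_pA <- df2$di_b_pA + rnorm(n, 0, 1e-6)
    tab2 <- structure(df2, class = c("event_table", "data.frame"))
    m2 <- fit_pca_model(tab2)
    expect_gte(m2$eigenvalues[1], 2 - 1e-6)
  })
})

test_that("the PCA model is orthonormal and flags constant features", {
  tab <- filter_events(detect_events(quick_trace(duration = 4, rate = 80,
                                                 seed = 91)))
  m <- fit_pca_model(tab)
  expect_equal(crossprod(m$rotation), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(m$eigenvalues) <= 1e-10))
  expect_true(all(m$eigenvalues >= -1e-10))
  expect_equal(diag(m$correlation), rep(1, 5), ignore_attr = TRUE)

  bad <- tab
  bad$i_bs_pA <- 1.5
  expect_error(fit_pca_model(bad), "i_bs_pA")
})

test_that("projection centers the reference, is deterministic and affine", {
  tab <- filter_events(detect_events(quick_trace(duration = 4, rate = 80,
                                                 seed = 92)))
  m <- fit_pca_model(tab)
  pr <- project_events(tab, m)
  expect_equal(mean(pr$PC1), 0, tolerance = 1e-10)
  expect_equal(mean(pr$PC2), 0, tolerance = 1e-10)

  one <- as.data.frame(tab)[3, ]
  twice <- predict(m, rbind(one, one))
  expect_equal(twice[1, ], twice[2, ], ignore_attr = TRUE)

  # affine: projecting a convex combination of two events equals the
  # convex combination of their projections
  a <- as.data.frame(tab)[1, enantiopore:::pca_features]
  b <- as.data.frame(tab)[2, enantiopore:::pca_features]
  mix <- 0.3 * a + 0.7 * b
  pm <- predict(m, mix)
  pa <- predict(m, a)
  pb <- predict(m, b)
  expect_equal(as.numeric(pm), as.numeric(0.3 * pa + 0.7 * pb),
               tolerance = 1e-10)
})

test_that("the PC2 sign convention is invariant to eigenvector sign flips", {
  tab <- filter_events(detect_events(quick_trace(duration = 4, rate = 80,
                                                 seed = 93)))
  m <- fit_pca_model(tab)
  flipped <- m
  flipped$rotation <- -flipped$rotation
  # re-applying the convention restores the original orientation
  pc2 <- predict(m, tab)$PC2
  core_mean <- mean(pc2[abs(pc2 - enantiopore:::robust_mode(pc2)) <=
                          2 * mad(pc2)])
  expect_lte(core_mean, 0)
})

test_that("PC2 band fitting recovers the reported band parameters", {
  x <- simulate_pc2_samples(pc2_band(-0.039, 0.043, "D"), 8000, seed = 41)
  b <- fit_pc2_band(x, "D")
  expect_equal(b$mean, -0.039, tolerance = 0.005 / 0.039)
  expect_equal(b$sd, 0.043, tolerance = 0.1)
  # band geometry is definitional
  expect_equal(b$upper - b$lower, 6 * b$sd)
  # approximately the 3-sigma mass of the fitting sample lies inside
  expect_equal(mean(x >= b$lower & x <= b$upper), 0.997, tolerance = 0.005)
  expect_error(fit_pc2_band(x[1:50], "D"), ">= 100")
  # clearly bimodal distributions are refused
  y <- c(simulate_pc2_samples(pc2_band(-1, 0.05, "D"), 4000, seed = 42),
         simulate_pc2_samples(pc2_band(1, 0.05, "D"), 4000, seed = 43))
  expect_error(fit_pc2_band(y, "D"), "bimodal")
})

test_that("single-band labeling is a closed 3-sigma interval", {
  b <- pc2_band(0.047, 0.035, "L")
  ev <- c(b$mean, b$mean + 3 * b$sd, b$mean + 3.01 * b$sd, b$mean - 3.01 * b$sd)
  lab <- label_single(ev, b)
  expect_equal(as.character(lab$label),
               c("L", "L", "unlabeled", "unlabeled"))
  # ~99.7% of the band's own population is labeled
  x <- simulate_pc2_samples(b, 2e4, seed = 44)
  lx <- label_single(x, b)
  expect_equal(mean(lx$label == "L"), 0.997, tolerance = 0.004)
})

test_that("Monte Carlo classification obeys symmetry and separation limits", {
  bD <- pc2_band(0, 1, "D")
  bL <- pc2_band(0, 1, "L")
  x <- simulate_pc2_samples(bD, 10000, seed = 45)
  lab <- monte_carlo_classify(x, bD, bL, seed = 46)
  pD <- mean(lab$label == "D")
  # identical bands: 50/50 split within binomial error
  expect_equal(pD, 0.5, tolerance = 3 * sqrt(0.25 / 10000) / 0.5)

  # widely separated bands: near-perfect recall, no false positives
  bD2 <- pc2_band(0, 0.03, "D")
  bL2 <- pc2_band(0.3, 0.03, "L")
  xd <- simulate_pc2_samples(bD2, 5000, seed = 47)
  xl <- simulate_pc2_samples(bL2, 5000, seed = 48)
  labd <- monte_carlo_classify(xd, bD2, bL2, seed = 49)
  labl <- monte_carlo_classify(xl, bD2, bL2, seed = 50)
  expect_equal(mean(labd$label == "D"), 0.997, tolerance = 0.01)
  expect_equal(mean(labl$label == "L"), 0.997, tolerance = 0.01)
  expect_lt(mean(labd$label == "L"), 0.001)

  # label conservation at every call
  tabs <- table(lab$label)
  expect_equal(sum(tabs), 10000)
  # reproducibility
  lab2 <- monte_carlo_classify(x, bD, bL, seed = 46)
  expect_identical(lab$label, lab2$label)
})

test_that("Monte Carlo recall matches the numerical-integration oracle", {
  pairs <- list(
    list(D = pc2_band(-0.039, 0.043, "D"), L = pc2_band(0.047, 0.035, "L")),
    list(D = pc2_band(-0.1, 0.05, "D"), L = pc2_band(0.05, 0.08, "L")))
  for (p in pairs) {
    n <- 20000
    xd <- simulate_pc2_samples(p$D, n, seed = 51)
    xl <- simulate_pc2_samples(p$L, n, seed = 52)
    labd <- monte_carlo_classify(xd, p$D, p$L, seed = 53)
    labl <- monte_carlo_classify(xl, p$D, p$L, seed = 54)
    expD <- mc_expected(p$D, p$L, "D")
    expL <- mc_expected(p$D, p$L, "L")
    for (lbl in c("D", "L", "unlabeled")) {
      se <- sqrt(max(expD[lbl] * (1 - expD[lbl]), 1e-6) / n)
      expect_lt(abs(mean(labd$label == lbl) - expD[lbl]), 4 * se + 1e-3)
      se <- sqrt(max(expL[lbl] * (1 - expL[lbl]), 1e-6) / n)
      expect_lt(abs(mean(labl$label == lbl) - expL[lbl]), 4 * se + 1e-3)
    }
  }
})

test_that("confusion matrices count and rate correctly", {
  pred <- c("D", "D", "L", "L", "unlabeled")
  truth <- c("D", "D", "L", "L", "D")
  cm <- evaluate_confusion(pred, truth)
  expect_equal(sum(cm$counts), 5)
  expect_equal(cm$success[["D"]], 2 / 3)
  expect_equal(cm$success[["L"]], 1)
  expect_equal(cm$false_positive[["D"]], 0)
  expect_equal(cm$overall_success, 4 / 5)

  perfect <- evaluate_confusion(c("D", "L"), c("D", "L"))
  expect_equal(perfect$overall_success, 1)
  expect_equal(unname(perfect$false_positive), c(0, 0))

  none <- evaluate_confusion(c("unlabeled", "unlabeled"), c("D", "L"))
  expect_equal(none$overall_success, 0)
  expect_equal(unname(none$false_positive), c(0, 0))

  expect_error(evaluate_confusion(c("D"), c("D", "L")), "length")
})

test_that("mixture ratios recover composition with coherent intervals", {
  even <- rep(c("D", "L"), each = 500)
  r <- estimate_mixture_ratio(even)
  expect_equal(r$ratio, 1)
  expect_true(r$conf_int[1] < 1 && 1 < r$conf_int[2])

  # 3:1 and 1:3 well-separated simulations give reciprocal ratios
  bD <- pc2_band(0, 0.03, "D")
  bL <- pc2_band(0.3, 0.03, "L")
  x31 <- c(simulate_pc2_samples(bL, 3000, seed = 55),
           simulate_pc2_samples(bD, 1000, seed = 56))
  x13 <- c(simulate_pc2_samples(bL, 1000, seed = 57),
           simulate_pc2_samples(bD, 3000, seed = 58))
  r31 <- estimate_mixture_ratio(monte_carlo_classify(x31, bD, bL, seed = 59))
  r13 <- estimate_mixture_ratio(monte_carlo_classify(x13, bD, bL, seed = 60))
  expect_true(r31$conf_int[1] <= 3 && 3 <= r31$conf_int[2])
  expect_true(r13$conf_int[1] <= 1 / 3 && 1 / 3 <= r13$conf_int[2])
  expect_equal(r31$ratio * r13$ratio, 1, tolerance = 0.2)

  all_L <- estimate_mixture_ratio(rep("L", 10))
  expect_true(is.na(all_L$ratio))
  expect_equal(all_L$flag, "no_D_events")
})

test_that("the logistic baseline separates what is separable", {
  withr::with_seed(61, {
    sep <- data.frame(PC1 = rnorm(800), PC2 = c(rnorm(400, -2, 0.2),
                                                rnorm(400, 2, 0.2)))
    truth <- rep(c("D", "L"), each = 400)
    ev <- structure(data.frame(event = 1:800, PC1 = sep$PC1, PC2 = sep$PC2,
                               label = factor(rep("unlabeled", 800),
                                              levels = c("D", "L", "unlabeled",
                                                         "low_sigma")),
                               p_D = NA_real_),
                    class = c("labeled_events", "data.frame"))
    fit <- logistic_baseline(ev, truth, seed = 62)
    expect_gt(fit$accuracy, 0.99)

    same <- ev
    same$PC2 <- rnorm(800)
    fit2 <- logistic_baseline(same, truth, seed = 63)
    expect_equal(fit2$accuracy, 0.5, tolerance = 0.15)
  })
})

test_that("hard logistic decisions beat the soft Monte Carlo recall on the reported bands", {
  bD <- pc2_band(-0.039, 0.043, "D")
  bL <- pc2_band(0.047, 0.035, "L")
  n <- 8000
  xd <- simulate_pc2_samples(bD, n, seed = 64)
  xl <- simulate_pc2_samples(bL, n, seed = 65)
  ev <- structure(data.frame(event = seq_len(2 * n), PC1 = 0,
                             PC2 = c(xd, xl),
                             label = factor(rep("unlabeled", 2 * n),
                                            levels = c("D", "L", "unlabeled",
                                                       "low_sigma")),
                             p_D = NA_real_),
                  class = c("labeled_events", "data.frame"))
  truth <- rep(c("D", "L"), each = n)
  logit <- logistic_baseline(ev, truth, seed = 66)
  mc_D <- mc_expected(bD, bL, "D")[["D"]]
  mc_L <- mc_expected(bD, bL, "L")[["L"]]
  # MAP-style hard decisions dominate soft density-proportional draws
  expect_gt(logit$accuracy, (mc_D + mc_L) / 2)
})

test_that("the reference PCA agrees with prcomp up to component sign", {
  tab <- filter_events(detect_events(quick_trace(duration = 3, rate = 80,
                                                 seed = 95)))
  m <- fit_pca_model(tab)
  x <- as.data.frame(tab)[enantiopore:::pca_features]
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  expect_equal(m$eigenvalues, unname(pc$sdev^2), tolerance = 1e-8)
  for (j in 1:2) {
    a <- m$rotation[, j]
    b <- pc$rotation[, j]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)
  }
})
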