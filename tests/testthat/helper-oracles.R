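# numerical-integration oracle for the density-proportional Monte Carlo
# rule: expected fraction of class `cl` draws receiving each label,
# independent of the package's sampling implementation
mc_expected <- function(band_D, band_L, cl = c("D", "L")) {
  cl <- match.arg(cl)
  f <- function(x, b) dnorm(x, b$mean, b$sd)
  inb <- function(x, b) x >= b$lower & x <= b$upper
  self <- if (cl == "D") band_D else band_L
  p_lab <- function(x, target) {
    iD <- inb(x, band_D); iL <- inb(x, band_L)
    w <- f(x, band_D) / (f(x, band_D) + f(x, band_L))
    pD <- ifelse(iD & !iL, 1, ifelse(iD & iL, w, 0))
    pL <- ifelse(iL & !iD, 1, ifelse(iD & iL, 1 - w, 0))
    if (target == "D") pD else pL
  }
  lo <- min(band_D$lower, band_L$lower) - 1
  hi <- max(band_D$upper, band_L$upper) + 1
  pD <- stats::integrate(function(x) f(x, self) * p_lab(x, "D"), lo, hi,
                         subdivisions = 500L)$value
  pL <- stats::integrate(function(x) f(x, self) * p_lab(x, "L"), lo, hi,
                         subdivisions = 500L)$value
  c(D = pD, L = pL, unlabeled = 1 - pD - pL)
}
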