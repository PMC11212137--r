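#' Event-population presets for the vasopressin enantiomer conditions
#'
#' Returns the list of [population_spec()] objects emulating one
#' experimental condition of the l-/d-vasopressin (AVP) aerolysin study
#' at 110 mV in 4 M KCl. Normalized blockade levels, dwell-time scales
#' and total event frequencies follow the per-condition values measured
#' for those recordings:
#'
#' * native l-AVP: Type I 0.72 (tau ~440 us), Type IIa 0.43 and
#'   Type IIb 0.48 (tau ~820 us), total frequency 19.1 Hz;
#' * native d-AVP: Type I 0.71 (tau ~390 us), Type IIa 0.39 and
#'   Type IIb 0.43 (tau ~1140 us), total frequency 28.1 Hz;
#' * reduced (+TCEP) l-AVP: single population 0.53, 153.3 Hz;
#' * reduced (+TCEP) d-AVP: single population 0.49, 107.2 Hz;
#' * native mixtures: the two Type IIa populations (0.43 l / 0.39 d)
#'   at their per-peptide arrival rates scaled by the mixing fractions.
#'
#' The condition rate is split 15% Type I / 85% Type II, the Type II
#' share split 70:30 between IIa and IIb (the saddle:open conformer
#' ratio reported for l-AVP by NMR). Population widths and the TCEP
#' dwell scale are package choices documented in the methods vignette.
#'
#' @param condition One of `"l_native"`, `"d_native"`, `"l_tcep"`,
#'   `"d_tcep"`, `"mix_eq_native"`, `"mix_31_native"`, `"mix_13_native"`
#'   (mixture names give the l:d concentration ratio).
#' @return List of `population_spec` objects.
#' @seealso [avp_sim_config()]
#' @export
avp_populations <- function(condition = c("l_native", "d_native", "l_tcep",
                                          "d_tcep", "mix_eq_native",
                                          "mix_31_native", "mix_13_native")) {
  condition <- match.arg(condition)
  split3 <- function(rate) c(I = 0.15, IIa = 0.85 * 0.7, IIb = 0.85 * 0.3) * rate
  mix <- function(w_l, w_d) list(
    population_spec("TypeIIa_L", 0.43, 0.015, 820, 19.1 * 0.595 * w_l),
    population_spec("TypeIIa_D", 0.39, 0.015, 1140, 28.1 * 0.595 * w_d))
  switch(condition,
    l_native = {
      r <- split3(19.1)
      list(population_spec("TypeI_L", 0.72, 0.02, 440, r[["I"]]),
           population_spec("TypeIIa_L", 0.43, 0.015, 820, r[["IIa"]]),
           population_spec("TypeIIb_L", 0.48, 0.015, 820, r[["IIb"]]))
    },
    d_native = {
      r <- split3(28.1)
      list(population_spec("TypeI_D", 0.71, 0.02, 390, r[["I"]]),
           population_spec("TypeIIa_D", 0.39, 0.015, 1140, r[["IIa"]]),
           population_spec("TypeIIb_D", 0.43, 0.015, 1140, r[["IIb"]]))
    },
    l_tcep = list(population_spec("TCEP_L", 0.53, 0.02, 900, 153.3)),
    d_tcep = list(population_spec("TCEP_D", 0.49, 0.02, 900, 107.2)),
    mix_eq_native = mix(1, 1),
    mix_31_native = mix(0.75, 0.25),
    mix_13_native = mix(0.25, 0.75))
}

#' Full simulation configuration for a named experimental condition
#'
#' Wraps [avp_populations()] with the per-condition open-pore current and
#' noise measured for those recordings (e.g. I0 = 243.82 +/- 1.77 pA for
#' native l-AVP), 250 kHz sampling and the 5 kHz low-pass.
#'
#' @inheritParams avp_populations
#' @param duration Recording length in seconds.
#' @param seed Integer seed.
#' @return A [sim_config()] object.
#' @export
#' @examples
#' cfg <- avp_sim_config("l_tcep", duration = 2, seed = 42)
avp_sim_config <- function(condition, duration, seed = 1L) {
  base <- switch(condition,
    l_native = c(243.82, 1.77),
    d_native = c(246.78, 2.04),
    l_tcep   = c(259.22, 3.33),
    d_tcep   = c(250.16, 3.46),
    c(250, 2))
  sim_config(duration = duration,
             populations = avp_populations(condition),
             i0 = base[1], baseline_noise_sd = base[2],
             seed = seed, voltage_mV = 110, condition = condition)
}

#' Default blockade-level selection windows
#'
#' The analysis windows used to select event populations by normalized
#' blockade level: Type I between 0.7 and 0.8, Type II between 0.35 and
#' 0.55, and 0.4 to 0.8 in the presence of TCEP.
#'
#' @param label `"TypeI"`, `"TypeII"` or `"TCEP"`, or `NULL` to build a
#'   custom window from `lower`/`upper`.
#' @param lower,upper Custom normalized blockade bounds in `[0, 1]`.
#' @return A `population_window` list with `lower`, `upper`, `label`.
#' @export
#' @examples
#' population_window("TypeII")
#' population_window(lower = 0.38, upper = 0.6, label = "TypeII_fig")
population_window <- function(label = NULL, lower = NULL, upper = NULL) {
  if (!is.null(label) && is.null(lower)) {
    preset <- switch(label,
      TypeI = c(0.7, 0.8),
      TypeII = c(0.35, 0.55),
      TCEP = c(0.4, 0.8),
      stop("unknown window preset: ", label, call. = FALSE))
    lower <- preset[1]; upper <- preset[2]
  }
  if (is.null(label)) label <- sprintf("%g-%g", lower, upper)
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (!(lower >= 0 && lower < upper && upper <= 1)) {
    stop("window must satisfy 0 <= lower < upper <= 1", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, label = label),
            class = "population_window")
}
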