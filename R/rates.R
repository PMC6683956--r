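#' Rate constants for the AAPH / curcumin consumption model
#'
#' Bundles the four kinetic parameters of the radical-generation and
#' scavenging network. `k_A` and `k_el` default to literature values for
#' thermal AAPH decomposition at 37 degrees C and for the elimination of the
#' short-lived alkyl/peroxyl radical pool (half-life on the order of 1 ms:
#' `log(2)/k_el` is about 1.7e-5 min). The second-order consumption
#' constants `k_C` (curcumin) and `k_CM` (curcumin monoacrylate) default to
#' zero and are normally supplied explicitly or estimated with
#' [fit_rate_constants()].
#'
#' @param k_A First-order AAPH decomposition rate, 1/min.
#' @param k_el First-order radical elimination rate, 1/min.
#' @param k_C Second-order curcumin consumption rate, 1/(uM min).
#' @param k_CM Second-order curcumin monoacrylate consumption rate,
#'   1/(uM min).
#' @return An object of class `rate_constants`: a named list of the four
#'   non-negative rates.
#' @examples
#' rate_constants(k_C = 200)
#' @export
rate_constants <- function(k_A = 1.26e-6, k_el = 4.16e4, k_C = 0, k_CM = 0) {
  k <- list(k_A = k_A, k_el = k_el, k_C = k_C, k_CM = k_CM)
  for (nm in names(k)) {
    v <- k[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("rate constant '", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  }
  structure(k, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (uM, min basis):\n")
  cat(sprintf("  k_A  = %g /min (AAPH decomposition)\n", x$k_A))
  cat(sprintf("  k_el = %g /min (radical elimination, t1/2 = %.3g min)\n",
              x$k_el, if (x$k_el > 0) log(2) / x$k_el else Inf))
  cat(sprintf("  k_C  = %g /(uM min) (curcumin)\n", x$k_C))
  cat(sprintf("  k_CM = %g /(uM min) (curcumin monoacrylate)\n", x$k_CM))
  invisible(x)
}

#' Species concentration state
#'
#' Concentrations of the four model species, all in uM: AAPH (`C_A`), the
#' pooled free-radical species (`C_R`), curcumin (`C_C`) and curcumin
#' monoacrylate (`C_CM`). Radicals start at zero in every standard scenario;
#' they only exist through generation from AAPH.
#'
#' @param C_A,C_R,C_C,C_CM Concentrations in uM, each >= 0.
#' @return A named numeric vector of class `species_state`.
#' @examples
#' species_state(C_A = aaph_mM_to_uM(10), C_C = 135.7)
#' @export
species_state <- function(C_A = 0, C_R = 0, C_C = 0, C_CM = 0) {
  s <- c(C_A = C_A, C_R = C_R, C_C = C_C, C_CM = C_CM)
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0))
    stop("all concentrations must be finite and >= 0 (uM)", call. = FALSE)
  structure(s, class = "species_state")
}

#' Unit conversions at the model boundary
#'
#' The model works in uM and minutes throughout. These helpers convert the
#' two user-facing input units: AAPH is conventionally dosed in mM, and
#' curcumin solutions are prepared gravimetrically in ug/ml (curcumin
#' MW 368.38 g/mol).
#'
#' @param mM AAPH concentration in mM.
#' @param ug_ml Curcumin mass concentration in ug/ml.
#' @param mw Molecular weight in g/mol; defaults to curcumin's 368.38.
#' @return Concentration in uM.
#' @examples
#' aaph_mM_to_uM(10)         # 10000 uM
#' curcumin_ugml_to_uM(50)   # about 135.7 uM
#' @export
aaph_mM_to_uM <- function(mM) {
  stopifnot(is.numeric(mM), all(mM >= 0))
  mM * 1000
}

#' @rdname aaph_mM_to_uM
#' @export
curcumin_ugml_to_uM <- function(ug_ml, mw = 368.38) {
  stopifnot(is.numeric(ug_ml), all(ug_ml >= 0), mw > 0)
  ug_ml / mw * 1000
}

#' Dosing scheme: boluses and zero-order release windows
#'
#' Describes how scavenger is delivered during a simulation. Boluses are
#' instantaneous additions applied as state jumps; rate segments add a
#' constant zero-order release (uM/min) to a species over a time window,
#' the idealization of controlled release from degrading microparticles.
#'
#' @param boluses `NULL` or a data.frame with columns `time` (min),
#'   `species` (`"curcumin"` or `"curcumin_monoacrylate"`) and `amount`
#'   (uM).
#' @param rate_segments `NULL` or a data.frame with columns `t_start`,
#'   `t_end` (min), `species` and `rate` (uM/min). Segments must not
#'   overlap within a species.
#' @return An object of class `dosing_scheme`.
#' @examples
#' dosing_scheme(boluses = data.frame(time = 0, species = "curcumin",
#'                                    amount = 225))
#' dosing_scheme(rate_segments = data.frame(t_start = 0, t_end = 1440,
#'                                          species = "curcumin",
#'                                          rate = 225 / 1440))
#' @export
dosing_scheme <- function(boluses = NULL, rate_segments = NULL) {
  valid_species <- c("curcumin", "curcumin_monoacrylate")
  if (!is.null(boluses)) {
    boluses <- as.data.frame(boluses)
    stopifnot(all(c("time", "species", "amount") %in% names(boluses)))
    if (any(boluses$amount < 0) || any(boluses$time < 0))
      stop("bolus times and amounts must be >= 0", call. = FALSE)
    if (!all(boluses$species %in% valid_species))
      stop("bolus species must be one of: ",
           paste(valid_species, collapse = ", "), call. = FALSE)
  }
  if (!is.null(rate_segments)) {
    rate_segments <- as.data.frame(rate_segments)
    stopifnot(all(c("t_start", "t_end", "species", "rate") %in%
                    names(rate_segments)))
    if (any(rate_segments$rate < 0))
      stop("release rates must be >= 0", call. = FALSE)
    if (any(rate_segments$t_end <= rate_segments$t_start))
      stop("each rate segment needs t_end > t_start", call. = FALSE)
    if (!all(rate_segments$species %in% valid_species))
      stop("segment species must be one of: ",
           paste(valid_species, collapse = ", "), call. = FALSE)
    for (sp in unique(rate_segments$species)) {
      seg <- rate_segments[rate_segments$species == sp, , drop = FALSE]
      seg <- seg[order(seg$t_start), , drop = FALSE]
      if (nrow(seg) > 1 &&
          any(seg$t_start[-1] < seg$t_end[-nrow(seg)] - 1e-12))
        stop("rate segments overlap for species '", sp, "'", call. = FALSE)
    }
  }
  structure(list(boluses = boluses, rate_segments = rate_segments),
            class = "dosing_scheme")
}

#' Full model configuration for a simulation
#'
#' Collects everything [simulate_kinetics()] needs: rate constants, the
#' initial state, the horizon, the dosing scheme, solver controls and the
#' integration mode. The system is very stiff in `full_stiff` mode (radical
#' elimination is ~1e10 times faster than AAPH decomposition), so the
#' default tolerances are tight and an absolute tolerance far below the
#' quasi-steady radical level (~6e-7 uM at 10 mM AAPH) is used for `C_R`.
#' `quasi_steady_radical` mode replaces the radical ODE with its algebraic
#' steady state and integrates only the slow species; it is the fast,
#' numerically clean choice inside fitting loops and for deviation analyses.
#'
#' @param rate_constants A [rate_constants()] object.
#' @param initial_state A [species_state()] object; `C_R` must be 0 in
#'   `quasi_steady_radical` mode.
#' @param horizon Simulation horizon, min (> 0).
#' @param dosing A [dosing_scheme()]; dose times must lie within the
#'   horizon.
#' @param mode `"full_stiff"` (integrate all four ODEs with an implicit
#'   stiff method) or `"quasi_steady_radical"`.
#' @param rtol Relative solver tolerance.
#' @param atol_radical Absolute tolerance for `C_R`, uM (full-stiff mode).
#' @param atol_slow Absolute tolerance for the slow species, uM.
#' @param max_step Maximum internal step, min.
#' @param generation Radical generation term: `"mass_action_aaph"` uses
#'   `2*k_A*C_A` (two radicals per decomposed AAPH molecule);
#'   `"literal_radical"` is a compatibility form `2*k_A*C_R` for
#'   sensitivity analysis only — with `C_R(0) = 0` it generates nothing.
#' @return An object of class `kinetic_config`.
#' @examples
#' cfg <- kinetic_config(
#'   rate_constants = rate_constants(k_C = 200),
#'   initial_state = species_state(C_A = aaph_mM_to_uM(10), C_C = 135.7))
#' @export
kinetic_config <- function(rate_constants = curox::rate_constants(),
                           initial_state = species_state(),
                           horizon = 1440,
                           dosing = dosing_scheme(),
                           mode = c("full_stiff", "quasi_steady_radical"),
                           rtol = 1e-8,
                           atol_radical = 1e-12,
                           atol_slow = 1e-9,
                           max_step = Inf,
                           generation = c("mass_action_aaph",
                                          "literal_radical")) {
  mode <- match.arg(mode)
  generation <- match.arg(generation)
  stopifnot(inherits(rate_constants, "rate_constants"),
            inherits(initial_state, "species_state"),
            inherits(dosing, "dosing_scheme"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be a single positive number of minutes", call. = FALSE)
  if (rtol <= 0 || atol_radical <= 0 || atol_slow <= 0 || max_step <= 0)
    stop("solver tolerances and max_step must be > 0", call. = FALSE)
  times_used <- c(dosing$boluses$time, dosing$rate_segments$t_start,
                  dosing$rate_segments$t_end)
  if (length(times_used) && any(times_used > horizon + 1e-9))
    stop("dosing times must lie within the simulation horizon", call. = FALSE)
  structure(list(rate_constants = rate_constants,
                 initial_state = initial_state,
                 horizon = horizon, dosing = dosing, mode = mode,
                 rtol = rtol, atol_radical = atol_radical,
                 atol_slow = atol_slow, max_step = max_step,
                 generation = generation),
            class = "kinetic_config")
}
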