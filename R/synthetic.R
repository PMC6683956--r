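#' Observation noise model
#'
#' Additive i.i.d. Gaussian noise on the observation scale, optionally
#' clipped at zero (absorbance and peak areas cannot go negative). The
#' default sigma of 0.02 on the normalized scale is an arbitrary but
#' visually realistic choice for triplicate UV-Vis/HPLC readouts.
#'
#' @param sigma Noise standard deviation on the observation scale (>= 0).
#' @param clip_at_zero Truncate negative draws at 0.
#' @param seed Optional RNG seed; identical seeds give identical series.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.02, clip_at_zero = TRUE, seed = NULL) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(kind = "additive_gaussian", sigma = sigma,
                 clip_at_zero = clip_at_zero, seed = seed),
            class = "noise_model")
}

#' Generate a noisy observed series from the model
#'
#' Samples the model of `config` at `sample_times` for one species,
#' normalizes to the first time point (unless `scale = "uM"`), and adds
#' noise per the noise model. This emulates periodic UV-Vis absorbance or
#' HPLC peak-area sampling of a consumption experiment — by default 13
#' samples every 2 h over 24 h.
#'
#' @param config A [kinetic_config()].
#' @param sample_times Sampling times, min; default `seq(0, 1440, 120)`.
#' @param noise A [noise_model()].
#' @param species Species to observe.
#' @param scale `"normalized"` or `"uM"`.
#' @return An [observed_series()] carrying the generating sigma.
#' @export
generate_observed_series <- function(config,
                                     sample_times = seq(0, 1440, by = 120),
                                     noise = noise_model(),
                                     species = "curcumin",
                                     scale = "normalized") {
  stopifnot(inherits(noise, "noise_model"))
  vals <- predict_observable(config, species, sample_times, scale)
  if (noise$sigma > 0) {
    if (!is.null(noise$seed)) set.seed(noise$seed)
    vals <- vals + stats::rnorm(length(vals), sd = noise$sigma)
  }
  if (noise$clip_at_zero) vals <- pmax(vals, 0)
  if (scale == "normalized") vals <- pmin(vals, 1.5)
  observed_series(sample_times, vals, species, scale, sigma = noise$sigma)
}

#' Generate paired release-product consumption series
#'
#' Emulates the fully-degraded-microparticle experiment: the supernatant
#' holds curcumin and curcumin monoacrylate from time zero (split
#' `fractions` of `total_uM`; default 60/40, reflecting the residual
#' acrylate on roughly 40% of released molecules), AAPH is added, and both
#' species are consumed through the shared radical pool. Returns one noisy
#' normalized series per species.
#'
#' @param k A [rate_constants()] object (consumption constants for both
#'   species; defaults `k_C = 75`, `k_CM = 25`).
#' @param fractions Length-2 vector `(curcumin, monoacrylate)` summing to 1.
#' @param total_uM Total scavenger at t = 0, uM; defaults to a 50 ug/ml
#'   curcumin-equivalent preparation (about 135.7 uM).
#' @param aaph_mM AAPH added, mM.
#' @param sample_times Sampling times, min.
#' @param noise A [noise_model()]; seeds are offset per species so the two
#'   series are independent but jointly reproducible.
#' @return A list of two [observed_series()]: `curcumin` and
#'   `curcumin_monoacrylate`.
#' @export
generate_release_product_series <- function(k = rate_constants(k_C = 75, k_CM = 25),
                                            fractions = c(0.6, 0.4),
                                            total_uM = curcumin_ugml_to_uM(50),
                                            aaph_mM = 10,
                                            sample_times = seq(0, 1440, by = 120),
                                            noise = noise_model()) {
  stopifnot(length(fractions) == 2, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-9)
  cfg <- kinetic_config(k,
                        species_state(C_A = aaph_mM_to_uM(aaph_mM),
                                      C_C = fractions[1] * total_uM,
                                      C_CM = fractions[2] * total_uM),
                        horizon = max(sample_times, 1),
                        mode = "quasi_steady_radical")
  noise_for <- function(offset) {
    n <- noise
    if (!is.null(n$seed)) n$seed <- n$seed + offset
    n
  }
  out <- list(
    curcumin = generate_observed_series(cfg, sample_times, noise_for(0L),
                                        "curcumin"),
    curcumin_monoacrylate = if (fractions[2] > 0)
      generate_observed_series(cfg, sample_times, noise_for(1L),
                               "curcumin_monoacrylate") else NULL)
  out[!vapply(out, is.null, logical(1))]
}

#' Write the deterministic synthetic fixture suite
#'
#' Generates the full set of CSV fixtures the estimation stage exercises:
#' free-curcumin consumption at 10 and 100 mM AAPH (`k_C = 200`) and
#' two-species release-product consumption at both AAPH levels
#' (`k_C = 75`, `k_CM = 25`), each noiseless and at sigma = 0.02, plus a
#' manifest recording every generating parameter and seed. Re-running with
#' the same base seed reproduces every file byte for byte.
#'
#' @param out_dir Output directory (created if missing).
#' @param base_seed Integer base seed; each fixture uses `base_seed + i`.
#' @return Invisibly, a data.frame manifest of the files written.
#' @export
generate_fixture_suite <- function(out_dir, base_seed = 20190213L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sample_times <- seq(0, 1440, by = 120)
  entries <- list(); idx <- 0L
  emit <- function(name, series_list, params) {
    path <- file.path(out_dir, name)
    write_timeseries_csv(series_list, path)
    data.frame(file = name, params, stringsAsFactors = FALSE)
  }
  for (aaph in c(10, 100)) {
    for (sg in c(0, 0.02)) {
      idx <- idx + 1L
      seed <- base_seed + idx
      cfg <- kinetic_config(rate_constants(k_C = 200),
                            species_state(C_A = aaph_mM_to_uM(aaph),
                                          C_C = curcumin_ugml_to_uM(50)),
                            mode = "quasi_steady_radical")
      s <- generate_observed_series(cfg, sample_times,
                                    noise_model(sigma = sg, seed = seed))
      entries[[length(entries) + 1L]] <-
        emit(sprintf("free_curcumin_%dmM_sigma%s.csv", aaph, sg), list(s),
             data.frame(kind = "free_curcumin", aaph_mM = aaph, sigma = sg,
                        seed = seed, k_C = 200, k_CM = NA, n_species = 1L))
      idx <- idx + 1L
      seed <- base_seed + idx
      rel <- generate_release_product_series(
        aaph_mM = aaph, sample_times = sample_times,
        noise = noise_model(sigma = sg, seed = seed))
      entries[[length(entries) + 1L]] <-
        emit(sprintf("release_products_%dmM_sigma%s.csv", aaph, sg), rel,
             data.frame(kind = "release_products", aaph_mM = aaph, sigma = sg,
                        seed = seed, k_C = 75, k_CM = 25, n_species = 2L))
    }
  }
  manifest <- do.call(rbind, entries)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
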