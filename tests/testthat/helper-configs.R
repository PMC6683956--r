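# Shared study-condition configurations used across test files.

default_k <- function(...) rate_constants(...)

free_curcumin_config <- function(k_C = 200, aaph_mM = 10,
                                 curcumin_uM = curcumin_ugml_to_uM(50),
                                 mode = "quasi_steady_radical") {
  kinetic_config(rate_constants(k_C = k_C),
                 species_state(C_A = aaph_mM_to_uM(aaph_mM),
                               C_C = curcumin_uM),
                 mode = mode)
}

release_products_config <- function(k_C = 75, k_CM = 25, aaph_mM = 10,
                                    total_uM = curcumin_ugml_to_uM(50),
                                    mode = "quasi_steady_radical") {
  kinetic_config(rate_constants(k_C = k_C, k_CM = k_CM),
                 species_state(C_A = aaph_mM_to_uM(aaph_mM),
                               C_C = 0.6 * total_uM, C_CM = 0.4 * total_uM),
                 mode = mode)
}

sample_grid <- seq(0, 1440, by = 120)

# Relative-difference expectation: waldo's tolerance switches to absolute
# comparison when the magnitudes are below it, which would make checks on
# uM-scale deviations (1e-7) vacuous.
expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
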