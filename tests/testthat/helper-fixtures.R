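# Shared fixtures built in code.

# band-dated records lying exactly on a VBGF (one record per age class)
exact_vbgf_records <- function(L_inf, K, ages, reps = 1L) {
  a <- rep(ages, each = reps)
  data.frame(site = "X", patch = "P1",
             length_mm = L_inf * (1 - exp(-K * a)),
             mass_g = NA_real_, band_age_years = as.integer(a))
}

# an age_structure from explicit counts on classes 0..(length(counts)-1)
structure_from_counts <- function(counts, site = "X") {
  aged <- data.frame(age_class = rep(seq_along(counts) - 1L, counts))
  build_age_structure(aged, site = site)
}

# noise-free exponential age structure (real-valued counts, bypassing the
# integer tabulation) for exactness checks
exact_exponential_structure <- function(N0, Z, max_age, site = "X") {
  structure(list(site = site, age = 0:max_age,
                 observed = N0 * exp(-Z * (0:max_age)),
                 theoretical = NULL, n = max_age + 1L),
            class = "age_structure")
}

small_config <- function(...) {
  simulation_config(n_sites = 2L, expected_n = c(150L, 150L),
                    Z = c(0.2, 0.2), max_age = 15L, seed = 7L, ...)
}
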