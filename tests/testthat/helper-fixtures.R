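# Shared fixtures: small parameter sets and hand-built cohorts.

fast_params <- function(n = 4000, seed = 1, ...) {
  sim_params(n_individuals = n, seed = seed, ...)
}

# all loadings zero: status carries no information about anything
null_params <- function(n = 4000, seed = 1, n_background = 200,
                        background_rate = 8, prevalence = 0.05) {
  pools <- stats::setNames(rep(20L, n_background / 20L),
                           as.character(seq_len(n_background / 20L)))
  sim_params(
    n_individuals = n, endo_prevalence = prevalence,
    prs_r2 = 0, shared_factor_loading = 0,
    comorbidities = default_comorbidities(prs_loading = 0, shared_loading = 0)[0, ],
    background_rate = background_rate, chapter_pool_sizes = pools,
    seed = seed
  )
}

# the documented default simulation of the index-event analysis
p1_params <- function(seed) sim_params(seed = seed)

# cohort built by hand from explicit code streams
manual_cohort <- function(codes, endo_case, prs_z = NULL, label = "M") {
  n <- length(codes)
  as_cohort(tibble::tibble(
    id = sprintf("%s%03d", label, seq_len(n)),
    endo_case = endo_case,
    age = rep(50, n),
    prs_z = prs_z %||% rep(0, n),
    codes = codes
  ), label = label)
}

# the generator's true comorbid code set (resolution 4)
true_comorbid_set <- function(params = sim_params(), label = "truth") {
  code_set(params$comorbidities$icd_code, resolution = 4L, label = label)
}

`%||%` <- rlang::`%||%`
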