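#' Specify one simulated comorbidity
#'
#' Each comorbidity has its own unit-variance liability built from the same
#' ingredients as the endometriosis liability: a pleiotropic loading
#' `prs_loading` on the genetic score and a loading `shared_loading` on the
#' latent shared factor (capturing non-genetic risk common to endometriosis
#' and its comorbidities). A participant is diagnosed when the liability
#' exceeds the standard-normal quantile set by `prevalence`, in which case
#' `icd_code` is appended to their diagnosis stream.
#'
#' @param name Snake-case label, e.g. `"uterine_fibroids"`.
#' @param icd_code 4-character ICD-10-style code attached on diagnosis.
#' @param prevalence Population prevalence in (0, 1).
#' @param prs_loading Loading of the genetic score on the liability.
#' @param shared_loading Loading of the latent shared factor.
#' @return A one-row tibble.
#' @export
comorbidity_spec <- function(name, icd_code, prevalence,
                             prs_loading = 0.1, shared_loading = 0.5) {
  if (prevalence <= 0 || prevalence >= 1) {
    rlang::abort("comorbidity prevalence must lie in (0,1)", class = "endoprs_param_error")
  }
  if (prs_loading^2 + shared_loading^2 > 1) {
    rlang::abort(
      sprintf("comorbidity '%s': prs_loading^2 + shared_loading^2 exceeds 1", name),
      class = "endoprs_param_error"
    )
  }
  tibble::tibble(
    name = name,
    icd_code = normalize_code(icd_code),
    prevalence = prevalence,
    prs_loading = prs_loading,
    shared_loading = shared_loading
  )
}

#' Default set of simulated comorbidities
#'
#' Twenty comorbid conditions: the six index comorbidities routinely studied
#' alongside endometriosis (asthma, diverticular disease, irritable bowel
#' syndrome, uterine fibroids, dysmenorrhea, heavy menstrual bleeding) at
#' field-typical prevalences, plus fourteen further conditions spread across
#' chapters at 7% prevalence. All share the default loadings
#' `prs_loading = 0.1`, `shared_loading = 0.5`.
#'
#' @param prs_loading,shared_loading Loadings applied to every comorbidity.
#' @return A tibble of [comorbidity_spec()] rows.
#' @export
default_comorbidities <- function(prs_loading = 0.1, shared_loading = 0.5) {
  index <- tibble::tribble(
    ~name,                     ~icd_code, ~prevalence,
    "asthma",                  "J459",    0.12,
    "diverticular_disease",    "K579",    0.08,
    "irritable_bowel_syndrome","K589",    0.05,
    "uterine_fibroids",        "D259",    0.10,
    "dysmenorrhea",            "N946",    0.05,
    "heavy_menstrual_bleeding","N920",    0.10
  )
  other_codes <- c(
    "I109", "E109", "F329", "G439", "M545", "L209", "H539",
    "B370", "N390", "R104", "O219", "Q509", "J069", "K219"
  )
  other <- tibble::tibble(
    name = paste0("comorbidity_", substr(other_codes, 1, 4)),
    icd_code = other_codes,
    prevalence = 0.07
  )
  dplyr::mutate(
    dplyr::bind_rows(index, other),
    prs_loading = prs_loading,
    shared_loading = shared_loading
  )
}

#' Default background-code pools per chapter
#'
#' Background (status-independent) diagnoses are drawn from per-chapter
#' pools of distinct 4-character codes. The default gives chapters 1--18
#' twenty codes each, enumerated from the start of each chapter's range so
#' they never collide with the comorbidity codes of
#' [default_comorbidities()].
#'
#' @return Named integer vector, names are chapter numbers.
#' @export
default_chapter_pools <- function() {
  stats::setNames(rep(20L, 18L), as.character(1:18))
}

#' Enumerate background codes for a chapter
#'
#' Deterministically lists the first `size` 4-character codes of an ICD-10
#' chapter (stem by stem, final digit 0-9, from the start of the chapter's
#' range). Used to build the background-diagnosis pools and synthetic code
#' catalogues of known size.
#'
#' @param chapter Chapter number in 1..22.
#' @param size Number of codes wanted.
#' @return Character vector of `size` codes.
#' @examples
#' chapter_code_pool(11, 5)
#' @export
chapter_code_pool <- function(chapter, size) {
  ranges <- icd10_chapter_ranges()
  r <- ranges[ranges$chapter == chapter, ]
  lo <- stem_ordinal(r$from); hi <- stem_ordinal(r$to)
  stems <- character()
  o <- lo
  while (o <= hi && length(stems) * 10L < size + 10L) {
    stems <- c(stems, paste0(LETTERS[o %/% 100L + 1L], sprintf("%02d", o %% 100L)))
    o <- o + 1L
  }
  codes <- as.vector(t(outer(stems, 0:9, paste0)))
  utils::head(codes, size)
}

#' Simulation parameters for a synthetic biobank cohort
#'
#' Bundles every quantity of the generative liability-threshold model. The
#' endometriosis liability of individual *i* is
#' \deqn{L_i = \sqrt{r^2}\, g_i + b\, C_i + \sqrt{1 - r^2 - b^2}\, e_i}
#' with `g`, `C`, `e` independent standard normals; a case is declared when
#' `L` exceeds the quantile implied by `endo_prevalence`. Comorbidity
#' liabilities reuse `g` and `C` with their own loadings.
#'
#' @param n_individuals Cohort size.
#' @param endo_prevalence Endometriosis prevalence in (0, 1). The default is
#'   the case fraction of a 1:17 age-matched case-control cohort
#'   (5432 / 97776).
#' @param prs_r2 Proportion of liability variance explained by the genetic
#'   score, in \[0, 1).
#' @param shared_factor_loading Loading `b` of the latent shared factor on
#'   the endometriosis liability.
#' @param comorbidities Tibble of [comorbidity_spec()] rows.
#' @param background_rate Mean number of background (status-independent)
#'   diagnosis draws per person.
#' @param chapter_pool_sizes Named integer vector, chapter -> number of
#'   distinct background codes.
#' @param age_range Two-element numeric, inclusive bounds of the uniform age
#'   distribution in years.
#' @param control_case_ratio Target controls per case for age matching.
#' @param background_shared_coupling Optional coupling of the individual
#'   background rate to the shared factor `C` (log-linear, mean-preserving);
#'   0 keeps background diagnoses independent of everything.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `endoprs_params`.
#' @export
sim_params <- function(n_individuals = 200000L,
                       endo_prevalence = 5432 / 97776,
                       prs_r2 = 0.26,
                       shared_factor_loading = 0.45,
                       comorbidities = default_comorbidities(),
                       background_rate = 5,
                       chapter_pool_sizes = default_chapter_pools(),
                       age_range = c(40, 69),
                       control_case_ratio = 17L,
                       background_shared_coupling = 0,
                       seed = 1L) {
  if (n_individuals < 1L) {
    rlang::abort("n_individuals must be positive", class = "endoprs_param_error")
  }
  if (endo_prevalence <= 0 || endo_prevalence >= 1) {
    rlang::abort("endo_prevalence must lie in (0,1)", class = "endoprs_param_error")
  }
  if (prs_r2 < 0 || prs_r2 >= 1) {
    rlang::abort("prs_r2 must lie in [0,1)", class = "endoprs_param_error")
  }
  if (prs_r2 + shared_factor_loading^2 > 1) {
    rlang::abort(
      "infeasible variance decomposition: prs_r2 + shared_factor_loading^2 exceeds 1",
      class = "endoprs_param_error"
    )
  }
  if (nrow(comorbidities)) {
    bad <- comorbidities$prevalence <= 0 | comorbidities$prevalence >= 1 |
      comorbidities$prs_loading^2 + comorbidities$shared_loading^2 > 1
    if (any(bad)) {
      rlang::abort(
        paste0("invalid comorbidity spec(s): ",
               paste(comorbidities$name[bad], collapse = ", ")),
        class = "endoprs_param_error"
      )
    }
  }
  if (background_rate < 0) {
    rlang::abort("background_rate must be nonnegative", class = "endoprs_param_error")
  }
  if (background_rate > 0 && (!length(chapter_pool_sizes) || all(chapter_pool_sizes <= 0L))) {
    rlang::abort("chapter pools must be nonempty when background_rate > 0",
                 class = "endoprs_param_error")
  }
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    rlang::abort("age_range must be [min, max]", class = "endoprs_param_error")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      endo_prevalence = endo_prevalence,
      prs_r2 = prs_r2,
      shared_factor_loading = shared_factor_loading,
      comorbidities = comorbidities,
      background_rate = background_rate,
      chapter_pool_sizes = chapter_pool_sizes,
      age_range = age_range,
      control_case_ratio = as.integer(control_case_ratio),
      background_shared_coupling = background_shared_coupling,
      seed = as.integer(seed)
    ),
    class = "endoprs_params"
  )
}
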