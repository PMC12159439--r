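#' Simulate a case-control biobank cohort under the liability-threshold model
#'
#' Draws, per individual, a standardized genetic score `g`, a latent shared
#' factor `C` and independent noise, combines them into unit-variance
#' liabilities for endometriosis and for each comorbidity, and thresholds
#' each liability at the standard-normal quantile of its prevalence.
#' Diagnosed comorbidities append their ICD-10-style code to the
#' participant's diagnosis stream; endometriosis cases carry the code
#' `N809`. On top sits a Poisson number of background diagnoses drawn
#' uniformly from per-chapter code pools, independent of status unless
#' `background_shared_coupling` ties the individual rate to `C`.
#'
#' @param params An [sim_params()] object.
#' @param g Optional pre-computed standardized genetic score vector of
#'   length `n_individuals` (e.g. from [score_genotypes()] on simulated
#'   dosages); by default the true liability-scale genetic score is drawn
#'   directly.
#' @param label Cohort label (e.g. `"A"`, `"B"`).
#' @return A tibble of class `endoprs_cohort`, one row per participant:
#'   `id`, `endo_case`, `age`, `prs_z`, a list-column `codes`, and one
#'   logical `has_<name>` column per comorbidity. The generating parameters
#'   are kept in the `params` attribute.
#' @examples
#' p <- sim_params(n_individuals = 500, seed = 7)
#' cohort <- simulate_cohort(p)
#' dplyr::count(cohort, endo_case)
#' @export
simulate_cohort <- function(params, g = NULL, label = "A") {
  stopifnot(inherits(params, "endoprs_params"))
  n <- params$n_individuals
  set.seed(params$seed)

  if (is.null(g)) {
    g <- stats::rnorm(n)
  } else if (length(g) != n) {
    rlang::abort("g must have length n_individuals", class = "endoprs_param_error")
  }
  C <- stats::rnorm(n)
  resid_sd <- sqrt(1 - params$prs_r2 - params$shared_factor_loading^2)
  liab <- sqrt(params$prs_r2) * g + params$shared_factor_loading * C +
    resid_sd * stats::rnorm(n)
  endo_case <- liab > stats::qnorm(1 - params$endo_prevalence)

  if (all(endo_case) || !any(endo_case)) {
    arm <- if (all(endo_case)) "control" else "case"
    rlang::abort(
      sprintf("degenerate cohort: zero participants in the %s arm", arm),
      class = "endoprs_degenerate_cohort"
    )
  }

  specs <- params$comorbidities
  flags <- matrix(FALSE, nrow = n, ncol = nrow(specs))
  for (j in seq_len(nrow(specs))) {
    res_j <- sqrt(1 - specs$prs_loading[j]^2 - specs$shared_loading[j]^2)
    liab_j <- specs$prs_loading[j] * g + specs$shared_loading[j] * C +
      res_j * stats::rnorm(n)
    flags[, j] <- liab_j > stats::qnorm(1 - specs$prevalence[j])
  }

  age <- sample(seq(params$age_range[1], params$age_range[2]), n, replace = TRUE)

  # background diagnoses: Poisson counts, codes uniform over the pooled chapters
  pool <- unlist(lapply(names(params$chapter_pool_sizes), function(ch) {
    size <- params$chapter_pool_sizes[[ch]]
    if (size > 0L) chapter_code_pool(as.integer(ch), size) else character()
  }), use.names = FALSE)
  coupling <- params$background_shared_coupling
  rate <- params$background_rate * exp(coupling * C - coupling^2 / 2)
  n_bg <- if (params$background_rate > 0) stats::rpois(n, rate) else integer(n)
  bg_codes <- if (sum(n_bg) > 0L) sample(pool, sum(n_bg), replace = TRUE) else character()

  # assemble per-participant streams from one long (participant, code) table
  comorb_codes <- specs$icd_code
  hit <- which(flags, arr.ind = TRUE)
  long_idx <- c(if (nrow(specs)) hit[, 1L], which(endo_case), rep.int(seq_len(n), n_bg))
  long_code <- c(if (nrow(specs)) comorb_codes[hit[, 2L]],
                 rep("N809", sum(endo_case)), bg_codes)
  codes <- lapply(split(long_code, factor(long_idx, levels = seq_len(n))), unique)
  names(codes) <- NULL

  out <- tibble::tibble(
    id = sprintf("%s%06d", label, seq_len(n)),
    endo_case = endo_case,
    age = as.numeric(age),
    prs_z = as.vector(scale(g)),
    codes = codes
  )
  for (j in seq_len(nrow(specs))) {
    out[[paste0("has_", specs$name[j])]] <- flags[, j]
  }
  new_cohort(out, label = label, params = params)
}

new_cohort <- function(data, label, params = NULL) {
  structure(data, label = label, params = params,
            class = unique(c("endoprs_cohort", class(data))))
}

#' Assemble a cohort from a participant table
#'
#' Turns a data frame with at least `id`, `endo_case`, `age` and a `codes`
#' list-column (plus optional `prs_z` and `has_*` flags) into an
#' `endoprs_cohort`, validating id uniqueness.
#'
#' @param data Participant data frame.
#' @param label Cohort label.
#' @return An `endoprs_cohort` tibble.
#' @export
as_cohort <- function(data, label = "") {
  need <- c("id", "endo_case", "age", "codes")
  miss <- setdiff(need, colnames(data))
  if (length(miss)) {
    rlang::abort(paste0("cohort table missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "endoprs_schema_error")
  }
  if (anyDuplicated(data$id)) {
    rlang::abort("duplicate participant ids", class = "endoprs_schema_error")
  }
  new_cohort(tibble::as_tibble(data), label = label)
}

#' Cohort label
#' @param cohort An `endoprs_cohort`.
#' @return Its label string (empty if the attribute was lost).
#' @export
cohort_label <- function(cohort) {
  lab <- attr(cohort, "label", exact = TRUE)
  if (is.null(lab)) "" else lab
}

#' Simulate genotype dosages and a score weight table
#'
#' Provides file-based inputs for [score_genotypes()]: per-SNP effect-allele
#' frequencies uniform on (0.05, 0.5), dosages binomial(2, freq), and
#' standard-normal weights. The standardized weighted dosage sum is returned
#' as `g` so it can be passed to [simulate_cohort()] as the liability-scale
#' genetic score, making the simulated phenotypes consistent with the
#' genotype files.
#'
#' @param params An [sim_params()] object (supplies `n_individuals`, `seed`).
#' @param n_snps Number of SNPs (at least 1).
#' @return A list with `dosages` (tibble: `id` + one column per SNP),
#'   `weights` (tibble: `snp_id`, `effect_allele`, `weight`, `freq`) and
#'   `g` (standardized score vector).
#' @export
simulate_genotypes <- function(params, n_snps) {
  stopifnot(inherits(params, "endoprs_params"))
  if (n_snps < 1L) {
    rlang::abort("n_snps must be at least 1", class = "endoprs_param_error")
  }
  set.seed(params$seed + 1000003L)
  n <- params$n_individuals
  freq <- stats::runif(n_snps, 0.05, 0.5)
  dose <- vapply(freq, function(f) stats::rbinom(n, 2L, f), numeric(n))
  if (n == 1L) dose <- matrix(dose, nrow = 1L)
  weight <- stats::rnorm(n_snps)
  snp_id <- sprintf("rs%06d", seq_len(n_snps))
  colnames(dose) <- snp_id
  raw <- as.vector(dose %*% weight)
  g <- if (stats::sd(raw) > 0) as.vector(scale(raw)) else raw
  list(
    dosages = dplyr::bind_cols(
      tibble::tibble(id = sprintf("G%06d", seq_len(n))),
      tibble::as_tibble(dose)
    ),
    weights = tibble::tibble(
      snp_id = snp_id,
      effect_allele = sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
      weight = weight,
      freq = freq
    ),
    g = g
  )
}

#' Age-match controls to cases
#'
#' Greedy 1:`ratio` matching without replacement: cases are processed in id
#' order and each receives up to `ratio` controls whose age differs by at
#' most `tolerance_years`, nearest ages first.
#'
#' @param cases Tibble of case participants.
#' @param pool Tibble of candidate controls (must contain no cases).
#' @param ratio Target controls per case.
#' @param tolerance_years Maximum absolute age difference.
#' @return An `endoprs_cohort` tibble of the cases plus matched controls,
#'   with a `match_counts` attribute (tibble: `case_id`, `n_matched`).
#' @export
age_match_controls <- function(cases, pool, ratio, tolerance_years = 0) {
  if (any(pool$endo_case)) {
    rlang::abort("matching pool must contain only non-cases", class = "endoprs_param_error")
  }
  if (nrow(cases) == 0L) {
    rlang::abort("no cases to match", class = "endoprs_degenerate_cohort")
  }
  pool_age <- pool$age
  available <- rep(TRUE, nrow(pool))
  picked <- integer()
  n_matched <- integer(nrow(cases))
  unmatched <- character()
  for (i in order(cases$id)) {
    d <- abs(pool_age - cases$age[i])
    elig <- which(available & d <= tolerance_years)
    if (length(elig) == 0L) {
      unmatched <- c(unmatched, cases$id[i])
      next
    }
    take <- elig[order(d[elig])][seq_len(min(ratio, length(elig)))]
    available[take] <- FALSE
    picked <- c(picked, take)
    n_matched[i] <- length(take)
  }
  if (length(unmatched)) {
    rlang::abort(
      paste0("no eligible controls for case(s): ", paste(unmatched, collapse = ", ")),
      class = "endoprs_matching_error",
      unmatched = unmatched
    )
  }
  out <- dplyr::bind_rows(cases, pool[sort(picked), , drop = FALSE])
  lab <- attr(cases, "label", exact = TRUE)
  res <- new_cohort(out, label = if (is.null(lab)) "" else lab,
                    params = attr(cases, "params", exact = TRUE))
  attr(res, "match_counts") <- tibble::tibble(case_id = cases$id, n_matched = n_matched)
  res
}

assert_cohort_nondegenerate <- function(cohort) {
  if (!any(cohort$endo_case)) {
    rlang::abort("degenerate cohort: zero participants in the case arm",
                 class = "endoprs_degenerate_cohort")
  }
  if (all(cohort$endo_case)) {
    rlang::abort("degenerate cohort: zero participants in the control arm",
                 class = "endoprs_degenerate_cohort")
  }
  invisible(cohort)
}
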