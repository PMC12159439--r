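#' Association test for one 2x2 case-control table
#'
#' Tests a single diagnosis code against case status. Following common
#' epidemiological practice, Fisher's exact test (two-sided,
#' point-probability method) is used whenever any expected cell count is
#' below 5, and the Pearson chi-squared test without continuity correction
#' otherwise. The odds ratio is the cross-product `ad/bc`, reported as
#' `Inf`/`0` sentinels when a zero cell makes it degenerate (optionally the
#' Haldane-Anscombe +0.5 correction can be requested).
#'
#' @param case_with,case_without,control_with,control_without Cell counts.
#' @param haldane Add 0.5 to every cell for the odds ratio when any cell is
#'   zero (the p-value is unaffected).
#' @return One-row tibble: `p_value`, `odds_ratio`, `method`.
#' @examples
#' test_code_association(10, 20, 5, 40)
#' @export
test_code_association <- function(case_with, case_without,
                                  control_with, control_without,
                                  haldane = FALSE) {
  cells <- c(case_with, case_without, control_with, control_without)
  if (any(cells < 0)) {
    rlang::abort("cell counts must be nonnegative", class = "endoprs_param_error")
  }
  if (case_with + case_without == 0 || control_with + control_without == 0) {
    rlang::abort("degenerate table: an empty case or control margin",
                 class = "endoprs_degenerate_table")
  }
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    p <- stats::fisher.test(m)$p.value
    method <- "fisher"
  } else {
    p <- stats::chisq.test(m, correct = FALSE)$p.value
    method <- "chi_squared"
  }
  p <- min(max(p, 0), 1)   # guard against floating-point excursions past 1
  or <- if (haldane && any(cells == 0)) {
    ((case_with + 0.5) * (control_without + 0.5)) /
      ((case_without + 0.5) * (control_with + 0.5))
  } else if (case_without * control_with == 0) {
    if (case_with * control_without == 0) NaN else Inf
  } else {
    (case_with * control_without) / (case_without * control_with)
  }
  tibble::tibble(p_value = p, odds_ratio = or, method = method)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `q`: with ordered p-values `p_(1) <= ... <=
#' p_(m)`, every test up to the largest `i` with `p_(i) <= i q / m` is
#' declared significant. Flags are derived from the standard BH-adjusted
#' p-values, to which they are equivalent.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return Tibble: `p_value`, `p_adjusted`, `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) {
    return(tibble::tibble(p_value = numeric(), p_adjusted = numeric(),
                          significant = logical()))
  }
  if (any(p_values < 0 | p_values > 1)) {
    rlang::abort("p-values must lie in [0,1]", class = "endoprs_param_error")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, p_adjusted = adj, significant = adj <= q)
}

#' Phenome-wide comorbidity scan
#'
#' Tests every distinct 4-character diagnosis code carried by at least one
#' participant for association with endometriosis status. Per-person code
#' presence is binary (a code counts once however often it was recorded),
#' 5-character codes are first simplified to 4 characters, and BH-FDR is
#' applied across all tested codes.
#'
#' @param cohort An `endoprs_cohort` tibble with cases and controls.
#' @param q FDR level.
#' @param haldane Passed to [test_code_association()].
#' @return A tibble of class `endoprs_scan`: one row per code with the 2x2
#'   counts, `odds_ratio`, `p_value`, `method`, `p_adjusted`,
#'   `fdr_significant`, `direction` and `chapter`. Attributes: `label`
#'   (cohort label), `q`, `n_case`, `n_control`.
#' @export
phenome_scan <- function(cohort, q = 0.05, haldane = FALSE) {
  assert_cohort_nondegenerate(cohort)
  long <- cohort_diagnoses(cohort)
  long$code <- reduce_resolution(long$code, 4L)
  # per-person presence is binary: dedupe (participant, code) pairs
  id_int <- match(long$id, cohort$id)
  u <- unique(long$code)
  cidx <- match(long$code, u)
  keep <- !duplicated((id_int - 1) * (length(u) + 1) + cidx)
  case <- cohort$endo_case[id_int][keep]
  cidx <- cidx[keep]
  n_case <- sum(cohort$endo_case)
  n_control <- sum(!cohort$endo_case)
  counts <- tibble::tibble(
    code = u,
    case_with = tabulate(cidx[case], length(u)),
    control_with = tabulate(cidx[!case], length(u))
  )
  counts <- dplyr::mutate(
    counts,
    case_without = n_case - .data$case_with,
    control_without = n_control - .data$control_with
  )
  tests <- purrr::pmap_dfr(
    counts[, c("case_with", "case_without", "control_with", "control_without")],
    test_code_association, haldane = haldane
  )
  res <- dplyr::bind_cols(counts, tests)
  fdr <- bh_fdr(res$p_value, q)
  res$p_adjusted <- fdr$p_adjusted
  res$fdr_significant <- fdr$significant
  res$direction <- dplyr::case_when(
    is.nan(res$odds_ratio) | res$odds_ratio == 1 ~ NA_character_,
    res$odds_ratio > 1 ~ "increased",
    TRUE ~ "decreased"
  )
  res$fdr_significant <- res$fdr_significant & !is.na(res$direction)
  res$chapter <- chapter_of(res$code)
  res <- dplyr::arrange(res, .data$p_value)
  structure(res, label = cohort_label(cohort), q = q,
            n_case = n_case, n_control = n_control,
            class = unique(c("endoprs_scan", class(res))))
}

#' Build the comorbid code set from a scan
#'
#' Retains FDR-significant codes with increased risk in cases, then applies
#' the exclusion rules (external-factor chapters and endometriosis
#' subcodes). Codes significantly *less* frequent in cases — mostly
#' pregnancy-related — are dropped by the direction filter.
#'
#' @param scan An `endoprs_scan` result.
#' @param rules An [exclusion_rules()] object.
#' @return A [code_set()] at resolution 4 labelled with the scanned
#'   cohort's label.
#' @export
build_comorbid_set <- function(scan, rules = exclusion_rules()) {
  keep <- scan$fdr_significant & !is.na(scan$direction) &
    scan$direction == "increased"
  codes <- apply_exclusions(scan$code[keep], rules)
  code_set(codes, resolution = 4L, label = attr(scan, "label", exact = TRUE) %||% "")
}
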