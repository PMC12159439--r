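#' Score genotype dosages against a weight table
#'
#' Computes, per individual, the average-per-allele polygenic score
#' `sum_m(weight_m * dosage_im) / (2 * M_i)` where `M_i` is the number of
#' non-missing SNPs for that individual — the plink `--score` averaging
#' convention. Missing dosages are imputed to `2 * freq` when the weight
#' table carries effect-allele frequencies; otherwise the SNP is dropped
#' for that individual and the divisor adjusted.
#'
#' @param dosages Tibble/data frame: `id` column plus one numeric column per
#'   SNP with values in \[0, 2\].
#' @param weights Tibble: `snp_id`, `effect_allele`, `weight`, optionally
#'   `freq`.
#' @return Tibble of class `endoprs_scores`: `id`, `score`. The
#'   `standardized` attribute is `FALSE`.
#' @export
score_genotypes <- function(dosages, weights) {
  missing_snps <- setdiff(weights$snp_id, colnames(dosages))
  if (length(missing_snps)) {
    rlang::abort(
      paste0("SNP(s) absent from the dosage matrix: ",
             paste(missing_snps, collapse = ", ")),
      class = "endoprs_scoring_error", snps = missing_snps
    )
  }
  d <- as.matrix(dosages[, weights$snp_id, drop = FALSE])
  w <- weights$weight
  if (anyNA(d)) {
    if ("freq" %in% colnames(weights)) {
      imp <- matrix(rep(2 * weights$freq, each = nrow(d)), nrow = nrow(d))
      d[is.na(d)] <- imp[is.na(d)]
      raw <- as.vector(d %*% w) / (2 * length(w))
    } else {
      obs <- !is.na(d)
      d0 <- d; d0[!obs] <- 0
      raw <- as.vector(d0 %*% w) / (2 * rowSums(obs))
    }
  } else {
    raw <- as.vector(d %*% w) / (2 * length(w))
  }
  structure(tibble::tibble(id = dosages$id, score = raw),
            standardized = FALSE,
            class = c("endoprs_scores", class(tibble::tibble())))
}

#' Standardize scores to z-scores
#'
#' Centers and scales over the full analysis cohort (cases and controls
#' together), using the n-1 standard deviation.
#'
#' @param scores An `endoprs_scores` tibble or any tibble with `id` and
#'   `score` columns.
#' @return Tibble: `id`, `prs_z`, with `standardized = TRUE` attribute.
#' @export
standardize_scores <- function(scores) {
  x <- scores$score
  if (length(unique(x)) < 2L || stats::sd(x) == 0) {
    rlang::abort("cannot standardize scores with zero variance",
                 class = "endoprs_param_error")
  }
  structure(tibble::tibble(id = scores$id, prs_z = as.vector(scale(x))),
            standardized = TRUE,
            class = c("endoprs_scores", class(tibble::tibble())))
}

#' Assign individuals to score quantile bins
#'
#' Rank-based stratification into `k` equal-size bins (deciles `k = 10`,
#' centiles `k = 100`): bin `b` receives the individuals with rank in
#' `((b-1) n / k, b n / k]`. Ties are broken by stable id order; if every
#' score is identical the assignment is still produced (with a warning)
#' purely by that order.
#'
#' @param data Data frame with an id column and a score column.
#' @param k Number of bins.
#' @param score_col,id_col Column names (strings).
#' @return Tibble: `id`, `score`, `quantile_bin`, with a `bin_edges`
#'   attribute (maximum score per bin).
#' @export
assign_quantiles <- function(data, k = 10L, score_col = "prs_z", id_col = "id") {
  n <- nrow(data)
  if (n < k) {
    rlang::abort("need at least k individuals", class = "endoprs_param_error")
  }
  s <- data[[score_col]]
  if (length(unique(s)) == 1L) {
    rlang::warn("all scores identical; quantile bins assigned by id order alone")
  }
  ord <- order(s, data[[id_col]], method = "radix")
  rank <- integer(n); rank[ord] <- seq_len(n)
  bin <- ceiling(rank * k / n)
  out <- tibble::tibble(
    id = data[[id_col]],
    score = s,
    quantile_bin = as.integer(bin)
  )
  edges <- vapply(split(s, bin), max, numeric(1))
  structure(out, k = as.integer(k), bin_edges = edges,
            class = c("endoprs_quantiles", class(out)))
}

#' Per-quantile odds ratios against a reference bin
#'
#' For every score bin, forms the 2x2 table of case/control counts against
#' the reference bin (the 50th centile / middle bin by default) and reports
#' the odds ratio with a Woolf (log-normal) 95% confidence interval, plus
#' the mean score per bin for plotting. The reference bin's odds ratio is
#' exactly 1 with a degenerate CI.
#'
#' @param assignment An [assign_quantiles()] result.
#' @param status Logical vector of case status aligned with `assignment`
#'   rows, or a data frame with `id` and `endo_case` to join on.
#' @param reference Reference bin; defaults to `ceiling(k / 2)`.
#' @return Tibble of class `endoprs_or_table`: `quantile_bin`, `mean_score`,
#'   `n_case`, `n_control`, `odds_ratio`, `ci_low`, `ci_high`, `reference`.
#' @export
or_by_quantile <- function(assignment, status, reference = NULL) {
  k <- attr(assignment, "k", exact = TRUE)
  if (is.data.frame(status)) {
    status <- unname(stats::setNames(status$endo_case, status$id)[assignment$id])
  }
  if (is.null(reference)) reference <- as.integer(ceiling(k / 2))
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = assignment$quantile_bin,
                                   score = assignment$score,
                                   case = status), .data$bin),
    mean_score = mean(.data$score),
    n_case = sum(.data$case),
    n_control = sum(!.data$case),
    .groups = "drop"
  )
  ref <- tab[tab$bin == reference, ]
  if (nrow(ref) == 0L || ref$n_case == 0 || ref$n_control == 0) {
    rlang::abort("reference bin lacks cases or controls",
                 class = "endoprs_degenerate_table")
  }
  out <- dplyr::mutate(
    tab,
    odds_ratio = (.data$n_case * ref$n_control) / (.data$n_control * ref$n_case),
    se_log = sqrt(1 / .data$n_case + 1 / .data$n_control +
                    1 / ref$n_case + 1 / ref$n_control),
    ci_low = exp(log(.data$odds_ratio) - 1.96 * .data$se_log),
    ci_high = exp(log(.data$odds_ratio) + 1.96 * .data$se_log),
    reference = .data$bin == reference
  )
  out$odds_ratio[out$reference] <- 1
  out$ci_low[out$reference] <- 1
  out$ci_high[out$reference] <- 1
  out <- dplyr::rename(out, quantile_bin = "bin")
  structure(dplyr::select(out, -"se_log"),
            k = k, reference_bin = reference,
            class = c("endoprs_or_table", class(out)))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random case scores
#' above a random control, ties counted one half.
#'
#' @param scores Numeric vector of scores.
#' @param status Logical vector, `TRUE` for cases.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(1, 3, 0, 2), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_auc <- function(scores, status) {
  status <- as.logical(status)
  n1 <- sum(status); n0 <- sum(!status)
  if (n1 == 0L || n0 == 0L) {
    rlang::abort("both classes must be present", class = "endoprs_degenerate_table")
  }
  r <- rank(scores)
  (sum(r[status]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Endometriosis prevalence by diagnosis burden
#'
#' Groups participants by their unique diagnosis count and reports the
#' prevalence of endometriosis within each group, with exact binomial 95%
#' confidence intervals. Counts above `cap` are pooled into a top bin.
#'
#' @param cohort An `endoprs_cohort` tibble.
#' @param profiles [count_burden()] output covering the cohort.
#' @param metric `"total"` or `"comorbid"` diagnosis count.
#' @param resolution 3 or 4.
#' @param cap Optional top-binning threshold for the count.
#' @return Tibble: `burden`, `n`, `n_case`, `prevalence`, `ci_low`,
#'   `ci_high`; empty groups are absent.
#' @export
prevalence_by_burden <- function(cohort, profiles, metric = c("total", "comorbid"),
                                 resolution = 3L, cap = NULL) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_", resolution, "char")
  dat <- dplyr::left_join(
    dplyr::select(cohort, "id", "endo_case"),
    dplyr::select(profiles, "id", burden = dplyr::all_of(col)),
    by = "id"
  )
  if (!is.null(cap)) dat$burden <- pmin(dat$burden, cap)
  out <- dplyr::summarise(
    dplyr::group_by(dat, .data$burden),
    n = dplyr::n(),
    n_case = sum(.data$endo_case),
    .groups = "drop"
  )
  ci <- purrr::map2_dfr(out$n_case, out$n, function(x, n) {
    b <- stats::binom.test(x, n)$conf.int
    tibble::tibble(ci_low = b[1], ci_high = b[2])
  })
  dplyr::arrange(
    dplyr::bind_cols(dplyr::mutate(out, prevalence = .data$n_case / .data$n), ci),
    .data$burden
  )
}
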