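#' Ordinary least squares with classical standard errors
#'
#' Thin wrapper around [stats::lm()] on an explicit named design matrix,
#' returning a broom-style fit object. Standard errors are the classical
#' homoskedastic ones; two-sided p-values come from the t distribution with
#' `n - p` degrees of freedom. Heteroskedasticity-robust (HC) standard
#' errors are available behind `robust = TRUE`.
#'
#' @param response Numeric response vector.
#' @param design Numeric matrix or data frame with named columns, including
#'   an intercept column if one is wanted.
#' @param robust Use HC1 sandwich standard errors instead of classical.
#' @return An object of class `endoprs_lm`; see [tidy.endoprs_lm()].
#' @export
fit_ols <- function(response, design, robust = FALSE) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rlang::abort(
      paste0("rank-deficient design; collinear column(s): ",
             paste(dropped, collapse = ", ")),
      class = "endoprs_rank_error", columns = dropped
    )
  }
  fit <- stats::lm(response ~ X - 1)
  est <- unname(stats::coef(fit))
  n <- length(response); p <- ncol(X)
  if (robust) {
    # HC1 sandwich: (X'X)^-1 X' diag(e^2) X (X'X)^-1 * n/(n-p)
    e <- stats::residuals(fit)
    bread <- chol2inv(qr.R(qrX))
    meat <- crossprod(X * e)
    vc <- bread %*% meat %*% bread * n / (n - p)
    se <- sqrt(diag(vc))
  } else {
    se <- sqrt(diag(stats::vcov(fit)))
  }
  tval <- est / se
  out <- tibble::tibble(
    term = colnames(X),
    estimate = est,
    std_error = unname(se),
    statistic = unname(tval),
    p_value = 2 * stats::pt(abs(unname(tval)), df = n - p, lower.tail = FALSE)
  )
  structure(
    list(coefficients = out, n = n,
         sigma2 = sum(stats::residuals(fit)^2) / (n - p),
         df_residual = n - p, robust = robust),
    class = "endoprs_lm"
  )
}

#' Logistic regression by maximum likelihood
#'
#' Wrapper around [stats::glm()] (binomial, IRLS) on an explicit named
#' design matrix. Standard errors come from the inverse observed
#' information. Complete or quasi-complete separation is detected (fitted
#' probabilities numerically 0/1 or non-convergence) and reported as a
#' non-converged fit with coefficients withheld rather than returning
#' meaningless numbers.
#'
#' @param outcome Logical/0-1 response with both classes present.
#' @param design Numeric matrix or data frame with named columns.
#' @return An object of class `endoprs_logit`; see [tidy.endoprs_logit()].
#' @export
fit_logistic <- function(outcome, design) {
  outcome <- as.numeric(outcome)
  if (length(unique(outcome)) < 2L) {
    rlang::abort("both outcome classes must be present",
                 class = "endoprs_degenerate_table")
  }
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rlang::abort(
      paste0("rank-deficient design; collinear column(s): ",
             paste(dropped, collapse = ", ")),
      class = "endoprs_rank_error", columns = dropped
    )
  }
  fit <- suppressWarnings(
    stats::glm(outcome ~ X - 1, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  )
  eps <- 1e-8
  separated <- !fit$converged ||
    any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    any(abs(stats::coef(fit)) > 15)
  est <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  if (separated) {
    est <- rep(NA_real_, ncol(X))
    se <- rep(NA_real_, ncol(X))
  }
  z <- est / se
  out <- tibble::tibble(
    term = colnames(X),
    estimate = est,
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * stats::pnorm(abs(unname(z)), lower.tail = FALSE)
  )
  structure(
    list(coefficients = out, n = length(outcome),
         converged = !separated, iterations = fit$iter,
         separation = separated),
    class = "endoprs_logit"
  )
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom, used to
#' compare burden distributions between cases and controls.
#'
#' @param a,b Numeric vectors of length at least 2.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    rlang::abort("each sample needs at least two observations",
                 class = "endoprs_param_error")
  }
  ht <- stats::t.test(a, b)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b)
  )
}

#' Burden ~ PRS x status interaction (linear model)
#'
#' The central index-event analysis: models the comorbidity (or total)
#' diagnosis burden by PRS, endometriosis status, and their interaction,
#' `burden ~ prs_z + endo + prs_z:endo`. Under a liability-threshold model
#' with shared risk factors, conditioning on case status induces a negative
#' PRS-burden relationship among cases, so the interaction term is expected
#' negative. Chapter-wise (`scope = "chapter"`) and leave-one-chapter-out
#' (`scope = "leave_out"`) sensitivity fits use the 3-character chapter
#' counts.
#'
#' @param cohort An `endoprs_cohort` tibble.
#' @param profiles [burden_profiles()] output (list with `overall` and
#'   `by_chapter`), or a [count_burden()] tibble when only `scope = "all"`
#'   is needed.
#' @param metric `"comorbid"` or `"total"`.
#' @param resolution 3 or 4 (scope `"all"` only; chapter scopes are always
#'   3-character).
#' @param scope `"all"`, `"chapter"` or `"leave_out"`.
#' @param chapter Chapter number for the chapter scopes.
#' @param robust Passed to [fit_ols()].
#' @return An `endoprs_lm` with terms `intercept`, `prs`, `endo`,
#'   `prs_x_endo`.
#' @export
burden_prs_interaction <- function(cohort, profiles,
                                   metric = c("comorbid", "total"),
                                   resolution = 3L,
                                   scope = c("all", "chapter", "leave_out"),
                                   chapter = NULL, robust = FALSE) {
  metric <- match.arg(metric)
  scope <- match.arg(scope)
  overall <- if (is.data.frame(profiles)) profiles else profiles$overall
  if (scope == "all") {
    col <- paste0(metric, "_", resolution, "char")
    y <- dplyr::left_join(dplyr::select(cohort, "id"),
                          dplyr::select(overall, "id", y = dplyr::all_of(col)),
                          by = "id")$y
  } else {
    if (is.data.frame(profiles) || is.null(chapter)) {
      rlang::abort("chapter scopes need burden_profiles() output and a chapter",
                   class = "endoprs_param_error")
    }
    ch <- profiles$by_chapter
    col <- switch(scope,
                  chapter = paste0(metric, "_3char"),
                  leave_out = paste0("loo_", metric, "_3char"))
    sel <- ch[ch$chapter == chapter, c("id", col)]
    names(sel)[2] <- "y"
    y <- dplyr::left_join(dplyr::select(cohort, "id"), sel, by = "id")$y
    if (scope == "chapter") {
      y[is.na(y)] <- 0
    } else {
      # participants with nothing in `chapter` keep their full count
      full_col <- paste0(metric, "_3char")
      full <- dplyr::left_join(dplyr::select(cohort, "id"),
                               dplyr::select(overall, "id",
                                             full = dplyr::all_of(full_col)),
                               by = "id")$full
      y[is.na(y)] <- full[is.na(y)]
    }
  }
  endo <- as.numeric(cohort$endo_case)
  X <- cbind(intercept = 1, prs = cohort$prs_z, endo = endo,
             prs_x_endo = cohort$prs_z * endo)
  fit_ols(y, X, robust = robust)
}

#' Interaction fits across all chapter scopes
#'
#' Runs [burden_prs_interaction()] for the overall count, each of the 22
#' chapter-specific counts, and each of the 22 leave-one-chapter-out
#' counts, collecting the interaction term of every fit.
#'
#' @inheritParams burden_prs_interaction
#' @param chapters Chapters to sweep (default all present in the profiles).
#' @return Tibble: `scope`, `chapter`, `estimate`, `std_error`, `p_value`
#'   for the `prs_x_endo` term.
#' @export
burden_interaction_scan <- function(cohort, profiles,
                                    metric = c("comorbid", "total"),
                                    chapters = NULL) {
  metric <- match.arg(metric)
  if (is.null(chapters)) chapters <- sort(unique(profiles$by_chapter$chapter))
  grab <- function(fit, scope, chapter) {
    row <- fit$coefficients[fit$coefficients$term == "prs_x_endo", ]
    tibble::tibble(scope = scope, chapter = chapter,
                   estimate = row$estimate, std_error = row$std_error,
                   p_value = row$p_value)
  }
  all_fit <- grab(burden_prs_interaction(cohort, profiles, metric, scope = "all"),
                  "all", NA_integer_)
  per_ch <- purrr::map_dfr(chapters, function(ch) {
    dplyr::bind_rows(
      grab(burden_prs_interaction(cohort, profiles, metric,
                                  scope = "chapter", chapter = ch), "chapter", ch),
      grab(burden_prs_interaction(cohort, profiles, metric,
                                  scope = "leave_out", chapter = ch), "leave_out", ch)
    )
  })
  dplyr::bind_rows(all_fit, per_ch)
}

#' Multiplicative-scale PRS x comorbidity interaction
#'
#' Logistic regression of endometriosis status on PRS, index-comorbidity
#' presence, and their product: `endo ~ prs_z + comorbidity +
#' prs_z:comorbidity`. The interaction coefficient is the multiplicative-
#' scale interaction on the odds scale.
#'
#' @param cohort An `endoprs_cohort` tibble with `has_<name>` flag columns.
#' @param comorbidity_name Name of the comorbidity (e.g.
#'   `"uterine_fibroids"`).
#' @return An `endoprs_logit` with terms `intercept`, `prs`, `comorbidity`,
#'   `prs_x_comorbidity`.
#' @export
multiplicative_interaction <- function(cohort, comorbidity_name) {
  flag_col <- paste0("has_", comorbidity_name)
  if (!flag_col %in% colnames(cohort)) {
    rlang::abort(paste0("cohort lacks comorbidity flag column '", flag_col, "'"),
                 class = "endoprs_param_error")
  }
  com <- as.numeric(cohort[[flag_col]])
  X <- cbind(intercept = 1, prs = cohort$prs_z, comorbidity = com,
             prs_x_comorbidity = cohort$prs_z * com)
  fit_logistic(cohort$endo_case, X)
}

#' Ratio of two prevalence differences
#'
#' Summary statistic of the additive-scale analysis: how many times larger
#' the absolute prevalence increase on comorbidity diagnosis is in the top
#' PRS decile than in the bottom one. Reported to one decimal place by
#' convention.
#'
#' @param diff_low Absolute prevalence difference (percentage points) in
#'   the low-PRS stratum.
#' @param diff_high Same in the high-PRS stratum.
#' @param digits Rounding digits.
#' @return A number, or `NA` when the low-stratum difference is zero or
#'   either input is missing.
#' @examples
#' difference_ratio(5.67, 15.57)
#' @export
difference_ratio <- function(diff_low, diff_high, digits = 1L) {
  if (is.na(diff_low) || is.na(diff_high) || diff_low == 0) return(NA_real_)
  round(diff_high / diff_low, digits)
}

#' Additive-scale PRS x comorbidity interaction
#'
#' For each PRS decile, the endometriosis prevalence among participants
#' with and without the comorbidity, their absolute difference in
#' percentage points, and exact binomial confidence intervals per arm. The
#' summary ratio compares the top decile's difference to the bottom
#' decile's. Deciles with an empty arm are flagged and excluded from the
#' ratio with a warning.
#'
#' @param cohort An `endoprs_cohort` tibble.
#' @param comorbidity_name Name of the comorbidity flag.
#' @param assignment Optional [assign_quantiles()] result (k = 10); computed
#'   from `prs_z` when absent.
#' @return Tibble of class `endoprs_additive`: one row per decile with
#'   columns `decile`, `n_with`, `n_without`, `prevalence_with`,
#'   `prevalence_without`, CI bounds, `difference_pp`, `ok`; the
#'   decile-10 / decile-1 ratio is in the `ratio` attribute.
#' @export
additive_interaction <- function(cohort, comorbidity_name, assignment = NULL) {
  flag_col <- paste0("has_", comorbidity_name)
  if (!flag_col %in% colnames(cohort)) {
    rlang::abort(paste0("cohort lacks comorbidity flag column '", flag_col, "'"),
                 class = "endoprs_param_error")
  }
  if (is.null(assignment)) assignment <- assign_quantiles(cohort, k = 10L)
  dat <- tibble::tibble(
    decile = assignment$quantile_bin[match(cohort$id, assignment$id)],
    endo = cohort$endo_case,
    com = cohort[[flag_col]]
  )
  out <- purrr::map_dfr(sort(unique(dat$decile)), function(d) {
    dd <- dat[dat$decile == d, ]
    n_with <- sum(dd$com); n_without <- sum(!dd$com)
    ok <- n_with > 0L && n_without > 0L
    pw <- if (n_with) mean(dd$endo[dd$com]) else NA_real_
    po <- if (n_without) mean(dd$endo[!dd$com]) else NA_real_
    ci_w <- if (n_with) stats::binom.test(sum(dd$endo & dd$com), n_with)$conf.int else c(NA, NA)
    ci_o <- if (n_without) stats::binom.test(sum(dd$endo & !dd$com), n_without)$conf.int else c(NA, NA)
    tibble::tibble(
      decile = d, n_with = n_with, n_without = n_without,
      prevalence_with = pw, prevalence_without = po,
      ci_with_low = ci_w[1], ci_with_high = ci_w[2],
      ci_without_low = ci_o[1], ci_without_high = ci_o[2],
      difference_pp = 100 * (pw - po),
      ok = ok
    )
  })
  bad <- out$decile[!out$ok]
  if (length(bad)) {
    rlang::warn(paste0("decile(s) with an empty arm excluded from the ratio: ",
                       paste(bad, collapse = ", ")))
  }
  d1 <- out$difference_pp[out$decile == 1 & out$ok]
  d10 <- out$difference_pp[out$decile == max(out$decile) & out$ok]
  ratio <- if (length(d1) == 1L && length(d10) == 1L) {
    difference_ratio(d1, d10)
  } else NA_real_
  structure(out, comorbidity = comorbidity_name, ratio = ratio,
            class = c("endoprs_additive", class(out)))
}
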