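#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a linear interaction fit
#'
#' @param x An `endoprs_lm` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.endoprs_lm <- function(x, ...) x$coefficients

#' @rdname tidy.endoprs_lm
#' @export
glance.endoprs_lm <- function(x, ...) {
  tibble::tibble(n = x$n, sigma2 = x$sigma2, df_residual = x$df_residual,
                 robust = x$robust)
}

#' Tidy a logistic interaction fit
#'
#' @param x An `endoprs_logit` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value` (all `NA` when separation was detected).
#' @export
tidy.endoprs_logit <- function(x, ...) x$coefficients

#' @rdname tidy.endoprs_logit
#' @export
glance.endoprs_logit <- function(x, ...) {
  tibble::tibble(n = x$n, converged = x$converged,
                 iterations = x$iterations, separation = x$separation)
}

#' @export
print.endoprs_lm <- function(x, ...) {
  cat("Linear interaction fit (n =", x$n, ")\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
print.endoprs_logit <- function(x, ...) {
  cat("Logistic interaction fit (n =", x$n,
      if (x$separation) ", separation detected" else "", ")\n")
  print(x$coefficients)
  invisible(x)
}

#' Confidence intervals for fit terms
#'
#' @param object An `endoprs_lm` or `endoprs_logit`.
#' @param parm Terms to keep (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `ci_low`, `ci_high`.
#' @export
confint.endoprs_lm <- function(object, parm = NULL, level = 0.95, ...) {
  co <- object$coefficients
  if (!is.null(parm)) co <- co[co$term %in% parm, ]
  q <- stats::qt(1 - (1 - level) / 2, df = object$df_residual)
  tibble::tibble(term = co$term, estimate = co$estimate,
                 ci_low = co$estimate - q * co$std_error,
                 ci_high = co$estimate + q * co$std_error)
}

#' @rdname confint.endoprs_lm
#' @export
confint.endoprs_logit <- function(object, parm = NULL, level = 0.95, ...) {
  co <- object$coefficients
  if (!is.null(parm)) co <- co[co$term %in% parm, ]
  q <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(term = co$term, estimate = co$estimate,
                 ci_low = co$estimate - q * co$std_error,
                 ci_high = co$estimate + q * co$std_error)
}
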