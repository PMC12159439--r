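#' Construct a code set
#'
#' A code set is a tibble of distinct normalized codes at a declared maximum
#' resolution, typically the filtered output of a phenome scan. Membership is
#' decided at the set's resolution: a query code is truncated to that
#' resolution and matched exactly.
#'
#' @param codes Character vector of codes (normalized on entry).
#' @param resolution Maximum resolution of the set (3, 4 or 5).
#' @param label Free-text label, e.g. the cohort the set was derived from.
#' @return A tibble of class `endoprs_code_set` with columns `code` and
#'   `chapter`.
#' @export
code_set <- function(codes, resolution = 4L, label = "") {
  codes <- unique(normalize_code(codes))
  if (any(nchar(codes) > resolution)) {
    rlang::abort(
      "code set members must not exceed the declared resolution",
      class = "endoprs_param_error"
    )
  }
  out <- tibble::tibble(code = codes, chapter = if (length(codes)) chapter_of(codes) else integer())
  structure(out, label = label, resolution = as.integer(resolution),
            class = c("endoprs_code_set", class(out)))
}

#' Membership of codes in a code set
#'
#' @param codes Character vector of normalized codes (any resolution).
#' @param set An [code_set()] object.
#' @return Logical vector: is each code's truncation to the set's resolution
#'   a member?
#' @export
code_in_set <- function(codes, set) {
  reduce_resolution(codes, attr(set, "resolution")) %in% set$code
}

#' Cross-cohort code-set overlap
#'
#' Counts codes found in both sets and in each set only, the summary used to
#' compare comorbid-code catalogues discovered in two biobanks.
#'
#' @param set_a,set_b [code_set()] objects at the same resolution.
#' @return A one-row tibble with columns `n_both`, `n_only_a`, `n_only_b`.
#' @examples
#' a <- code_set(c("D259", "K579", "I10"))
#' b <- code_set(c("D259", "N920"))
#' compare_code_sets(a, b)
#' @export
compare_code_sets <- function(set_a, set_b) {
  if (!identical(attr(set_a, "resolution"), attr(set_b, "resolution"))) {
    rlang::abort("code sets must share a resolution", class = "endoprs_param_error")
  }
  both <- length(intersect(set_a$code, set_b$code))
  tibble::tibble(
    n_both = both,
    n_only_a = length(set_a$code) - both,
    n_only_b = length(set_b$code) - both
  )
}

#' Chapter-wise two-proportion comparison of two code sets
#'
#' For every ICD-10 chapter represented in either set, tests whether the
#' proportion of the set's codes falling in that chapter differs between the
#' two sets, using the two-proportion z-test with Yates continuity
#' correction ([stats::prop.test()] defaults). Chapters absent from both
#' sets are reported with `NA` statistics.
#'
#' @param set_a,set_b Non-empty [code_set()] objects.
#' @return A tibble with one row per chapter: counts, proportions, `p_value`
#'   and `applicable`.
#' @export
compare_chapter_proportions <- function(set_a, set_b) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) {
    rlang::abort("both code sets must be non-empty", class = "endoprs_param_error")
  }
  n_a <- nrow(set_a); n_b <- nrow(set_b)
  purrr::map_dfr(1:22, function(ch) {
    x_a <- sum(set_a$chapter == ch)
    x_b <- sum(set_b$chapter == ch)
    if (x_a + x_b == 0L) {
      return(tibble::tibble(
        chapter = ch, n_a = 0L, n_b = 0L,
        prop_a = 0, prop_b = 0, p_value = NA_real_, applicable = FALSE
      ))
    }
    p <- suppressWarnings(stats::prop.test(c(x_a, x_b), c(n_a, n_b)))$p.value
    tibble::tibble(
      chapter = ch, n_a = x_a, n_b = x_b,
      prop_a = x_a / n_a, prop_b = x_b / n_b,
      p_value = p, applicable = TRUE
    )
  })
}
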