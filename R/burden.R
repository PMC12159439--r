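#' Per-participant diagnosis long table
#'
#' Unnests a cohort's `codes` list-column into a two-column long tibble and
#' normalizes the codes. The building block of every burden metric.
#'
#' @param cohort An `endoprs_cohort` tibble.
#' @return Tibble with columns `id`, `code`.
#' @export
cohort_diagnoses <- function(cohort) {
  tibble::tibble(
    id = rep(cohort$id, lengths(cohort$codes)),
    code = normalize_code(unlist(cohort$codes, use.names = FALSE))
  )
}

check_cross_cohort <- function(cohort, comorbid_set, allow_same_cohort) {
  set_src <- attr(comorbid_set, "label", exact = TRUE)
  coh_lab <- cohort_label(cohort)
  if (!allow_same_cohort && !is.null(set_src) && nzchar(set_src) &&
      nzchar(coh_lab) && identical(set_src, coh_lab)) {
    rlang::abort(
      paste0(
        "comorbid set was derived from the same cohort ('", coh_lab, "') it is ",
        "being counted in; use the alternate cohort's set, or pass ",
        "allow_same_cohort = TRUE to accept the circularity"
      ),
      class = "endoprs_circularity_error"
    )
  }
}

# normalize -> exclude -> annotate chapter and the 4-character reduction
prepared_diagnoses <- function(cohort, rules) {
  long <- cohort_diagnoses(cohort)
  if (nrow(long)) {
    ch <- chapter_of(long$code)
    drop <- ch %in% rules$excluded_chapters |
      reduce_resolution(long$code, 4L) %in% rules$excluded_codes
    if (rules$drop_all_n80) drop <- drop | reduce_resolution(long$code, 3L) == "N80"
    long <- long[!drop, , drop = FALSE]
    long$chapter <- ch[!drop]
  } else {
    long$chapter <- integer()
  }
  long$code4 <- reduce_resolution(long$code, 4L)
  long
}

# integer-encoded dedup machinery shared by the counting functions: unique
# (participant, code) pairs via numeric keys, counts via tabulate()
burden_indices <- function(cohort, long, comorbid_set) {
  id_int <- match(long$id, cohort$id)
  u4 <- unique(long$code4)
  c4 <- match(long$code4, u4)
  code3 <- reduce_resolution(u4, 3L)[c4]
  u3 <- unique(code3)
  list(
    id_int = id_int,
    n = nrow(cohort),
    key4 = (id_int - 1) * (length(u4) + 1) + c4,
    key3 = (id_int - 1) * (length(u3) + 1) + match(code3, u3),
    comorbid = code_in_set(u4, comorbid_set)[c4]
  )
}

#' Comorbidity-burden profiles
#'
#' Computes, per participant, the count of unique diagnosed conditions
#' ("total diagnoses") and of unique conditions previously found comorbid
#' with endometriosis ("comorbid diagnoses"), at both 3- and 4-character
#' resolution. The sequence is: normalize, apply exclusion rules (external
#' causes, health-service contact, endometriosis subcodes), truncate,
#' deduplicate. Comorbid membership is decided at 4-character resolution
#' against `comorbid_set`; the 3-character comorbid count is the number of
#' unique 3-character stems among codes whose 4-character form is comorbid.
#'
#' To guard against circular inflation, a set derived from a scan of the
#' same cohort label is refused unless `allow_same_cohort = TRUE`.
#'
#' @param cohort An `endoprs_cohort` tibble.
#' @param comorbid_set A [code_set()] at resolution 4, typically from
#'   [build_comorbid_set()] on the alternate cohort's scan.
#' @param rules An [exclusion_rules()] object.
#' @param allow_same_cohort Override the cross-cohort contract.
#' @return Tibble: `id`, `total_3char`, `comorbid_3char`, `total_4char`,
#'   `comorbid_4char`, one row per participant (zeroes for empty streams).
#' @export
count_burden <- function(cohort, comorbid_set, rules = exclusion_rules(),
                         allow_same_cohort = FALSE) {
  check_cross_cohort(cohort, comorbid_set, allow_same_cohort)
  long <- prepared_diagnoses(cohort, rules)
  ix <- burden_indices(cohort, long, comorbid_set)
  keep4 <- !duplicated(ix$key4)
  keep3 <- !duplicated(ix$key3)
  com <- ix$comorbid
  keep3c <- logical(length(com))
  keep3c[com] <- !duplicated(ix$key3[com])
  tibble::tibble(
    id = cohort$id,
    total_3char = tabulate(ix$id_int[keep3], ix$n),
    comorbid_3char = tabulate(ix$id_int[keep3c], ix$n),
    total_4char = tabulate(ix$id_int[keep4], ix$n),
    comorbid_4char = tabulate(ix$id_int[keep4 & com], ix$n)
  )
}

#' Chapter-wise burden profiles
#'
#' Unique 3-character diagnosis counts within each ICD-10 chapter, total and
#' comorbid, for the chapter-wise and leave-one-chapter-out sensitivity
#' analyses. Only observed (participant, chapter) combinations are returned;
#' absent combinations are zero counts.
#'
#' @inheritParams count_burden
#' @return Tibble: `id`, `chapter`, `total_3char`, `comorbid_3char`.
#' @export
count_burden_by_chapter <- function(cohort, comorbid_set, rules = exclusion_rules(),
                                    allow_same_cohort = FALSE) {
  check_cross_cohort(cohort, comorbid_set, allow_same_cohort)
  long <- prepared_diagnoses(cohort, rules)
  ix <- burden_indices(cohort, long, comorbid_set)
  keep3 <- !duplicated(ix$key3)
  com <- ix$comorbid
  keep3c <- logical(length(com))
  keep3c[com] <- !duplicated(ix$key3[com])
  # chapter is a function of the 3-character stem, so (id, chapter) counts
  # are tabulations of the deduplicated (id, stem) rows
  keych <- (ix$id_int - 1) * 22 + long$chapter
  tot <- tabulate(keych[keep3], ix$n * 22)
  cm <- tabulate(keych[keep3c], ix$n * 22)
  nz <- which(tot > 0L)
  tibble::tibble(
    id = cohort$id[(nz - 1) %/% 22 + 1],
    chapter = as.integer((nz - 1) %% 22 + 1),
    total_3char = tot[nz],
    comorbid_3char = cm[nz]
  )
}

#' Full burden profile including leave-one-chapter-out counts
#'
#' Convenience wrapper joining [count_burden()] and
#' [count_burden_by_chapter()]: for each participant and chapter, the
#' leave-one-out count equals the full 3-character count minus that
#' chapter's count.
#'
#' @inheritParams count_burden
#' @return A list with elements `overall` (per-participant scalar counts)
#'   and `by_chapter` (long tibble with `loo_total_3char`,
#'   `loo_comorbid_3char` columns added).
#' @export
burden_profiles <- function(cohort, comorbid_set, rules = exclusion_rules(),
                            allow_same_cohort = FALSE) {
  overall <- count_burden(cohort, comorbid_set, rules, allow_same_cohort)
  by_ch <- count_burden_by_chapter(cohort, comorbid_set, rules, allow_same_cohort)
  by_ch <- dplyr::left_join(
    by_ch,
    dplyr::select(overall, "id",
                  full_total = "total_3char", full_comorbid = "comorbid_3char"),
    by = "id"
  )
  by_ch <- dplyr::mutate(
    by_ch,
    loo_total_3char = .data$full_total - .data$total_3char,
    loo_comorbid_3char = .data$full_comorbid - .data$comorbid_3char
  )
  list(
    overall = overall,
    by_chapter = dplyr::select(by_ch, -"full_total", -"full_comorbid")
  )
}
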