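#' Normalize raw ICD-10-style diagnosis codes
#'
#' Biobank diagnosis streams mix dotted (`"N80.1"`) and dot-less (`"N801"`)
#' dialects and inconsistent case. `normalize_code()` maps every input onto
#' the canonical dot-less uppercase form: one letter followed by two to four
#' digits (three to five characters in total).
#'
#' @param raw Character vector of raw code strings.
#' @return Character vector of normalized codes, same length as `raw`.
#'   The "resolution" of a code is simply its character count (3, 4 or 5).
#' @examples
#' normalize_code(c("N80.1", "k57", "C50.9"))
#' @export
normalize_code <- function(raw) {
  if (length(raw) == 0L) return(character())
  if (any(is.na(raw) | !nzchar(raw))) {
    rlang::abort("codes must be non-empty strings", class = "endoprs_malformed_code")
  }
  x <- toupper(trimws(raw))
  # a single dot is only legal after the 3-character stem (e.g. N80.1)
  x <- sub("^([A-Z][0-9]{2})\\.", "\\1", x)
  bad <- !grepl("^[A-Z][0-9]{2,4}$", x)
  if (any(bad)) {
    rlang::abort(
      paste0(
        "malformed ICD-10-style code(s): ",
        paste(unique(raw[bad]), collapse = ", ")
      ),
      class = "endoprs_malformed_code",
      raw = unique(raw[bad])
    )
  }
  x
}

#' Truncate codes to a coarser resolution
#'
#' Codes at or below the requested resolution are returned unchanged, so a
#' native 3-character code is a valid member of a 4-character analysis set.
#'
#' @param code Character vector of normalized codes.
#' @param level Target maximum resolution: 3 or 4 (5 is a no-op).
#' @return Character vector of truncated codes.
#' @examples
#' reduce_resolution(c("K5732", "N801", "K57"), 4)
#' @export
reduce_resolution <- function(code, level) {
  stopifnot(length(level) == 1L, level %in% c(3L, 4L, 5L))
  substr(code, 1L, level)
}

# Chapter boundaries on the 3-character stem (WHO ICD-10). Each row:
# first stem, last stem, chapter. Stems are compared as letter*100 + number.
icd10_chapter_ranges <- function() {
  tibble::tribble(
    ~from,  ~to,    ~chapter,
    "A00", "B99", 1L,
    "C00", "D48", 2L,
    "D50", "D89", 3L,
    "E00", "E90", 4L,
    "F00", "F99", 5L,
    "G00", "G99", 6L,
    "H00", "H59", 7L,
    "H60", "H95", 8L,
    "I00", "I99", 9L,
    "J00", "J99", 10L,
    "K00", "K93", 11L,
    "L00", "L99", 12L,
    "M00", "M99", 13L,
    "N00", "N99", 14L,
    "O00", "O99", 15L,
    "P00", "P96", 16L,
    "Q00", "Q99", 17L,
    "R00", "R99", 18L,
    "S00", "T98", 19L,
    "V01", "Y98", 20L,
    "Z00", "Z99", 21L,
    "U00", "U99", 22L
  )
}

stem_ordinal <- function(stem) {
  (match(substr(stem, 1L, 1L), LETTERS) - 1L) * 100L +
    as.integer(substr(stem, 2L, 3L))
}

#' ICD-10 chapter of a code
#'
#' Maps the 3-character stem of each code onto the 22 WHO ICD-10 chapters
#' (A00--B99 is chapter 1, ..., U00--U99 is chapter 22). Stems falling in a
#' gap of the classification (such as D49) raise an error rather than being
#' silently assigned, so dialect mismatches fail loudly.
#'
#' @param code Character vector of normalized codes.
#' @return Integer vector of chapter numbers in 1..22.
#' @examples
#' chapter_of(c("K579", "O26", "C509"))
#' @export
chapter_of <- function(code) {
  if (length(code) == 0L) return(integer())
  ranges <- icd10_chapter_ranges()
  # flat ordinal -> chapter lookup (26 letters x 100 numbers) for O(n) mapping
  lookup <- rep(NA_integer_, 2600L)
  for (r in seq_len(nrow(ranges))) {
    span <- stem_ordinal(ranges$from[r]):stem_ordinal(ranges$to[r])
    lookup[span + 1L] <- ranges$chapter[r]
  }
  ord <- stem_ordinal(substr(code, 1L, 3L))
  idx <- lookup[ord + 1L]
  if (anyNA(idx)) {
    rlang::abort(
      paste0(
        "code stem(s) outside the ICD-10 chapter ranges: ",
        paste(unique(substr(code[is.na(idx)], 1L, 3L)), collapse = ", ")
      ),
      class = "endoprs_unmapped_code"
    )
  }
  idx
}

#' Exclusion rules for burden counting
#'
#' The comorbidity analyses drop diagnoses reflecting external causes or
#' health-service contact (chapters 19, 20, 21) and the endometriosis
#' subcodes N80.1--N80.9 themselves. N80.0 (adenomyosis) is retained by
#' default; set `drop_all_n80 = TRUE` to remove every N80 code.
#'
#' @param excluded_chapters Integer vector of chapter numbers to drop.
#' @param excluded_codes Character vector of 4-character codes to drop.
#' @param drop_all_n80 If `TRUE`, drop every code whose 3-character stem is
#'   N80 regardless of `excluded_codes`.
#' @return An object of class `endoprs_rules`.
#' @export
exclusion_rules <- function(excluded_chapters = c(19L, 20L, 21L),
                            excluded_codes = paste0("N80", 1:9),
                            drop_all_n80 = FALSE) {
  excluded_chapters <- as.integer(excluded_chapters)
  if (length(excluded_chapters) && any(excluded_chapters < 1L | excluded_chapters > 22L)) {
    rlang::abort("excluded chapters must lie in 1..22", class = "endoprs_param_error")
  }
  structure(
    list(
      excluded_chapters = excluded_chapters,
      excluded_codes = if (length(excluded_codes)) normalize_code(excluded_codes) else character(),
      drop_all_n80 = isTRUE(drop_all_n80)
    ),
    class = "endoprs_rules"
  )
}

#' Apply exclusion rules to a code vector
#'
#' @param codes Character vector of normalized codes.
#' @param rules An [exclusion_rules()] object.
#' @return The surviving codes, order preserved.
#' @examples
#' apply_exclusions(c("N804", "S720", "D259"), exclusion_rules())
#' @export
apply_exclusions <- function(codes, rules = exclusion_rules()) {
  if (length(codes) == 0L) return(character())
  drop <- chapter_of(codes) %in% rules$excluded_chapters
  drop <- drop | reduce_resolution(codes, 4L) %in% rules$excluded_codes
  if (rules$drop_all_n80) drop <- drop | reduce_resolution(codes, 3L) == "N80"
  codes[!drop]
}

#' Does a code stream indicate endometriosis?
#'
#' `TRUE` when any code reduces to the 3-character stem N80. Used when case
#' status must be derived from a diagnosis stream rather than a phenotype
#' column.
#'
#' @param codes Character vector of normalized codes.
#' @return Length-one logical.
#' @export
endo_case_codes <- function(codes) {
  length(codes) > 0L && any(reduce_resolution(codes, 3L) == "N80")
}
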