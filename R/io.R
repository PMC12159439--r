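#' Write a cohort to phenotype + diagnosis TSVs
#'
#' Phenotype schema: `id`, `endo_case` (0/1), `age`, `prs_z`, plus any
#' `has_*` flag columns. Diagnosis schema (long): `id`, `code` (dot-less).
#'
#' @param cohort An `endoprs_cohort`.
#' @param phenotype_path,diagnosis_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, phenotype_path, diagnosis_path) {
  pheno <- dplyr::select(tibble::as_tibble(cohort), -"codes")
  pheno$endo_case <- as.integer(pheno$endo_case)
  for (col in grep("^has_", colnames(pheno), value = TRUE)) {
    pheno[[col]] <- as.integer(pheno[[col]])
  }
  readr::write_tsv(pheno, phenotype_path)
  readr::write_tsv(cohort_diagnoses(cohort), diagnosis_path)
  invisible(c(phenotype_path, diagnosis_path))
}

#' Load a cohort from phenotype + diagnosis TSVs
#'
#' Validates the schemas, joins the diagnosis stream onto the phenotype
#' table, silently normalizes dotted codes (logged via message when
#' `verbose`), and optionally merges a separate score file.
#'
#' @param phenotype_path TSV with columns `id`, `endo_case`, `age` and
#'   optionally `prs_z` and `has_*` flags.
#' @param diagnosis_path Long TSV with columns `id`, `code`.
#' @param score_path Optional TSV with columns `id`, `prs_z`.
#' @param label Cohort label.
#' @param verbose Emit join diagnostics.
#' @return An `endoprs_cohort` tibble.
#' @export
load_cohort <- function(phenotype_path, diagnosis_path, score_path = NULL,
                        label = "", verbose = FALSE) {
  pheno <- readr::read_tsv(phenotype_path, show_col_types = FALSE)
  need <- c("id", "endo_case", "age")
  miss <- setdiff(need, colnames(pheno))
  if (length(miss)) {
    rlang::abort(paste0("phenotype file missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "endoprs_schema_error")
  }
  diag <- readr::read_tsv(diagnosis_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(c("id", "code"), colnames(diag))
  if (length(miss)) {
    rlang::abort(paste0("diagnosis file missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "endoprs_schema_error")
  }
  dotted <- grepl("\\.", diag$code)
  diag$code <- normalize_code(diag$code)
  if (verbose && any(dotted)) {
    message(sum(dotted), " dotted code(s) normalized")
  }
  orphan <- setdiff(unique(diag$id), pheno$id)
  if (length(orphan)) {
    rlang::abort(
      paste0(length(orphan), " diagnosis id(s) absent from the phenotype file"),
      class = "endoprs_load_error"
    )
  }
  if (anyDuplicated(pheno$id)) {
    rlang::abort("duplicate participant ids", class = "endoprs_load_error")
  }
  if (!is.null(score_path)) {
    sc <- readr::read_tsv(score_path, show_col_types = FALSE)
    miss <- setdiff(c("id", "prs_z"), colnames(sc))
    if (length(miss)) {
      rlang::abort(paste0("score file missing column(s): ",
                          paste(miss, collapse = ", ")),
                   class = "endoprs_schema_error")
    }
    pheno$prs_z <- sc$prs_z[match(pheno$id, sc$id)]
  }
  streams <- split(diag$code, factor(diag$id, levels = pheno$id))
  pheno$codes <- lapply(unname(streams), unique)
  pheno$endo_case <- as.logical(pheno$endo_case)
  for (col in grep("^has_", colnames(pheno), value = TRUE)) {
    pheno[[col]] <- as.logical(pheno[[col]])
  }
  pheno <- dplyr::relocate(pheno, "codes", .after = dplyr::last_col())
  if (verbose) {
    message(nrow(pheno), " participants, ", nrow(diag), " diagnosis rows loaded")
  }
  new_cohort(tibble::as_tibble(pheno), label = label)
}

#' Read a plink-style score weight table
#'
#' Three columns in plink `--score` order: `snp_id`, `effect_allele`,
#' `weight`; an optional fourth column `freq` carries effect-allele
#' frequencies for missing-dosage imputation.
#'
#' @param path TSV path.
#' @return Tibble validated for unique SNP ids and frequencies in (0,1).
#' @export
read_weight_table <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("snp_id", "effect_allele", "weight"), colnames(w))
  if (length(miss)) {
    rlang::abort(paste0("weight table missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "endoprs_schema_error")
  }
  if (anyDuplicated(w$snp_id)) {
    rlang::abort("duplicate snp_id in weight table", class = "endoprs_schema_error")
  }
  if (!all(w$effect_allele %in% c("A", "C", "G", "T"))) {
    rlang::abort("effect_allele must be one of A/C/G/T", class = "endoprs_schema_error")
  }
  if ("freq" %in% colnames(w) && any(w$freq <= 0 | w$freq >= 1)) {
    rlang::abort("frequencies must lie in (0,1)", class = "endoprs_schema_error")
  }
  w
}

#' Write / read a code set TSV
#'
#' Schema: `code`, `chapter`, `label`.
#'
#' @param set A [code_set()].
#' @param path TSV path.
#' @return `write_code_set()` the path invisibly; `read_code_set()` a
#'   [code_set()].
#' @export
write_code_set <- function(set, path) {
  out <- tibble::as_tibble(set)
  out$label <- attr(set, "label", exact = TRUE) %||% ""
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_code_set
#' @param resolution Resolution of the stored set.
#' @export
read_code_set <- function(path, resolution = 4L) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(code = readr::col_character()))
  label <- if ("label" %in% colnames(x) && nrow(x)) x$label[1] else ""
  code_set(x$code, resolution = resolution, label = label)
}
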