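#' Derive a named substream seed
#'
#' Stage seeds are derived from one root seed and a stage name, so adding a
#' stage never perturbs the draws of earlier stages. The result is kept
#' below 2^31.
#'
#' @param root Integer root seed.
#' @param name Stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(root, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(root) * 7919 + h * 104729) %% 2147483629) + 1L
}

#' Pipeline configuration
#'
#' Bundles the simulation parameters of the two cohorts and the analysis
#' settings of the full run. The two cohorts must use distinct seeds: the
#' cross-cohort design (scan in one biobank, count in the other) is the
#' package's guard against circular comorbid-set inflation.
#'
#' @param params_a,params_b [sim_params()] for cohorts "A" and "B".
#' @param q FDR level of the phenome scan.
#' @param rules [exclusion_rules()] applied throughout.
#' @param index_comorbidities Names of comorbidities for the interaction
#'   analyses (must match `has_*` flags of the cohorts).
#' @param k_quantiles Number of bins for the odds-ratio stratification.
#' @param chapter_scan Also run the chapter-wise / leave-one-out
#'   interaction sweep (slower).
#' @return An object of class `endoprs_config`.
#' @export
pipeline_config <- function(params_a, params_b, q = 0.05,
                            rules = exclusion_rules(),
                            index_comorbidities = c(
                              "uterine_fibroids", "heavy_menstrual_bleeding",
                              "dysmenorrhea", "irritable_bowel_syndrome",
                              "diverticular_disease", "asthma"
                            ),
                            k_quantiles = 100L,
                            chapter_scan = FALSE) {
  stopifnot(inherits(params_a, "endoprs_params"), inherits(params_b, "endoprs_params"))
  if (identical(params_a$seed, params_b$seed)) {
    rlang::abort("cohorts A and B must use distinct seeds",
                 class = "endoprs_param_error")
  }
  if (q <= 0 || q >= 1) {
    rlang::abort("q must lie in (0,1)", class = "endoprs_param_error")
  }
  structure(
    list(params_a = params_a, params_b = params_b, q = q, rules = rules,
         index_comorbidities = index_comorbidities,
         k_quantiles = as.integer(k_quantiles),
         chapter_scan = isTRUE(chapter_scan)),
    class = "endoprs_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [sim_params()] under `cohort_a:` / `cohort_b:` keys
#' (comorbidities as a list of records), plus top-level `q`,
#' `index_comorbidities`, `k_quantiles`, `chapter_scan` and `seed`. A
#' cohort block may omit `seed`, in which case one is derived from the
#' top-level seed via [derive_seed()].
#'
#' @param path YAML file path.
#' @return An `endoprs_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(block, stage) {
    args <- block
    if (!is.null(args$comorbidities)) {
      args$comorbidities <- purrr::map_dfr(args$comorbidities, function(cm) {
        do.call(comorbidity_spec, cm)
      })
    }
    if (!is.null(args$chapter_pool_sizes)) {
      args$chapter_pool_sizes <- unlist(args$chapter_pool_sizes)
    }
    if (is.null(args$seed)) {
      if (is.null(y$seed)) {
        rlang::abort("a seed must be given per cohort or at top level",
                     class = "endoprs_param_error")
      }
      args$seed <- derive_seed(y$seed, stage)
    }
    if (!is.null(args$age_range)) args$age_range <- unlist(args$age_range)
    do.call(sim_params, args)
  }
  pipeline_config(
    params_a = build(y$cohort_a %||% list(), "cohort_a"),
    params_b = build(y$cohort_b %||% list(), "cohort_b"),
    q = y$q %||% 0.05,
    index_comorbidities = unlist(y$index_comorbidities) %||% c(
      "uterine_fibroids", "heavy_menstrual_bleeding", "dysmenorrhea",
      "irritable_bowel_syndrome", "diverticular_disease", "asthma"
    ),
    k_quantiles = y$k_quantiles %||% 100L,
    chapter_scan = y$chapter_scan %||% FALSE
  )
}

stage_paths <- function(out_dir, label) {
  list(
    pheno = file.path(out_dir, paste0("cohort_", label, "_phenotypes.tsv")),
    diag = file.path(out_dir, paste0("cohort_", label, "_diagnoses.tsv")),
    scan = file.path(out_dir, paste0("scan_", label, ".tsv")),
    set = file.path(out_dir, paste0("comorbid_set_", label, ".tsv")),
    burden = file.path(out_dir, paste0("burden_", label, ".tsv"))
  )
}

#' Pipeline stages
#'
#' File-based stages composing to [run_endo_pipeline()]: each reads its
#' inputs from `out_dir` (as written by the previous stage) and writes its
#' outputs there, so running them in sequence is byte-identical to the
#' all-in-one driver.
#'
#' @param config An `endoprs_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (lab in c("A", "B")) {
    params <- if (lab == "A") config$params_a else config$params_b
    coh <- simulate_cohort(params, label = lab)
    p <- stage_paths(out_dir, lab)
    write_cohort(coh, p$pheno, p$diag)
    files <- c(files, p$pheno, p$diag)
  }
  invisible(files)
}

load_stage_cohort <- function(out_dir, lab) {
  p <- stage_paths(out_dir, lab)
  load_cohort(p$pheno, p$diag, label = lab)
}

#' @rdname pipeline-stages
#' @export
stage_scan <- function(config, out_dir) {
  files <- character()
  for (lab in c("A", "B")) {
    coh <- load_stage_cohort(out_dir, lab)
    scan <- phenome_scan(coh, q = config$q)
    p <- stage_paths(out_dir, lab)
    out <- dplyr::rename(
      tibble::as_tibble(scan),
      n_case_with = "case_with", n_case_without = "case_without",
      n_control_with = "control_with", n_control_without = "control_without",
      or = "odds_ratio", p = "p_value"
    )
    readr::write_tsv(out, p$scan)
    cset <- build_comorbid_set(scan, config$rules)
    if (nrow(cset) == 0L) {
      rlang::warn(paste0("cohort ", lab, ": empty comorbid code set"))
    }
    write_code_set(cset, p$set)
    files <- c(files, p$scan, p$set)
  }
  invisible(files)
}

#' @rdname pipeline-stages
#' @export
stage_burden <- function(config, out_dir) {
  files <- character()
  for (lab in c("A", "B")) {
    other <- setdiff(c("A", "B"), lab)
    coh <- load_stage_cohort(out_dir, lab)
    cset <- read_code_set(stage_paths(out_dir, other)$set)
    prof <- count_burden(coh, cset, config$rules)
    p <- stage_paths(out_dir, lab)
    readr::write_tsv(prof, p$burden)
    files <- c(files, p$burden)
  }
  invisible(files)
}

#' @rdname pipeline-stages
#' @export
stage_prs <- function(config, out_dir) {
  files <- character()
  for (lab in c("A", "B")) {
    coh <- load_stage_cohort(out_dir, lab)
    prof <- readr::read_tsv(stage_paths(out_dir, lab)$burden, show_col_types = FALSE)
    auc <- roc_auc(coh$prs_z, coh$endo_case)
    f_auc <- file.path(out_dir, paste0("auc_", lab, ".tsv"))
    readr::write_tsv(tibble::tibble(cohort = lab, auc = auc), f_auc)
    k <- min(config$k_quantiles, nrow(coh) %/% 2L)
    ortab <- tryCatch({
      asg <- assign_quantiles(coh, k = k)
      or_by_quantile(asg, coh)
    }, error = function(e) {
      rlang::warn(paste0("cohort ", lab, ": OR table skipped (", conditionMessage(e), ")"))
      NULL
    })
    f_or <- file.path(out_dir, paste0("or_by_quantile_", lab, ".tsv"))
    if (!is.null(ortab)) readr::write_tsv(tibble::as_tibble(ortab), f_or)
    f_prev <- character()
    for (metric in c("total", "comorbid")) {
      prev <- prevalence_by_burden(coh, prof, metric = metric)
      f <- file.path(out_dir, paste0("prevalence_by_", metric, "_burden_", lab, ".tsv"))
      readr::write_tsv(prev, f)
      f_prev <- c(f_prev, f)
    }
    files <- c(files, f_auc, if (!is.null(ortab)) f_or, f_prev)
  }
  invisible(files)
}

#' @rdname pipeline-stages
#' @export
stage_interact <- function(config, out_dir) {
  files <- character()
  for (lab in c("A", "B")) {
    coh <- load_stage_cohort(out_dir, lab)
    other <- setdiff(c("A", "B"), lab)
    cset <- read_code_set(stage_paths(out_dir, other)$set)
    fits <- list()
    if (config$chapter_scan) {
      prof <- burden_profiles(coh, cset, config$rules)
      for (metric in c("comorbid", "total")) {
        sweep <- burden_interaction_scan(coh, prof, metric = metric)
        f <- file.path(out_dir, paste0("interaction_scan_", metric, "_", lab, ".tsv"))
        readr::write_tsv(sweep, f)
        files <- c(files, f)
      }
      overall <- prof$overall
    } else {
      overall <- readr::read_tsv(stage_paths(out_dir, lab)$burden,
                                 show_col_types = FALSE)
    }
    for (metric in c("comorbid", "total")) {
      fit <- burden_prs_interaction(coh, overall, metric = metric)
      fits[[paste0("burden_", metric)]] <- dplyr::mutate(tidy(fit),
                                                         model = paste0("burden_", metric))
    }
    for (cm in config$index_comorbidities) {
      if (!paste0("has_", cm) %in% colnames(coh)) next
      mult <- multiplicative_interaction(coh, cm)
      fits[[paste0("multiplicative_", cm)]] <-
        dplyr::mutate(tidy(mult), model = paste0("multiplicative_", cm))
      addt <- additive_interaction(coh, cm)
      f <- file.path(out_dir, paste0("additive_", cm, "_", lab, ".tsv"))
      readr::write_tsv(
        dplyr::mutate(tibble::as_tibble(addt), ratio_d10_d1 = attr(addt, "ratio")),
        f
      )
      files <- c(files, f)
    }
    f_fit <- file.path(out_dir, paste0("interaction_fits_", lab, ".tsv"))
    readr::write_tsv(dplyr::bind_rows(fits), f_fit)
    files <- c(files, f_fit)
  }
  invisible(files)
}

#' Run the full cross-cohort pipeline
#'
#' Simulates cohorts A and B, scans each phenome-wide, builds comorbid code
#' sets, counts burden in each cohort using the *other* cohort's set,
#' computes the PRS summaries (AUC, per-quantile odds ratios, prevalence by
#' burden) and the interaction analyses (linear burden x PRS x status;
#' multiplicative and additive PRS x comorbidity for every index
#' comorbidity), writing plain TSVs plus a JSON run manifest.
#'
#' @param config An `endoprs_config`.
#' @param out_dir Output directory.
#' @return The manifest, invisibly: config hash, per-stage timings, and an
#'   md5 registry of every file written. Re-running with an identical
#'   config reproduces identical hashes.
#' @export
run_endo_pipeline <- function(config, out_dir) {
  stages <- list(
    simulate = stage_simulate, scan = stage_scan, burden = stage_burden,
    prs = stage_prs, interact = stage_interact
  )
  timings <- list()
  files <- character()
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(stages[[nm]](config, out_dir), error = function(e) {
      rlang::abort(
        paste0("pipeline stage '", nm, "' failed: ", conditionMessage(e)),
        class = "endoprs_pipeline_error", stage = nm,
        manifest = list(completed = names(timings), files = files)
      )
    })
    timings[[nm]] <- proc.time()[["elapsed"]] - t0
    files <- c(files, res)
  }
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config_digestible(config), cfg_file, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("endoprs")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seeds = c(cohort_a = config$params_a$seed, cohort_b = config$params_b$seed),
    stage_seconds = lapply(timings, round, 3),
    files = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_digestible <- function(config) {
  list(
    params_a = params_digestible(config$params_a),
    params_b = params_digestible(config$params_b),
    q = config$q,
    rules = unclass(config$rules),
    index_comorbidities = config$index_comorbidities,
    k_quantiles = config$k_quantiles,
    chapter_scan = config$chapter_scan
  )
}

params_digestible <- function(p) {
  out <- unclass(p)
  out$comorbidities <- as.data.frame(out$comorbidities)
  out$chapter_pool_sizes <- as.list(out$chapter_pool_sizes)
  out
}
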