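test_that("genotype scoring follows the average-per-allele convention", {
  dos <- tibble::tibble(id = c("a", "b", "c"), rs1 = c(0, 1, 2))
  w <- tibble::tibble(snp_id = "rs1", effect_allele = "A", weight = 1)
  sc <- score_genotypes(dos, w)
  expect_equal(sc$score, c(0, 0.5, 1))
  # linearity: doubling weights doubles scores
  w2 <- dplyr::mutate(w, weight = 2)
  expect_equal(score_genotypes(dos, w2)$score, 2 * sc$score)
  # missing SNP is reported by name
  w3 <- tibble::tibble(snp_id = c("rs1", "rs9"), effect_allele = "A",
                       weight = 1)
  expect_error(score_genotypes(dos, w3), "rs9",
               class = "endoprs_scoring_error")
})

test_that("missing dosages are imputed from frequency or dropped with divisor", {
  dos <- tibble::tibble(id = c("a", "b"), rs1 = c(2, NA), rs2 = c(0, 2))
  w <- tibble::tibble(snp_id = c("rs1", "rs2"), effect_allele = "A",
                      weight = c(1, 1), freq = c(0.25, 0.4))
  sc <- score_genotypes(dos, w)
  expect_equal(sc$score[2], (2 * 0.25 + 2) / 4)    # imputed to 2*freq
  sc2 <- score_genotypes(dos, dplyr::select(w, -freq))
  expect_equal(sc2$score[2], 2 / 2)                # rs1 dropped, divisor 2*1
})

test_that("standardization matches the n-1 z-score and validates input", {
  sc <- structure(tibble::tibble(id = c("a", "b"), score = c(0, 1)),
                  class = c("endoprs_scores", class(tibble::tibble())))
  z <- standardize_scores(sc)
  expect_equal(z$prs_z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  big <- tibble::tibble(id = as.character(1:100), score = rnorm(100))
  zb <- standardize_scores(big)
  expect_equal(mean(zb$prs_z), 0, tolerance = 1e-12)
  expect_equal(stats::var(zb$prs_z), 1, tolerance = 1e-12)
  expect_error(standardize_scores(tibble::tibble(id = "a", score = 1)),
               class = "endoprs_param_error")
})

test_that("quantile bins are balanced, including the biobank-sized centile case", {
  d <- tibble::tibble(id = sprintf("i%03d", 1:100), prs_z = rnorm(100))
  a <- assign_quantiles(d, k = 10)
  expect_equal(unname(table(a$quantile_bin)), rep(10L, 10), ignore_attr = TRUE)
  # ties: stable id order still yields balanced bins, with a warning
  d2 <- tibble::tibble(id = sprintf("i%03d", 1:100), prs_z = 0)
  expect_warning(a2 <- assign_quantiles(d2, k = 10), "identical")
  expect_equal(unname(table(a2$quantile_bin)), rep(10L, 10), ignore_attr = TRUE)
  # n = 5432 + 92344 split into centiles: sizes 977 or 978
  n <- 97776
  d3 <- tibble::tibble(id = sprintf("i%06d", 1:n), prs_z = rnorm(n))
  a3 <- assign_quantiles(d3, k = 100)
  sizes <- table(a3$quantile_bin)
  expect_true(all(sizes %in% c(977L, 978L)))
  expect_equal(length(sizes), 100L)
  expect_error(assign_quantiles(d, k = 101), class = "endoprs_param_error")
})

test_that("per-quantile odds ratios are taken against the reference bin", {
  # bins of 100: reference (10 case, 90 ctrl), bin 2 (20 case, 80 ctrl)
  status <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 20), rep(FALSE, 80))
  d <- tibble::tibble(
    id = sprintf("i%03d", 1:200),
    prs_z = c(rep(0, 100), rep(1, 100))[order(c(rep(1, 100), rep(2, 100)))]
  )
  d$prs_z <- rep(c(0, 1), each = 100)
  asg <- assign_quantiles(d, k = 2)
  tab <- or_by_quantile(asg, status, reference = 1)
  expect_equal(tab$odds_ratio[tab$quantile_bin == 1], 1)
  expect_equal(tab$ci_low[tab$reference], 1)
  expect_equal(tab$odds_ratio[tab$quantile_bin == 2], (20 * 90) / (80 * 10))
  expect_error(or_by_quantile(asg, rep(FALSE, 200), reference = 1),
               class = "endoprs_degenerate_table")
})

test_that("AUC matches brute-force pair counting and its known values", {
  expect_equal(roc_auc(c(1, 3, 0, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  brute <- function(s, y) {
    cs <- s[y]; ct <- s[!y]
    tot <- 0
    for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(cs) * length(ct))
  }
  set.seed(17)
  for (i in 1:25) {
    y <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (all(y) || !any(y)) next
    s <- sample(1:8, 30, replace = TRUE)   # heavy ties
    expect_identical(roc_auc(s, y), brute(s, y))
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "endoprs_degenerate_table")
})

test_that("AUC is rank-invariant and agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- c(rep(TRUE, 40), rep(FALSE, 160))
  s <- rnorm(200) + y
  a_raw <- roc_auc(s, y)
  a_std <- roc_auc(as.vector(scale(s)), y)
  expect_identical(a_raw, a_std)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(a_raw, ref, tolerance = 1e-12)
})

test_that("prevalence by burden handles flat, extreme and capped groupings", {
  # perfectly separated: prevalence 1 and 0 in the two groups
  coh <- manual_cohort(
    codes = c(rep(list(c("A00", "B00", "C00", "E00", "F00")), 5),
              rep(list(character()), 5)),
    endo_case = c(rep(TRUE, 5), rep(FALSE, 5))
  )
  prof <- count_burden(coh, code_set(character(), label = "x"))
  tab <- prevalence_by_burden(coh, prof, metric = "total")
  expect_equal(tab$prevalence[tab$burden == 5], 1)
  expect_equal(tab$prevalence[tab$burden == 0], 0)
  expect_equal(sum(tab$n), 10)
  # burden independent of status: regression of prevalence on count is flat
  coh2 <- simulate_cohort(null_params(n = 30000, seed = 19))
  prof2 <- count_burden(coh2, code_set(character(), label = "x"))
  tab2 <- prevalence_by_burden(coh2, prof2, metric = "total", cap = 15)
  fit <- stats::lm(prevalence ~ burden, data = tab2, weights = tab2$n)
  ci <- stats::confint(fit)["burden", ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})
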