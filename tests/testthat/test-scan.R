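test_that("2x2 association test picks the right method and odds ratio", {
  r <- test_code_association(10, 20, 5, 40)
  expect_equal(r$odds_ratio, 4)
  expect_equal(r$method, "chi_squared")
  r2 <- test_code_association(50, 50, 50, 50)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_value, 1)
  # expected cell below 5 switches to Fisher
  r3 <- test_code_association(1, 3, 2, 94)
  expect_equal(r3$method, "fisher")
  expect_error(test_code_association(0, 0, 5, 5),
               class = "endoprs_degenerate_table")
  # zero-cell sentinels
  expect_equal(test_code_association(5, 5, 0, 90)$odds_ratio, Inf)
  expect_equal(test_code_association(0, 10, 5, 85)$odds_ratio, 0)
  expect_true(is.finite(test_code_association(5, 5, 0, 90,
                                              haldane = TRUE)$odds_ratio))
})

test_that("Fisher p-value matches exhaustive hypergeometric enumeration", {
  # two-sided point-probability method: sum of all table probabilities
  # no larger than the observed one, at fixed margins
  fisher_oracle <- function(a, b, c, d) {
    m1 <- a + b; n1 <- a + c; n <- a + b + c + d
    supp <- max(0, n1 - (n - m1)):min(n1, m1)
    probs <- stats::dhyper(supp, m1, n - m1, n1)
    p_obs <- stats::dhyper(a, m1, n - m1, n1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tables <- list(c(1, 3, 2, 94), c(2, 8, 1, 39), c(0, 5, 3, 12), c(4, 1, 2, 6))
  for (tb in tables) {
    got <- test_code_association(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got$method, "fisher")
    expect_equal(got$p_value,
                 fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("chi-squared p equals the squared-z two-proportion test", {
  tb <- c(40, 160, 60, 340)
  got <- test_code_association(tb[1], tb[2], tb[3], tb[4])
  p1 <- tb[1] / (tb[1] + tb[2]); p2 <- tb[3] / (tb[3] + tb[4])
  n1 <- tb[1] + tb[2]; n2 <- tb[3] + tb[4]
  pp <- (tb[1] + tb[3]) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(got$p_value, 2 * stats::pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("Fisher and chi-squared agree on large expected counts", {
  # force both routes on the same amply-powered table
  m <- matrix(c(120, 380, 90, 410), 2, byrow = TRUE)
  p_chi <- stats::chisq.test(m, correct = FALSE)$p.value
  p_fis <- stats::fisher.test(m)$p.value
  expect_gt(p_fis / p_chi, 0.5)
  expect_lt(p_fis / p_chi, 2)
})

test_that("BH step-up flags follow the hand-applied rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$significant))           # p_(4) = 0.04 <= 4*0.05/4
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_true(bh_fdr(0.04, q = 0.05)$significant)
  expect_equal(nrow(bh_fdr(numeric())), 0)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "endoprs_param_error")
})

test_that("BH flags are monotone in p and adjusted p is nondecreasing", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(50)^2
    r <- bh_fdr(p, q = 0.1)
    sig_max <- suppressWarnings(max(r$p_value[r$significant]))
    if (is.finite(sig_max)) {
      expect_true(all(r$significant[r$p_value <= sig_max]))
    }
    o <- order(r$p_value)
    expect_true(all(diff(r$p_adjusted[o]) >= -1e-15))
  }
})

test_that("the phenome scan finds a loaded comorbidity and is binary per person", {
  p <- fast_params(n = 30000, seed = 21,
                   comorbidities = comorbidity_spec(
                     "target", "D259", 0.08,
                     prs_loading = 0.3, shared_loading = 0.3))
  coh <- simulate_cohort(p)
  scan <- phenome_scan(coh)
  row <- scan[scan$code == "D259", ]
  expect_true(row$fdr_significant)
  expect_equal(row$direction, "increased")
  # margins equal cohort totals for every code
  expect_true(all(scan$case_with + scan$case_without == sum(coh$endo_case)))
  expect_true(all(scan$control_with + scan$control_without == sum(!coh$endo_case)))
})

test_that("a code carried by everyone is not significant", {
  coh <- manual_cohort(
    codes = rep(list(c("I109")), 40),
    endo_case = rep(c(TRUE, FALSE), 20)
  )
  scan <- phenome_scan(coh)
  expect_equal(scan$p_value[scan$code == "I109"], 1)
  expect_false(scan$fdr_significant[scan$code == "I109"])
  # duplicate recordings count once
  coh2 <- manual_cohort(
    codes = list(c("I109", "I109", "J459"), c("J459"), c("I109")),
    endo_case = c(TRUE, FALSE, FALSE)
  )
  scan2 <- phenome_scan(coh2)
  expect_equal(scan2$case_with[scan2$code == "I109"], 1L)
  expect_equal(scan2$control_with[scan2$code == "I109"], 1L)
})

test_that("comorbid-set construction filters direction and exclusions", {
  scan <- tibble::tibble(
    code = c("D259", "O800", "Z001", "K579", "N801", "E109"),
    odds_ratio = c(2.5, 0.4, 3.0, 1.8, 9.0, 0.6),
    fdr_significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    direction = c("increased", "decreased", "increased", "increased",
                  "increased", "decreased")
  )
  attr(scan, "label") <- "A"
  cset <- build_comorbid_set(structure(scan, class = c("endoprs_scan", class(scan))))
  # decreased-risk (pregnancy-type), chapter-21, N80x and non-significant all out
  expect_setequal(cset$code, c("D259", "K579"))
  expect_equal(attr(cset, "label"), "A")
})

test_that("code-set overlap arithmetic matches the two-biobank bookkeeping", {
  a <- code_set(paste0("A", sprintf("%02d", 0:4)), label = "A")
  b <- code_set(paste0("A", sprintf("%02d", 3:9)), label = "B")
  cmp <- compare_code_sets(a, b)
  expect_equal(unlist(cmp), c(n_both = 2L, n_only_a = 3L, n_only_b = 5L))
  expect_equal(unlist(compare_code_sets(a, a)),
               c(n_both = 5L, n_only_a = 0L, n_only_b = 0L))
  d <- code_set(c("B00", "B01", "B02"), label = "D")
  e <- code_set(c("C00", "C01", "C02", "C03", "C04"), label = "E")
  expect_equal(unlist(compare_code_sets(d, e)),
               c(n_both = 0L, n_only_a = 3L, n_only_b = 5L))
})

test_that("chapter proportions use the continuity-corrected two-proportion z", {
  # 40/100 vs 10/100 in chapter 11, closed-form Yates-corrected z
  a <- code_set(c(paste0("K", sprintf("%02d", 0:39)),
                  paste0("A", sprintf("%02d", 0:59))), label = "A")
  b <- code_set(c(paste0("K", sprintf("%02d", 0:9)),
                  paste0("A", sprintf("%02d", 0:89))), label = "B")
  res <- compare_chapter_proportions(a, b)
  row <- res[res$chapter == 11, ]
  pp <- (40 + 10) / 200
  z <- (abs(0.4 - 0.1) - (1 / 100)) / sqrt(pp * (1 - pp) * (2 / 100))
  expect_equal(row$p_value, 2 * stats::pnorm(-z), tolerance = 1e-10)
  # chapters absent from both sets are reported not-applicable
  expect_false(res$applicable[res$chapter == 15])
  # identical compositions: all applicable p = 1
  same <- compare_chapter_proportions(a, a)
  expect_true(all(same$p_value[same$applicable] == 1))
})
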