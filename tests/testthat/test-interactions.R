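test_that("OLS recovers exact fits and matches the normal-equations oracle", {
  x <- 1:5
  # exact fit: lm's "essentially perfect fit" advisory is expected here
  fit <- suppressWarnings(fit_ols(2 + 3 * x, cbind(intercept = 1, x = x)))
  expect_equal(tidy(fit)$estimate, c(2, 3), tolerance = 1e-12)
  expect_equal(glance(fit)$sigma2, 0, tolerance = 1e-20)

  set.seed(41)
  X <- cbind(intercept = 1, a = rnorm(6), b = rnorm(6))
  y <- rnorm(6)
  fit2 <- fit_ols(y, X)
  beta <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(tidy(fit2)$estimate, as.vector(beta), tolerance = 1e-10)
  s2 <- sum((y - X %*% beta)^2) / (6 - 3)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(tidy(fit2)$std_error, unname(se), tolerance = 1e-10)
  tv <- as.vector(beta) / unname(se)
  expect_equal(tidy(fit2)$p_value, 2 * stats::pt(abs(tv), 3, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(fit_ols(y, cbind(a = X[, 2], a_copy = X[, 2], one = 1)),
               "a_copy|a", class = "endoprs_rank_error")
})

test_that("logistic slope on a grouped 2x2 equals the closed-form log odds ratio", {
  x <- c(rep(1, 30), rep(0, 45))
  y <- c(rep(1, 10), rep(0, 20), rep(1, 5), rep(0, 40))
  fit <- fit_logistic(y, cbind(intercept = 1, x = x))
  expect_true(fit$converged)
  expect_equal(tidy(fit)$estimate[2], log(4), tolerance = 1e-6)
  expect_equal(tidy(fit)$estimate[1], log(5 / 40), tolerance = 1e-6)
})

test_that("logistic regression flags separation instead of reporting numbers", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(y, cbind(intercept = 1, x = x))
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_true(all(is.na(tidy(fit)$estimate)))
  expect_error(fit_logistic(rep(1, 5), cbind(intercept = 1, x = 1:5)),
               class = "endoprs_degenerate_table")
  expect_error(fit_logistic(c(0, 1, 0, 1), cbind(a = c(1, 1, 1, 1), b = rep(1, 4))),
               class = "endoprs_rank_error")
})

test_that("null logistic fit returns zero slope and the logit of prevalence", {
  x <- rep(c(-1, 1), each = 50)
  y <- rep(c(0, 1), 50)
  fit <- fit_logistic(y, cbind(intercept = 1, x = x))
  expect_equal(tidy(fit)$estimate[2], 0, tolerance = 1e-8)
  expect_equal(tidy(fit)$estimate[1], stats::qlogis(0.5), tolerance = 1e-8)
})

test_that("logistic and linear-probability slopes keep the 4x relation at p=0.5", {
  set.seed(47)
  n <- 40000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.12 * x))
  lg <- tidy(fit_logistic(y, cbind(intercept = 1, x = x)))$estimate[2]
  ln <- tidy(fit_ols(y, cbind(intercept = 1, x = x)))$estimate[2]
  expect_gt(lg / ln, 3.5)
  expect_lt(lg / ln, 4.5)
})

test_that("Welch t matches the hand formula and its invariances", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- welch_t(a, b)
  va <- stats::var(a) / 3; vb <- stats::var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_equal(got$df, df_hand, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_hand), df_hand),
               tolerance = 1e-10)
  same <- welch_t(c(1, 2, 4), c(1, 2, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  scaled <- welch_t(10 * a, 10 * b)
  expect_equal(scaled$t, got$t, tolerance = 1e-12)
  expect_equal(scaled$p_value, got$p_value, tolerance = 1e-12)
  expect_error(welch_t(1, b), class = "endoprs_param_error")
})

test_that("the burden interaction wrapper equals fit_ols on the explicit design", {
  coh <- simulate_cohort(fast_params(n = 3000, seed = 51))
  prof <- count_burden(coh, true_comorbid_set())
  fit <- burden_prs_interaction(coh, prof, metric = "comorbid")
  endo <- as.numeric(coh$endo_case)
  X <- cbind(intercept = 1, prs = coh$prs_z, endo = endo,
             prs_x_endo = coh$prs_z * endo)
  y <- prof$comorbid_3char[match(coh$id, prof$id)]
  manual <- fit_ols(y, X)
  expect_equal(tidy(fit), tidy(manual))
})

test_that("chapter and leave-one-out scopes partition the overall fit response", {
  coh <- simulate_cohort(fast_params(n = 2500, seed = 53))
  prof <- burden_profiles(coh, true_comorbid_set())
  sweep <- burden_interaction_scan(coh, prof, metric = "total")
  expect_true("all" %in% sweep$scope)
  chapters <- sort(unique(prof$by_chapter$chapter))
  expect_equal(sum(sweep$scope == "chapter"), length(chapters))
  expect_equal(sum(sweep$scope == "leave_out"), length(chapters))
  # for one chapter: chapter fit + loo fit responses sum to the overall response
  ch <- chapters[1]
  f_ch <- burden_prs_interaction(coh, prof, "total", scope = "chapter", chapter = ch)
  f_lo <- burden_prs_interaction(coh, prof, "total", scope = "leave_out", chapter = ch)
  expect_equal(glance(f_ch)$n, nrow(coh))
  expect_equal(glance(f_lo)$n, nrow(coh))
})

test_that("multiplicative interaction surfaces design problems", {
  coh <- simulate_cohort(fast_params(n = 2000, seed = 55))
  coh$has_uterine_fibroids <- FALSE      # constant flag: collinear with nothing
  expect_error(multiplicative_interaction(coh, "uterine_fibroids"),
               class = "endoprs_rank_error")
  expect_error(multiplicative_interaction(coh, "no_such"),
               class = "endoprs_param_error")
})

test_that("multiplicative main effects are positive under the threshold model", {
  coh <- simulate_cohort(fast_params(n = 60000, seed = 57))
  fit <- tidy(multiplicative_interaction(coh, "uterine_fibroids"))
  expect_gt(fit$estimate[fit$term == "prs"], 0)
  expect_gt(fit$estimate[fit$term == "comorbidity"], 0)
  expect_lt(fit$p_value[fit$term == "prs"], 0.05)
  expect_lt(fit$p_value[fit$term == "comorbidity"], 0.05)
})

test_that("additive table reports per-decile differences and flags empty arms", {
  # comorbidity independent of everything: differences near zero
  set.seed(59)
  n <- 20000
  coh <- as_cohort(tibble::tibble(
    id = sprintf("i%05d", 1:n),
    endo_case = rbinom(n, 1, 0.1) == 1,
    age = 50, prs_z = rnorm(n),
    codes = rep(list(character()), n),
    has_x = rbinom(n, 1, 0.3) == 1
  ))
  tab <- additive_interaction(coh, "x")
  # per-decile difference SE is about 1.4 points here; 5 points ~ 3.5 SD
  expect_true(all(abs(tab$difference_pp) < 5))
  expect_equal(tab$difference_pp,
               100 * (tab$prevalence_with - tab$prevalence_without))
  # empty arm: flagged, excluded from the ratio with a warning
  coh$has_x[1:n] <- coh$prs_z > quantile(coh$prs_z, 0.9)
  expect_warning(tab2 <- additive_interaction(coh, "x"), "empty arm")
  expect_true(any(!tab2$ok))
  expect_true(is.na(attr(tab2, "ratio")))
})

test_that("threshold-model differences trend upward across PRS deciles", {
  coh <- simulate_cohort(fast_params(n = 100000, seed = 61))
  tab <- additive_interaction(coh, "uterine_fibroids")
  ct <- stats::cor.test(tab$decile, tab$difference_pp, method = "spearman")
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("an additive-scale gradient can coexist with a non-positive multiplicative term", {
  # the multiplicative statistic depends on baseline risk: rising absolute
  # differences across deciles do not imply a positive odds-scale product term
  coh <- simulate_cohort(fast_params(n = 100000, seed = 1))
  tab <- additive_interaction(coh, "uterine_fibroids")
  expect_gt(attr(tab, "ratio"), 1)
  mult <- tidy(multiplicative_interaction(coh, "uterine_fibroids"))
  expect_lte(mult$estimate[mult$term == "prs_x_comorbidity"], 0)
})

test_that("difference ratio mirrors the published rounding convention", {
  expect_equal(difference_ratio(5.67, 15.57), 2.7)
  expect_equal(difference_ratio(5, 10, digits = 2), 2)
  expect_true(is.na(difference_ratio(0, 10)))
  expect_true(is.na(difference_ratio(NA, 10)))
})
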