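test_that("imputation-model fit reproduces the 2x2 closed forms", {
  d <- counts_2x2_data(40, 30, 20, 10, mis_y0 = 5, mis_y1 = 5)
  fit <- fit_imputation_model(d, x ~ y)
  expect_equal(unname(fit$theta[1]), log(20 / 40), tolerance = 1e-7)
  expect_equal(unname(fit$theta[2]), log(10 * 40 / (30 * 20)), tolerance = 1e-7)
  expect_identical(fit$type, "binary")
  expect_identical(fit$base_level, "0")
  expect_equal(fit$n_obs, 100)
})

test_that("independence of x and y in the complete records gives theta_y near 0", {
  set.seed(51)
  d <- simulate_full_data(20000, beta_x = 0)
  d <- apply_selection(d, selection_spec("M1", 0.2))
  fit <- fit_imputation_model(d, x ~ y)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$theta[2]), 3 * se[2])
})

test_that("empty cells and degenerate fits raise informative estimation errors", {
  d <- counts_2x2_data(40, 30, 0, 0, mis_y0 = 5)
  expect_error(fit_imputation_model(d, x ~ y), "no complete records with x = 1")
  d2 <- counts_2x2_data(40, 0, 0, 30, mis_y0 = 5)  # perfect separation
  expect_error(fit_imputation_model(d2, x ~ y), "separation")
})

test_that("posterior parameter draws follow N(theta_hat, U)", {
  d <- counts_2x2_data(40, 30, 20, 10, mis_y0 = 10)
  fit <- fit_imputation_model(d, x ~ y)
  # degenerate covariance: the draw is the ML estimate
  fit0 <- fit
  fit0$vcov <- matrix(0, 2, 2)
  expect_equal(unname(draw_parameters(fit0)), unname(fit$theta))
  # reproducibility and first-moment recovery
  set.seed(52); a <- draw_parameters(fit)
  set.seed(52); b <- draw_parameters(fit)
  expect_identical(a, b)
  set.seed(53)
  draws <- t(replicate(4000, draw_parameters(fit)))
  mc_se <- sqrt(diag(fit$vcov) / 4000)
  expect_lt(max(abs(colMeans(draws) - fit$theta) / mc_se), 3.5)
})

test_that("nuisance-proportion draws have the stated normal-approximation spread", {
  set.seed(54)
  d <- apply_selection(simulate_full_data(2000), selection_spec("M1", 0.2))
  fit <- fit_imputation_model(d, x ~ y)
  n <- nrow(d); n_obs <- sum(!is.na(d$x))
  p_r_hat <- n_obs / n
  p_x_hat <- mean(d$x[!is.na(d$x)] == "1")
  draws <- replicate(4000, unlist(draw_nuisance_proportions(d, fit)))
  expect_equal(sd(draws["p_r", ]), sqrt(p_r_hat * (1 - p_r_hat) / n),
               tolerance = 0.08)
  expect_equal(sd(draws["p_obs.1", ]), sqrt(p_x_hat * (1 - p_x_hat) / n_obs),
               tolerance = 0.08)
  expect_true(all(draws > 0 & draws < 1))
  # no missing data (or none observed): the response proportion is degenerate
  full <- simulate_full_data(50)
  fitf <- fit  # reuse level bookkeeping
  expect_error(draw_nuisance_proportions(full, fitf), "observed and missing")
})

test_that("categorical nuisance and reference draws live on the simplex", {
  set.seed(55)
  d <- simulate_casestudy_cohort(4000)
  fit <- fit_imputation_model(d, x ~ y)
  nu <- draw_nuisance_proportions(d, fit)
  expect_equal(sum(nu$p_obs), 1)
  expect_true(all(nu$p_obs > 0))
  ref <- population_reference(c(White = 0.6, Asian = 0.18, Black = 0.13,
                                Other = 0.09), "estimated", n_ex = 5000)
  pd <- draw_population_proportion(ref)
  expect_equal(sum(pd), 1)
})

test_that("population-proportion draws are fixed or spread per the external SE", {
  ref_fixed <- population_reference(c("0" = 0.3, "1" = 0.7))
  expect_identical(replicate(5, draw_population_proportion(ref_fixed)["1"]),
                   rep(c("1" = 0.7), 5))
  ref_est <- population_reference(c("0" = 0.3, "1" = 0.7), "estimated",
                                  n_ex = 10000)
  set.seed(56)
  draws <- replicate(4000, draw_population_proportion(ref_est)[["1"]])
  expect_equal(sd(draws), sqrt(0.7 * 0.3 / 10000), tolerance = 0.08)
})

test_that("imputation never alters observed values and is seed-reproducible", {
  set.seed(57)
  d <- apply_selection(simulate_full_data(1500), default_selection_specs()$M4)
  ref <- population_reference(c("0" = 0.3, "1" = 0.7))
  set.seed(58)
  mi <- multiply_impute(d, x ~ y, method = "calibrated", M = 3, ref = ref)
  obs_idx <- !is.na(d$x)
  for (m in 1:3) {
    expect_identical(mi$imputations[[m]]$x[obs_idx], d$x[obs_idx])
    expect_false(anyNA(mi$imputations[[m]]$x))
  }
  # imputations differ across m but the whole list reproduces under the seed
  expect_false(identical(mi$imputations[[1]]$x, mi$imputations[[2]]$x))
  set.seed(58)
  mi2 <- multiply_impute(d, x ~ y, method = "calibrated", M = 3, ref = ref)
  expect_identical(mi$imputations, mi2$imputations)
  expect_error(multiply_impute(d, x ~ y, method = "standard", M = 1), "M >= 2")
})

test_that("a zero offset in the calibrated path reproduces standard MI draws", {
  set.seed(59)
  d <- apply_selection(simulate_full_data(1000), default_selection_specs()$M3)
  fit <- fit_imputation_model(d, x ~ y)
  set.seed(60)
  std <- impute_once(d, fit, method = "standard")
  set.seed(60)
  cal0 <- impute_once(d, fit, method = "calibrated", delta = 0)
  expect_identical(std$x, cal0$x)
})

test_that("no-missing input passes through unchanged", {
  d <- simulate_full_data(200, seed = 61)
  fit <- fit_imputation_model(
    apply_selection(simulate_full_data(500, seed = 61), selection_spec("M1", 0)),
    x ~ y)
  out <- impute_once(d, fit, method = "standard")
  expect_identical(out$x, d$x)
})

test_that("calibrated MI recovers the reference marginal; standard MI stays biased under M3", {
  set.seed(62)
  d <- apply_selection(simulate_full_data(5000), default_selection_specs()$M3)
  ref <- population_reference(c("0" = 0.3, "1" = 0.7))
  cal <- multiply_impute(d, x ~ y, method = "calibrated", M = 10, ref = ref)
  cal_props <- vapply(cal$imputations, function(z) mean(z$x == "1"), 0)
  # defining property: across-imputation mean marginal matches the reference
  expect_lt(abs(mean(cal_props) - 0.7), 3 * sqrt(0.7 * 0.3 / 5000) + sd(cal_props))
  std <- multiply_impute(d, x ~ y, method = "standard", M = 10)
  std_props <- vapply(std$imputations, function(z) mean(z$x == "1"), 0)
  # under M3 respondents underrepresent x = 1, and standard MI inherits that
  expect_lt(mean(std_props), 0.7 - 0.03)
  # brute-force expectation: observed part plus the complete-record model's
  # mean prediction over the nonrespondents
  fit <- fit_imputation_model(d, x ~ y)
  p_model <- mean(plogis(fit$theta[1] + fit$theta[2] * d$y[is.na(d$x)]))
  expected <- mean(d$r) * mean(d$x == "1", na.rm = TRUE) +
    (1 - mean(d$r)) * p_model
  expect_equal(mean(std_props), expected, tolerance = 0.02)
})

test_that("complete-record coefficients are untouched by the offset construction", {
  set.seed(63)
  d <- apply_selection(simulate_full_data(3000), default_selection_specs()$M4)
  fit <- fit_imputation_model(d, x ~ y)
  cr <- d[!is.na(d$x), ]
  # refit with an explicit zero offset on the records the model sees:
  # identical ML estimates, as the offset only acts on nonrespondent predictions
  refit <- glm(I(x == "1") ~ y + offset(rep(0, nrow(cr))), family = binomial(),
               data = cr)
  expect_equal(unname(coef(refit)), unname(fit$theta), tolerance = 1e-8)
  ref <- population_reference(c("0" = 0.3, "1" = 0.7))
  mi <- multiply_impute(d, x ~ y, method = "calibrated", M = 2, ref = ref)
  expect_identical(mi$fit$theta, fit$theta)
})

test_that("complete records and single imputation behave as documented", {
  set.seed(64)
  d <- apply_selection(simulate_full_data(2000), default_selection_specs()$M1)
  cr <- complete_records(d)
  expect_identical(nrow(cr), sum(!is.na(d$x)))
  full <- simulate_full_data(50, seed = 65)
  expect_identical(complete_records(full), full)
  all_mis <- d; all_mis$x[] <- NA
  expect_error(complete_records(all_mis), "no complete records")

  si <- single_impute_reference(d, "0")
  expect_identical(sum(si$x == "0"),
                   sum(d$x == "0", na.rm = TRUE) + sum(is.na(d$x)))
  expect_identical(single_impute_reference(full, "1")$x, full$x)
  expect_error(single_impute_reference(d, "White"), "not a declared level")
})

test_that("multinomial calibrated MI recovers a 4-level reference distribution", {
  set.seed(66)
  d <- simulate_casestudy_cohort(8000)
  probs <- c(White = 0.6, Asian = 0.18, Black = 0.13, Other = 0.09)
  ref <- population_reference(probs)
  mi <- multiply_impute(d, x ~ y + age_group + sex + townsend,
                        method = "calibrated", M = 5, ref = ref)
  completed <- rowMeans(vapply(mi$imputations,
                               function(z) as.numeric(prop.table(table(z$x))),
                               numeric(4)))
  expect_lt(max(abs(completed - probs)), 0.02)
  # observed data alone are visibly off the reference (MNAR by construction)
  expect_gt(prop.table(table(d$x))[["White"]], probs[["White"]] + 0.02)
})
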