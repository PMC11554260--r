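test_that("model specs build the intended fixed and random structure", {
  s <- model_spec("degree", interaction = "type_availability")
  f <- deparse1(build_formula(s))
  expect_match(f, "food_type \\* food_availability")
  expect_match(f, "1 \\| individual_id")
  expect_match(f, "1 \\| frame_rate_bin")

  g <- model_spec("density", level = "group")
  fg <- deparse1(build_formula(g))
  expect_match(fg, "mean_frame_rate_ips")
  expect_false(grepl("individual_id", fg))

  p <- model_spec("degree", interaction = "none", poly_group_size = TRUE)
  expect_match(deparse1(build_formula(p)), "poly\\(group_size, 2\\)")
  expect_error(model_spec("x", interaction = "three_way",
                          poly_group_size = TRUE),
               class = "troph_invalid_spec")

  cands <- candidate_specs("degree", include_poly = TRUE)
  expect_length(cands, 6)
  expect_named(cands, c("none", "type_availability", "size_type",
                        "size_availability", "three_way", "poly_none"))
})

test_that("when random variances profile to zero the LMM reproduces OLS coefficients", {
  cfg <- effect_config(n_groups = 12, trials_per_group = 2, n_per_group = 8,
                       sd_group = 0, sd_individual = 0, sd_frame_rate = 0,
                       sd_resid = 1, seed = 1)
  d <- simulate_measures(cfg)
  spec <- model_spec("degree_like", interaction = "type_availability")
  fit <- suppressWarnings(fit_lmm(spec, d, criterion = "ML"))
  # premise of the identity: the profiled variance components hit zero
  expect_true(all(fit$random_variances < 1e-10))
  ols <- stats::lm(degree_like ~ group_size + food_type * food_availability,
                   data = d)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("AIC identity 2k - 2 logLik holds for every fit", {
  d <- simulate_measures(effect_config(n_groups = 15, n_per_group = 8,
                                       seed = 3))
  for (spec in candidate_specs("degree_like")) {
    fit <- fit_lmm(spec, d, criterion = "ML")
    expect_equal(fit$aic, 2 * fit$k - 2 * fit$logLik, tolerance = 1e-10)
    expect_equal(fit$aic, stats::AIC(fit$model), tolerance = 1e-10)
  }
})

test_that("a constant response gives zero variance components and zero slopes", {
  d <- simulate_measures(effect_config(n_groups = 10, n_per_group = 6,
                                       seed = 4))
  d$degree_like <- 7
  fit <- suppressWarnings(
    fit_lmm(model_spec("degree_like", interaction = "none"), d))
  expect_true(all(abs(fit$coefficients$estimate[-1]) < 1e-8))
  expect_true(all(fit$random_variances < 1e-8))
})

test_that("type II Wald chi-square equals the squared z for a single-df term", {
  d <- simulate_measures(effect_config(seed = 10))
  fit <- fit_lmm(model_spec("degree_like", interaction = "none"), d)
  w <- wald_type2_anova(fit)
  co <- fit$coefficients
  for (term in c("group_size", "food_type", "food_availability")) {
    row <- co[grep(term, co$term), ][1, ]
    expect_equal(w$chisq[w$term == term], (row$estimate / row$se)^2,
                 tolerance = 1e-8)
    expect_equal(w$df[w$term == term], 1)
  }
})

test_that("the three-way Wald table lists all seven terms and is order-invariant", {
  d <- simulate_measures(effect_config(n_groups = 20, n_per_group = 10,
                                       seed = 12))
  fit <- fit_lmm(model_spec("degree_like", interaction = "three_way"), d)
  w <- wald_type2_anova(fit)
  expect_equal(nrow(w), 7)
  expect_true(all(w$chisq >= 0))
  # same model with main effects listed in a different order
  f2 <- stats::as.formula(
    "degree_like ~ food_availability * food_type * group_size +
     (1 | group_id) + (1 | individual_id) + (1 | frame_rate_bin)")
  m2 <- lme4::lmer(f2, data = d, REML = TRUE)
  w2 <- car::Anova(m2, type = "II", test.statistic = "Chisq")
  for (term in c("group_size", "food_type", "food_availability")) {
    i2 <- grep(paste0("^", term, "$"), rownames(w2))
    expect_equal(w$chisq[w$term == term], w2$Chisq[i2], tolerance = 1e-6)
  }
})

test_that("AIC selection ranks candidates, breaks ties to fewer parameters, and refits under REML", {
  cfg <- effect_config(n_groups = 25, n_per_group = 10, seed = 20)
  d <- simulate_measures(cfg)
  sel <- suppressWarnings(select_model_aic(candidate_specs("degree_like"), d))
  expect_equal(sel$best_name, "type_availability")
  expect_equal(sel$table$candidate[1], "type_availability")
  expect_true(all(diff(sel$table$aic[sel$table$converged]) >= 0))
  expect_equal(sel$best_fit$criterion, "REML")

  # exact tie: duplicated candidate resolves to the first, deterministically
  two <- list(a = model_spec("degree_like", interaction = "none"),
              b = model_spec("degree_like", interaction = "none"))
  tie <- suppressWarnings(select_model_aic(two, d, refit_best = FALSE))
  expect_equal(tie$best_name, "a")
})

test_that("the gamma log-link GLMM recovers a planted log-scale slope", {
  slopes <- numeric(20)
  for (r in seq_len(20)) {
    cfg <- effect_config(n_groups = 40, trials_per_group = 2,
                         n_per_group = 10, gamma_beta_group_size = 0.05,
                         gamma_sd_group = 0.1, gamma_sd_individual = 0.1,
                         seed = 100 + r)
    d <- simulate_measures(cfg)
    fit <- suppressWarnings(fit_glmm_gamma_log(
      model_spec("betweenness_like", family = "gamma_log",
                 interaction = "none"), d))
    slopes[r] <- fit$coefficients$estimate[
      fit$coefficients$term == "group_size"]
  }
  expect_lt(abs(mean(slopes) - 0.05) / 0.05, 0.10)
})

test_that("gamma zero handling shifts, drops, or errors as requested", {
  d <- simulate_measures(effect_config(n_groups = 12, trials_per_group = 1,
                                       n_per_group = 6, seed = 30))
  d$betweenness_like[1:5] <- 0
  spec <- model_spec("betweenness_like", family = "gamma_log",
                     interaction = "none")
  expect_error(fit_glmm_gamma_log(spec, d, zero_handling = "error"),
               class = "troph_nonpositive_response")
  fshift <- suppressWarnings(fit_glmm_gamma_log(spec, d,
                                                zero_handling = "shift"))
  expect_equal(fshift$zero_handling, "shift")
  expect_equal(nrow(stats::model.frame(fshift$model)), nrow(d))
  fdrop <- suppressWarnings(fit_glmm_gamma_log(spec, d,
                                               zero_handling = "drop"))
  expect_equal(nrow(stats::model.frame(fdrop$model)), nrow(d) - 5)
  # near-constant positive response: slope ~ 0, intercept ~ log(level)
  d2 <- d
  set.seed(1)
  d2$betweenness_like <- 3 * exp(stats::rnorm(nrow(d2), 0, 0.1))
  f2 <- suppressWarnings(fit_glmm_gamma_log(spec, d2))
  expect_lt(abs(f2$coefficients$estimate[
    f2$coefficients$term == "group_size"]), 5e-3)
  expect_equal(f2$coefficients$estimate[1], log(3), tolerance = 0.05)
})

test_that("R2 components partition variance and respect their bounds", {
  d <- simulate_measures(effect_config(seed = 17))
  fit <- fit_lmm(model_spec("degree_like",
                            interaction = "type_availability"), d)
  r2 <- r2_components(fit)
  expect_gte(r2$marginal, 0)
  expect_lte(r2$marginal, r2$conditional)
  expect_lte(r2$conditional, 1)
  expect_equal(r2$random_explained_pct,
               100 * (r2$conditional - r2$marginal))

  # variances profiled to zero: conditional collapses onto marginal
  cfg0 <- effect_config(n_groups = 12, trials_per_group = 2, n_per_group = 8,
                        sd_group = 0, sd_individual = 0, sd_frame_rate = 0,
                        seed = 1)
  d0 <- simulate_measures(cfg0)
  fit0 <- suppressWarnings(fit_lmm(model_spec("degree_like",
                                              interaction = "type_availability"),
                                   d0))
  expect_true(all(fit0$random_variances < 1e-10))
  r20 <- r2_components(fit0)
  expect_lt(r20$random_explained_pct, 1e-6)
})

test_that("with equal group and residual variance and no fixed effects, the random share approaches 50%", {
  cfg <- effect_config(n_groups = 150, trials_per_group = 2, n_per_group = 15,
                       beta_group_size = 0, beta_food_type = 0,
                       beta_availability = 0, beta_interaction = 0,
                       sd_group = 1, sd_individual = 0, sd_frame_rate = 0,
                       sd_resid = 1, seed = 23)
  d <- simulate_measures(cfg)
  fit <- suppressWarnings(fit_lmm(model_spec("degree_like",
                                             interaction = "none"), d))
  r2 <- r2_components(fit)
  expect_lt(abs(r2$random_explained_pct - 50), 5)
  expect_lt(r2$marginal, 0.02)
})

test_that("marginal-mean contrasts reproduce the model's cell differences with Satterthwaite df", {
  cfg <- effect_config(seed = 19)
  d <- simulate_measures(cfg)
  fit <- fit_lmm(model_spec("degree_like",
                            interaction = "type_availability"), d)
  ct <- emm_contrasts(fit, within = "food_type",
                      compare = "food_availability")
  expect_equal(nrow(ct), 2)
  expect_equal(ct$t_ratio, ct$estimate / ct$se, tolerance = 1e-8)
  expect_true(all(is.finite(ct$df) & ct$df > 0))
  expect_false(any(ct$df == round(ct$df)))  # fractional Satterthwaite df

  # dummy-coded identities: the availability contrast within carbohydrate is
  # -beta_availability; within protein it also subtracts the interaction
  co <- fit$coefficients
  b_fa <- co$estimate[co$term == "food_availabilityunlimited"]
  b_int <- co$estimate[
    co$term == "food_typeprotein:food_availabilityunlimited"]
  sgn <- if (startsWith(ct$contrast[1], "limited")) -1 else 1
  expect_equal(ct$estimate[ct$within_level == "carbohydrate"], sgn * b_fa,
               tolerance = 1e-8)
  expect_equal(ct$estimate[ct$within_level == "protein"],
               sgn * (b_fa + b_int), tolerance = 1e-8)

  expect_error(emm_contrasts(fit, within = "nope", compare = "food_type"),
               class = "troph_missing_factor")
})
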