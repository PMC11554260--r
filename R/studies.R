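# Seeded simulation studies validating the statistical stack by parameter
# recovery, model-selection consistency, and null calibration.  Each study
# draws per-replicate seeds from one master seed so results are exactly
# reproducible.

replicate_seeds <- function(n, seed) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

# planted value of each fixed-effect coefficient, by lme4 coefficient name
true_coefs <- function(cfg) {
  c("(Intercept)" = cfg$beta0,
    group_size = cfg$beta_group_size,
    food_typeprotein = cfg$beta_food_type,
    food_availabilityunlimited = cfg$beta_availability,
    "food_typeprotein:food_availabilityunlimited" = cfg$beta_interaction)
}

#' Fixed-effect recovery study for the LMM stack
#'
#' Repeatedly simulates measure tables from a known effect structure
#' ([simulate_measures()]), fits the type-by-availability LMM, and collects
#' fixed-effect estimates, Wald 95% confidence-interval coverage, and the
#' estimated-marginal-means interaction contrast (the difference between the
#' availability contrast in the protein cell and in the carbohydrate cell,
#' whose truth is the planted interaction coefficient).
#'
#' @param n_reps number of replicates.
#' @param cfg an [effect_config()]; its `seed` field is overridden per
#'   replicate.
#' @param response which simulated response to analyse.
#' @param seed master seed.
#' @return list with `mean_estimates`, `true_values`, `coverage` (per
#'   coefficient), `emm_interaction_mean`, `emm_interaction_se` (Monte-Carlo
#'   standard error of that mean), and the per-replicate `estimates` matrix.
#' @export
run_recovery_study <- function(n_reps = 500, cfg = effect_config(),
                               response = "degree_like", seed = 1L) {
  seeds <- replicate_seeds(n_reps, seed)
  truth <- true_coefs(cfg)
  est <- matrix(NA_real_, n_reps, length(truth),
                dimnames = list(NULL, names(truth)))
  covered <- matrix(NA, n_reps, length(truth),
                    dimnames = list(NULL, names(truth)))
  emm_int <- numeric(n_reps)
  z <- stats::qnorm(0.975)
  spec <- model_spec(response, level = "individual",
                     interaction = "type_availability")
  for (r in seq_len(n_reps)) {
    cfg$seed <- seeds[r]
    d <- simulate_measures(cfg)
    fit <- fit_lmm(spec, d, criterion = "REML")
    co <- fit$coefficients
    idx <- match(names(truth), co$term)
    est[r, ] <- co$estimate[idx]
    covered[r, ] <- abs(co$estimate[idx] - truth) <= z * co$se[idx]
    ct <- emm_contrasts(fit, within = "food_type",
                        compare = "food_availability",
                        df_method = "asymptotic")
    sgn <- if (startsWith(ct$contrast[1], "limited")) 1 else -1
    e_carb <- ct$estimate[ct$within_level == "carbohydrate"]
    e_prot <- ct$estimate[ct$within_level == "protein"]
    emm_int[r] <- sgn * (e_carb - e_prot)
  }
  list(mean_estimates = colMeans(est), true_values = truth,
       coverage = colMeans(covered),
       emm_interaction_mean = mean(emm_int),
       emm_interaction_se = stats::sd(emm_int) / sqrt(n_reps),
       estimates = est)
}

#' AIC model-selection consistency study
#'
#' Generates data whose fixed-effect structure is one of the five candidate
#' structures and records how often AIC selection recovers it.
#'
#' @param n_reps number of replicates.
#' @param truth generating structure: `"none"` (interaction coefficient set
#'   to 0) or `"type_availability"` (the planted interaction retained).
#' @param cfg an [effect_config()]; `seed` overridden per replicate, and
#'   `beta_interaction` zeroed when `truth = "none"`.
#' @param response which simulated response to analyse.
#' @param seed master seed.
#' @return list with `selection_rate` (fraction of replicates selecting the
#'   generating structure) and `picks` (per-replicate winners).
#' @export
run_selection_study <- function(n_reps = 200,
                                truth = c("none", "type_availability"),
                                cfg = effect_config(), response = "degree_like",
                                seed = 1L) {
  truth <- match.arg(truth)
  if (truth == "none") cfg$beta_interaction <- 0
  seeds <- replicate_seeds(n_reps, seed)
  specs <- candidate_specs(response, level = "individual")
  picks <- character(n_reps)
  for (r in seq_len(n_reps)) {
    cfg$seed <- seeds[r]
    d <- simulate_measures(cfg)
    sel <- suppressWarnings(select_model_aic(specs, d, refit_best = FALSE))
    picks[r] <- sel$best_name
  }
  list(selection_rate = mean(picks == truth), picks = picks)
}

#' Null calibration of the type II Wald chi-square test
#'
#' Simulates data in which one term has a true effect of zero, fits the
#' no-interaction LMM, and collects that term's Wald chi-square statistic;
#' under the null the statistics should follow a chi-square distribution
#' with the term's degrees of freedom.
#'
#' @param n_reps number of replicates.
#' @param cfg an [effect_config()]; the tested term's coefficient (and the
#'   interaction) are zeroed.
#' @param term fixed-effect term whose null distribution is checked.
#' @param response which simulated response to analyse.
#' @param seed master seed.
#' @return list with `chisq` (per-replicate statistics), `df`, and `ks_p`
#'   (Kolmogorov-Smirnov p-value against the reference chi-square).
#' @export
run_wald_null_study <- function(n_reps = 1000, cfg = effect_config(),
                                term = "food_type", response = "degree_like",
                                seed = 1L) {
  cfg$beta_interaction <- 0
  if (term == "food_type") cfg$beta_food_type <- 0
  if (term == "food_availability") cfg$beta_availability <- 0
  if (term == "group_size") cfg$beta_group_size <- 0
  seeds <- replicate_seeds(n_reps, seed)
  spec <- model_spec(response, level = "individual", interaction = "none")
  chisq <- numeric(n_reps)
  df <- NA_integer_
  for (r in seq_len(n_reps)) {
    cfg$seed <- seeds[r]
    d <- simulate_measures(cfg)
    fit <- fit_lmm(spec, d, criterion = "REML")
    # occasional convergence notes on single replicates are not actionable
    # inside a 1000-replicate calibration sweep
    w <- suppressWarnings(wald_type2_anova(fit))
    row <- w[w$term == term, ]
    chisq[r] <- row$chisq
    df <- row$df
  }
  ks <- stats::ks.test(chisq, stats::pchisq, df = df)
  list(chisq = chisq, df = df, ks_p = ks$p.value)
}

#' Interaction-recovery study on the trajectory simulator
#'
#' Simulates full tracking trials with planted head-to-head interactions in
#' noiseless mode, runs the trajectory-to-network inference at the operating
#' threshold, and counts false-positive and false-negative edges against the
#' simulator's ground truth.
#'
#' @param n_trials trials per seed.
#' @param seeds integer vector of master seeds.
#' @param duration_s trial duration (short trials keep the choreography
#'   feasible and the study desk-scale).
#' @param threshold_px detection threshold applied.
#' @return list with `false_positives`, `false_negatives`, `n_trials`,
#'   `n_planted_edges`.
#' @export
run_interaction_recovery_study <- function(n_trials = 20,
                                           seeds = 1:5,
                                           duration_s = 420,
                                           threshold_px = 102) {
  fp <- 0L; fn <- 0L; n_planted <- 0L; total <- 0L
  for (s in seeds) {
    expt <- simulate_experiment(n_trials = n_trials, seed = s,
                                duration_s = duration_s)
    for (tr in expt$trials) {
      traj <- build_trajectories(tr$detections)
      edges <- detect_interactions(traj, threshold_px = threshold_px)
      got <- pair_key(edges$ant_i, edges$ant_j)
      want <- pair_key(tr$ground_truth$interacting_pairs$ant_i,
                       tr$ground_truth$interacting_pairs$ant_j)
      fp <- fp + length(setdiff(got, want))
      fn <- fn + length(setdiff(want, got))
      n_planted <- n_planted + length(want)
      total <- total + 1L
    }
  }
  list(false_positives = fp, false_negatives = fn,
       n_trials = total, n_planted_edges = n_planted)
}
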