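#' Specify a mixed model for one behavioral measure
#'
#' Fixed effects are group size (continuous), food type, and food
#' availability, with one of five interaction structures: none, one of the
#' three pairwise interactions, or the full three-way factorial (interaction
#' terms always carry their marginal main effects).  Group size can
#' optionally enter as a second-degree polynomial.  The random structure
#' follows the measurement level: group-level responses (density, cluster
#' count) get a group random intercept with mean frame rate as a fixed
#' covariate; individual-level responses (degree, betweenness, distance) get
#' group, individual, and frame-rate-bin random intercepts.
#'
#' @param response name of the response column.
#' @param level `"individual"` or `"group"`.
#' @param family `"gaussian"` (identity link LMM) or `"gamma_log"` (gamma
#'   GLMM with log link, for positive skewed responses like betweenness).
#' @param interaction one of `"none"`, `"type_availability"`, `"size_type"`,
#'   `"size_availability"`, `"three_way"`.
#' @param poly_group_size if `TRUE`, group size enters as a second-degree
#'   polynomial (only with `interaction = "none"`).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response,
                       level = c("individual", "group"),
                       family = c("gaussian", "gamma_log"),
                       interaction = c("none", "type_availability",
                                       "size_type", "size_availability",
                                       "three_way"),
                       poly_group_size = FALSE) {
  level <- match.arg(level)
  family <- match.arg(family)
  interaction <- match.arg(interaction)
  if (poly_group_size && interaction != "none") {
    troph_error("invalid_spec",
                "polynomial group size is only offered without interactions")
  }
  structure(list(response = response, level = level, family = family,
                 interaction = interaction,
                 poly_group_size = poly_group_size),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s ~ %s [%s, %s level]\n", x$response,
              fixed_terms(x), x$family, x$level))
  invisible(x)
}

fixed_terms <- function(spec) {
  gs <- if (spec$poly_group_size) "poly(group_size, 2)" else "group_size"
  switch(spec$interaction,
    none = paste(gs, "+ food_type + food_availability"),
    type_availability = paste(gs, "+ food_type * food_availability"),
    size_type = paste(gs, "* food_type + food_availability"),
    size_availability = paste(gs, "* food_availability + food_type"),
    three_way = paste(gs, "* food_type * food_availability"))
}

#' Model formula implied by a spec
#'
#' @param spec a [model_spec()].
#' @return a formula including the random-effect terms.
#' @export
build_formula <- function(spec) {
  rand <- if (spec$level == "individual") {
    "(1 | group_id) + (1 | individual_id) + (1 | frame_rate_bin)"
  } else {
    "mean_frame_rate_ips + (1 | group_id)"
  }
  stats::as.formula(paste(spec$response, "~", fixed_terms(spec), "+", rand),
                    env = globalenv())
}

new_fit_result <- function(model, spec, criterion, converged,
                           notes = character(0), data = NULL) {
  ll <- stats::logLik(model)
  k <- attr(ll, "df")
  fe <- lme4::fixef(model)
  # vcov can fail on degenerate fits (e.g. constant response); keep the fit
  se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(model)))),
                 error = function(e) rep(NA_real_, length(fe)))
  vc <- lme4::VarCorr(model)
  rand_var <- vapply(vc, function(m) m[1, 1], numeric(1))
  structure(list(
    model = model, spec = spec, criterion = criterion,
    coefficients = data.frame(term = names(fe), estimate = as.numeric(fe),
                              se = as.numeric(se), stringsAsFactors = FALSE),
    random_variances = rand_var,
    sigma = stats::sigma(model),
    logLik = as.numeric(ll), k = k,
    aic = 2 * k - 2 * as.numeric(ll),
    converged = converged, notes = notes, data = data
  ), class = "troph_fit")
}

#' @export
print.troph_fit <- function(x, ...) {
  cat(sprintf("<troph_fit> %s (%s, %s): AIC %.2f, logLik %.2f, k %d%s\n",
              x$spec$response, x$spec$family, x$criterion, x$aic, x$logLik,
              x$k, if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

check_spec_columns <- function(spec, data) {
  need <- c(spec$response, "group_size", "food_type", "food_availability",
            "group_id",
            if (spec$level == "individual") c("individual_id", "frame_rate_bin")
            else "mean_frame_rate_ips")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    troph_error("missing_column",
                sprintf("data lacks columns: %s", paste(miss, collapse = ", ")))
  }
  for (g in intersect(c("group_id", "individual_id", "frame_rate_bin"), need)) {
    if (length(unique(data[[g]])) < 2) {
      troph_warn("degenerate_grouping",
                 sprintf("random grouping factor '%s' has < 2 levels; its variance is pinned at 0", g))
    }
  }
  invisible(TRUE)
}

# fit and capture convergence / singularity messages without failing
quiet_fit <- function(expr) {
  notes <- character(0)
  model <- withCallingHandlers(
    expr,
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  conv <- !any(grepl("failed to converge|unable to evaluate|degenerate",
                     notes, ignore.case = TRUE))
  list(model = model, converged = conv, notes = notes)
}

#' Fit a linear mixed model
#'
#' @param spec a [model_spec()] with Gaussian family.
#' @param data the measure table (e.g. from [assemble_measures()] or
#'   [simulate_measures()]).
#' @param criterion `"REML"` (for reported coefficients) or `"ML"` (for AIC
#'   comparison of fixed-effect structures).
#' @return a `troph_fit`: the lme4 model plus extracted coefficients,
#'   variance components, log-likelihood, AIC (= 2k - 2 logLik), and a
#'   convergence flag.
#' @export
fit_lmm <- function(spec, data, criterion = c("REML", "ML")) {
  stopifnot(inherits(spec, "model_spec"), spec$family == "gaussian")
  criterion <- match.arg(criterion)
  check_spec_columns(spec, data)
  f <- build_formula(spec)
  # individuals measured once make their intercept variance inseparable from
  # the residual; the fit is still valid, so relax lme4's level-count check
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore")
  q <- quiet_fit(lme4::lmer(f, data = data, REML = criterion == "REML",
                            control = ctrl))
  new_fit_result(q$model, spec, criterion, q$converged, q$notes, data = data)
}

#' Fit a gamma log-link generalized linear mixed model
#'
#' Used for betweenness, whose positive skewed scale suits a multiplicative
#' model.  The gamma family requires strictly positive responses; ants on no
#' shortest path have betweenness 0, so a zero-handling rule is applied
#' first and recorded on the result.
#'
#' @param spec a [model_spec()] with `family = "gamma_log"`.
#' @param data the measure table.
#' @param zero_handling `"shift"` (add `shift` to every response, default),
#'   `"drop"` (drop non-positive rows), or `"error"`.
#' @param shift constant added under `"shift"`.
#' @return a `troph_fit` (Laplace approximation); `fit$zero_handling`
#'   records the rule applied.
#' @export
fit_glmm_gamma_log <- function(spec, data,
                               zero_handling = c("shift", "drop", "error"),
                               shift = 1) {
  stopifnot(inherits(spec, "model_spec"), spec$family == "gamma_log")
  zero_handling <- match.arg(zero_handling)
  check_spec_columns(spec, data)
  y <- data[[spec$response]]
  if (any(y <= 0)) {
    if (zero_handling == "error") {
      troph_error("nonpositive_response",
                  "gamma family needs positive responses; zeros present")
    } else if (zero_handling == "drop") {
      data <- data[y > 0, , drop = FALSE]
    } else {
      data[[spec$response]] <- y + shift
    }
  }
  f <- build_formula(spec)
  ctrl <- lme4::glmerControl(check.nobs.vs.nlev = "ignore",
                             check.nobs.vs.rankZ = "ignore",
                             check.nobs.vs.nRE = "ignore",
                             check.response.not.const = "ignore")
  q <- quiet_fit(lme4::glmer(f, data = data,
                             family = stats::Gamma(link = "log"),
                             control = ctrl))
  out <- new_fit_result(q$model, spec, "ML", q$converged, q$notes,
                        data = data)
  out$zero_handling <- zero_handling
  out
}

fit_spec <- function(spec, data, criterion = "REML", ...) {
  if (spec$family == "gaussian") fit_lmm(spec, data, criterion = criterion)
  else fit_glmm_gamma_log(spec, data, ...)
}

#' The five candidate fixed-effect structures
#'
#' @inheritParams model_spec
#' @param include_poly also include the second-degree-polynomial group-size
#'   candidate (a supplementary comparison).
#' @return named list of [model_spec()]s.
#' @export
candidate_specs <- function(response, level = "individual",
                            family = "gaussian", include_poly = FALSE) {
  structures <- c("none", "type_availability", "size_type",
                  "size_availability", "three_way")
  out <- lapply(structures, function(s) {
    model_spec(response, level = level, family = family, interaction = s)
  })
  names(out) <- structures
  if (include_poly) {
    out$poly_none <- model_spec(response, level = level, family = family,
                                interaction = "none", poly_group_size = TRUE)
  }
  out
}

#' AIC model selection over candidate fixed-effect structures
#'
#' Fits every candidate by maximum likelihood (structures differ in their
#' fixed effects, so ML rather than REML likelihoods are compared), ranks
#' them by AIC, and returns the winner together with the full table.  Ties
#' are broken toward fewer parameters, then by candidate order, for
#' determinism.  Candidates that fail to converge are excluded with a
#' warning.  The winner is refit under REML (Gaussian families) so that its
#' reported coefficients follow standard practice.
#'
#' @param specs list of candidate [model_spec()]s (e.g. [candidate_specs()]).
#' @param data the measure table.
#' @param refit_best refit the winner under REML (Gaussian only); set
#'   `FALSE` to skip when only the selection itself is of interest.
#' @param ... passed on to [fit_glmm_gamma_log()] for gamma families.
#' @return list with `best_name`, `best_spec`, `best_fit` (REML refit for
#'   Gaussian, the ML fit for gamma), and `table` (candidate, AIC, k,
#'   logLik, converged), ordered by AIC.
#' @export
select_model_aic <- function(specs, data, refit_best = TRUE, ...) {
  stopifnot(length(specs) >= 1)
  fits <- lapply(specs, function(sp) {
    tryCatch(fit_spec(sp, data, criterion = "ML", ...),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  conv <- ok & vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv)) {
    troph_warn("nonconverged_candidate",
               sprintf("candidates excluded from selection: %s",
                       paste(names(specs)[!conv], collapse = ", ")))
  }
  if (!any(conv)) troph_error("nonconvergence", "no candidate converged")
  tab <- data.frame(
    candidate = names(specs),
    aic = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$aic,
                 numeric(1)),
    k = vapply(fits, function(f) if (inherits(f, "error")) NA_integer_ else f$k,
               integer(1)),
    logLik = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$logLik,
                    numeric(1)),
    converged = conv,
    stringsAsFactors = FALSE
  )
  eligible <- which(conv)
  ord <- eligible[order(tab$aic[eligible], tab$k[eligible], eligible)]
  best_i <- ord[1]
  tab <- tab[order(!tab$converged, tab$aic, tab$k), ]
  rownames(tab) <- NULL
  best_spec <- specs[[best_i]]
  best_fit <- if (best_spec$family == "gaussian" && refit_best) {
    fit_lmm(best_spec, data, criterion = "REML")
  } else {
    fits[[best_i]]
  }
  list(best_name = names(specs)[best_i], best_spec = best_spec,
       best_fit = best_fit, table = tab)
}

#' Type II Wald chi-square analysis of deviance
#'
#' Per fixed-effect term, a Wald chi-square test respecting type-II
#' marginality: each term is tested after all other terms of equal or lower
#' order, ignoring its own higher-order relatives.
#'
#' @param fit a `troph_fit`.
#' @return data frame with columns `term, chisq, df, p`.
#' @export
wald_type2_anova <- function(fit) {
  stopifnot(inherits(fit, "troph_fit"))
  if (!fit$converged) {
    troph_warn("nonconverged_fit", "Wald table computed on a non-converged fit")
  }
  a <- car::Anova(fit$model, type = "II", test.statistic = "Chisq")
  data.frame(term = rownames(a), chisq = a[["Chisq"]], df = a[["Df"]],
             p = a[["Pr(>Chisq)"]], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R-squared (Nakagawa & Schielzeth): marginal R2 is the
#' fixed-effect variance over the total (fixed + summed random intercepts +
#' residual); conditional R2 adds the random-intercept variances to the
#' numerator.  The variance explained by the random effects is reported as
#' conditional minus marginal, in percent.  For the gamma log link the
#' observation-level variance is the trigamma of the shape (the standard
#' log-link choice); a lognormal approximation `log(1 + 1/shape)` is
#' available via `gamma_method`.
#'
#' @param fit a `troph_fit`.
#' @param gamma_method `"trigamma"` (default) or `"lognormal"`.
#' @return list with `marginal`, `conditional`, and `random_explained_pct`.
#' @export
r2_components <- function(fit, gamma_method = c("trigamma", "lognormal")) {
  stopifnot(inherits(fit, "troph_fit"))
  gamma_method <- match.arg(gamma_method)
  model <- fit$model
  X <- lme4::getME(model, "X")
  var_f <- stats::var(as.vector(X %*% lme4::fixef(model)))
  var_r <- sum(fit$random_variances)
  var_e <- if (fit$spec$family == "gaussian") {
    stats::sigma(model)^2
  } else {
    shape <- 1 / stats::sigma(model)^2
    if (gamma_method == "trigamma") trigamma(shape) else log1p(1 / shape)
  }
  denom <- var_f + var_r + var_e
  marginal <- var_f / denom
  conditional <- (var_f + var_r) / denom
  list(marginal = marginal, conditional = conditional,
       random_explained_pct = 100 * (conditional - marginal))
}

#' Tukey-adjusted contrasts of estimated marginal means
#'
#' Estimated marginal means are computed on the reference grid (covariates
#' at their sample means), and the `compare` factor is contrasted pairwise
#' within each level of the `within` factor, with Tukey (studentized-range)
#' adjustment over the contrast family and Satterthwaite denominator degrees
#' of freedom by default.
#'
#' @param fit a `troph_fit`.
#' @param within factor whose levels partition the contrast families
#'   (e.g. `"food_type"`).
#' @param compare factor compared within each `within` level
#'   (e.g. `"food_availability"`).
#' @param adjust p-value adjustment, default `"tukey"`.
#' @param df_method `"satterthwaite"` (default; gives the fractional
#'   denominator d.f.), `"kenward-roger"`, or `"asymptotic"`.
#' @return data frame with columns `contrast, within_level, estimate, se,
#'   df, t_ratio, p`.
#' @export
emm_contrasts <- function(fit, within, compare, adjust = "tukey",
                          df_method = c("satterthwaite", "kenward-roger",
                                        "asymptotic")) {
  stopifnot(inherits(fit, "troph_fit"))
  df_method <- match.arg(df_method)
  dat <- stats::model.frame(fit$model)
  for (f in c(within, compare)) {
    if (!f %in% names(dat)) {
      troph_error("missing_factor", sprintf("factor '%s' not in the model", f))
    }
  }
  model <- fit$model
  # Satterthwaite / Kenward-Roger denominator d.f. need the lmerTest
  # machinery; refit through it on the stored data
  if (df_method != "asymptotic" && inherits(model, "lmerMod") &&
      !inherits(model, "lmerModLmerTest") && !is.null(fit$data)) {
    model <- suppressWarnings(suppressMessages(
      lmerTest::lmer(build_formula(fit$spec), data = fit$data,
                     REML = fit$criterion == "REML",
                     control = lme4::lmerControl(
                       check.nobs.vs.nlev = "ignore",
                       check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore"))))
  }
  em <- emmeans::emmeans(model,
                         specs = stats::as.formula(paste("~", compare, "|", within)),
                         lmer.df = df_method, data = fit$data)
  ct <- summary(emmeans::contrast(em, method = "pairwise", adjust = adjust))
  ct <- as.data.frame(ct)
  stat_col <- intersect(c("t.ratio", "z.ratio"), names(ct))[1]
  df_col <- if ("df" %in% names(ct)) ct[["df"]] else NA_real_
  data.frame(contrast = as.character(ct$contrast),
             within_level = as.character(ct[[within]]),
             estimate = ct$estimate, se = ct$SE, df = df_col,
             t_ratio = ct[[stat_col]], p = ct$p.value,
             stringsAsFactors = FALSE)
}
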