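#' Configuration for the measure-level generator
#'
#' Generates per-ant measure tables with a known fixed/random-effect
#' structure, used to validate the statistical stack by parameter recovery.
#' Gaussian responses (`degree_like`, `distance_like`) follow
#'
#'   y = b0 + b_gs * group_size + b_ft * protein + b_fa * unlimited
#'       + b_int * protein:unlimited + u_group + u_individual + u_rate + e
#'
#' with independent Gaussian random intercepts for group, individual, and
#' frame-rate bin.  The `betweenness_like` response is gamma with a log link
#' on its own (smaller-coefficient) linear predictor, mimicking the positive
#' skewed scale of betweenness.
#'
#' Defaults encode the standard recovery conditions used throughout the test
#' harnesses: 40 groups tested twice, 20 individuals per group, group-size
#' covariate drawn from the study's 14--30 range, b_gs = 0.5,
#' b_int = -2, sd_group = 1, sd_individual = 0.5, sd_resid = 1.
#'
#' @param n_groups number of groups.
#' @param trials_per_group trials per group (the study reused groups); the
#'   same individuals are measured in every trial of their group.
#' @param n_per_group individuals measured per group.
#' @param group_size_range group-size covariate range (uniform integer draw
#'   per trial).
#' @param beta0,beta_group_size,beta_food_type,beta_availability,beta_interaction
#'   fixed effects (dummy coding: protein vs carbohydrate, unlimited vs
#'   limited, interaction = protein AND unlimited).
#' @param sd_group,sd_individual,sd_frame_rate random-intercept SDs.
#' @param sd_resid residual SD of the Gaussian responses.
#' @param gamma_beta0,gamma_beta_group_size log-scale coefficients of the
#'   gamma response.
#' @param gamma_sd_group,gamma_sd_individual log-scale random-intercept SDs
#'   of the gamma response.
#' @param gamma_shape gamma shape parameter.
#' @param seed integer seed.
#' @return an `effect_config` list.
#' @export
effect_config <- function(n_groups = 40, trials_per_group = 2,
                          n_per_group = 20, group_size_range = c(14L, 30L),
                          beta0 = 5, beta_group_size = 0.5,
                          beta_food_type = 1, beta_availability = 1,
                          beta_interaction = -2,
                          sd_group = 1, sd_individual = 0.5,
                          sd_frame_rate = 0.25, sd_resid = 1,
                          gamma_beta0 = 1, gamma_beta_group_size = 0.05,
                          gamma_sd_group = 0.2, gamma_sd_individual = 0.1,
                          gamma_shape = 2, seed = 1L) {
  stopifnot(sd_group >= 0, sd_individual >= 0, sd_frame_rate >= 0,
            sd_resid >= 0, gamma_shape > 0)
  structure(as.list(environment()), class = "effect_config")
}

#' Simulate a per-ant measure table with known effect structure
#'
#' @param cfg an [effect_config()].
#' @return data frame with columns `group_id, individual_id, trial_id,
#'   group_size, food_type, food_availability, frame_rate, frame_rate_bin,
#'   degree_like, distance_like, betweenness_like`.
#' @export
simulate_measures <- function(cfg) {
  stopifnot(inherits(cfg, "effect_config"))
  set.seed(cfg$seed)
  n_trials <- cfg$n_groups * cfg$trials_per_group
  groups <- sprintf("G%03d", seq_len(cfg$n_groups))

  # balanced-as-possible randomized assignment of trials to the 4 cells
  cells <- expand.grid(food_type = c("carbohydrate", "protein"),
                       food_availability = c("limited", "unlimited"),
                       stringsAsFactors = FALSE)
  cell_idx <- sample(rep_len(seq_len(nrow(cells)), n_trials))

  trial_tab <- data.frame(
    trial_id = sprintf("T%04d", seq_len(n_trials)),
    group_id = rep(groups, each = cfg$trials_per_group),
    group_size = sample(seq(cfg$group_size_range[1], cfg$group_size_range[2]),
                        n_trials, replace = TRUE),
    food_type = cells$food_type[cell_idx],
    food_availability = cells$food_availability[cell_idx],
    frame_rate = stats::runif(n_trials, 0.31, 2.92),
    stringsAsFactors = FALSE
  )
  trial_tab$frame_rate_bin <- bin_frame_rate(trial_tab$frame_rate)

  u_group <- stats::rnorm(cfg$n_groups, 0, cfg$sd_group)
  names(u_group) <- groups
  indiv_ids <- as.vector(vapply(groups, function(g) {
    paste(g, sprintf("i%02d", seq_len(cfg$n_per_group)), sep = ":")
  }, character(cfg$n_per_group)))
  u_indiv <- stats::rnorm(length(indiv_ids), 0, cfg$sd_individual)
  names(u_indiv) <- indiv_ids
  bins <- unique(trial_tab$frame_rate_bin)
  u_rate <- stats::rnorm(length(bins), 0, cfg$sd_frame_rate)
  names(u_rate) <- bins
  vg_group <- stats::rnorm(cfg$n_groups, 0, cfg$gamma_sd_group)
  names(vg_group) <- groups
  vg_indiv <- stats::rnorm(length(indiv_ids), 0, cfg$gamma_sd_individual)
  names(vg_indiv) <- indiv_ids

  rows <- trial_tab[rep(seq_len(n_trials), each = cfg$n_per_group), ]
  rows$individual_id <- paste(rows$group_id,
                              sprintf("i%02d", seq_len(cfg$n_per_group)),
                              sep = ":")
  n_obs <- nrow(rows)

  protein <- as.numeric(rows$food_type == "protein")
  unlimited <- as.numeric(rows$food_availability == "unlimited")
  eta <- cfg$beta0 + cfg$beta_group_size * rows$group_size +
    cfg$beta_food_type * protein + cfg$beta_availability * unlimited +
    cfg$beta_interaction * protein * unlimited +
    u_group[rows$group_id] + u_indiv[rows$individual_id] +
    u_rate[rows$frame_rate_bin]
  rows$degree_like <- eta + stats::rnorm(n_obs, 0, cfg$sd_resid)
  rows$distance_like <- eta + stats::rnorm(n_obs, 0, cfg$sd_resid)

  eta_g <- cfg$gamma_beta0 + cfg$gamma_beta_group_size * rows$group_size +
    vg_group[rows$group_id] + vg_indiv[rows$individual_id]
  mu <- exp(eta_g)
  rows$betweenness_like <- stats::rgamma(n_obs, shape = cfg$gamma_shape,
                                         rate = cfg$gamma_shape / mu)

  rows <- rows[, c("group_id", "individual_id", "trial_id", "group_size",
                   "food_type", "food_availability", "frame_rate",
                   "frame_rate_bin", "degree_like", "distance_like",
                   "betweenness_like")]
  rownames(rows) <- NULL
  rows
}
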