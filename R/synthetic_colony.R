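#' Configuration for one simulated tracking trial
#'
#' The simulator emulates the study conditions of a tagged-ant feeding trial:
#' a group of 14--30 ants in a 90 mm circular arena imaged at 0.04 mm/px
#' (radius 1125 px), filmed for an hour at a frame rate between 0.31 and
#' 2.92 images/sec that may change during the trial.  Each ant performs a
#' correlated random walk confined to a small home territory; the home
#' territories sit on a ring spaced so that, in noiseless mode, no two
#' non-planted ants ever come within `separation_factor * threshold_px` of
#' one another.  Planted pairs are choreographed: one pair at a time leaves
#' its territories, walks to the arena centre, dwells head-to-head at
#' `contact_dist_px` (< threshold) long enough to be captured at the lowest
#' admissible frame rate, and returns.  This yields an exact ground truth for
#' interaction-recovery tests.
#'
#' @param trial_id,group_id identifiers.
#' @param group_size number of ants; `NULL` draws uniformly from
#'   `group_size_range` at simulation time.
#' @param group_size_range inclusive range used when `group_size` is `NULL`.
#' @param arena_radius_px arena radius; default 1125 px = 45 mm / 0.04 mm/px.
#' @param duration_s trial length in seconds.
#' @param frame_rate_schedule data frame with columns `duration_s`, `rate_ips`
#'   (piecewise-constant sampling rates); `NULL` draws two equal segments with
#'   rates uniform on `[0.31, 2.92]`.
#' @param speed_px_s mean walking speed of the confined random walk.
#' @param turn_sd_rad standard deviation of the per-tick heading change.
#' @param n_planted_pairs number of planted interacting pairs (ignored when
#'   `planted_pairs` is given).
#' @param planted_pairs optional 2-column matrix of ant indices (1-based).
#' @param threshold_px head-to-head interaction threshold; default 102 px.
#' @param separation_factor non-planted pairs are kept strictly beyond
#'   `separation_factor * threshold_px` (noiseless mode guarantee).
#' @param home_jitter_px radius of each ant's home territory.
#' @param approach_speed_px_s walking speed during choreographed excursions.
#' @param dwell_s time a planted pair spends head-to-head at the centre;
#'   must cover at least two sampling intervals at the slowest rate.
#' @param contact_dist_px head-to-head distance held during the dwell.
#' @param food_type,food_availability treatment labels for the metadata.
#' @param pixel_scale_mm mm per pixel.
#' @param tick_s internal simulation step; detections are sampled from ticks.
#' @param seed integer seed; the same seed reproduces the trial exactly.
#' @return a `trial_config` list.
#' @export
trial_config <- function(trial_id = "T1", group_id = "G1",
                         group_size = NULL, group_size_range = c(14L, 30L),
                         arena_radius_px = 1125, duration_s = 3600,
                         frame_rate_schedule = NULL,
                         speed_px_s = 16, turn_sd_rad = 0.6,
                         n_planted_pairs = 3, planted_pairs = NULL,
                         threshold_px = 102, separation_factor = 1.5,
                         home_jitter_px = 20, approach_speed_px_s = 120,
                         dwell_s = 12, contact_dist_px = 50,
                         food_type = c("carbohydrate", "protein"),
                         food_availability = c("limited", "unlimited"),
                         pixel_scale_mm = 0.04, tick_s = 0.1, seed = 1L) {
  structure(list(
    trial_id = trial_id, group_id = group_id,
    group_size = group_size, group_size_range = as.integer(group_size_range),
    arena_radius_px = arena_radius_px, duration_s = duration_s,
    frame_rate_schedule = frame_rate_schedule,
    speed_px_s = speed_px_s, turn_sd_rad = turn_sd_rad,
    n_planted_pairs = n_planted_pairs, planted_pairs = planted_pairs,
    threshold_px = threshold_px, separation_factor = separation_factor,
    home_jitter_px = home_jitter_px,
    approach_speed_px_s = approach_speed_px_s,
    dwell_s = dwell_s, contact_dist_px = contact_dist_px,
    food_type = match.arg(food_type),
    food_availability = match.arg(food_availability),
    pixel_scale_mm = pixel_scale_mm, tick_s = tick_s,
    seed = as.integer(seed)
  ), class = "trial_config")
}

# canonical unordered pair key "a|b" with a < b (as character)
pair_key <- function(a, b) {
  ifelse(as.character(a) < as.character(b),
         paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Simulate one tracking trial with planted ground-truth interactions
#'
#' @param config a [trial_config()].
#' @return list with elements `detections` (a `detection_table`), `metadata`
#'   (one-row data frame: trial_id, group_id, group_size, food_type,
#'   food_availability, pixel_scale_mm, mean_frame_rate_ips), and
#'   `ground_truth` (list: `interacting_pairs` data frame of ant-ID pairs,
#'   `margin_px` = minimum distance ever attained by any non-planted pair,
#'   `path_length_px` = named per-ant full-resolution path lengths).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$group_size
  if (is.null(n)) {
    n <- sample(seq(cfg$group_size_range[1], cfg$group_size_range[2]), 1)
  }
  if (n < 2) troph_error("infeasible_config", "need at least 2 ants")

  sched <- cfg$frame_rate_schedule
  if (is.null(sched)) {
    sched <- data.frame(duration_s = rep(cfg$duration_s / 2, 2),
                        rate_ips = stats::runif(2, 0.31, 2.92))
  }
  if (any(sched$rate_ips <= 0)) {
    troph_error("infeasible_config", "frame rates must be positive")
  }
  min_rate <- min(sched$rate_ips)
  if (cfg$dwell_s < 2 / min_rate) {
    troph_error("infeasible_config",
                sprintf("dwell %.1fs cannot guarantee a sampled frame at %.2f images/sec",
                        cfg$dwell_s, min_rate))
  }
  if (max(sched$rate_ips) > 1 / cfg$tick_s) {
    troph_error("infeasible_config",
                "tick_s too coarse for the requested frame rate")
  }

  # ---- geometry: homes on a ring ------------------------------------------
  sep_needed <- cfg$separation_factor * cfg$threshold_px
  ring_r <- cfg$arena_radius_px - cfg$home_jitter_px - 60
  # nearest-neighbour home spacing minus both territories must clear margin
  spacing <- 2 * ring_r * sin(pi / n) - 2 * cfg$home_jitter_px
  # clearance between a radial excursion path and a neighbouring territory
  radial_clear <- ring_r * sin(2 * pi / n) - cfg$home_jitter_px
  if (spacing <= sep_needed || radial_clear <= sep_needed) {
    troph_error("infeasible_config",
                sprintf("cannot keep %d non-planted ants separated beyond %.0f px in a %.0f px arena",
                        n, sep_needed, cfg$arena_radius_px))
  }
  if (cfg$contact_dist_px >= cfg$threshold_px) {
    troph_error("infeasible_config", "contact_dist_px must be below threshold_px")
  }
  ang0 <- stats::runif(1, 0, 2 * pi)
  home_ang <- ang0 + 2 * pi * (seq_len(n) - 1) / n
  home <- cbind(ring_r * cos(home_ang), ring_r * sin(home_ang))

  # ---- planted pairs and excursion windows --------------------------------
  pairs <- cfg$planted_pairs
  if (is.null(pairs)) {
    k <- cfg$n_planted_pairs
    if (k > 0) {
      all_pairs <- t(utils::combn(n, 2))
      if (k > nrow(all_pairs)) {
        troph_error("infeasible_config", "more planted pairs than ant pairs")
      }
      pairs <- all_pairs[sample(nrow(all_pairs), k), , drop = FALSE]
    } else {
      pairs <- matrix(integer(0), ncol = 2)
    }
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    if (any(pairs[, 1] == pairs[, 2]) || any(pairs < 1) || any(pairs > n)) {
      troph_error("infeasible_config", "planted pairs must be distinct ants in 1..n")
    }
    pairs <- unique(t(apply(pairs, 1, sort)))
    pairs <- matrix(pairs, ncol = 2)
  }

  travel_s <- (ring_r - cfg$contact_dist_px / 2) / cfg$approach_speed_px_s
  win_len <- 2 * travel_s + cfg$dwell_s
  n_pairs <- nrow(pairs)
  gap_s <- 5
  lead_s <- 10
  total_needed <- lead_s + n_pairs * (win_len + gap_s) + lead_s
  if (n_pairs > 0 && total_needed > cfg$duration_s) {
    troph_error("infeasible_config",
                sprintf("duration %.0fs too short for %d choreographed excursions (need %.0fs)",
                        cfg$duration_s, n_pairs, total_needed))
  }
  win_start <- lead_s + (seq_len(n_pairs) - 1) * (win_len + gap_s)

  # ---- base confined correlated random walk -------------------------------
  ticks <- seq(0, cfg$duration_s, by = cfg$tick_s)
  n_t <- length(ticks)
  step_mean <- cfg$speed_px_s * cfg$tick_s
  X <- matrix(0, n_t, n); Y <- matrix(0, n_t, n)
  heading <- stats::runif(n, 0, 2 * pi)
  pos <- home + cbind(stats::runif(n, -1, 1), stats::runif(n, -1, 1)) *
    cfg$home_jitter_px / 2
  X[1, ] <- pos[, 1]; Y[1, ] <- pos[, 2]
  for (t in 2:n_t) {
    heading <- heading + stats::rnorm(n, 0, cfg$turn_sd_rad)
    step <- stats::rgamma(n, shape = 2, rate = 2 / step_mean)
    nx <- pos[, 1] + step * cos(heading)
    ny <- pos[, 2] + step * sin(heading)
    dx <- nx - home[, 1]; dy <- ny - home[, 2]
    r <- sqrt(dx^2 + dy^2)
    out <- r > cfg$home_jitter_px
    if (any(out)) {
      # pull escapees back to just inside the territory, heading homeward
      sc <- (cfg$home_jitter_px * 0.95) / r[out]
      nx[out] <- home[out, 1] + dx[out] * sc
      ny[out] <- home[out, 2] + dy[out] * sc
      heading[out] <- atan2(home[out, 2] - ny[out], home[out, 1] - nx[out]) +
        stats::rnorm(sum(out), 0, 0.3)
    }
    pos[, 1] <- nx; pos[, 2] <- ny
    X[t, ] <- nx; Y[t, ] <- ny
  }

  # tag direction = instantaneous movement direction
  TH <- matrix(0, n_t, n)
  TH[1, ] <- stats::runif(n, 0, 2 * pi)
  if (n_t > 1) {
    TH[2:n_t, ] <- atan2(Y[2:n_t, , drop = FALSE] - Y[1:(n_t - 1), , drop = FALSE],
                         X[2:n_t, , drop = FALSE] - X[1:(n_t - 1), , drop = FALSE])
  }

  # ---- overlay choreographed excursions -----------------------------------
  if (n_pairs > 0) {
    for (k in seq_len(n_pairs)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      t0 <- win_start[k]
      # meeting points: each ant stops short of the centre on its own radius
      mi <- home[i, ] * (cfg$contact_dist_px / 2) / ring_r
      mj <- home[j, ] * (cfg$contact_dist_px / 2) / ring_r
      # if homes nearly coincide in angle the meeting distance shrinks; fine
      for (idx in list(list(a = i, m = mi, other = j, mo = mj),
                       list(a = j, m = mj, other = i, mo = mi))) {
        a <- idx$a; m <- idx$m
        sel_out <- ticks >= t0 & ticks < t0 + travel_s
        sel_dwell <- ticks >= t0 + travel_s & ticks < t0 + travel_s + cfg$dwell_s
        sel_back <- ticks >= t0 + travel_s + cfg$dwell_s & ticks <= t0 + win_len
        frac_out <- (ticks[sel_out] - t0) / travel_s
        X[sel_out, a] <- home[a, 1] + frac_out * (m[1] - home[a, 1])
        Y[sel_out, a] <- home[a, 2] + frac_out * (m[2] - home[a, 2])
        X[sel_dwell, a] <- m[1]; Y[sel_dwell, a] <- m[2]
        frac_back <- (ticks[sel_back] - (t0 + travel_s + cfg$dwell_s)) / travel_s
        X[sel_back, a] <- m[1] + frac_back * (home[a, 1] - m[1])
        Y[sel_back, a] <- m[2] + frac_back * (home[a, 2] - m[2])
        # face along travel, face the partner while dwelling
        TH[sel_out, a] <- atan2(m[2] - home[a, 2], m[1] - home[a, 1])
        TH[sel_dwell, a] <- atan2(idx$mo[2] - m[2], idx$mo[1] - m[1])
        TH[sel_back, a] <- atan2(home[a, 2] - m[2], home[a, 1] - m[1])
      }
    }
  }
  TH <- TH %% (2 * pi)

  # ---- sample detection frames per the frame-rate schedule ----------------
  seg_end <- cumsum(sched$duration_s)
  seg_start <- c(0, utils::head(seg_end, -1))
  sample_t <- unlist(lapply(seq_len(nrow(sched)), function(s) {
    seq(seg_start[s], min(seg_end[s], cfg$duration_s) - 1e-9,
        by = 1 / sched$rate_ips[s])
  }))
  sample_t <- c(sample_t[sample_t <= cfg$duration_s], cfg$duration_s)
  tick_idx <- unique(pmin(round(sort(sample_t) / cfg$tick_s) + 1, n_t))
  frames <- seq_along(tick_idx) - 1L

  ant_ids <- sprintf("a%02d", seq_len(n))
  det <- data.frame(
    trial_id = cfg$trial_id,
    frame = rep(frames, each = n),
    time_s = rep(ticks[tick_idx], each = n),
    ant_id = rep(ant_ids, times = length(tick_idx)),
    x_px = as.vector(t(X[tick_idx, , drop = FALSE])),
    y_px = as.vector(t(Y[tick_idx, , drop = FALSE])),
    theta_rad = as.vector(t(TH[tick_idx, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
  det <- validate_detections(det)

  # ---- ground truth -------------------------------------------------------
  planted_ids <- if (n_pairs > 0) {
    data.frame(ant_i = pmin(ant_ids[pairs[, 1]], ant_ids[pairs[, 2]]),
               ant_j = pmax(ant_ids[pairs[, 1]], ant_ids[pairs[, 2]]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(ant_i = character(0), ant_j = character(0))
  }
  planted_set <- pair_key(planted_ids$ant_i, planted_ids$ant_j)
  margin <- Inf
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (pair_key(ant_ids[i], ant_ids[j]) %in% planted_set) next
      d2 <- (X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2
      margin <- min(margin, sqrt(min(d2)))
    }
  }
  path_len <- sqrt(diff(X)^2 + diff(Y)^2)
  path_len <- colSums(path_len)
  names(path_len) <- ant_ids

  tr <- frame_rate_summary(det)
  metadata <- data.frame(
    trial_id = cfg$trial_id, group_id = cfg$group_id, group_size = n,
    food_type = cfg$food_type, food_availability = cfg$food_availability,
    pixel_scale_mm = cfg$pixel_scale_mm,
    mean_frame_rate_ips = tr$mean_ips,
    stringsAsFactors = FALSE
  )
  list(detections = det, metadata = metadata,
       ground_truth = list(interacting_pairs = planted_ids,
                           margin_px = margin,
                           path_length_px = path_len,
                           threshold_px = cfg$threshold_px))
}

#' Simulate a multi-trial feeding experiment
#'
#' Emulates the study design: trials spread over the four food treatments
#' (carbohydrate/protein crossed with limited/unlimited), group sizes drawn
#' from 14--30, frame rates varying across trials within 0.31--2.92
#' images/sec, and group IDs reused across trials so that repeated-measures
#' handling downstream is exercised.
#'
#' @param n_trials number of trials.
#' @param seed integer seed governing every random draw.
#' @param n_groups number of distinct groups; default `ceiling(n_trials / 2)`
#'   so reuse happens (the study reused groups, median three trials each).
#' @param duration_s trial duration passed to each [trial_config()].
#' @param n_planted_range planted interacting pairs per trial drawn uniformly
#'   from this inclusive range.
#' @param ... further arguments forwarded to [trial_config()].
#' @return list with `trials` (list of [simulate_trial()] results) and
#'   `metadata` (row-bound trial metadata).
#' @export
simulate_experiment <- function(n_trials = 4, seed = 1L,
                                n_groups = NULL, duration_s = 600,
                                n_planted_range = c(3L, 10L), ...) {
  if (n_trials < 1) troph_error("infeasible_config", "need at least one trial")
  set.seed(seed)
  if (is.null(n_groups)) n_groups <- max(1L, ceiling(n_trials / 2))
  group_ids <- sprintf("G%02d", sample(rep_len(seq_len(n_groups), n_trials)))
  cells <- expand.grid(food_type = c("carbohydrate", "protein"),
                       food_availability = c("limited", "unlimited"),
                       stringsAsFactors = FALSE)
  cell_idx <- sample(rep_len(seq_len(nrow(cells)), n_trials))
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)
  n_planted <- sample(seq(n_planted_range[1], n_planted_range[2]),
                      n_trials, replace = TRUE)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- trial_config(trial_id = sprintf("T%03d", i),
                        group_id = group_ids[i],
                        duration_s = duration_s,
                        n_planted_pairs = n_planted[i],
                        food_type = cells$food_type[cell_idx[i]],
                        food_availability = cells$food_availability[cell_idx[i]],
                        seed = trial_seeds[i], ...)
    trials[[i]] <- simulate_trial(cfg)
  }
  metadata <- do.call(rbind, lapply(trials, `[[`, "metadata"))
  rownames(metadata) <- NULL
  list(trials = trials, metadata = metadata)
}
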