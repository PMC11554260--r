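#' Describe the column layout of a detection table file
#'
#' A detection table holds one row per tag detection: the frame index, the
#' time in seconds, the ant (tag) identity, the tag-centre pixel coordinates,
#' and the tag's front direction in radians.  The dialect maps the canonical
#' column names onto whatever a particular file calls them, and records the
#' coordinate conventions (image convention: origin top-left, y increasing
#' downwards; angles are measured in that same frame, counterclockwise from
#' the +x axis as seen in the stored coordinates).
#'
#' @param trial_id,frame,time_s,ant_id,x_px,y_px,theta_rad column names in the
#'   file for each canonical field.  `trial_id` and `time_s` may be absent
#'   from the file (see `read_detections()`).
#' @param nominal_rate_ips if the file has no time column, timestamps are
#'   reconstructed as `frame / nominal_rate_ips`; `NULL` means a missing time
#'   column is an error.
#' @return an object of class `detection_dialect`.
#' @export
detection_dialect <- function(trial_id = "trial_id", frame = "frame",
                              time_s = "time_s", ant_id = "ant_id",
                              x_px = "x_px", y_px = "y_px",
                              theta_rad = "theta_rad",
                              nominal_rate_ips = NULL) {
  structure(list(trial_id = trial_id, frame = frame, time_s = time_s,
                 ant_id = ant_id, x_px = x_px, y_px = y_px,
                 theta_rad = theta_rad, nominal_rate_ips = nominal_rate_ips),
            class = "detection_dialect")
}

#' Read and validate a tag-detection table
#'
#' Reads a CSV of per-frame tag detections, renames columns to the canonical
#' schema, validates the invariants (finite coordinates, no ant detected
#' twice in one frame, non-negative frame indices), wraps tag angles into
#' `[0, 2*pi)`, and sorts rows by `(frame, ant_id)`.
#'
#' @param path path to a CSV file.
#' @param dialect a [detection_dialect()] describing the file's columns.
#' @param trial_id trial identifier to use when the file has no trial column.
#' @return a `data.frame` of class `detection_table` with columns
#'   `trial_id, frame, time_s, ant_id, x_px, y_px, theta_rad` and attributes
#'   `n_ants` and `n_frames`.
#' @export
read_detections <- function(path, dialect = detection_dialect(),
                            trial_id = NULL) {
  if (!file.exists(path)) {
    troph_error("missing_file", sprintf("detection file not found: %s", path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- as_detection_table(raw, dialect = dialect, trial_id = trial_id)
  df
}

#' Coerce an in-memory data frame to a validated detection table
#'
#' @inheritParams read_detections
#' @param df a data frame with the dialect's columns.
#' @export
as_detection_table <- function(df, dialect = detection_dialect(),
                               trial_id = NULL) {
  needed <- c("frame", "ant_id", "x_px", "y_px", "theta_rad")
  for (field in needed) {
    if (!dialect[[field]] %in% names(df)) {
      troph_error("missing_column",
                  sprintf("required column '%s' (field %s) not present",
                          dialect[[field]], field))
    }
  }
  out <- data.frame(
    frame = as.integer(df[[dialect$frame]]),
    ant_id = as.character(df[[dialect$ant_id]]),
    x_px = as.numeric(df[[dialect$x_px]]),
    y_px = as.numeric(df[[dialect$y_px]]),
    theta_rad = as.numeric(df[[dialect$theta_rad]]),
    stringsAsFactors = FALSE
  )
  if (dialect$trial_id %in% names(df)) {
    out$trial_id <- as.character(df[[dialect$trial_id]])
  } else {
    out$trial_id <- if (is.null(trial_id)) "trial" else as.character(trial_id)
  }
  if (dialect$time_s %in% names(df)) {
    out$time_s <- as.numeric(df[[dialect$time_s]])
  } else if (!is.null(dialect$nominal_rate_ips)) {
    out$time_s <- out$frame / dialect$nominal_rate_ips
    message("time_s reconstructed from frame index at ",
            dialect$nominal_rate_ips, " images/sec")
  } else {
    troph_error("missing_column",
                "no time column and no nominal_rate_ips to reconstruct it")
  }
  out <- out[, c("trial_id", "frame", "time_s", "ant_id",
                 "x_px", "y_px", "theta_rad")]
  validate_detections(out)
}

validate_detections <- function(df) {
  if (nrow(df) > 0) {
    if (any(!is.finite(df$x_px)) || any(!is.finite(df$y_px))) {
      troph_error("nonfinite_coordinate",
                  "non-finite tag coordinates in detection table")
    }
    if (any(df$frame < 0)) {
      troph_error("invalid_frame", "negative frame index")
    }
    key <- paste(df$trial_id, df$frame, df$ant_id, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- df[duplicated(key), , drop = FALSE][1, ]
      troph_error("duplicate_detection",
                  sprintf("ant '%s' detected more than once in frame %d of trial '%s'",
                          dup$ant_id, dup$frame, dup$trial_id))
    }
    df$theta_rad <- df$theta_rad %% (2 * pi)
    df <- df[order(df$trial_id, df$frame, df$ant_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df,
            class = c("detection_table", "data.frame"),
            n_ants = length(unique(df$ant_id)),
            n_frames = length(unique(df$frame)))
}

#' Write a detection table to CSV in the canonical dialect
#'
#' @param table a `detection_table`.
#' @param path output path.
#' @export
write_detections <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("<detection_table> %d detections, %d ants, %d frames\n",
              nrow(x), attr(x, "n_ants"), attr(x, "n_frames")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Head position from tag centre and tag direction
#'
#' The head proxy is the tag centre displaced by `head_offset_px` along the
#' tag's front direction.  With the default offset of 0 the head proxy
#' coincides with the tag centre: the proximity threshold is calibrated from
#' manually measured head-to-head distances and so already absorbs a constant
#' centre-to-head displacement.
#'
#' @param x_px,y_px tag-centre coordinates (vectorised).
#' @param theta_rad tag front direction, radians, measured in the image frame.
#' @param head_offset_px displacement along the tag direction, pixels.
#' @return a two-column matrix `cbind(x, y)` of head coordinates.
#' @export
head_position <- function(x_px, y_px, theta_rad, head_offset_px = 0) {
  stopifnot(is.finite(head_offset_px), head_offset_px >= 0)
  cbind(x = x_px + head_offset_px * cos(theta_rad),
        y = y_px + head_offset_px * sin(theta_rad))
}

#' Build per-ant trajectories from a detection table
#'
#' One trajectory per ant, ordered by frame, with head positions attached.
#' Frame gaps (missed detections) are recorded but never interpolated:
#' downstream interactions and distances use only frames where detections
#' exist.
#'
#' @param table a `detection_table`.
#' @param head_offset_px passed to [head_position()].
#' @return an object of class `trajectory_set`: a list with elements `ants`
#'   (named list of per-ant data frames with columns
#'   `frame, time_s, x_px, y_px, theta_rad, hx_px, hy_px`), `gaps` (named list
#'   of integer vectors: frames after which a gap follows), `trial_id`, and
#'   `head_offset_px`.
#' @export
build_trajectories <- function(table, head_offset_px = 0) {
  stopifnot(inherits(table, "detection_table"))
  df <- as.data.frame(table)
  ants <- list()
  gaps <- list()
  if (nrow(df) > 0) {
    for (piece in split(df, df$ant_id)) {
      piece <- piece[order(piece$frame), , drop = FALSE]
      if (anyDuplicated(piece$frame)) {
        troph_error("duplicate_detection", "duplicate frame within one ant")
      }
      h <- head_position(piece$x_px, piece$y_px, piece$theta_rad,
                         head_offset_px)
      traj <- data.frame(frame = piece$frame, time_s = piece$time_s,
                         x_px = piece$x_px, y_px = piece$y_px,
                         theta_rad = piece$theta_rad,
                         hx_px = h[, 1], hy_px = h[, 2])
      rownames(traj) <- NULL
      id <- piece$ant_id[1]
      ants[[id]] <- traj
      jump <- which(diff(piece$frame) > 1L)
      gaps[[id]] <- piece$frame[jump]
    }
  }
  structure(list(ants = ants, gaps = gaps,
                 trial_id = if (nrow(df) > 0) df$trial_id[1] else NA_character_,
                 head_offset_px = head_offset_px),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> trial '%s': %d ants, head offset %.1f px\n",
              x$trial_id, length(x$ants), x$head_offset_px))
  invisible(x)
}

#' Frame-rate summary of a trial
#'
#' Mean rate is `(n_frames - 1) / (t_last - t_first)`; per-window rates are
#' detection-frame counts over fixed-duration bins, exposing within-trial
#' frame-rate variation (image storage can slow capture mid-trial).
#'
#' @param table a `detection_table`.
#' @param window_s window length in seconds for the per-window rates.
#' @return list with `mean_ips`, `min_ips`, `max_ips`, and `windows`
#'   (data frame `t_start, t_end, n_frames, rate_ips`).
#' @export
frame_rate_summary <- function(table, window_s = 60) {
  times <- sort(unique(table$time_s))
  if (length(times) < 2) {
    troph_error("insufficient_frames",
                "need at least 2 distinct timestamps for a frame rate")
  }
  mean_ips <- (length(times) - 1) / (times[length(times)] - times[1])
  span <- times[length(times)] - times[1]
  n_win <- floor(span / window_s)
  if (n_win >= 1) {
    starts <- times[1] + (seq_len(n_win) - 1) * window_s
    counts <- vapply(starts, function(s) {
      sum(times >= s & times < s + window_s)
    }, integer(1))
    windows <- data.frame(t_start = starts, t_end = starts + window_s,
                          n_frames = counts, rate_ips = counts / window_s)
    rng <- range(windows$rate_ips)
  } else {
    windows <- data.frame(t_start = times[1], t_end = times[length(times)],
                          n_frames = length(times), rate_ips = mean_ips)
    rng <- c(mean_ips, mean_ips)
  }
  list(mean_ips = mean_ips, min_ips = rng[1], max_ips = rng[2],
       windows = windows)
}
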