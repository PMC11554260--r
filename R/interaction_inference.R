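#' Calibrate the head-to-head interaction threshold
#'
#' The operating threshold is calibrated from manual measurements of
#' head-to-head distances in frames sampled from each trial (the study used
#' 50 randomly selected frames per trial): the measurements of each trial are
#' averaged, and the single threshold applied to every trial is the highest
#' of the per-trial averages.
#'
#' @param measurements named list: trial id -> numeric vector of manually
#'   measured head-to-head distances (pixels).
#' @param target_frames expected number of sampled frames per trial; a
#'   warning is raised for trials with fewer measurements.
#' @return list of class `threshold_calibration` with `per_trial_mean_px`,
#'   `n_measurements`, and `threshold_px` (the max of the per-trial means).
#' @export
calibrate_threshold <- function(measurements, target_frames = 50) {
  if (length(measurements) == 0 ||
      any(vapply(measurements, length, integer(1)) == 0)) {
    troph_error("empty_measurements",
                "every trial needs at least one manual distance measurement")
  }
  means <- vapply(measurements, mean, numeric(1))
  if (any(means <= 0)) {
    troph_error("empty_measurements", "distance measurements must be positive")
  }
  n_meas <- vapply(measurements, length, integer(1))
  short <- names(measurements)[n_meas < target_frames]
  if (length(short) > 0) {
    troph_warn("undersampled_calibration",
               sprintf("trials sampled below %d frames: %s", target_frames,
                       paste(short, collapse = ", ")))
  }
  structure(list(per_trial_mean_px = means, n_measurements = n_meas,
                 threshold_px = max(means)),
            class = "threshold_calibration")
}

#' Detect head-to-head interactions from trajectories
#'
#' Two ants are considered to have interacted if, in any frame where both
#' were detected, their head positions were at Euclidean distance less than
#' or equal to the threshold (boundary inclusive).  Each pair appears at most
#' once regardless of how many frames were in contact; interactions are
#' occurrence-only because frame rates varied across and within trials, so
#' durations are never measured.  Frames with a missed detection of either
#' ant contribute nothing: co-detection is required.
#'
#' @param traj a `trajectory_set` from [build_trajectories()].
#' @param threshold_px interaction distance threshold; default 102 px, the
#'   calibrated operating value.
#' @return data frame of class `edge_set` with columns
#'   `ant_i, ant_j, first_contact_frame` (`ant_i < ant_j`), sorted.
#' @export
detect_interactions <- function(traj, threshold_px = 102) {
  stopifnot(inherits(traj, "trajectory_set"), threshold_px > 0)
  empty <- data.frame(ant_i = character(0), ant_j = character(0),
                      first_contact_frame = integer(0),
                      stringsAsFactors = FALSE)
  if (length(traj$ants) < 2) return(structure(empty, class = c("edge_set", "data.frame")))
  flat <- data.table::rbindlist(lapply(names(traj$ants), function(id) {
    a <- traj$ants[[id]]
    data.table::data.table(ant = id, frame = a$frame, hx = a$hx_px, hy = a$hy_px)
  }))
  other <- data.table::copy(flat)
  data.table::setnames(other, c("ant", "hx", "hy"), c("ant2", "hx2", "hy2"))
  joined <- flat[other, on = "frame", allow.cartesian = TRUE]
  joined <- joined[ant < ant2]
  joined <- joined[(hx - hx2)^2 + (hy - hy2)^2 <= threshold_px^2]
  if (nrow(joined) == 0) return(structure(empty, class = c("edge_set", "data.frame")))
  first <- joined[, list(first_contact_frame = min(frame)), by = c("ant", "ant2")]
  out <- data.frame(ant_i = first$ant, ant_j = first$ant2,
                    first_contact_frame = as.integer(first$first_contact_frame),
                    stringsAsFactors = FALSE)
  out <- out[order(out$ant_i, out$ant_j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("edge_set", "data.frame"))
}

#' Build an interaction network from an edge set
#'
#' The network is a simple, undirected, unweighted graph.  Under the default
#' `participants` policy the node set is exactly the ants incident to at
#' least one edge, so networks may contain fewer individuals than the group
#' (not all ants interact).  Under `all_tagged` the node set is the full
#' roster, with non-interacting ants as isolates (used for density
#' sensitivity analyses).
#'
#' @param edges an `edge_set` (or data frame with columns `ant_i`, `ant_j`).
#' @param roster character vector of all tagged ant IDs in the group.
#' @param policy node policy, `"participants"` or `"all_tagged"`.
#' @param trial_id optional trial identifier stored on the network.
#' @return object of class `interaction_network`: list with `graph` (igraph),
#'   `roster`, `policy`, `trial_id`, `group_size` (= length of roster).
#' @export
build_network <- function(edges, roster,
                          policy = c("participants", "all_tagged"),
                          trial_id = NA_character_) {
  policy <- match.arg(policy)
  roster <- as.character(roster)
  bad <- setdiff(unique(c(edges$ant_i, edges$ant_j)), roster)
  if (length(bad) > 0) {
    troph_error("unknown_ant",
                sprintf("edge endpoints not on roster: %s",
                        paste(bad, collapse = ", ")))
  }
  participants <- sort(unique(c(edges$ant_i, edges$ant_j)))
  nodes <- if (policy == "participants") participants else sort(roster)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$ant_i, to = edges$ant_j),
    directed = FALSE,
    vertices = data.frame(name = nodes,
                          participant = nodes %in% participants)
  )
  g <- igraph::simplify(g)
  structure(list(graph = g, roster = sort(roster), policy = policy,
                 trial_id = trial_id, group_size = length(roster)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> trial '%s': %d nodes (%s policy), %d edges, group size %d\n",
              x$trial_id, igraph::vcount(x$graph), x$policy,
              igraph::ecount(x$graph), x$group_size))
  invisible(x)
}

#' Proportion of the group participating in the interaction network
#'
#' @param net an `interaction_network`.
#' @param group_size number of tagged ants in the group; defaults to the
#'   roster size stored on the network.
#' @return fraction in `[0, 1]`: participants divided by group size.
#' @export
participation_proportion <- function(net, group_size = net$group_size) {
  n_part <- sum(igraph::V(net$graph)$participant)
  if (group_size < n_part) {
    troph_error("inconsistent_roster",
                "group size smaller than number of participants")
  }
  if (group_size == 0) return(0)
  n_part / group_size
}

#' Write an interaction network to GraphML
#'
#' Node attribute `participant` marks interacting ants (informative under the
#' `all_tagged` policy).
#'
#' @param net an `interaction_network`.
#' @param path output file.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Write an edge set to CSV
#'
#' @param edges an `edge_set`.
#' @param trial_id trial identifier column value.
#' @param path output file.
#' @export
write_edge_list <- function(edges, trial_id, path) {
  out <- data.frame(trial_id = rep(trial_id, nrow(edges)),
                    as.data.frame(edges))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
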