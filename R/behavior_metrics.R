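#' Network density
#'
#' Observed edges divided by all possible node pairs.  By default the
#' denominator uses the constructed graph's node set (which, under the
#' `participants` policy, excludes ants that never interacted); setting
#' `denominator = "group_size"` instead uses all `choose(group_size, 2)`
#' pairs of tagged ants, a sensitivity variant for when the possible-pair
#' count should include ants that never interacted.
#'
#' @param net an `interaction_network`.
#' @param denominator `"nodes"` (default) or `"group_size"`.
#' @return fraction in `[0, 1]`; 0 with a warning when fewer than 2 nodes.
#' @export
network_density <- function(net, denominator = c("nodes", "group_size")) {
  denominator <- match.arg(denominator)
  n <- if (denominator == "nodes") igraph::vcount(net$graph) else net$group_size
  if (n < 2) {
    troph_warn("degenerate_graph", "density undefined below 2 nodes; returning 0")
    return(0)
  }
  igraph::ecount(net$graph) / choose(n, 2)
}

#' Degree of every ant in the network
#'
#' Number of unique individuals each ant interacted with at least once.
#' Repeated contacts with the same partner count once (the graph is simple,
#' unweighted and undirected).
#'
#' @param net an `interaction_network`.
#' @return named integer vector, ant id -> degree.
#' @export
degree_per_ant <- function(net) {
  d <- igraph::degree(net$graph, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Betweenness of every ant in the network
#'
#' For each ant, the number of shortest paths between pairs of other ants
#' that pass through it, with multiple shortest paths between a pair counted
#' fractionally (each pair contributes sigma_st(v) / sigma_st), each
#' unordered pair counted once, unreachable pairs contributing 0.
#' Unnormalised; isolated nodes get 0.
#'
#' @param net an `interaction_network`.
#' @return named numeric vector, ant id -> betweenness.
#' @export
betweenness_per_ant <- function(net) {
  igraph::betweenness(net$graph, directed = FALSE, normalized = FALSE)
}

#' Number of walktrap clusters in the network
#'
#' Runs the random-walk (walktrap) community-detection algorithm
#' ([walktrap_communities()]) and reports the number of communities at the
#' maximum-modularity cut of its merge dendrogram.
#'
#' @param net an `interaction_network`.
#' @param steps random-walk length, default 4.
#' @return list with `membership` (named integer vector) and `n_clusters`.
#' @export
walktrap_clusters <- function(net, steps = 4) {
  res <- walktrap_communities(net$graph, steps = steps)
  list(membership = res$membership, n_clusters = res$n_clusters)
}

#' Total distance moved by each ant
#'
#' The distance an ant moved between two consecutive detections, summed over
#' the whole trial (tag-centre positions, pixels).  Frames where the ant was
#' not detected contribute the straight-line distance across the gap — no
#' interpolation is performed, so with subsampling the result is a lower
#' bound on the continuous path length.
#'
#' @param traj a `trajectory_set`, or a single per-ant trajectory data frame.
#' @return named numeric vector of pixel distances (a single number for a
#'   single trajectory); a single detection yields 0.
#' @export
total_distance <- function(traj) {
  one <- function(a) {
    if (nrow(a) < 2) return(0)
    sum(sqrt(diff(a$x_px)^2 + diff(a$y_px)^2))
  }
  if (inherits(traj, "trajectory_set")) {
    vapply(traj$ants, one, numeric(1))
  } else {
    one(traj)
  }
}

#' Assemble the per-trial and per-ant measure tables
#'
#' Joins network measures, activity, and trial metadata into the two analysis
#' tables: one global row per trial (density, number of walktrap clusters)
#' and one row per participating ant (degree, betweenness, total distance
#' moved).  The per-ant table carries `individual_id` (`group:ant` so that
#' the same tag id in different groups is a different individual) and
#' `frame_rate_bin`, the trial's mean frame rate rounded to `rate_bin_width`,
#' used downstream as a random-effect grouping factor.
#'
#' @param networks named list (trial id -> `interaction_network`).
#' @param trajectories named list (trial id -> `trajectory_set`).
#' @param metadata data frame of trial metadata (one row per trial id).
#' @param walktrap_steps passed to [walktrap_clusters()].
#' @param density_denominator passed to [network_density()].
#' @param rate_bin_width width (images/sec) of the frame-rate bins.
#' @return list of class `trial_measures` with data frames `global` and
#'   `individual`.
#' @export
assemble_measures <- function(networks, trajectories, metadata,
                              walktrap_steps = 4,
                              density_denominator = "nodes",
                              rate_bin_width = 0.1) {
  ids <- names(networks)
  if (!setequal(ids, names(trajectories)) ||
      !all(ids %in% metadata$trial_id)) {
    troph_error("join_mismatch",
                "trial ids of networks, trajectories and metadata must agree")
  }
  globals <- list()
  indivs <- list()
  for (id in ids) {
    net <- networks[[id]]
    traj <- trajectories[[id]]
    meta <- metadata[metadata$trial_id == id, , drop = FALSE][1, ]
    wt <- walktrap_clusters(net, steps = walktrap_steps)
    globals[[id]] <- data.frame(
      trial_id = id,
      density = network_density(net, denominator = density_denominator),
      n_clusters = wt$n_clusters,
      n_participants = sum(igraph::V(net$graph)$participant),
      group_id = meta$group_id, group_size = meta$group_size,
      food_type = meta$food_type, food_availability = meta$food_availability,
      mean_frame_rate_ips = meta$mean_frame_rate_ips,
      stringsAsFactors = FALSE
    )
    deg <- degree_per_ant(net)
    btw <- betweenness_per_ant(net)
    dist <- total_distance(traj)
    ants <- names(deg)
    if (length(ants) > 0) {
      indivs[[id]] <- data.frame(
        trial_id = id, ant_id = ants,
        individual_id = paste(meta$group_id, ants, sep = ":"),
        degree = as.integer(deg[ants]),
        betweenness = as.numeric(btw[ants]),
        total_distance_px = as.numeric(dist[ants]),
        group_id = meta$group_id, group_size = meta$group_size,
        food_type = meta$food_type,
        food_availability = meta$food_availability,
        mean_frame_rate_ips = meta$mean_frame_rate_ips,
        frame_rate_bin = bin_frame_rate(meta$mean_frame_rate_ips,
                                        rate_bin_width),
        stringsAsFactors = FALSE
      )
      if (any(is.na(indivs[[id]]$total_distance_px))) {
        troph_error("join_mismatch",
                    sprintf("trial %s: network ants missing from trajectories", id))
      }
    }
  }
  global <- do.call(rbind, globals)
  individual <- if (length(indivs) > 0) do.call(rbind, indivs) else NULL
  rownames(global) <- NULL
  if (!is.null(individual)) rownames(individual) <- NULL
  structure(list(global = global, individual = individual),
            class = "trial_measures")
}

#' Bin a continuous frame rate into a grouping level
#'
#' Continuous mean frame rates are rounded to a fixed width (default 0.1
#' images/sec) so that "frame rate" can serve as a random-effect grouping
#' factor.
#'
#' @param rate_ips numeric frame rates.
#' @param width bin width in images/sec.
#' @return character vector of bin labels.
#' @export
bin_frame_rate <- function(rate_ips, width = 0.1) {
  sprintf("fr%.2f", round(rate_ips / width) * width)
}
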