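test_that("density follows edges over possible pairs under both denominators", {
  k4 <- make_net(t(utils::combn(1:4, 2)), 1:4)
  expect_equal(network_density(k4), 1.0)

  path4 <- make_net(rbind(c(1, 2), c(2, 3), c(3, 4)), 1:4)
  expect_equal(network_density(path4), 0.5)

  sparse <- make_net(rbind(c(1, 2)), 1:5, policy = "all_tagged")
  expect_equal(network_density(sparse), 1 / choose(5, 2))
  empty <- build_network(data.frame(ant_i = character(0),
                                    ant_j = character(0)),
                         as.character(1:5), policy = "all_tagged")
  expect_equal(network_density(empty), 0)

  # group-size denominator never exceeds the participants one
  part <- make_net(rbind(c(1, 2), c(2, 3)), 1:6)
  expect_lte(network_density(part, "group_size"), network_density(part))
  expect_equal(network_density(part, "group_size"), 2 / choose(6, 2))
})

test_that("degree counts distinct partners and satisfies the handshake lemma", {
  star <- make_net(cbind(1, 2:5), 1:5)
  d <- degree_per_ant(star)
  expect_equal(unname(d["1"]), 4L)
  expect_true(all(d[c("2", "3", "4", "5")] == 1L))

  tri <- make_net(rbind(c(1, 2), c(2, 3), c(1, 3)), 1:3)
  expect_true(all(degree_per_ant(tri) == 2L))

  set.seed(31)
  for (i in 1:20) {
    g <- random_sim_graph(sample(4:10, 1), runif(1, 0.2, 0.8))
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    net <- list(graph = g)
    d <- degree_per_ant(net)
    expect_equal(unname(d), unname(rowSums(A > 0)))
    expect_equal(sum(d), 2 * igraph::ecount(g))
  }
})

test_that("betweenness matches fixtures and the matrix-power oracle", {
  path3 <- make_net(rbind(c(1, 2), c(2, 3)), 1:3)
  b <- betweenness_per_ant(path3)
  expect_equal(unname(b[c("1", "2", "3")]), c(0, 1, 0))

  star <- make_net(cbind(1, 2:5), 1:5)
  expect_equal(unname(betweenness_per_ant(star)["1"]), choose(4, 2))

  k5 <- make_net(t(utils::combn(1:5, 2)), 1:5)
  expect_true(all(betweenness_per_ant(k5) == 0))

  set.seed(90)
  for (i in 1:30) {
    g <- random_sim_graph(sample(4:12, 1), runif(1, 0.15, 0.7))
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    got <- betweenness_per_ant(list(graph = g))
    expect_equal(unname(got), bf_betweenness(A), tolerance = 1e-9)
  }
})

test_that("tree betweenness equals pair counts across each node", {
  # path a-b-c-d-e: interior nodes bridge all pairs split by them
  p5 <- make_net(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)), 1:5)
  b <- betweenness_per_ant(p5)
  expect_equal(unname(b[c("1", "2", "3", "4", "5")]), c(0, 3, 4, 3, 0))
})

test_that("walktrap agrees with the igraph reference on fixtures and random graphs", {
  two_k3 <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
    directed = FALSE)
  expect_equal(walktrap_communities(two_k3, 4)$n_clusters, 2)
  expect_equal(length(igraph::cluster_walktrap(two_k3, steps = 4)), 2)

  k6 <- igraph::make_full_graph(6)
  expect_equal(walktrap_communities(k6, 4)$n_clusters, 1)

  barbell <- igraph::add_edges(
    igraph::disjoint_union(igraph::make_full_graph(5),
                           igraph::make_full_graph(5)), c(1, 6))
  expect_equal(walktrap_communities(barbell, 4)$n_clusters, 2)
  expect_equal(length(igraph::cluster_walktrap(barbell, steps = 4)), 2)

  set.seed(202)
  for (i in 1:25) {
    g <- igraph::sample_gnp(sample(5:30, 1), runif(1, 0.08, 0.5))
    if (igraph::ecount(g) < 1) next
    expect_equal(walktrap_communities(g, steps = 4)$n_clusters,
                 length(igraph::cluster_walktrap(g, steps = 4)))
  }
})

test_that("walktrap respects components, isolates, and node relabeling", {
  set.seed(55)
  for (i in 1:10) {
    g <- igraph::sample_gnp(sample(8:20, 1), runif(1, 0.08, 0.3))
    if (igraph::ecount(g) < 2) next
    res <- walktrap_communities(g, steps = 4)
    expect_gte(res$n_clusters, igraph::components(g)$no)
    # isolates sit in singleton communities
    iso <- which(igraph::degree(g) == 0)
    if (length(iso) > 0) {
      expect_true(all(table(res$membership)[res$membership[iso]] == 1))
    }
    # relabeling permutes membership but not the partition
    pm <- sample(igraph::vcount(g))
    g2 <- igraph::permute(g, pm)
    res2 <- walktrap_communities(g2, steps = 4)
    expect_equal(res2$n_clusters, res$n_clusters)
    same_block <- outer(res$membership, res$membership, "==")
    same_block2 <- outer(res2$membership[pm], res2$membership[pm], "==")
    expect_true(all(same_block == same_block2))
  }
})

test_that("total distance sums consecutive steps and ignores rigid motion", {
  tab <- as_detection_table(data.frame(
    trial_id = "t", frame = 0:2, time_s = 0:2, ant_id = "A",
    x_px = c(0, 3, 3), y_px = c(0, 4, 4), theta_rad = 0
  ))
  traj <- build_trajectories(tab)
  expect_equal(unname(total_distance(traj)), 5)

  set.seed(8)
  df <- data.frame(trial_id = "t", frame = 0:30, time_s = 0:30, ant_id = "A",
                   x_px = cumsum(rnorm(31)), y_px = cumsum(rnorm(31)),
                   theta_rad = 0)
  d0 <- total_distance(build_trajectories(as_detection_table(df)))
  phi <- 1.1
  df2 <- df
  df2$x_px <- cos(phi) * df$x_px - sin(phi) * df$y_px + 400
  df2$y_px <- sin(phi) * df$x_px + cos(phi) * df$y_px - 90
  d2 <- total_distance(build_trajectories(as_detection_table(df2)))
  expect_equal(d0, d2, tolerance = 1e-9)
  # distance is invariant to which frame index is labeled 0
  df3 <- df
  df3$frame <- df$frame + 100L
  expect_equal(total_distance(build_trajectories(as_detection_table(df3))), d0)
})

test_that("assemble_measures joins one global row per trial and one row per participant", {
  ex <- simulate_experiment(n_trials = 3, seed = 44, duration_s = 240,
                            n_planted_range = c(2L, 4L))
  nets <- list(); trajs <- list()
  for (tr in ex$trials) {
    id <- tr$metadata$trial_id
    trajs[[id]] <- build_trajectories(tr$detections)
    edges <- detect_interactions(trajs[[id]], 102)
    nets[[id]] <- build_network(edges, unique(tr$detections$ant_id),
                                trial_id = id)
  }
  meas <- assemble_measures(nets, trajs, ex$metadata)
  expect_equal(nrow(meas$global), 3)
  expect_equal(nrow(meas$individual),
               sum(meas$global$n_participants))
  expect_true(all(meas$individual$degree >= 1))  # participants policy
  expect_true(all(c("food_type", "food_availability", "group_id",
                    "frame_rate_bin") %in% names(meas$individual)))
  # density within [0,1], clusters bounded by nodes
  expect_true(all(meas$global$density >= 0 & meas$global$density <= 1))
  expect_true(all(meas$global$n_clusters <= meas$global$n_participants))

  expect_error(assemble_measures(nets[1], trajs, ex$metadata),
               class = "troph_join_mismatch")
})
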