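# Independent brute-force oracles used to validate the network measures.

# Betweenness via adjacency-matrix powers: walks of minimal length between
# two vertices are exactly their geodesics, so (A^d)[s,t] counts shortest
# paths once d = geodesic distance; paths through v factor as
# sigma(s,v) * sigma(v,t) whenever d(s,v) + d(v,t) = d(s,t).
bf_betweenness <- function(A) {
  n <- nrow(A)
  pow <- vector("list", n + 1)
  pow[[1]] <- diag(n)
  for (L in seq_len(n)) pow[[L + 1]] <- pow[[L]] %*% A
  Dst <- matrix(Inf, n, n)
  Sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      for (L in seq_len(n)) {
        if (pow[[L + 1]][s, t] > 0) {
          Dst[s, t] <- L
          Sig[s, t] <- pow[[L + 1]][s, t]
          break
        }
      }
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v || !is.finite(Dst[s, t])) next
        if (is.finite(Dst[s, v]) && is.finite(Dst[v, t]) &&
            Dst[s, v] + Dst[v, t] == Dst[s, t]) {
          btw[v] <- btw[v] + Sig[s, v] * Sig[v, t] / Sig[s, t]
        }
      }
    }
  }
  btw
}

# Per-frame pairwise scan of head positions: the definition applied directly.
bf_edges <- function(traj, threshold_px) {
  ids <- names(traj$ants)
  hits <- character(0)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      a <- traj$ants[[ids[i]]]
      b <- traj$ants[[ids[j]]]
      shared <- intersect(a$frame, b$frame)
      for (fr in shared) {
        pa <- a[a$frame == fr, c("hx_px", "hy_px")]
        pb <- b[b$frame == fr, c("hx_px", "hy_px")]
        if (sqrt(sum((pa - pb)^2)) <= threshold_px) {
          hits <- c(hits, paste(ids[i], ids[j], sep = "|"))
          break
        }
      }
    }
  }
  sort(hits)
}

random_sim_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("a%02d", seq_len(n))
  g
}

make_net <- function(edge_mat, roster, policy = "participants") {
  edges <- data.frame(ant_i = as.character(edge_mat[, 1]),
                      ant_j = as.character(edge_mat[, 2]),
                      stringsAsFactors = FALSE)
  build_network(edges, roster = as.character(roster), policy = policy)
}

tiny_detections <- function() {
  as_detection_table(data.frame(
    trial_id = "t1",
    frame = c(0L, 0L, 1L, 1L, 2L),
    time_s = c(0, 0, 0.5, 0.5, 1),
    ant_id = c("A", "B", "A", "B", "A"),
    x_px = c(0, 100, 3, 100, 3),
    y_px = c(0, 0, 4, 5, 4),
    theta_rad = c(0, pi, 0.5, pi, 0.5)
  ))
}
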