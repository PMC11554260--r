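# Random-walk community detection (walktrap, Pons & Latapy 2006).
#
# Vertices start as singleton communities and are agglomerated greedily: at
# each step the two adjacent communities with the smallest merge cost are
# joined, where the cost is based on the distance between t-step random-walk
# probability distributions,
#
#   r^2(C1, C2) = sum_k (P^t[C1, k] - P^t[C2, k])^2 / w(k)
#   ds(C1, C2)  = |C1| |C2| / (|C1| + |C2|) * r^2(C1, C2)
#
# with P^t[C, .] the t-step distribution of a walk started uniformly on C
# and w(k) the vertex's total transition weight.  Following the reference
# implementation, every vertex carries a self-loop whose weight equals its
# average incident edge weight (1 for unweighted graphs), which makes the
# walk lazy and well defined on leaves and isolates.
#
# Distance bookkeeping mirrors the reference implementation exactly,
# including its lazy-evaluation scheme: when two communities merge, a
# neighbour adjacent to both parts gets the exact Ward (Lance-Williams)
# update,
#
#   ds(C3,C) = ((s1+sc) ds(C1,C) + (s2+sc) ds(C2,C) - sc ds(C1,C2)) / (s1+s2+sc)
#
# while a neighbour adjacent to only one part gets a cheap placeholder with
# the unavailable distance replaced by ds(C1,C2), flagged as inexact.  A
# placeholder is recomputed from the probability vectors only if it reaches
# the current minimum; overestimating placeholders are never revisited, so
# the merge sequence follows the reference implementation merge for merge,
# not an idealised exact greedy.
#
# The dendrogram is cut at the partition of maximum Newman-Girvan modularity
# (original edges only, self-loops excluded).  Modularity is accumulated in
# the reference implementation's community-slot order (singletons first,
# merged communities appended in creation order) so that even floating-point
# ties resolve identically.  Isolated vertices never merge and count as
# their own communities.

#' Walktrap community detection
#'
#' @param graph an igraph object (undirected, simple, unweighted).
#' @param steps random-walk length `t`; default 4, the common published
#'   default.
#' @return list with `membership` (named integer vector, labels 1..k),
#'   `n_clusters`, and `modularity` (the modularity at the chosen cut).
#' @export
walktrap_communities <- function(graph, steps = 4) {
  stopifnot(steps >= 1)
  n <- igraph::vcount(graph)
  if (n == 0) return(list(membership = integer(0), n_clusters = 0L,
                          modularity = NA_real_))
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  deg <- rowSums(A)
  m <- sum(deg) / 2
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))

  if (m == 0) {
    memb <- seq_len(n); names(memb) <- vnames
    return(list(membership = memb, n_clusters = n, modularity = 0))
  }

  # lazy self-loop: weight = mean incident edge weight (1 when unweighted)
  tw <- deg + 1
  P <- A / tw
  diag(P) <- diag(P) + 1 / tw
  Pt <- diag(n)
  for (s in seq_len(steps)) Pt <- Pt %*% P
  # scaled vectors: squared row differences give r^2
  W0 <- sweep(Pt, 2, 1 / sqrt(tw), `*`)

  # community slots as in the reference implementation: 1..n singletons,
  # each merge appends a new slot
  nslot <- 2 * n
  size <- c(rep(1, n), rep(NA_real_, n))
  active <- c(rep(TRUE, n), rep(FALSE, n))
  int_w <- c(rep(0, n), rep(NA_real_, n))        # internal edge weight
  tot_w <- c(deg / 2, rep(NA_real_, n))          # half-degree convention
  members <- c(as.list(seq_len(n)), vector("list", n))
  Wc <- rbind(W0, matrix(NA_real_, n, n))
  D <- matrix(NA_real_, nslot, nslot)
  E <- matrix(FALSE, nslot, nslot)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (A[i, j] > 0) {
        D[i, j] <- D[j, i] <- 0.5 * sum((W0[i, ] - W0[j, ])^2)
        E[i, j] <- E[j, i] <- TRUE
      }
    }
  }

  # modularity accumulated in ascending slot order, matching the reference
  # implementation's floating-point summation
  n_created <- n
  mod_now <- function() {
    q <- 0
    for (i in seq_len(n_created)) {
      if (active[i]) q <- q + (int_w[i] - tot_w[i] * tot_w[i] / m)
    }
    q / m
  }
  partitions <- list(rep(seq_len(n)))
  part_of <- seq_len(n)
  mods <- mod_now()

  repeat {
    if (all(is.na(D))) break
    # pop the minimum, lazily recomputing placeholders that surface
    repeat {
      mn <- min(D, na.rm = TRUE)
      idx <- which(D == mn, arr.ind = TRUE)
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      a <- idx[1, 1]; b <- idx[1, 2]
      if (E[a, b]) break
      ex <- size[a] * size[b] / (size[a] + size[b]) *
        sum((Wc[a, ] - Wc[b, ])^2)
      D[a, b] <- D[b, a] <- ex
      E[a, b] <- E[b, a] <- TRUE
    }
    s1 <- size[a]; s2 <- size[b]; d12 <- D[a, b]
    new <- n_created + 1L
    va <- members[[a]]; vb <- members[[b]]
    cross <- sum(A[va, vb, drop = FALSE])
    for (c in which(active)) {
      if (c == a || c == b) next
      d1 <- D[a, c]; d2 <- D[b, c]; sc <- size[c]
      if (!is.na(d1) && !is.na(d2)) {
        D[new, c] <- D[c, new] <-
          ((s1 + sc) * d1 + (s2 + sc) * d2 - sc * d12) / (s1 + s2 + sc)
        E[new, c] <- E[c, new] <- E[a, c] && E[b, c]
      } else if (!is.na(d1)) {
        D[new, c] <- D[c, new] <- ((s1 + sc) * d1 + s2 * d12) / (s1 + s2 + sc)
      } else if (!is.na(d2)) {
        D[new, c] <- D[c, new] <- (s1 * d12 + (s2 + sc) * d2) / (s1 + s2 + sc)
      }
    }
    Wc[new, ] <- (s1 * Wc[a, ] + s2 * Wc[b, ]) / (s1 + s2)
    size[new] <- s1 + s2
    int_w[new] <- int_w[a] + int_w[b] + cross
    tot_w[new] <- tot_w[a] + tot_w[b]
    members[[new]] <- c(va, vb)
    active[new] <- TRUE
    active[a] <- FALSE; active[b] <- FALSE
    D[c(a, b), ] <- NA; D[, c(a, b)] <- NA
    E[c(a, b), ] <- FALSE; E[, c(a, b)] <- FALSE
    n_created <- new
    part_of[members[[new]]] <- new
    partitions[[length(partitions) + 1]] <- part_of
    mods <- c(mods, mod_now())
  }

  pick <- which.max(mods)
  memb_raw <- partitions[[pick]]
  memb <- match(memb_raw, sort(unique(memb_raw)))
  names(memb) <- vnames
  list(membership = memb, n_clusters = length(unique(memb)),
       modularity = mods[pick])
}
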