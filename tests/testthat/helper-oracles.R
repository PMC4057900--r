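# Independent oracles used across the suite.

# Floyd-Warshall all-pairs shortest paths on a unit-length edge list.
# Deliberately naive: O(V^3) triple loop, no BFS.
fw_distances <- function(edges, vertex_names) {
  n <- length(vertex_names)
  d <- matrix(Inf, n, n, dimnames = list(vertex_names, vertex_names))
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- match(edges[r, 1], vertex_names)
    j <- match(edges[r, 2], vertex_names)
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Distance oracle for a congener: Floyd-Warshall over the skeleton edge
# list (shares the graph construction, not the distance algorithm).
oracle_distances <- function(spec) {
  sk <- build_skeleton(spec)
  fw_distances(sk$edges, sk$vertices$name)
}

# Naive descriptor oracle: re-derives the reciprocal-square sums straight
# from the oracle distance matrix with explicit double loops.
oracle_mdev <- function(spec) {
  sk <- build_skeleton(spec)
  d <- fw_distances(sk$edges, sk$vertices$name)
  v <- sk$vertices
  br <- v$name[v$element == "Br"]
  rings <- list(A = v$name[v$ring == "A"], B = v$name[v$ring == "B"])
  mu1 <- 0
  if (length(br) >= 2) {
    for (i in seq_along(br)) {
      for (j in seq_along(br)) {
        if (j > i) mu1 <- mu1 + 1 / d[br[i], br[j]]^2
      }
    }
  }
  mu2 <- 0
  for (b in br) {
    for (ring in rings) mu2 <- mu2 + 1 / min(d[b, ring])^2
  }
  list(mu1 = mu1, mu2 = mu2, mu3 = 1 / min(d[rings$A, rings$B])^2)
}

# Random congener spec with at least min_br bromines.
random_spec <- function(min_br = 1L) {
  repeat {
    a <- (2:6)[stats::runif(5) < 0.5]
    b <- (2:6)[stats::runif(5) < 0.5]
    if (length(a) + length(b) >= min_br) {
      return(congener_spec(a, b))
    }
  }
}

# 6-cycle distance between ring positions.
ring_cycle_dist <- function(p, q) {
  d <- abs(p - q) %% 6L
  as.integer(min(d, 6L - d))
}
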