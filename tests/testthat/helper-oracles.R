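# Independent brute-force oracles and fixture generators. These deliberately
# avoid the package's own code paths: distances by Floyd-Warshall, clustering
# by neighbor-pair enumeration, moving SD by explicit per-window stats::sd.

# -- kinematics ---------------------------------------------------------------

# Direct two-pass evaluation of the four RMS metrics from raw r/w series.
oracle_sdr <- function(r) {
  m <- sum(r) / length(r)
  s <- 0
  for (v in r) s <- s + (v - m)^2
  sqrt(s / length(r))
}
oracle_rmse <- function(v, ref) {
  s <- 0
  for (x in v) s <- s + (x - ref)^2
  sqrt(s / length(v))
}

random_polar_trace <- function(n = 60L) {
  t <- cumsum(runif(n, 0.02, 0.06))
  r <- abs(rnorm(n, 1, 0.3)) + 0.1
  theta <- cumsum(rnorm(n, 0.1, 0.05))
  w <- rnorm(n, 1.5, 0.4)
  structure(list(t = t, r = r, theta = theta, w = w,
                 r_bar = mean(r), w_bar = mean(w),
                 guide_radius = runif(1, 0.5, 2),
                 guide_angular_velocity = 1.5,
                 hand = "right", condition = "RHCW", trial = 1L),
            class = "polar_trace")
}

random_cartesian_trace <- function(n = 80L, rate = 30) {
  t <- (seq_len(n) - 1) / rate
  theta <- 2 * pi * 0.3 * t + cumsum(rnorm(n, 0, 0.01))
  r <- 1 + rnorm(n, 0, 0.05)
  trajectory_trace(t = t, x = r * cos(theta), y = r * sin(theta),
                   guide_radius = 1, guide_angular_velocity = 2 * pi * 0.3)
}

# -- preprocessing ------------------------------------------------------------

oracle_moving_sd <- function(x, window) {
  n <- length(x)
  half_lo <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- i - half_lo
    b <- a + window - 1L
    if (a >= 1L && b <= n) out[i] <- stats::sd(x[a:b])
  }
  out
}

make_conc_recording <- function(mat, fs = 11, events = NULL) {
  nm <- sprintf("c%02d", seq_len(ncol(mat)))
  colnames(mat) <- nm
  regions <- stats::setNames(rep(c("LPFC", "RPFC", "LMC", "RMC", "LOL", "ROL"),
                                 length.out = ncol(mat)), nm)
  nirs_recording(t = (seq_len(nrow(mat)) - 1) / fs, channels = mat,
                 signal_kind = "concentration", channel_regions = regions,
                 events = events)
}

# -- graphs -------------------------------------------------------------------

# Floyd-Warshall all-pairs shortest paths (triple loop).
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_global_efficiency <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(adj)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

oracle_node_efficiency <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + 1 / D[i, j]
    s / (n - 1)
  }, numeric(1))
}

# Fraction of neighbor pairs that are connected, by enumeration.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(u) {
    nb <- which(adj[u, ] != 0)
    k <- length(nb)
    if (k < 2L) return(0)
    cnt <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (adj[nb[a], nb[b]] != 0) cnt <- cnt + 1
    }
    cnt / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(u) {
    nb <- which(adj[u, ] != 0)
    if (length(nb) < 2L) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    D <- oracle_distances(sub)
    s <- 0
    m <- length(nb)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    }
    s / (m * (m - 1))
  }, numeric(1))
}

oracle_connected <- function(adj) all(is.finite(oracle_distances(adj)))

random_connected_graph <- function(n, p = 0.35) {
  repeat {
    a <- matrix(runif(n * n) < p, n, n)
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    diag(a) <- FALSE
    mode(a) <- "numeric"
    if (oracle_connected(a)) return(a)
  }
}

random_weighted_network <- function(n) {
  w <- matrix(runif(n * n, 0.05, 0.95), n, n)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 1
  nm <- sprintf("n%02d", seq_len(n))
  dimnames(w) <- list(nm, nm)
  structure(list(plv = w,
                 channel_regions = stats::setNames(rep("LPFC", n), nm)),
            class = "connectivity_network")
}

# Exhaustive threshold sweep: largest candidate threshold keeping the graph
# connected (candidates are the distinct edge weights).
oracle_bottleneck_threshold <- function(w) {
  cand <- sort(unique(w[upper.tri(w)]), decreasing = TRUE)
  for (tau in cand) {
    adj <- (w >= tau)
    diag(adj) <- FALSE
    mode(adj) <- "numeric"
    if (oracle_connected(adj)) return(tau)
  }
  min(cand)
}

watts_strogatz_adj <- function(n, k, p) {
  g <- igraph::sample_smallworld(1, n, k / 2, p, loops = FALSE, multiple = FALSE)
  a <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  mode(a) <- "numeric"
  a
}

# All connected graphs on <= `max_n` nodes, one per isomorphism class, from
# the graph atlas shipped with igraph (complete up to 7 nodes).
atlas_connected_graphs <- function(max_n = 6L) {
  out <- list()
  for (i in 1:1252) {
    g <- igraph::graph_from_atlas(i)
    if (igraph::vcount(g) < 2L || igraph::vcount(g) > max_n) next
    if (!igraph::is_connected(g)) next
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    mode(a) <- "numeric"
    out[[length(out) + 1L]] <- a
  }
  out
}
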