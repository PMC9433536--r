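# Binary graph metrics on thresholded connectivity networks: clustering
# coefficient, global / node / node-local efficiency, degree, and the
# small-world index against degree-preserving rewired null graphs, plus
# aggregation of channel-level metrics to brain regions.

# All-pairs shortest-path lengths of a simple undirected graph by breadth-first
# expansion of the reachability matrix (adjacency powers over the boolean
# semiring); Inf for disconnected pairs.
#' @noRd
bfs_distances <- function(adj) {
  n <- nrow(adj)
  A <- matrix(as.numeric(adj), n, n)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  frontier <- A > 0
  d <- 1
  while (any(frontier & !reach)) {
    D[frontier & !reach] <- d
    reach <- reach | frontier
    frontier <- (matrix(as.numeric(frontier), n, n) %*% A) > 0
    d <- d + 1
    if (d > n) break
  }
  D
}

#' @noRd
check_adjacency <- function(adj) {
  adj <- adj != 0
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop("`adj` must be a square matrix", call. = FALSE)
  }
  if (any(adj != t(adj))) stop("`adj` must be symmetric", call. = FALSE)
  if (any(diag(adj))) stop("`adj` must have an empty diagonal", call. = FALSE)
  adj
}

#' @noRd
is_connected_adj <- function(adj) {
  all(is.finite(bfs_distances(adj)))
}

#' Global efficiency and clustering coefficient
#'
#' Global efficiency is the mean over ordered node pairs of the inverse
#' shortest-path length (network integration); the clustering coefficient is
#' the mean over nodes of the fraction of neighbor pairs that are themselves
#' connected (network segregation), with 0 for nodes of degree < 2.
#'
#' @param adj Logical/0-1 symmetric adjacency matrix of a connected graph.
#' @return List with `global_efficiency` and `clustering_coefficient`.
#' @export
global_metrics <- function(adj) {
  adj <- check_adjacency(adj)
  D <- bfs_distances(adj)
  if (any(!is.finite(D))) stop("graph must be connected", call. = FALSE)
  n <- nrow(adj)
  inv <- 1 / D
  diag(inv) <- 0
  A <- matrix(as.numeric(adj), n, n)
  k <- rowSums(A)
  tri2 <- diag(A %*% A %*% A)        # 2 x triangles per node ... actually 2*t
  cc <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  list(global_efficiency = sum(inv) / (n * (n - 1)),
       clustering_coefficient = mean(cc))
}

#' Per-node graph metrics
#'
#' Degree (neighbor count), node efficiency (mean inverse distance to every
#' other node), and node-local efficiency (global efficiency of the subgraph
#' induced by the node's neighbors; 0 with fewer than 2 neighbors).
#'
#' @param adj Adjacency matrix of a connected graph.
#' @return Data frame `node`, `degree`, `efficiency`, `local_efficiency`.
#' @export
local_metrics <- function(adj) {
  adj <- check_adjacency(adj)
  D <- bfs_distances(adj)
  if (any(!is.finite(D))) stop("graph must be connected", call. = FALSE)
  n <- nrow(adj)
  inv <- 1 / D
  diag(inv) <- 0
  node_eff <- rowSums(inv) / (n - 1)
  loc_eff <- vapply(seq_len(n), function(u) {
    nb <- which(adj[u, ])
    if (length(nb) < 2L) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    Ds <- bfs_distances(sub)
    invs <- 1 / Ds
    diag(invs) <- 0
    invs[!is.finite(invs)] <- 0
    sum(invs) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  data.frame(node = if (!is.null(rownames(adj))) rownames(adj) else as.character(seq_len(n)),
             degree = as.integer(rowSums(adj)),
             efficiency = node_eff,
             local_efficiency = loc_eff,
             stringsAsFactors = FALSE)
}

# Characteristic path length (mean shortest path over unordered pairs).
#' @noRd
char_path_length <- function(adj) {
  D <- bfs_distances(adj != 0)
  n <- nrow(D)
  sum(D[upper.tri(D)]) / (n * (n - 1) / 2)
}

#' Small-world index
#'
#' `sigma = (C / C_rand) / (L / L_rand)` where `C` is the clustering
#' coefficient, `L` the characteristic path length, and the null values are
#' means over degree-preserving (Maslov-Sneppen) rewired connected graphs.
#' `sigma > 1` indicates small-world organization.
#'
#' @param adj Adjacency matrix of a connected graph with >= 4 nodes.
#' @param n_null Number of null graphs (default 100).
#' @param seed Integer seed for the rewiring.
#' @param rewire_per_edge Rewiring attempts per edge per null (default 10).
#' @return sigma, with attributes `n_null_used`, `C`, `L`, `C_rand`, `L_rand`.
#' @export
small_world_sigma <- function(adj, n_null = 100L, seed = 1L,
                              rewire_per_edge = 10L) {
  adj <- check_adjacency(adj)
  if (nrow(adj) < 4L) stop("need >= 4 nodes", call. = FALSE)
  gm <- global_metrics(adj)
  C <- gm$clustering_coefficient
  L <- char_path_length(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  n_edges <- igraph::ecount(g)
  Cr <- numeric(0)
  Lr <- numeric(0)
  with_seed(seed, {
    attempts <- 0L
    while (length(Cr) < n_null && attempts < 10L * n_null) {
      attempts <- attempts + 1L
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = rewire_per_edge * n_edges))
      ar <- as.matrix(igraph::as_adjacency_matrix(gr)) > 0
      if (!is_connected_adj(ar)) next
      gmr <- global_metrics(ar)
      Cr <- c(Cr, gmr$clustering_coefficient)
      Lr <- c(Lr, char_path_length(ar))
    }
  })
  if (length(Cr) < n_null) {
    warning(sprintf("only %d of %d connected nulls achieved", length(Cr), n_null),
            call. = FALSE)
  }
  if (!length(Cr)) stop("no connected null graph could be generated", call. = FALSE)
  C_rand <- mean(Cr)
  L_rand <- mean(Lr)
  sigma <- if (C_rand == 0) {
    warning("null clustering is 0; sigma undefined, returning NA", call. = FALSE)
    NA_real_
  } else {
    (C / C_rand) / (L / L_rand)
  }
  structure(sigma, n_null_used = length(Cr), C = C, L = L,
            C_rand = C_rand, L_rand = L_rand)
}

#' Aggregate channel-level metrics to regions
#'
#' Unweighted mean of each local metric over the channels mapped to each
#' region. Empty regions are omitted with a warning.
#'
#' @param local Data frame from [local_metrics()] (columns `node` plus metric
#'   columns).
#' @param channel_regions Named character vector, channel -> region.
#' @return Data frame `region` plus the per-region means of every numeric
#'   metric column.
#' @export
region_aggregate <- function(local, channel_regions) {
  stopifnot(is.data.frame(local), "node" %in% names(local))
  unmapped <- setdiff(local$node, names(channel_regions))
  if (length(unmapped)) {
    stop("unmapped channels: ", paste(unmapped, collapse = ", "), call. = FALSE)
  }
  local$region <- unname(channel_regions[local$node])
  empty <- setdiff(unique(channel_regions), local$region)
  if (length(empty)) {
    warning("regions with no channels omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  num_cols <- names(local)[vapply(local, is.numeric, logical(1))]
  out <- stats::aggregate(local[num_cols], by = list(region = local$region), FUN = mean)
  out[order(out$region), , drop = FALSE]
}

#' All network metrics for one thresholded network
#'
#' @param net A [threshold_connected()] result.
#' @param n_null,seed Passed to [small_world_sigma()] (set `n_null = 0` to
#'   skip sigma).
#' @return List with `global` (global efficiency, clustering, sigma), `local`
#'   (per-node data frame) and `regional` (per-region means).
#' @export
network_metric_set <- function(net, n_null = 100L, seed = 1L) {
  stopifnot(inherits(net, "connectivity_network"))
  if (is.null(net$adjacency)) stop("network is not thresholded yet", call. = FALSE)
  adj <- net$adjacency
  gm <- global_metrics(adj)
  lm <- local_metrics(adj)
  sigma <- if (n_null > 0) {
    as.numeric(small_world_sigma(adj, n_null = n_null, seed = seed))
  } else NA_real_
  list(global = c(global_efficiency = gm$global_efficiency,
                  clustering_coefficient = gm$clustering_coefficient,
                  small_world_sigma = sigma),
       local = lm,
       regional = region_aggregate(lm, net$channel_regions))
}
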