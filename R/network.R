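#' Build a Spearman co-occurrence network over features
#'
#' Nodes are features surviving a prevalence filter (constant features are
#' excluded: they have zero rank variance). Every feature pair gets a
#' Spearman correlation with mid-rank ties and a p-value from the t
#' approximation; p-values are BH-corrected across all pairs, and an
#' undirected edge is drawn iff `|rho| >= rho_threshold` and
#' `q <= q_threshold`. Isolated nodes are retained.
#'
#' @param t Abundance matrix (samples x features), at least 4 samples.
#' @param rho_threshold Absolute-correlation threshold for an edge.
#' @param q_threshold BH q-value threshold for an edge.
#' @param min_prevalence Minimum fraction of samples with a non-zero value.
#' @return list(nodes, edges = data.frame(u, v, rho, q)) of class
#'   `cooccurrence_network`.
#' @export
build_network <- function(t, rho_threshold = 0.6, q_threshold = 0.05,
                          min_prevalence = 0.2) {
  t <- as.matrix(t)
  if (nrow(t) < 4L) stop("too few samples for correlation (need >= 4)")
  prev <- colMeans(t > 0)
  keep <- prev >= min_prevalence & apply(t, 2L, function(v) stats::sd(v) > 0)
  nodes <- colnames(t)[keep]
  edges <- data.frame(u = character(0), v = character(0),
                      rho = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(nodes) >= 2L) {
    pairs <- utils::combn(nodes, 2L)
    res <- lapply(seq_len(ncol(pairs)), function(k) {
      spearman_test(t[, pairs[1L, k]], t[, pairs[2L, k]])
    })
    rho <- vapply(res, `[[`, 0, "rho")
    p <- vapply(res, `[[`, 0, "p")
    q <- stats::p.adjust(p, method = "BH")
    sel <- !is.na(rho) & abs(rho) >= rho_threshold & q <= q_threshold
    edges <- data.frame(u = pairs[1L, sel], v = pairs[2L, sel],
                        rho = rho[sel], q = q[sel], stringsAsFactors = FALSE)
  }
  net <- list(nodes = nodes, edges = edges)
  class(net) <- "cooccurrence_network"
  net
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("u", "v"), drop = FALSE],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Summary statistics of a co-occurrence network
#'
#' * density: `2E / (V (V - 1))` over all nodes (isolated ones included);
#' * diameter / radius: max / min vertex eccentricity by unweighted shortest
#'   paths on the largest connected component;
#' * centralization: Freeman degree centralization
#'   `sum_i (d_max - d_i) / ((V - 1)(V - 2))` on the whole graph (0 when
#'   `V < 3`), 1 for a star, 0 for a regular graph;
#' * component_count: number of connected components.
#'
#' @param net A `cooccurrence_network` (or list with `nodes` and `edges`).
#' @return list(density, diameter, radius, centralization, component_count).
#' @export
network_stats <- function(net) {
  v <- length(net$nodes)
  if (v < 1L) stop("network has no nodes")
  e <- nrow(net$edges)
  g <- as_igraph(net)
  density <- if (v < 2L) 0 else 2 * e / (v * (v - 1))
  comp <- igraph::components(g)
  if (e == 0L) {
    diameter <- radius <- 0
  } else {
    giant <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == giant))
    ecc <- igraph::eccentricity(sub)
    diameter <- max(ecc)
    radius <- min(ecc)
  }
  deg <- igraph::degree(g)
  centralization <- if (v < 3L) 0 else
    sum(max(deg) - deg) / ((v - 1) * (v - 2))
  list(density = density, diameter = as.numeric(diameter),
       radius = as.numeric(radius), centralization = centralization,
       component_count = comp$no)
}
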