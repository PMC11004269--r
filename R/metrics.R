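#' Topology panel of a co-occurrence network
#'
#' Computes the standard descriptive panel: edge and node counts split by
#' sign and domain, edge density \eqn{2E/(N(N-1))}, average degree
#' \eqn{2E/N}, average shortest-path length over all connected ordered
#' pairs, and Freeman centralizations of degree, betweenness and closeness.
#' Centralizations use \eqn{C = \sum_i (c_{max} - c_i) / C^{max}} with the
#' classical undirected maxima: \eqn{(N-1)(N-2)} for degree,
#' \eqn{(N-1)^2(N-2)/2} for (unnormalized) betweenness and
#' \eqn{(N-1)(N-2)/(2N-3)} for normalized closeness. On disconnected
#' graphs path length averages over connected pairs only and closeness is
#' computed within each node's component.
#'
#' @param net An \code{igraph} network; edges may carry a \code{sign}
#'   attribute ("+"/"-") and nodes a \code{domain} attribute
#'   ("bacteria"/"fungi"); the corresponding counts are \code{NA} when the
#'   attribute is absent.
#' @return One-row data frame with columns \code{edges},
#'   \code{num_pos_edges}, \code{num_neg_edges}, \code{positive_pct},
#'   \code{nodes}, \code{bacteria_nodes}, \code{fungus_nodes},
#'   \code{edge_density}, \code{average_degree}, \code{average_path_length},
#'   \code{degree_centralization}, \code{betweenness_centralization},
#'   \code{closeness_centralization}.
#' @export
topology_summary <- function(net) {
  stopifnot(inherits(net, "igraph"))
  n <- as.integer(igraph::vcount(net))
  if (n == 0L) stop("empty network: ratio metrics are undefined", call. = FALSE)
  e <- as.integer(igraph::ecount(net))
  sgn <- igraph::edge_attr(net, "sign")
  pos <- if (is.null(sgn)) NA_integer_ else as.integer(sum(sgn == "+"))
  neg <- if (is.null(sgn)) NA_integer_ else as.integer(sum(sgn == "-"))
  dom <- igraph::vertex_attr(net, "domain")
  bac <- if (is.null(dom)) NA_integer_ else as.integer(sum(dom == "bacteria"))
  fun <- if (is.null(dom)) NA_integer_ else as.integer(sum(dom == "fungi"))

  deg <- igraph::degree(net)
  apl <- if (n >= 2L && e >= 1L) {
    igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
  } else NA_real_

  if (n >= 3L) {
    deg_cent <- sum(max(deg) - deg) / ((n - 1) * (n - 2))
    btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
    btw_cent <- sum(max(btw) - btw) / ((n - 1)^2 * (n - 2) / 2)
    clo <- .component_closeness(net)
    clo_cent <- sum(max(clo) - clo) / ((n - 1) * (n - 2) / (2 * n - 3))
  } else {
    deg_cent <- btw_cent <- clo_cent <- NA_real_
  }

  data.frame(edges = e,
             num_pos_edges = pos,
             num_neg_edges = neg,
             positive_pct = if (e > 0 && !is.na(pos)) 100 * pos / e else NA_real_,
             nodes = n,
             bacteria_nodes = bac,
             fungus_nodes = fun,
             edge_density = if (n >= 2L) 2 * e / (n * (n - 1)) else NA_real_,
             average_degree = 2 * e / n,
             average_path_length = apl,
             degree_centralization = deg_cent,
             betweenness_centralization = btw_cent,
             closeness_centralization = clo_cent)
}

# normalized closeness computed within each node's connected component:
# c_i = (n_comp - 1) / sum of distances to the component's other nodes;
# isolated nodes get closeness 0
.component_closeness <- function(net) {
  comp <- igraph::components(net)$membership
  d <- igraph::distances(net)
  vapply(seq_along(comp), function(i) {
    same <- which(comp == comp[i])
    if (length(same) < 2L) return(0)
    (length(same) - 1) / sum(d[i, setdiff(same, i)])
  }, numeric(1))
}

#' Ratio metrics from printed network counts
#'
#' The arithmetic identities tying a topology panel's counts to its ratio
#' rows: \code{average_degree = 2E/N},
#' \code{edge_density = 2E/(N(N-1))} and
#' \code{positive_pct = 100 pos/E}. Useful for checking the internal
#' consistency of published topology tables.
#'
#' @param edges Edge count E.
#' @param nodes Node count N.
#' @param pos_edges Optional count of positive edges.
#' @return One-row data frame with \code{average_degree},
#'   \code{edge_density} and (if \code{pos_edges} given)
#'   \code{positive_pct}.
#' @export
topology_ratios <- function(edges, nodes, pos_edges = NULL) {
  stopifnot(edges >= 0, nodes >= 2)
  out <- data.frame(average_degree = 2 * edges / nodes,
                    edge_density = 2 * edges / (nodes * (nodes - 1)))
  if (!is.null(pos_edges)) out$positive_pct <- 100 * pos_edges / edges
  out
}

#' Natural connectivity
#'
#' The spectral redundancy measure
#' \eqn{\bar\lambda = \ln\left(\frac{1}{N}\sum_i e^{\lambda_i}\right)} where
#' \eqn{\lambda_i} are the eigenvalues of the unweighted, unsigned adjacency
#' matrix. It equals 0 for an edgeless graph, grows with the density of
#' closed walks, and is non-decreasing under edge addition at a fixed node
#' set. Computed with a log-sum-exp guard so large graphs do not overflow.
#'
#' @param net An \code{igraph} network (or square adjacency matrix) with at
#'   least one node.
#' @return Non-negative scalar.
#' @export
natural_connectivity <- function(net) {
  a <- if (inherits(net, "igraph")) {
    if (igraph::vcount(net) == 0L) stop("natural connectivity is undefined for an empty graph", call. = FALSE)
    as.matrix(igraph::as_adjacency_matrix(net, type = "both", sparse = TRUE))
  } else {
    as.matrix(net)
  }
  if (nrow(a) == 0L) stop("natural connectivity is undefined for an empty graph", call. = FALSE)
  a <- (a != 0) * 1       # unsigned, unweighted
  diag(a) <- 0
  lambda <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  m <- max(lambda)
  m + log(mean(exp(lambda - m)))
}

#' Robustness under random node removal
#'
#' Removes a fixed fraction of nodes uniformly at random (nodes that become
#' isolated stay in the subgraph), recomputes natural connectivity and
#' reports the mean and standard error over replicates of the ratio to the
#' intact network's value.
#'
#' @param net An \code{igraph} network.
#' @param fraction Fraction of nodes removed, in \[0, 1); 0 is allowed as a
#'   degenerate mode where the ratio is exactly 1.
#' @param n_reps Number of random-removal replicates (default 100).
#' @param seed Optional integer seed.
#' @return List of class \code{stability_result}:
#'   \code{natural_connectivity_full}, \code{robustness_mean},
#'   \code{robustness_se}, \code{n_reps}, \code{ratios}.
#' @export
robustness <- function(net, fraction = 0.5, n_reps = 100, seed = NULL) {
  stopifnot(inherits(net, "igraph"))
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  n <- igraph::vcount(net)
  n_remove <- floor(fraction * n)
  if (n - n_remove < 1L) stop("removal would leave no nodes", call. = FALSE)
  nc_full <- natural_connectivity(net)
  if (nc_full == 0) {
    stop("natural connectivity of the full network is 0: robustness ratio undefined",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  ratios <- vapply(seq_len(n_reps), function(k) {
    if (n_remove == 0L) return(1)
    keep <- sample.int(n, n - n_remove)
    natural_connectivity(igraph::induced_subgraph(net, keep)) / nc_full
  }, numeric(1))
  structure(
    list(natural_connectivity_full = nc_full,
         robustness_mean = mean(ratios),
         robustness_se = stats::sd(ratios) / sqrt(n_reps),
         n_reps = n_reps,
         ratios = ratios),
    class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Network stability: natural connectivity %.4f\n",
              x$natural_connectivity_full))
  cat(sprintf("  robustness (mean ratio after removal) %.4f +/- %.4f SE over %d reps\n",
              x$robustness_mean, x$robustness_se, x$n_reps))
  invisible(x)
}

#' Natural-connectivity decay curve
#'
#' Mean natural connectivity after removing 0, \code{step}, 2\code{step},
#' ... random nodes (averaged over \code{n_reps} random removal orders per
#' point). The first point is the intact network's value.
#'
#' @param net An \code{igraph} network.
#' @param step Removal increment (>= 1 node).
#' @param n_reps Replicates per removal count (default 10).
#' @param seed Optional integer seed.
#' @return Data frame with \code{nodes_removed},
#'   \code{natural_connectivity} (mean) and \code{se}.
#' @export
connectivity_decay_curve <- function(net, step = 1, n_reps = 10, seed = NULL) {
  stopifnot(inherits(net, "igraph"))
  if (step < 1 || step != round(step)) {
    stop("step must be a positive integer", call. = FALSE)
  }
  n <- igraph::vcount(net)
  if (n < 1L) stop("empty network", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  removals <- seq(0L, n - 1L, by = step)
  res <- lapply(removals, function(r) {
    vals <- vapply(seq_len(n_reps), function(k) {
      if (r == 0L) return(natural_connectivity(net))
      keep <- sample.int(n, n - r)
      natural_connectivity(igraph::induced_subgraph(net, keep))
    }, numeric(1))
    c(mean(vals), stats::sd(vals) / sqrt(n_reps))
  })
  res <- do.call(rbind, res)
  data.frame(nodes_removed = removals,
             natural_connectivity = res[, 1L],
             se = res[, 2L])
}
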