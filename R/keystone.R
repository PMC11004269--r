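#' Detect network modules
#'
#' Partitions the network into modules by modularity maximization. The
#' default \code{"greedy"} agglomeration is deterministic; \code{"louvain"}
#' is seedable multi-level optimization. Singleton components become
#' singleton modules. Edge signs and weights are ignored.
#'
#' @param net An \code{igraph} network with at least one edge.
#' @param method \code{"greedy"} (default) or \code{"louvain"}.
#' @param seed Integer seed (only the Louvain method is stochastic, but the
#'   seed is always applied for reproducibility).
#' @return List of class \code{module_assignment} with \code{membership}
#'   (named integer vector over all nodes), \code{modularity} (Q) and
#'   \code{method}.
#' @export
detect_modules <- function(net, method = c("greedy", "louvain"), seed = 1L) {
  stopifnot(inherits(net, "igraph"))
  method <- match.arg(method)
  if (igraph::ecount(net) == 0L) {
    stop("module detection needs at least one edge", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  comm <- switch(method,
                 greedy = igraph::cluster_fast_greedy(net, weights = NULL),
                 louvain = igraph::cluster_louvain(net, weights = NULL))
  membership <- igraph::membership(comm)
  structure(
    list(membership = stats::setNames(as.integer(membership),
                                      igraph::V(net)$name),
         modularity = igraph::modularity(comm),
         method = method),
    class = "module_assignment")
}

#' Within-module degree z-score (Zi) and participation coefficient (Pi)
#'
#' For node i in module s with \eqn{k_{is}} links to module s,
#' \deqn{Z_i = (k_{is(i)} - \bar k_{s(i)}) / \sigma_{k_{s(i)}}, \qquad
#'       P_i = 1 - \sum_s (k_{is}/k_i)^2,}
#' where the mean and standard deviation are taken over the nodes of i's own
#' module. Zi is set to 0 when the module has fewer than 2 nodes or zero
#' within-degree spread; Pi is 0 for a node whose links all stay in its own
#' module, and is defined as 0 (with a warning) for isolated nodes. Edge
#' signs are ignored.
#'
#' @param net An \code{igraph} network.
#' @param modules A \code{module_assignment} from [detect_modules()] (or a
#'   named membership vector covering every node).
#' @return Data frame with columns \code{node}, \code{module},
#'   \code{degree}, \code{zi}, \code{pi}.
#' @export
zi_pi <- function(net, modules) {
  stopifnot(inherits(net, "igraph"))
  membership <- if (inherits(modules, "module_assignment")) {
    modules$membership
  } else {
    modules
  }
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(net)))
  if (!all(nodes %in% names(membership))) {
    stop("module assignment must cover every network node", call. = FALSE)
  }
  mem <- membership[nodes]
  mods <- sort(unique(mem))
  # k[i, s]: links of node i into module s
  adj <- igraph::as_adjacency_matrix(net, type = "both", sparse = TRUE)
  adj <- (adj != 0) * 1
  ind <- outer(mem, mods, `==`) * 1
  k_is <- as.matrix(adj %*% ind)
  dimnames(k_is) <- list(nodes, mods)
  k_i <- rowSums(k_is)
  if (any(k_i == 0)) {
    warning(sum(k_i == 0),
            " isolated node(s): participation coefficient set to 0",
            call. = FALSE)
  }
  own <- match(mem, mods)
  k_own <- k_is[cbind(seq_along(nodes), own)]
  zi <- numeric(length(nodes))
  for (s in seq_along(mods)) {
    in_s <- which(own == s)
    if (length(in_s) >= 2L) {
      mu <- mean(k_own[in_s])
      sdev <- stats::sd(k_own[in_s])
      if (sdev > 0) zi[in_s] <- (k_own[in_s] - mu) / sdev
    }
  }
  pi_val <- ifelse(k_i == 0, 0, 1 - rowSums((k_is / pmax(k_i, 1))^2))
  data.frame(node = nodes,
             module = as.integer(mem),
             degree = as.integer(k_i),
             zi = zi,
             pi = pi_val,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify nodes into topological roles
#'
#' Guimera-Amaral role assignment from (Zi, Pi) with strict thresholds:
#' network hubs have \code{zi > zi_threshold} and \code{pi > pi_threshold};
#' module hubs \code{zi > zi_threshold} only; connectors
#' \code{pi > pi_threshold} only; everything else (including exact
#' boundary values) is peripheral. The four roles partition the nodes.
#'
#' @param roles Data frame from [zi_pi()] (columns \code{zi}, \code{pi}).
#' @param zi_threshold Within-module degree z-score threshold (default 2.5).
#' @param pi_threshold Participation coefficient threshold (default 0.62).
#' @return The input with a \code{role} factor column added (levels
#'   \code{peripheral}, \code{connector}, \code{module_hub},
#'   \code{network_hub}).
#' @export
classify_nodes <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(all(c("zi", "pi") %in% colnames(roles)))
  hi_z <- roles$zi > zi_threshold
  hi_p <- roles$pi > pi_threshold
  role <- ifelse(hi_z & hi_p, "network_hub",
                 ifelse(hi_z, "module_hub",
                        ifelse(hi_p, "connector", "peripheral")))
  roles$role <- factor(role, levels = c("peripheral", "connector",
                                        "module_hub", "network_hub"))
  roles
}

#' Keystone-taxon relative abundance by treatment
#'
#' Keystone taxa are the non-peripheral nodes of the network (or only the
#' module/network hubs, with \code{keystone = "hubs"}). Their counts are
#' pooled per treatment and aggregated at the requested taxonomic rank;
#' values are proportions of each treatment's total reads, so the column
#' sums equal the treatments' total keystone proportions.
#'
#' @param roles Classified role table from [classify_nodes()].
#' @param table Count matrix (taxa x samples); typically the unfiltered
#'   table so proportions refer to whole-community totals.
#' @param taxonomy Taxonomy data frame covering all keystone taxa.
#' @param metadata Metadata with \code{sample_id} and \code{treatment}.
#' @param rank Taxonomy column to aggregate by (default \code{"phylum"}).
#' @param keystone \code{"non_peripheral"} (default) or \code{"hubs"}.
#' @return Data frame: one row per rank level, one column per treatment;
#'   empty (0 rows) when there are no keystone nodes.
#' @export
keystone_abundance <- function(roles, table, taxonomy, metadata,
                               rank = "phylum",
                               keystone = c("non_peripheral", "hubs")) {
  keystone <- match.arg(keystone)
  stopifnot("role" %in% colnames(roles))
  sel <- if (keystone == "hubs") {
    roles$role %in% c("module_hub", "network_hub")
  } else {
    roles$role != "peripheral"
  }
  key_taxa <- roles$node[sel]
  treatments <- unique(metadata$treatment)
  if (!length(key_taxa)) {
    out <- as.data.frame(matrix(numeric(), 0, length(treatments),
                                dimnames = list(NULL, treatments)))
    out[[rank]] <- character()
    return(out[, c(rank, treatments), drop = FALSE])
  }
  missing <- setdiff(key_taxa, taxonomy$taxon_id)
  if (length(missing)) {
    stop("keystone taxa missing from taxonomy: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!rank %in% colnames(taxonomy)) {
    stop("taxonomy has no '", rank, "' column", call. = FALSE)
  }
  ranks <- taxonomy[[rank]][match(key_taxa, taxonomy$taxon_id)]
  lv <- sort(unique(ranks))
  res <- sapply(treatments, function(tr) {
    ids <- metadata$sample_id[metadata$treatment == tr]
    sub <- table[, colnames(table) %in% ids, drop = FALSE]
    total <- sum(sub)
    vapply(lv, function(r) {
      sum(sub[rownames(sub) %in% key_taxa[ranks == r], , drop = FALSE]) / total
    }, numeric(1))
  })
  res <- matrix(res, nrow = length(lv), ncol = length(treatments),
                dimnames = list(NULL, treatments))
  out <- data.frame(lv, res, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out)[1L] <- rank
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
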