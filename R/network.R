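#' Filter taxa by relative abundance and prevalence
#'
#' Screens a count table before network inference. In
#' \code{"total-proportion"} mode a taxon is retained when its grand-total
#' relative abundance strictly exceeds \code{abundance_threshold} (default
#' 0.1% of all reads) and it is present (count > 0) in strictly more than
#' \code{prevalence_threshold} of the samples (default 60%). In
#' \code{"top-fraction"} mode the abundance screen instead keeps the top
#' \code{ceiling(abundance_threshold * T)} taxa by total abundance, the
#' literal reading of "top 0.1% of taxa", before the same prevalence screen.
#' Original taxon order is preserved; the filter is idempotent.
#'
#' @param table Count matrix, taxa x samples.
#' @param abundance_threshold Proportion in (0, 1).
#' @param prevalence_threshold Proportion of samples in (0, 1).
#' @param abundance_mode \code{"total-proportion"} (default) or
#'   \code{"top-fraction"}.
#' @return The filtered count matrix.
#' @export
filter_taxa <- function(table,
                        abundance_threshold = 0.001,
                        prevalence_threshold = 0.60,
                        abundance_mode = c("total-proportion", "top-fraction")) {
  abundance_mode <- match.arg(abundance_mode)
  if (nrow(table) == 0L) stop("count table is empty", call. = FALSE)
  for (thr in c(abundance_threshold, prevalence_threshold)) {
    if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
      stop("filter thresholds must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  totals <- rowSums(table)
  if (abundance_mode == "total-proportion") {
    abundant <- totals / sum(table) > abundance_threshold
  } else {
    k <- ceiling(abundance_threshold * nrow(table))
    abundant <- rank(-totals, ties.method = "first") <= k
  }
  prevalent <- rowMeans(table > 0) > prevalence_threshold
  table[abundant & prevalent, , drop = FALSE]
}

#' Infer significant Spearman co-occurrence edges
#'
#' Tests every unordered pair of taxa with Spearman rank correlation
#' (average ranks for ties) and keeps pairs with \eqn{\rho^2} strictly above
#' \code{rho2_threshold} and (optionally BH-corrected) p strictly below
#' \code{alpha}. P-values use the t-distribution approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom.
#' The default \code{rho2_threshold = 0.9} corresponds to
#' \eqn{|\rho| > 0.9487}; set it to 0.81 for the looser \eqn{|\rho| > 0.9}
#' convention. Taxa constant across samples are excluded with a warning
#' (their correlation is undefined).
#'
#' @param table Count matrix (taxa x samples) with at least
#'   \code{min_samples} samples.
#' @param rho2_threshold Squared-correlation retention threshold in (0, 1).
#' @param alpha Significance level.
#' @param correction \code{"none"} (default) or \code{"BH"}
#'   (Benjamini-Hochberg across all tested pairs).
#' @param min_samples Hard floor on the number of samples (default 5; the
#'   t approximation is unreliable below).
#' @return Data frame of retained edges: \code{taxon_a}, \code{taxon_b},
#'   \code{rho}, \code{p}, \code{sign} ("+" or "-"). The number of tested
#'   pairs is attached as attribute \code{n_tests}.
#' @export
spearman_edges <- function(table,
                           rho2_threshold = 0.9,
                           alpha = 0.05,
                           correction = c("none", "BH"),
                           min_samples = 5) {
  correction <- match.arg(correction)
  n <- ncol(table)
  if (n < min_samples) {
    stop("Spearman edge inference needs at least ", min_samples,
         " samples (got ", n, ")", call. = FALSE)
  }
  if (rho2_threshold <= 0 || rho2_threshold >= 1) {
    stop("rho2_threshold must lie in (0, 1)", call. = FALSE)
  }
  constant <- apply(table, 1L, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    warning(sum(constant), " taxa constant across samples excluded from edge testing",
            call. = FALSE)
    table <- table[!constant, , drop = FALSE]
  }
  t_taxa <- nrow(table)
  if (t_taxa < 2L) {
    out <- data.frame(taxon_a = character(), taxon_b = character(),
                      rho = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_tests") <- 0L
    return(out)
  }
  rho <- stats::cor(t(table), method = "spearman")
  ut <- upper.tri(rho)
  r <- rho[ut]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  if (correction == "BH") p <- stats::p.adjust(p, method = "BH")
  ia <- row(rho)[ut]
  ib <- col(rho)[ut]
  keep <- r^2 > rho2_threshold & p < alpha
  out <- data.frame(taxon_a = rownames(table)[ia[keep]],
                    taxon_b = rownames(table)[ib[keep]],
                    rho = r[keep],
                    p = p[keep],
                    sign = ifelse(r[keep] > 0, "+", "-"),
                    stringsAsFactors = FALSE)
  attr(out, "n_tests") <- sum(ut)
  out
}

#' Assemble a signed cross-domain network
#'
#' Builds an undirected simple \code{igraph} graph from retained edges.
#' Nodes are taxa incident to at least one edge (plus, optionally, isolated
#' retained taxa) and carry \code{domain} and \code{phylum} attributes from
#' the taxonomy; edges carry \code{rho}, \code{p} and \code{sign}.
#'
#' @param edges Edge data frame from [spearman_edges()].
#' @param taxonomy Taxonomy data frame with \code{taxon_id} and
#'   \code{domain} columns; every edge endpoint must appear.
#' @param include_isolated If \code{TRUE}, also add the edge-less taxa in
#'   \code{taxa}.
#' @param taxa Character vector of retained taxon ids (required when
#'   \code{include_isolated = TRUE}).
#' @return An \code{igraph} object.
#' @export
build_network <- function(edges, taxonomy, include_isolated = FALSE,
                          taxa = NULL) {
  node_ids <- unique(c(edges$taxon_a, edges$taxon_b))
  if (include_isolated) {
    if (is.null(taxa)) {
      stop("include_isolated = TRUE requires the retained taxa via 'taxa'",
           call. = FALSE)
    }
    node_ids <- unique(c(node_ids, taxa))
  }
  missing <- setdiff(node_ids, taxonomy$taxon_id)
  if (length(missing)) {
    stop("taxa missing from taxonomy: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...", call. = FALSE)
  }
  idx <- match(node_ids, taxonomy$taxon_id)
  vertices <- data.frame(name = node_ids,
                         domain = taxonomy$domain[idx],
                         stringsAsFactors = FALSE)
  if ("phylum" %in% colnames(taxonomy)) {
    vertices$phylum <- taxonomy$phylum[idx]
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Per-treatment network construction
#'
#' Runs the filter/correlate/build chain for one treatment: the abundance
#' and prevalence screens use that treatment's samples, while correlations
#' are computed either across all samples (\code{samples = "all"}, the
#' default, appropriate when per-treatment replication is too small for
#' rank correlation) or within the treatment's samples only.
#'
#' @param table Full count matrix.
#' @param metadata Metadata with \code{sample_id} and \code{treatment}.
#' @param taxonomy Taxonomy table.
#' @param treatment Treatment label to build the network for.
#' @param samples \code{"all"} or \code{"treatment"}: which samples feed the
#'   correlations.
#' @param ... Passed on to [filter_taxa()] and [spearman_edges()]
#'   (\code{abundance_threshold}, \code{prevalence_threshold},
#'   \code{rho2_threshold}, \code{alpha}, \code{correction}).
#' @return An \code{igraph} network.
#' @export
treatment_network <- function(table, metadata, taxonomy, treatment,
                              samples = c("all", "treatment"), ...) {
  samples <- match.arg(samples)
  dots <- list(...)
  filt_args <- dots[names(dots) %in% c("abundance_threshold",
                                       "prevalence_threshold", "abundance_mode")]
  edge_args <- dots[names(dots) %in% c("rho2_threshold", "alpha",
                                       "correction", "min_samples")]
  ids <- metadata$sample_id[metadata$treatment == treatment]
  if (!length(ids)) stop("unknown treatment: ", treatment, call. = FALSE)
  sub <- table[, colnames(table) %in% ids, drop = FALSE]
  kept <- do.call(filter_taxa, c(list(sub), filt_args))
  corr_tab <- if (samples == "all") {
    table[rownames(kept), , drop = FALSE]
  } else {
    kept
  }
  edges <- do.call(spearman_edges, c(list(corr_tab), edge_args))
  build_network(edges, taxonomy)
}
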