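#' Abundance-based coverage estimator (ACE) of richness
#'
#' Chao & Lee's ACE splits taxa into rare (count <= \code{rare_cutoff}) and
#' abundant groups and estimates the unseen richness from the rare-group
#' frequency counts:
#' \deqn{S_{ACE} = S_{abund} + S_{rare}/C_{ACE} + (F_1/C_{ACE})\gamma^2}
#' with sample coverage \eqn{C_{ACE} = 1 - F_1/N_{rare}} and coefficient of
#' variation \eqn{\gamma^2 = \max[(S_{rare}/C_{ACE}) \sum i(i-1)F_i /
#' (N_{rare}(N_{rare}-1)) - 1,\, 0]}. When every rare read is a singleton
#' (\eqn{C_{ACE} = 0}) the estimator is undefined and the bias-corrected
#' Chao1 estimate \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} is returned instead,
#' mirroring common ecology-software behaviour.
#'
#' @param v Non-negative integer abundance vector for one sample.
#' @param rare_cutoff Count at or below which a taxon is "rare" (default 10).
#' @return Estimated richness (>= observed richness of the rare/abundant
#'   split assumptions; equals observed richness when there are no rare taxa).
#' @export
ace_index <- function(v, rare_cutoff = 10) {
  v <- .check_abundance(v)
  x <- v[v > 0]
  s_abund <- sum(x > rare_cutoff)
  rare <- x[x <= rare_cutoff]
  s_rare <- length(rare)
  if (s_rare == 0L) {
    return(s_abund)
  }
  n_rare <- sum(rare)
  f1 <- sum(rare == 1L)
  if (n_rare == f1) {
    # all rare reads are singletons: coverage 0, fall back to bias-corrected Chao1
    f2 <- sum(x == 2L)
    return(length(x) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  c_ace <- 1 - f1 / n_rare
  i <- seq_len(rare_cutoff)
  f_i <- vapply(i, function(k) sum(rare == k), numeric(1))
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * f_i) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Gini-Simpson diversity index
#'
#' Returns \eqn{1 - \sum_i p_i^2}, the probability that two reads drawn at
#' random belong to different taxa: 0 for a single-taxon sample,
#' \eqn{1 - 1/S} for S equally abundant taxa. (The complement orientation is
#' used because highly diverse amplicon communities then score near 1.)
#'
#' @param v Non-negative abundance vector with positive total.
#' @return Value in \[0, 1).
#' @export
simpson_index <- function(v) {
  v <- .check_abundance(v)
  p <- v / sum(v)
  1 - sum(p^2)
}

#' Analytic rarefaction curve
#'
#' Expected richness in a random subsample of \code{m} reads drawn without
#' replacement: \eqn{E[S_m] = \sum_i [1 - \binom{N-N_i}{m}/\binom{N}{m}]}
#' (computed through \code{vegan::rarefy}).
#'
#' @param v Non-negative integer abundance vector.
#' @param depths Subsample sizes; each must be at most \code{sum(v)}.
#' @return Data frame with columns \code{depth} and \code{richness};
#'   \code{richness} is non-decreasing and equals observed richness at full
#'   depth.
#' @export
rarefaction_curve <- function(v, depths) {
  v <- .check_abundance(v)
  if (any(depths < 1) || any(depths != round(depths))) {
    stop("depths must be positive integers", call. = FALSE)
  }
  if (any(depths > sum(v))) {
    stop("depth exceeds the sample's total count (", sum(v), ")", call. = FALSE)
  }
  rich <- vapply(depths, function(m) {
    # vegan nags when the vector has no singletons; irrelevant for the
    # analytic expectation
    suppressWarnings(unname(vegan::rarefy(v, sample = m)))
  }, numeric(1))
  data.frame(depth = depths, richness = rich)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between all
#' sample pairs of a count table (delegated to \code{vegan::vegdist}).
#'
#' @param table Count matrix, taxa x samples, with >= 2 samples.
#' @return Symmetric matrix in \[0, 1\] with zero diagonal and sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(table) {
  if (ncol(table) < 2L) {
    stop("Bray-Curtis dissimilarity needs at least 2 samples", call. = FALSE)
  }
  tot <- colSums(table)
  if (any(tot == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(table)[tot == 0], collapse = ", "), call. = FALSE)
  }
  as.matrix(vegan::vegdist(t(table), method = "bray"))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones. With average ranks \eqn{\bar r_B} and
#' \eqn{\bar r_W} of the \eqn{M = n(n-1)/2} pairwise dissimilarities,
#' \deqn{R = (\bar r_B - \bar r_W) / (n(n-1)/4),}
#' so R is 1 under perfect separation and scatters around 0 under the null.
#' The p-value uses the add-one permutation estimator
#' \eqn{p = (1 + \#\{R_{perm} \ge R\}) / (1 + n_{perm})}; ties in
#' dissimilarities receive average ranks.
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param groups Group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return List with \code{statistic} (R), \code{p_value}, \code{n_perm}.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.factor(groups)
  if (length(groups) != n) {
    stop("'groups' must have one label per sample", call. = FALSE)
  }
  if (nlevels(droplevels(groups)) < 2L) {
    stop("ANOSIM needs at least 2 groups", call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("every group must contain at least 2 samples", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  lt <- lower.tri(d)
  r <- rank(d[lt])  # average ranks for ties
  pair_i <- row(d)[lt]
  pair_j <- col(d)[lt]
  denom <- n * (n - 1) / 4
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  r_obs <- stat(groups)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  r_perm <- vapply(seq_len(n_perm), function(k) stat(sample(groups)),
                   numeric(1))
  list(statistic = r_obs,
       p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Per-sample alpha-diversity table
#'
#' Convenience wrapper computing observed richness, ACE and Gini-Simpson for
#' every sample of a count table.
#'
#' @param table Count matrix, taxa x samples.
#' @param rare_cutoff Passed to [ace_index()].
#' @return Data frame with one row per sample.
#' @export
alpha_diversity <- function(table, rare_cutoff = 10) {
  data.frame(sample_id = colnames(table),
             observed = colSums(table > 0),
             ace = apply(table, 2L, ace_index, rare_cutoff = rare_cutoff),
             simpson = apply(table, 2L, simpson_index),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

.check_abundance <- function(v) {
  v <- as.numeric(v)
  if (anyNA(v) || any(v < 0)) {
    stop("abundance vector must be non-negative and complete", call. = FALSE)
  }
  if (sum(v) <= 0) {
    stop("abundance vector has zero total count", call. = FALSE)
  }
  v
}
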