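#' Percent change relative to a control mean
#'
#' \eqn{100 (treated - control)/control}, rounded half-up to 2 decimal
#' places. Scale-invariant: multiplying both means by the same positive
#' factor leaves the value unchanged.
#'
#' @param treated_mean,control_mean Group means; \code{control_mean} must be
#'   non-zero. Vectorized over \code{treated_mean}.
#' @return Percent change(s) to 2 d.p.
#' @export
percent_change <- function(treated_mean, control_mean) {
  if (any(control_mean == 0)) {
    stop("percent change is undefined for a zero control mean", call. = FALSE)
  }
  round_half_up(100 * (treated_mean - control_mean) / control_mean, 2L)
}

#' Round half away from zero
#'
#' Decimal rounding where .5 always rounds away from zero (the convention of
#' most published tables), unlike base \code{round}'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' One-way ANOVA with LSD compact letter display
#'
#' Fits a one-way ANOVA, then performs all pairwise Fisher LSD t-tests with
#' the pooled mean-square error (\eqn{t = (\bar y_i - \bar y_j) /
#' \sqrt{MSE (1/n_i + 1/n_j)}} on the residual degrees of freedom) and
#' summarises them as letters: groups sharing a letter are not significantly
#' different at \code{alpha}, groups sharing none are. Letters are derived
#' from the maximal cliques of the non-significance graph and ordered by
#' descending group mean, so the display is valid for any significance
#' pattern. When the pooled MSE is zero, identical means share a letter and
#' distinct means do not.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @param alpha Significance level for the pairwise tests (default 0.05).
#' @param control Group treated as the control for percent changes (default
#'   the first factor level).
#' @return List of class \code{anova_lsd}: \code{summary} (group, n, mean,
#'   se, letters, pct_change), \code{f_value}, \code{p_value},
#'   \code{pairwise} (data frame of all pairwise tests), \code{alpha}.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05, control = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  if (length(values) != length(groups)) {
    stop("'values' and 'groups' lengths differ", call. = FALSE)
  }
  lv <- levels(groups)
  k <- length(lv)
  if (is.null(control)) control <- lv[1L]

  fit <- stats::aov(values ~ groups)
  # anova.lm warns on an exact zero-residual fit; the MSE = 0 case is
  # handled explicitly below
  ftab <- suppressWarnings(stats::anova(fit))
  mse <- ftab["Residuals", "Mean Sq"]
  df_res <- ftab["Residuals", "Df"]
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ses <- tapply(values, groups, function(x) stats::sd(x) / sqrt(length(x)))

  pairs <- utils::combn(k, 2)
  p_pair <- apply(pairs, 2L, function(ij) {
    diff <- means[ij[1L]] - means[ij[2L]]
    if (mse == 0) return(if (diff == 0) 1 else 0)
    tval <- diff / sqrt(mse * (1 / ns[ij[1L]] + 1 / ns[ij[2L]]))
    2 * stats::pt(-abs(tval), df_res)
  })
  pairwise <- data.frame(group_a = lv[pairs[1L, ]],
                         group_b = lv[pairs[2L, ]],
                         p = p_pair,
                         stringsAsFactors = FALSE)
  letters_out <- .letter_display(lv, means, pairwise, alpha)

  summary_df <- data.frame(group = lv,
                           n = as.integer(ns),
                           mean = as.numeric(means),
                           se = as.numeric(ses),
                           letters = letters_out,
                           pct_change = percent_change(as.numeric(means),
                                                       means[[control]]),
                           stringsAsFactors = FALSE)
  structure(
    list(summary = summary_df,
         f_value = ftab["groups", "F value"],
         p_value = ftab["groups", "Pr(>F)"],
         pairwise = pairwise,
         alpha = alpha),
    class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g; LSD letters at alpha = %g\n",
              x$f_value, x$p_value, x$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# compact letter display from maximal cliques of the non-significance graph;
# guarantees: share a letter <=> the pair is non-significant at alpha
.letter_display <- function(lv, means, pairwise, alpha) {
  k <- length(lv)
  nonsig <- matrix(FALSE, k, k, dimnames = list(lv, lv))
  diag(nonsig) <- TRUE
  for (r in seq_len(nrow(pairwise))) {
    if (pairwise$p[r] >= alpha) {
      nonsig[pairwise$group_a[r], pairwise$group_b[r]] <- TRUE
      nonsig[pairwise$group_b[r], pairwise$group_a[r]] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(nonsig, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  # order cliques by the largest member mean so 'a' marks the top group
  ord <- order(vapply(cliques, function(cl) -max(means[lv[as.integer(cl)]]),
                      numeric(1)))
  cliques <- cliques[ord]
  lab <- rep("", k)
  for (ci in seq_along(cliques)) {
    members <- as.integer(cliques[[ci]])
    lab[members] <- paste0(lab[members], letters[ci])
  }
  lab
}

#' Pairwise Pearson correlation panel
#'
#' Pearson r, two-sided p (t approximation on n-2 degrees of freedom) and
#' significance stars for every column pair of two matched tables, e.g.
#' soil covariates against network topology metrics.
#'
#' @param x,y Numeric matrices or data frames with matched rows.
#' @return List of class \code{pearson_panel} with matrices \code{r},
#'   \code{p}, \code{stars} ("" / "*" p < 0.05 / "**" p < 0.01) and
#'   \code{n}. Zero-variance columns are flagged with a warning and yield
#'   \code{NA} entries.
#' @export
pearson_matrix <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("'x' and 'y' must have matched rows", call. = FALSE)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 matched rows", call. = FALSE)
  const_x <- apply(x, 2L, stats::sd) == 0
  const_y <- apply(y, 2L, stats::sd) == 0
  if (any(const_x) || any(const_y)) {
    warning("zero-variance column(s): ",
            paste(c(colnames(x)[const_x], colnames(y)[const_y]), collapse = ", "),
            " (correlation undefined, set to NA)", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(x, y))
  r[const_x, ] <- NA_real_
  r[, const_y] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = n),
            class = "pearson_panel")
}

#' LMG relative importance decomposition
#'
#' Decomposes the \eqn{R^2} of a multiple linear regression into
#' non-negative per-predictor shares by averaging each predictor's
#' incremental \eqn{R^2} over all orderings in which it can enter the model
#' (equivalently, over all subsets with the ordering weights
#' \eqn{|S|!(p-|S|-1)!/p!}). The shares sum exactly to the full-model
#' \eqn{R^2} and do not depend on the input order of the predictors.
#' Exact subset enumeration restricts the method to at most 8 predictors.
#'
#' @param response Numeric response vector.
#' @param predictors Numeric matrix or data frame of predictors
#'   (\code{n > p + 1} rows, \code{p <= 8} columns, full column rank).
#' @return List of class \code{importance_shares}: \code{shares} (named,
#'   summing to \code{r_squared}), \code{r_squared}.
#' @export
lmg_importance <- function(response, predictors) {
  x <- as.matrix(predictors)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(response)
  p <- ncol(x)
  n <- nrow(x)
  if (p > 8L) {
    stop("at most 8 predictors are supported by exact enumeration; select a subset",
         call. = FALSE)
  }
  if (length(y) != n) stop("response and predictors lengths differ", call. = FALSE)
  if (n <= p + 1L) stop("need more observations than predictors + 1", call. = FALSE)
  if (qr(cbind(1, x))$rank < p + 1L) {
    stop("predictors are collinear to singularity; remove redundant columns",
         call. = FALSE)
  }
  # centered cross-products give R^2 for any subset without refitting
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- crossprod(xc)
  sxy <- crossprod(xc, yc)
  syy <- sum(yc^2)
  if (syy == 0) stop("response has zero variance", call. = FALSE)
  r2 <- function(idx) {
    if (!length(idx)) return(0)
    drop(crossprod(sxy[idx, , drop = FALSE],
                   solve(sxx[idx, idx, drop = FALSE],
                         sxy[idx, , drop = FALSE]))) / syy
  }
  # cache R^2 for all subsets keyed by bitmask
  r2_cache <- vapply(0:(2^p - 1), function(mask) {
    r2(which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0))
  }, numeric(1))
  shares <- numeric(p)
  fact <- factorial(0:p)
  for (k in seq_len(p)) {
    bit_k <- 2^(k - 1L)
    others <- 0:(2^p - 1)
    others <- others[bitwAnd(others, bit_k) == 0]
    for (mask in others) {
      sz <- sum(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
      w <- fact[sz + 1L] * fact[p - sz] / fact[p + 1L]
      shares[k] <- shares[k] +
        w * (r2_cache[mask + bit_k + 1L] - r2_cache[mask + 1L])
    }
  }
  structure(
    list(shares = stats::setNames(shares, colnames(x)),
         r_squared = r2_cache[2^p]),
    class = "importance_shares")
}

#' @export
print.importance_shares <- function(x, ...) {
  cat(sprintf("LMG relative importance (full-model R^2 = %.4f)\n", x$r_squared))
  print(round(x$shares, 4))
  invisible(x)
}

#' Treatment summary table for several variables
#'
#' Applies [anova_lsd()] to each numeric column of a metadata-style data
#' frame, producing a publication-shaped table of mean +/- SE with LSD
#' letters and percent change versus the control.
#'
#' @param data Data frame with a \code{treatment} column and numeric
#'   variable columns.
#' @param variables Columns to summarise (default: all numeric columns
#'   except \code{treatment}).
#' @param alpha Significance level for the letter displays.
#' @return Data frame with columns \code{variable}, \code{treatment},
#'   \code{mean}, \code{se}, \code{letters}, \code{pct_change},
#'   \code{f_value}, \code{p_value}.
#' @export
treatment_summary <- function(data, variables = NULL, alpha = 0.05) {
  stopifnot("treatment" %in% colnames(data))
  if (is.null(variables)) {
    variables <- setdiff(colnames(data)[vapply(data, is.numeric, TRUE)],
                         "treatment")
  }
  out <- lapply(variables, function(v) {
    res <- anova_lsd(data[[v]], data$treatment, alpha = alpha)
    cbind(variable = v, res$summary[, c("group", "mean", "se", "letters",
                                        "pct_change")],
          f_value = res$f_value, p_value = res$p_value)
  })
  out <- do.call(rbind, out)
  colnames(out)[colnames(out) == "group"] <- "treatment"
  rownames(out) <- NULL
  out
}
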