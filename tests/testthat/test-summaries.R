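test_that("percent change reproduces published-table arithmetic", {
  expect_equal(percent_change(36.45, 15.34), 137.61)
  expect_equal(percent_change(854.90, 551.70), 54.96)
  expect_equal(percent_change(7.3, 7.3), 0)
  expect_error(percent_change(5, 0), "zero control")
  # scale invariance
  with_seed(71, {
    for (rep in 1:10) {
      x <- runif(1, 1, 100); y <- runif(1, 1, 100); a <- runif(1, 0.1, 50)
      expect_equal(percent_change(a * x, a * y), percent_change(x, y))
    }
  })
})

test_that("half-up rounding rounds .5 away from zero", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(round_half_up(-1.25, 1), -1.3)
  expect_equal(round_half_up(2.4, 0), 2)
})

test_that("LSD letters collapse for identical groups and separate distant ones", {
  all_same <- anova_lsd(rep(5, 12), rep(c("A", "B", "C", "D"), each = 3))
  expect_true(all(all_same$summary$letters == "a"))

  with_seed(72, {
    v <- c(rnorm(3, 0, 1), rnorm(3, 100, 1))
    res <- anova_lsd(v, rep(c("lo", "hi"), each = 3))
    # letters ordered by descending mean: 'hi' gets 'a'
    expect_equal(res$summary$letters[res$summary$group == "hi"], "a")
    expect_equal(res$summary$letters[res$summary$group == "lo"], "b")
    expect_lt(res$p_value, 1e-6)
  })
  expect_error(anova_lsd(1:3, c("a", "a", "b")), "at least 2 observations")
})

test_that("letter displays exactly encode the pairwise LSD tests", {
  share_letter <- function(a, b) {
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  }
  with_seed(73, {
    for (rep in 1:12) {
      k <- sample(3:5, 1)
      mu <- rnorm(k, 0, sample(c(0.5, 1, 3), 1))
      v <- rnorm(3 * k, rep(mu, each = 3), 1)
      g <- rep(letters[1:k], each = 3)
      res <- anova_lsd(v, g, alpha = 0.05)
      # oracle: pooled-MSE pairwise t tests computed from scratch
      mse <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / (3 * k - k)
      for (r in seq_len(nrow(res$pairwise))) {
        ga <- res$pairwise$group_a[r]; gb <- res$pairwise$group_b[r]
        tval <- (mean(v[g == ga]) - mean(v[g == gb])) /
          sqrt(mse * (2 / 3))
        p_ref <- 2 * pt(-abs(tval), 3 * k - k)
        expect_equal(res$pairwise$p[r], p_ref, tolerance = 1e-10)
        la <- res$summary$letters[res$summary$group == ga]
        lb <- res$summary$letters[res$summary$group == gb]
        expect_identical(share_letter(la, lb), p_ref >= 0.05)
      }
    }
  })
})

test_that("Pearson panel hits exact anchors and flips sign under reversal", {
  x <- matrix(1:12, ncol = 1, dimnames = list(NULL, "x"))
  y <- cbind(lin = 2 * (1:12) + 1, anti = -(1:12) + 40)
  pan <- pearson_matrix(x, y)
  expect_equal(pan$r["x", "lin"], 1)
  expect_equal(pan$r["x", "anti"], -1)
  expect_equal(pan$stars["x", "lin"], "**")

  with_seed(74, {
    a <- matrix(rnorm(36), ncol = 3)
    b <- matrix(rnorm(24), ncol = 2)
    p1 <- pearson_matrix(a, b)
    p2 <- pearson_matrix(-a, b)
    expect_equal(p2$r, -p1$r, tolerance = 1e-12)
    expect_equal(p2$p, p1$p, tolerance = 1e-12)
  })
  flat <- cbind(c1 = rep(1, 12), c2 = rnorm(12))
  expect_warning(pan <- pearson_matrix(flat, y), "zero-variance")
  expect_true(all(is.na(pan$r["c1", ])))
})

test_that("LMG shares decompose R^2 for orthogonal predictors", {
  with_seed(75, {
    # build exactly orthogonal centered predictors
    q <- qr.Q(qr(cbind(1, matrix(rnorm(40), 20, 2))))[, 2:3]
    colnames(q) <- c("u", "v")
    y <- 3 * q[, 1] - 2 * q[, 2] + rnorm(20, 0, 0.5)
    imp <- lmg_importance(y, q)
    expect_equal(unname(imp$shares["u"]), cor(y, q[, 1])^2, tolerance = 1e-10)
    expect_equal(unname(imp$shares["v"]), cor(y, q[, 2])^2, tolerance = 1e-10)
    expect_equal(sum(imp$shares), imp$r_squared, tolerance = 1e-10)
  })
})

test_that("LMG equals explicit averaging over all predictor orderings", {
  r2_of <- function(y, x, idx) {
    if (!length(idx)) return(0)
    summary(lm(y ~ x[, idx, drop = FALSE]))$r.squared
  }
  with_seed(76, {
    x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    x[, 2] <- x[, 1] * 0.6 + x[, 2]          # induce correlation
    y <- x %*% c(1, 0.5, -0.8) + rnorm(20)
    imp <- lmg_importance(y, x)
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    ref <- numeric(3)
    for (pm in perms) {
      for (pos in 1:3) {
        k <- pm[pos]
        before <- pm[seq_len(pos - 1)]
        ref[k] <- ref[k] +
          (r2_of(y, x, c(before, k)) - r2_of(y, x, before)) / length(perms)
      }
    }
    expect_equal(unname(imp$shares), ref, tolerance = 1e-10)
    expect_true(all(imp$shares >= -1e-12))
    # invariance to predictor input order
    imp2 <- lmg_importance(y, x[, c(3, 1, 2)])
    expect_equal(imp2$shares[colnames(x)], imp$shares, tolerance = 1e-12)
  })
})

test_that("degenerate LMG inputs are refused", {
  with_seed(77, {
    x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(20)
    expect_error(lmg_importance(y, cbind(x, a2 = x[, 1])), "collinear")
    expect_error(lmg_importance(y, matrix(rnorm(20 * 9), 20, 9)), "8 predictors")
    expect_error(lmg_importance(rnorm(3), x[1:3, ]), "observations")
  })
})

test_that("treatment summaries cover all variables with letters and percent changes", {
  md <- simulate_env_and_traits(study_design(seed = 18))
  out <- treatment_summary(md, variables = c("AP", "stem_number"))
  expect_equal(nrow(out), 8)
  expect_true(all(out$pct_change[out$treatment == "P0"] == 0))
  expect_true(all(nchar(out$letters) >= 1))
})
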