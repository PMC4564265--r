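# rank-then-Pearson oracle for Spearman's rho with average ranks
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

test_that("spearman_matrix matches the rank-Pearson oracle, with ties", {
  d <- data.frame(x = c(1, 2, 2, 3), y = c(1, 3, 2, 4))
  res <- spearman_matrix(d, "x", "y")
  expect_equal(res$rho, spearman_oracle(d$x, d$y))
  expect_equal(res$n, 4)

  # monotone relations give +/- 1
  d2 <- data.frame(a = 1:10, up = 2 * (1:10), down = -(1:10))
  res2 <- spearman_matrix(d2, "a", c("up", "down"))
  expect_equal(res2$rho, c(1, -1))

  # random small cases with ties
  set.seed(11)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearman_matrix(data.frame(x = x, y = y), "x", "y")
    expect_equal(got$rho, spearman_oracle(x, y), tolerance = 1e-12)
  }

  # pairwise-complete deletion and constant flagging
  d3 <- data.frame(x = c(1, 2, 3, NA, 5), y = c(2, 1, NA, 4, 10),
                   k = rep(1, 5))
  res3 <- spearman_matrix(d3, "x", "y")
  expect_equal(res3$n, 3)
  expect_warning(rc <- spearman_matrix(d3, "k", "y"), "constant")
  expect_true(is.na(rc$rho))
})

test_that("spearman p-values use the t approximation", {
  set.seed(12)
  x <- rnorm(25); y <- x + rnorm(25)
  got <- spearman_matrix(data.frame(x = x, y = y), "x", "y")
  r <- spearman_oracle(x, y)
  tstat <- r * sqrt((25 - 2) / (1 - r^2))
  expect_equal(got$p, 2 * pt(abs(tstat), 23, lower.tail = FALSE),
               tolerance = 1e-9)
})

# brute-force BH: adjusted p as the monotone envelope of m*p/i, decisions by
# the step-up rule traced literally
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  adj <- pmin(adj, 1)
  thresh <- which(ps <= seq_len(m) / m * q)
  k <- if (length(thresh)) max(thresh) else 0
  sig <- rep(FALSE, m)
  if (k > 0) sig[seq_len(k)] <- TRUE
  list(adj = adj[order(ord)], sig = sig[order(ord)])
}

test_that("BH step-up matches the hand-traced rule and the envelope oracle", {
  r <- bh_adjust(c(0.01, 0.02, 0.04, 0.5), q = 0.05)
  expect_equal(r$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(bh_adjust(0.01, 0.05)$significant)
  expect_true(all(bh_adjust(rep(0.05, 7), q = 0.05)$significant))
  expect_equal(nrow(bh_adjust(numeric(0), 0.05)), 0)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(13)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- round(runif(m), sample(1:3, 1))
    got <- bh_adjust(p, q = 0.05)
    orc <- bh_oracle(p, 0.05)
    expect_equal(got$p_adjusted, orc$adj)
    expect_equal(got$significant, orc$sig)
    # monotonicity in q
    expect_lte(sum(got$significant), sum(bh_adjust(p, q = 0.1)$significant))
  }
})

test_that("chi-squared deviance test reproduces the analytic p mapping", {
  expect_equal(round(pchisq(4.11, 1, lower.tail = FALSE), 2), 0.04)
  f <- list(deviance = 100, n = 50, fixed = "x")
  r <- list(deviance = 104.11, n = 50, fixed = character(0))
  got <- lrt_drop_term(f, r)
  expect_equal(got$chisq, 4.11)
  expect_equal(round(got$p, 2), 0.04)
  same <- lrt_drop_term(f, list(deviance = 100, n = 50, fixed = character(0)))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  # floor at zero when the "reduced" deviance is numerically lower
  neg <- lrt_drop_term(list(deviance = 100, n = 50, fixed = "x"),
                       list(deviance = 99.9, n = 50, fixed = character(0)))
  expect_equal(neg$chisq, 0)
  expect_error(lrt_drop_term(f, list(deviance = 1, n = 49,
                                     fixed = character(0))), "different data")
})

test_that("presence GLMM recovers simulated effects and flags degeneracy", {
  sim_presence <- function(beta, seed, npp = 30) {
    set.seed(seed)
    pops <- sprintf("p%02d", 1:12)
    county <- rep(c("c1", "c2", "c3", "c4"), each = 3 * npp)
    population <- rep(pops, each = npp)
    x <- rnorm(12 * npp)
    b <- rnorm(12, 0, 0.5)[match(population, pops)]
    bc <- rnorm(4, 0, 0.3)[match(county, c("c1", "c2", "c3", "c4"))]
    data.frame(county, population, x = x,
               y = rbinom(12 * npp, 1, plogis(beta * x + b + bc)))
  }
  # strong effect: sign recovered and term significant
  hits <- 0
  for (i in 1:15) {
    d <- sim_presence(1.5, 100 + i)
    fit <- fit_presence_glmm(d, "y", "x")
    if (fit$coefficients[["x"]] > 0) hits <- hits + 1
  }
  expect_gte(hits, 14)
  # null effect: estimate near zero
  d0 <- sim_presence(0, 7)
  f0 <- fit_presence_glmm(d0, "y", "x")
  expect_lt(abs(f0$coefficients[["x"]]),
            2 * coef(summary(f0$model))["x", "Std. Error"] + 0.5)
  # standardization bookkeeping: raw-scale slope = z-scale slope / sd(x)
  expect_equal(f0$coefficients_raw[["x"]],
               f0$coefficients[["x"]] / sd(f0$data$x) * 1,
               tolerance = 0.05)
  # all-zero response flagged degenerate, not silent
  dz <- sim_presence(0, 8)
  dz$y <- 0
  fz <- suppressWarnings(fit_presence_glmm(dz, "y", "x"))
  expect_true(fz$degenerate)
  expect_error(fit_presence_glmm(d0[d0$population == "p01", ], "y", "x"),
               "2 populations")
})

test_that("marginal R2 follows the latent-scale closed form", {
  # zero fixed effects -> 0
  set.seed(21)
  d <- generate_field_survey(sim_config(seed = 21, plants_per_pop = c(20, 20),
                                        n_gs_assayed = NA, n_cn_assayed = NA))
  f0 <- fit_presence_glmm(d, "presence_pieris", character(0))
  expect_equal(marginal_r2(f0), 0)
  # closed form on a fitted model's components
  f1 <- fit_presence_glmm(d, "presence_pieris", "bg_ratio")
  eta <- as.vector(lme4::getME(f1$model, "X") %*% lme4::fixef(f1$model))
  vr <- sum(sapply(lme4::VarCorr(f1$model), function(v) sum(diag(v))))
  expect_equal(marginal_r2(f1), var(eta) / (var(eta) + vr + pi^2 / 3))
  # unit variances give 1 / (2 + pi^2/3)
  expect_equal(round(1 / (1 + 1 + pi^2 / 3), 3), 0.189)
})

test_that("VIF matches the closed form and the car oracle", {
  set.seed(31)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  v <- vif(d, c("x1", "x2", "x3"))
  expect_true(all(v$vif >= 1 & v$vif < 1.2))  # near-orthogonal draws
  # correlated pair: closed form 1/(1-r^2)
  y <- 0.9 * scale(x1)[, 1] + sqrt(1 - 0.81) * scale(x2)[, 1]
  d2 <- data.frame(a = x1, b = y)
  r2 <- cor(d2$a, d2$b)^2
  expect_equal(vif(d2, c("a", "b"))$vif, rep(1 / (1 - r2), 2),
               tolerance = 1e-9)
  # duplicated predictor -> infinite, flagged
  d3 <- data.frame(a = x1, b = x1, c = x2)
  v3 <- vif(d3, c("a", "b", "c"))
  expect_true(all(is.infinite(v3$vif[1:2])))
  expect_true(all(v3$above_10[1:2]))
  skip_if_not_installed("car")
  d4 <- data.frame(x1 = x1, x2 = x2, x3 = x1 + x2 + rnorm(n), y = rnorm(n))
  ours <- vif(d4, c("x1", "x2", "x3"))$vif
  theirs <- unname(car::vif(lm(y ~ x1 + x2 + x3, data = d4)))
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("backwards deletion keeps a strong term and prunes null ones", {
  sim_sel <- function(seed, beta) {
    set.seed(seed)
    npp <- 30
    pops <- sprintf("p%02d", 1:12)
    population <- rep(pops, each = npp)
    county <- rep(c("c1", "c2", "c3", "c4"), each = 3 * npp)
    n <- 12 * npp
    d <- data.frame(county, population,
                    g1 = rnorm(n), g2 = rnorm(n), g3 = rnorm(n))
    b <- rnorm(12, 0, 0.4)[match(population, pops)]
    d$y <- rbinom(n, 1, plogis(beta * d$g1 + b))
    d
  }
  kept <- 0
  for (i in 1:5) {
    sel <- backward_select(sim_sel(400 + i, 1.2), "y", c("g1", "g2", "g3"))
    if ("g1" %in% sel$retained) kept <- kept + 1
  }
  expect_equal(kept, 5)
  # all-null: most terms pruned (retention approximately alpha per term)
  sel0 <- backward_select(sim_sel(55, 0), "y", c("g1", "g2", "g3"))
  expect_lte(length(sel0$retained), 1)
  expect_true(all(sel0$trace$p[sel0$trace$dropped] > 0.05))
})
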