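test_that("rank pairing matches the stated rule and partitions the plants", {
  expect_equal(pair_by_rank(c(a = 7, b = 2), k = 1)$high_plant, "a")
  p <- pair_by_rank(c(w = 5, x = 1, y = 9, z = 3), k = 2)
  expect_equal(p$high_plant, c("y", "w"))
  expect_equal(p$low_plant, c("x", "z"))
  # perfect matching at k = n/2, separation between groups
  set.seed(41)
  v <- setNames(sample(100), paste0("p", 1:100))
  pp <- pair_by_rank(v, k = 50)
  expect_setequal(c(pp$high_plant, pp$low_plant), names(v))
  expect_lt(max(pp$low_value), min(pp$high_value))
  expect_error(pair_by_rank(v, k = 60), "at least")
})

test_that("exact two-tailed binomial test reproduces known values", {
  expect_equal(signif(exact_binomial_two_tailed(23, 32), 2), 0.020)
  expect_equal(exact_binomial_two_tailed(15, 30), 1.0)
  expect_equal(signif(exact_binomial_two_tailed(19, 30), 2), 0.20)
  expect_equal(exact_binomial_two_tailed(0, 5), 0.0625)
  # symmetry at p0 = 0.5, and agreement with stats::binom.test
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:40, 1); k <- sample(0:n, 1)
    p1 <- exact_binomial_two_tailed(k, n)
    expect_equal(p1, exact_binomial_two_tailed(n - k, n))
    expect_equal(p1, binom.test(k, n)$p.value, tolerance = 1e-9)
  }
})

test_that("performance comparison is a plant-level one-way LM", {
  # identical groups
  rec <- data.frame(plant_id = paste0("p", 1:8),
                    group = rep(c("high", "low"), each = 4),
                    mass = rep(5, 8))
  same <- compare_performance(rec, "mass")
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # zero within-group variance with a real difference is undefined
  rec2 <- rec; rec2$mass <- rep(c(5, 6), each = 4)
  expect_error(compare_performance(rec2, "mass"), "zero within-group")

  # F equals the squared equal-variance t statistic
  set.seed(43)
  d <- data.frame(plant_id = paste0("p", 1:20),
                  group = rep(c("high", "low"), each = 10),
                  mass = c(rnorm(10, 10), rnorm(10, 12)))
  got <- compare_performance(d, "mass")
  tt <- t.test(mass ~ group, data = d, var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)

  # larvae sharing a plant are averaged before testing
  d2 <- rbind(d, within(d, mass <- mass + 1))
  got2 <- compare_performance(d2, "mass")
  d_avg <- aggregate(mass ~ plant_id + group, data = d2, FUN = mean)
  tt2 <- t.test(mass ~ group, data = d_avg, var.equal = TRUE)
  expect_equal(got2$F, unname(tt2$statistic)^2, tolerance = 1e-10)
  expect_equal(got2$groups$n, c(10, 10))

  # log transform refuses zeros
  d$mass[1] <- 0
  expect_error(compare_performance(d, "mass", transform = "log"), "positive")
})

test_that("quasibinomial GLM detects overdispersion and reduces to binomial", {
  set.seed(44)
  grp <- rep(c("a", "b"), each = 20)
  den <- rep(50, 40)
  # overdispersed (beta-binomial, rho = 0.1): estimated dispersion > 1
  hits <- 0
  for (i in 1:10) {
    pr <- rbeta(40, 0.5 * 9, 0.5 * 9)  # mean .5, rho = 1/(9+1)
    num <- rbinom(40, den, pr)
    r <- quasibinomial_proportion_test(num, den, grp)
    if (r$dispersion > 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # equal proportions: p near 1 region (not significant)
  num0 <- rbinom(40, den, 0.4)
  r0 <- quasibinomial_proportion_test(num0, den, grp)
  expect_gt(r0$p, 0.05)
  # with dispersion ~1 the F statistic approximates chisq/df of binomial GLM
  num1 <- rbinom(40, den, ifelse(grp == "a", 0.35, 0.5))
  r1 <- quasibinomial_proportion_test(num1, den, grp)
  g <- glm(cbind(num1, den - num1) ~ grp, family = binomial())
  chisq <- anova(g)$Deviance[2]
  expect_equal(r1$F, chisq / r1$dispersion, tolerance = 0.05)
  expect_error(quasibinomial_proportion_test(0, 0, "a"), "zero")
})

# independent enumeration oracle over index subsets (positions, not ranks)
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  r <- rank(pooled)
  stat <- function(ix) sum(r[ix]) - n * (n + 1) / 2
  obs <- stat(seq_len(n))
  all_u <- apply(combn(N, n), 2, stat)
  mean(abs(all_u - n * length(y) / 2) >= abs(obs - n * length(y) / 2) - 1e-9)
}

test_that("Mann-Whitney exact branch equals the enumeration oracle", {
  # complete separation, n = m = 4: p = 2/70
  x <- c(10, 11, 12, 13); y <- c(1, 2, 3, 4)
  r <- mann_whitney(x, y)
  expect_equal(r$method, "exact")
  expect_equal(r$p, 2 / 70)
  expect_equal(r$W, 16)  # all pairs favour x
  # random small samples incl. ties
  set.seed(45)
  for (i in 1:25) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, m, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p, mw_oracle(x, y))
  }
  # no-ties exact branch also agrees with stats::wilcox.test(exact = TRUE)
  for (i in 1:10) {
    x <- sample(100, 5); y <- sample(200:300, 5)
    expect_equal(mann_whitney(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
  }
  # large samples switch to the normal approximation
  set.seed(46)
  big <- mann_whitney(rnorm(20), rnorm(20, 1))
  expect_equal(big$method, "normal")
})

test_that("Wilcoxon matched-pairs exact branch equals sign-flip enumeration", {
  # 6 all-positive differences: p = 2/64
  r <- wilcoxon_matched(rep(0, 6), 1:6)
  expect_equal(r$p, 2 / 64)
  expect_equal(r$W, 21)
  # identical samples carry no information
  expect_error(wilcoxon_matched(1:5, 1:5), "zero")
  # agreement with stats::wilcox.test exact branch (no ties)
  set.seed(47)
  for (i in 1:10) {
    b <- rnorm(8); a <- b + rnorm(8)
    expect_equal(wilcoxon_matched(b, a)$p,
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  big <- wilcoxon_matched(rnorm(30), rnorm(30, 1))
  expect_equal(big$method, "normal")
})

test_that("percent difference and growth rate follow their formulas", {
  expect_equal(percent_difference(1.74, 0.64), 171.875, tolerance = 1e-9)
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(12.46, 10.42), 19.578, tolerance = 1e-3)
  expect_error(percent_difference(1, 0), "> 0")
  expect_equal(relative_growth_rate(10, 100, 9, 24),
               log(10) / 15)
  expect_error(relative_growth_rate(0, 1, 1, 2))
})
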