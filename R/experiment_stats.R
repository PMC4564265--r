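# Greenhouse preference and performance analyses: rank pairing, exact
# binomial choice tests, LM/GLM comparisons, nonparametric tests, percent
# differences and growth rates.

#' Pair plants by rank for a choice experiment
#'
#' Selects the `k` plants with the highest metric values (the "high" group)
#' and the `k` with the lowest (the "low" group), ranks each group from
#' most extreme inwards, and pairs equal ranks: the highest plant overall
#' with the lowest plant overall, and so on. This keeps the within-pair
#' contrast roughly constant across pairs. Ties are broken by plant id.
#'
#' @param values Named numeric vector (names are plant ids).
#' @param k Number of pairs (default 30). Requires `2k <= length(values)`.
#' @return A data frame with columns `rank`, `high_plant`, `low_plant`,
#'   `high_value`, `low_value`.
#' @export
pair_by_rank <- function(values, k = 30) {
  n <- length(values)
  if (2 * k > n) stop("need at least 2k = ", 2 * k, " plants, got ", n)
  if (is.null(names(values))) names(values) <- as.character(seq_len(n))
  ord <- order(values, names(values))  # ascending, ties by id
  low <- names(values)[ord[seq_len(k)]]             # rank 1 = lowest
  high <- rev(names(values)[ord[(n - k + 1):n]])    # rank 1 = highest
  data.frame(rank = seq_len(k), high_plant = high, low_plant = low,
             high_value = unname(values[high]), low_value = unname(values[low]),
             stringsAsFactors = FALSE)
}

#' Exact two-tailed binomial test
#'
#' Doubling rule: `p = min(1, 2 min(P(X <= k), P(X >= k)))` under
#' `Binomial(n, p0)`. With `p0 = 0.5` the distribution is symmetric and
#' this equals the usual exact two-sided test.
#'
#' @param successes Number of successes `k`.
#' @param trials Number of trials `n`.
#' @param p0 Null success probability (default 0.5).
#' @return The two-tailed p-value.
#' @examples
#' exact_binomial_two_tailed(23, 32)  # 0.020
#' @export
exact_binomial_two_tailed <- function(successes, trials, p0 = 0.5) {
  stopifnot(successes >= 0, successes <= trials, p0 > 0, p0 < 1)
  lower <- stats::pbinom(successes, trials, p0)
  upper <- stats::pbinom(successes - 1, trials, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Compare a performance measure between two plant groups
#'
#' One-way linear model with Normal errors; the group effect is tested by
#' the F statistic on dropping the term. When multiple larvae share a
#' plant, their values are averaged first so the plant is the experimental
#' unit. Time-to-pupation and leaf-area responses are typically analysed on
#' the natural-log scale (`transform = "log"`); zero responses under the
#' log transform are an error.
#'
#' @param records Data frame with columns `plant_id`, `group` (two levels)
#'   and the response.
#' @param response Name of the response column.
#' @param transform `"none"` or `"log"` (natural log, no offset).
#' @return A list with `F`, `df`, `p`, and `groups` (a data frame of per-
#'   group n, mean and SEM on the original scale).
#' @export
compare_performance <- function(records, response,
                                transform = c("none", "log")) {
  transform <- match.arg(transform)
  stopifnot(all(c("plant_id", "group", response) %in% names(records)))
  d <- records[!is.na(records[[response]]), , drop = FALSE]
  # plant-level means
  agg <- stats::aggregate(d[[response]],
                          by = list(plant_id = d$plant_id, group = d$group),
                          FUN = mean)
  names(agg)[3] <- "value"
  tab <- table(agg$group)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 plants each")
  }
  groups <- do.call(rbind, lapply(split(agg$value, agg$group), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  groups <- cbind(group = rownames(groups), groups, row.names = NULL)
  if (all(vapply(split(agg$value, agg$group), stats::sd, numeric(1)) == 0)) {
    if (length(unique(agg$value)) == 1) {
      # identical values everywhere: no effect, but the F test is 0/0;
      # report the degenerate no-difference result directly
      return(list(F = 0, df = c(1, nrow(agg) - 2), p = 1, groups = groups))
    }
    stop("zero within-group variance; the F test is undefined")
  }
  y <- if (transform == "log") {
    if (any(agg$value <= 0)) stop("log transform requires positive responses")
    log(agg$value)
  } else agg$value
  fit <- stats::lm(y ~ group, data = agg)
  an <- stats::anova(fit)
  list(F = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
       p = an$`Pr(>F)`[1], groups = groups)
}

#' Quasibinomial GLM test of proportions between groups
#'
#' Binomial GLM with the dispersion estimated from the Pearson
#' chi-squared statistic (quasibinomial family), guarding against
#' overdispersed count proportions; the group term is tested by an F test
#' on its removal.
#'
#' @param numerators,denominators Integer vectors (`0 <= num <= den`).
#' @param group Factor or character vector of group labels.
#' @return A list with `F`, `df`, `p`, `dispersion` and `proportions`
#'   (per-group pooled proportions).
#' @export
quasibinomial_proportion_test <- function(numerators, denominators, group) {
  stopifnot(length(numerators) == length(denominators),
            length(group) == length(numerators),
            all(denominators >= numerators), all(numerators >= 0))
  if (all(denominators == 0)) stop("all denominators are zero")
  ok <- denominators > 0
  num <- numerators[ok]; den <- denominators[ok]; grp <- factor(group[ok])
  fit <- stats::glm(cbind(num, den - num) ~ grp,
                    family = stats::quasibinomial())
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  an <- stats::anova(fit, test = "F")
  props <- tapply(num, grp, sum) / tapply(den, grp, sum)
  list(F = an$F[2], df = c(an$Df[2], fit$df.residual), p = an$`Pr(>F)`[2],
       dispersion = disp,
       proportions = data.frame(group = names(props),
                                proportion = as.vector(props)))
}

# Null permutation distribution of the rank-sum U statistic by enumeration
# over all assignments of the pooled (possibly tied, average) ranks.
.mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  idx <- utils::combn(n + m, n)
  u_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Reports `W`, the number of (x, y) pairs with `x > y` counting ties as
#' half (the U statistic of the first sample, the convention of
#' `stats::wilcox.test`). For combined sample sizes of 12 or fewer the
#' two-sided p-value is exact, from full enumeration of the permutation
#' distribution of the ranks (valid under ties); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @return A list with `W`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n + m <= 12) {
    list(W = w, p = .mw_exact_p(x, y), method = "exact")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(W = w, p = wt$p.value, method = "normal")
  }
}

# Sign-flip enumeration of the signed-rank statistic.
.wsr_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired two-sided test of `before` vs `after`. Zero differences are
#' dropped; if every difference is zero the test is undefined and errors.
#' For 12 or fewer non-zero differences the p-value is exact by sign-flip
#' enumeration; otherwise the normal approximation with tie and continuity
#' corrections is used. `W` is the sum of the ranks of the positive
#' differences (`after - before`).
#'
#' @param before,after Numeric vectors of equal length.
#' @return A list with `W`, `p` and `method`.
#' @export
wilcoxon_matched <- function(before, after) {
  stopifnot(length(before) == length(after))
  d <- after - before
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero; no information")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (length(d) <= 12) {
    list(W = w, p = .wsr_exact_p(d), method = "exact")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    list(W = w, p = wt$p.value, method = "normal")
  }
}

#' Percent difference relative to a reference mean
#'
#' `100 (a - b) / b`: how much higher `a` is than the reference `b`,
#' in percent.
#'
#' @param a Comparison mean.
#' @param b Reference mean, `> 0`.
#' @return Percent difference.
#' @examples
#' percent_difference(12.46, 10.42)  # growth on high- vs low-B:G plants
#' @export
percent_difference <- function(a, b) {
  if (b <= 0) stop("reference mean must be > 0")
  100 * (a - b) / b
}

#' Relative growth rate from two weighings
#'
#' `(ln m2 - ln m1) / (t2 - t1)` in mg/mg/day: the per-day log mass gain
#' between the first and last weighing of a larva.
#'
#' @param mass1_mg,mass2_mg Masses at the two weighings (mg, `> 0`).
#' @param day1,day2 Ages at the two weighings (days, `day2 > day1`).
#' @return Relative growth rate (mg/mg/day).
#' @export
relative_growth_rate <- function(mass1_mg, mass2_mg, day1, day2) {
  stopifnot(all(mass1_mg > 0), all(mass2_mg > 0), all(day2 > day1))
  (log(mass2_mg) - log(mass1_mg)) / (day2 - day1)
}
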