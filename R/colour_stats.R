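# Field-survey statistics: correlation screens with FDR control, presence
# GLMMs with nested random intercepts, collinearity screening, backwards
# model selection, marginal R-squared.

#' Spearman correlation screen between two variable sets
#'
#' Rank correlations for every (x, y) pair with pairwise-complete deletion.
#' Ties get average ranks; p-values come from the large-sample t
#' approximation.
#'
#' @param data A data frame.
#' @param vars_x,vars_y Character vectors of column names.
#' @return A data frame with columns `x`, `y`, `n`, `rho`, `p`. Pairs where
#'   either variable is constant return `NA` rho with a warning.
#' @export
spearman_matrix <- function(data, vars_x, vars_y) {
  stopifnot(all(c(vars_x, vars_y) %in% names(data)))
  out <- expand.grid(x = vars_x, y = vars_y, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$n <- NA_integer_; out$rho <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    xv <- data[[out$x[i]]]; yv <- data[[out$y[i]]]
    ok <- stats::complete.cases(xv, yv)
    n <- sum(ok)
    out$n[i] <- n
    if (n < 3) next
    if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) {
      warning("constant variable in pair (", out$x[i], ", ", out$y[i],
              "); rho undefined")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(xv[ok], yv[ok], method = "spearman", exact = FALSE))
    out$rho[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}

#' Benjamini-Hochberg FDR adjustment and decisions
#'
#' Applies the step-up rule at level `q`: with sorted p-values, reject the
#' `k` smallest where `k = max(i : p_(i) <= (i/m) q)`. Also returns
#' BH-adjusted p-values (the monotone envelope of `m p_(i) / i`, capped at
#' 1), which satisfy `adjusted <= q` exactly for the rejected set.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, never
#'   rejected).
#' @param q FDR level (default 0.05).
#' @return A data frame with columns `p`, `p_adjusted`, `significant`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  sig <- rep(FALSE, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m > 0) {
    ord <- ok[order(p[ok])]
    ps <- p[ord]
    k <- max(c(0L, which(ps <= seq_len(m) / m * q)))
    if (k > 0) sig[ord[seq_len(k)]] <- TRUE
  }
  data.frame(p = p, p_adjusted = adj, significant = sig)
}

#' Binomial presence GLMM with populations nested in counties
#'
#' Fits a logistic mixed model of herbivore presence with random intercepts
#' for population nested within county, by Laplace-approximate maximum
#' likelihood (so deviance differences are valid for likelihood-ratio
#' tests). Numeric fixed effects are z-scored by default for conditioning;
#' estimates are reported on both scales.
#'
#' @param records Data frame with columns `county`, `population`, the
#'   response, and the fixed-effect variables.
#' @param response Name of the binary (0/1 or logical) response column.
#' @param fixed Character vector of fixed-effect column names (may be
#'   empty for an intercept-only model).
#' @param standardize Z-score numeric fixed effects before fitting
#'   (default `TRUE`).
#' @param counties Optional character vector restricting the data to these
#'   counties (e.g. excluding a county where the herbivore never occurs).
#' @return A `leaf_glmm` object: list with `model` (the `glmerMod`),
#'   `deviance`, `coefficients` (standardized scale), `coefficients_raw`
#'   (original scale, when standardized), `n`, `response`, `fixed`,
#'   `converged`, `degenerate` and `messages`.
#' @export
fit_presence_glmm <- function(records, response, fixed = character(0),
                              standardize = TRUE, counties = NULL) {
  stopifnot(all(c("county", "population", response, fixed) %in%
                  names(records)))
  d <- records
  if (!is.null(counties)) d <- d[d$county %in% counties, , drop = FALSE]
  y <- d[[response]]
  if (is.logical(y)) y <- as.integer(y)
  d$.y <- y
  d <- d[stats::complete.cases(d[c(".y", "county", "population", fixed)]), ,
         drop = FALSE]
  if (length(unique(d$population)) < 2) {
    stop("need at least 2 populations to fit nested random intercepts")
  }
  degenerate <- length(unique(d$.y)) < 2
  scales <- NULL
  if (standardize && length(fixed)) {
    scales <- lapply(fixed, function(v) {
      if (is.numeric(d[[v]])) {
        mu <- mean(d[[v]]); sdv <- stats::sd(d[[v]])
        if (sdv > 0) d[[v]] <<- (d[[v]] - mu) / sdv
        c(mean = mu, sd = sdv)
      } else NULL
    })
    names(scales) <- fixed
  }
  form <- stats::reformulate(c(if (length(fixed)) fixed else "1",
                               "(1 | county/population)"),
                             response = ".y")
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(form, data = d, family = stats::binomial()),
      error = function(e) {
        msgs <<- c(msgs, conditionMessage(e)); NULL
      }),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  converged <- !is.null(fit) &&
    length(fit@optinfo$conv$lme4) == 0 && fit@optinfo$conv$opt == 0
  coefs <- if (!is.null(fit)) lme4::fixef(fit) else NULL
  coefs_raw <- coefs
  if (!is.null(coefs) && !is.null(scales)) {
    for (v in fixed) {
      sc <- scales[[v]]
      if (!is.null(sc) && v %in% names(coefs_raw) && sc[["sd"]] > 0) {
        coefs_raw[[v]] <- coefs[[v]] / sc[["sd"]]
      }
    }
  }
  structure(
    list(model = fit, deviance = if (!is.null(fit)) stats::deviance(fit),
         coefficients = coefs, coefficients_raw = coefs_raw,
         n = nrow(d), response = response, fixed = fixed,
         converged = converged, degenerate = degenerate, messages = msgs,
         data = d),
    class = "leaf_glmm")
}

#' @export
print.leaf_glmm <- function(x, ...) {
  cat("<presence GLMM> ", x$response, " ~ ",
      if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
      " + (1 | county/population), n = ", x$n, "\n", sep = "")
  if (x$degenerate) cat("  DEGENERATE: response has a single level\n")
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  if (!is.null(x$coefficients)) {
    cat("  deviance ", round(x$deviance, 2), "; fixed effects: ",
        paste(names(x$coefficients), round(x$coefficients, 3), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Likelihood-ratio test for dropping a term
#'
#' The change in deviance between a reduced and a full model, referred to a
#' chi-squared distribution. Both models must be ML fits of the same data.
#'
#' @param full,reduced `leaf_glmm` objects (reduced nested in full).
#' @param df Degrees of freedom of the dropped term(s) (default 1).
#' @return A list with `chisq` (floored at 0), `df` and `p`.
#' @export
lrt_drop_term <- function(full, reduced, df = 1) {
  if (is.null(full$deviance) || is.null(reduced$deviance)) {
    stop("cannot test: a model failed to fit")
  }
  if (full$n != reduced$n) {
    stop("models were fitted to different data (n = ", full$n, " vs ",
         reduced$n, ")")
  }
  if (!all(reduced$fixed %in% full$fixed)) {
    stop("reduced model is not nested in the full model")
  }
  chisq <- max(0, reduced$deviance - full$deviance)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df = df, lower.tail = FALSE))
}

#' Marginal R-squared of a logistic mixed model
#'
#' The proportion of variance explained by the fixed effects on the latent
#' (logit) scale: `var_f / (var_f + sum(var_random) + pi^2/3)`, where
#' `var_f` is the variance of the fixed-effect linear predictor across the
#' sample and `pi^2/3` is the logistic distribution variance.
#'
#' @param fit A `leaf_glmm` from [fit_presence_glmm()].
#' @return A proportion in `[0, 1)`.
#' @export
marginal_r2 <- function(fit) {
  if (is.null(fit$model)) stop("model failed to fit; no variance components")
  m <- fit$model
  eta_f <- as.vector(lme4::getME(m, "X") %*% lme4::fixef(m))
  var_f <- stats::var(eta_f)
  vc <- lme4::VarCorr(m)
  var_r <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  var_f / (var_f + var_r + pi^2 / 3)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from the linear regression of predictor `j` on
#' all the others. Values above 3 indicate moderate and above 10 severe
#' multicollinearity; exactly collinear predictors report `Inf`.
#'
#' @param data A data frame.
#' @param predictors Character vector of (numeric) column names, length
#'   `>= 2`.
#' @return A data frame with columns `predictor`, `vif`, `above_3`,
#'   `above_10`.
#' @export
vif <- function(data, predictors) {
  stopifnot(length(predictors) >= 2, all(predictors %in% names(data)))
  d <- data[predictors]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) <= length(predictors)) stop("need n > number of predictors")
  v <- vapply(predictors, function(p) {
    fit <- stats::lm(stats::reformulate(setdiff(predictors, p), response = p),
                     data = d)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = predictors, vif = unname(v),
             above_3 = unname(v) > 3, above_10 = unname(v) > 10)
}

#' Backwards deletion to a minimum adequate model
#'
#' Starting from the global fixed-effect structure, repeatedly refits the
#' model without each remaining term, drops the least significant term
#' (largest likelihood-ratio p) while that p exceeds `alpha`, and stops
#' when every remaining term is significant on removal. Ties are broken by
#' dropping the term declared later in `global_fixed`. Random structure
#' (population in county) is kept throughout.
#'
#' @param records,response,counties As in [fit_presence_glmm()].
#' @param global_fixed Character vector: the global fixed-effect terms.
#' @param alpha Retention threshold (default 0.05).
#' @return A list with `model` (the minimum adequate `leaf_glmm`),
#'   `retained`, `dropped` (in order), and `trace` (a data frame of each
#'   deletion step with its chi-squared and p).
#' @export
backward_select <- function(records, response, global_fixed, alpha = 0.05,
                            counties = NULL) {
  current <- global_fixed
  # listwise deletion on the *global* variable set so every nested fit uses
  # identical data
  use <- records
  if (!is.null(counties)) use <- use[use$county %in% counties, , drop = FALSE]
  use <- use[stats::complete.cases(
    use[c(response, "county", "population", global_fixed)]), , drop = FALSE]
  fit_cur <- fit_presence_glmm(use, response, current)
  trace <- list()
  dropped <- character(0)
  repeat {
    if (!length(current)) break
    tests <- lapply(current, function(term) {
      red <- fit_presence_glmm(use, response, setdiff(current, term))
      lrt_drop_term(fit_cur, red, df = 1)
    })
    ps <- vapply(tests, `[[`, numeric(1), "p")
    # ties (and the max) resolved toward the later declared term
    worst <- max(which(ps == max(ps)))
    trace[[length(trace) + 1]] <- data.frame(
      term = current[worst], chisq = tests[[worst]]$chisq,
      p = ps[worst], dropped = ps[worst] > alpha)
    if (ps[worst] <= alpha) break
    dropped <- c(dropped, current[worst])
    current <- setdiff(current, current[worst])
    fit_cur <- fit_presence_glmm(use, response, current)
  }
  list(model = fit_cur, retained = current, dropped = dropped,
       trace = do.call(rbind, trace))
}
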