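# End-to-end pipeline: simulate -> colour -> survey statistics ->
# choice/performance analyses, with a JSON-able report.

#' Run the full analysis pipeline on synthetic data
#'
#' Chains every stage: generates the field survey and experiment tables
#' from `cfg`, screens colour-glucosinolate Spearman correlations with
#' Benjamini-Hochberg control at `fdr_screen`, fits one presence GLMM per
#' colour channel per herbivore (population nested in county; the aphid
#' models exclude Kent, where the aphid does not occur) and tests the
#' colour term by change in deviance with BH control at `fdr_glmm`,
#' computes marginal R-squared for each presence model, and analyses the
#' choice and performance experiments. Returns a structured report; with
#' `out` set, also writes it as JSON next to a provenance block (seed,
#' package version, configuration).
#'
#' @param cfg A [sim_config()].
#' @param fdr_screen FDR level for the correlation screen (default 0.05).
#' @param fdr_glmm FDR level for the presence models (default 0.1).
#' @param out Optional path for a JSON report.
#' @return A list with elements `provenance`, `survey` (n, drops),
#'   `correlations`, `presence`, `choice`, `performance`.
#' @export
run_pipeline <- function(cfg = sim_config(), fdr_screen = 0.05,
                         fdr_glmm = 0.1, out = NULL) {
  survey <- generate_field_survey(cfg)
  gs_cols <- c(rownames(cfg$gs_targets), "gs_total", "gs_total_aliphatic",
               "gs_total_indole")
  channels <- c("bg_ratio", "prg_ratio", "drg_ratio", "brightness")

  screen <- spearman_matrix(survey, channels, gs_cols)
  adj <- bh_adjust(screen$p, q = fdr_screen)
  screen$p_adjusted <- adj$p_adjusted
  screen$significant <- adj$significant

  presence <- list(
    pieris = .presence_stage(survey, "presence_pieris",
                             c("bg_ratio", "prg_ratio", "drg_ratio"),
                             counties = NULL, fdr_glmm),
    brassicae = .presence_stage(survey, "presence_brassicae",
                                c("bg_ratio_aphid", "brightness"),
                                counties = c("Cornwall", "Devon", "Dorset"),
                                fdr_glmm))

  trials_bg <- generate_choice_trials(30, 0.5, "bg_ratio")
  trials_drg <- generate_choice_trials(30, 0.5, "drg_ratio")
  choice <- lapply(list(bg_ratio = trials_bg, drg_ratio = trials_drg),
                   analyse_choice_trials)

  perf <- generate_performance(cfg)
  performance <- list(
    growth_rate = compare_performance(perf$larvae, "growth_rate"),
    pupal_mass = compare_performance(perf$larvae, "pupal_mass_mg"),
    time_to_pupation = compare_performance(perf$larvae,
                                           "time_to_pupation_days",
                                           transform = "log"),
    aphid_alate_proportion = quasibinomial_proportion_test(
      perf$aphids$alate, perf$aphids$total, perf$aphids$group))

  report <- list(
    provenance = list(seed = cfg$seed,
                      package = "leafsignal",
                      version = as.character(utils::packageVersion("leafsignal")),
                      fdr_screen = fdr_screen, fdr_glmm = fdr_glmm,
                      n_plants = nrow(survey),
                      archetype_mix = as.list(cfg$archetype_mix)),
    survey = list(n_plants = nrow(survey),
                  n_relocated = sum(survey$relocated),
                  n_gs_assayed = sum(!is.na(survey$gs_total)),
                  n_counties = length(unique(survey$county)),
                  n_populations = length(unique(survey$population))),
    correlations = screen,
    presence = presence,
    choice = choice,
    performance = performance)
  if (!is.null(out)) {
    jsonlite::write_json(.jsonable(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(report)
}

.presence_stage <- function(survey, response, channels, counties, fdr) {
  fits <- lapply(channels, function(ch) {
    full <- fit_presence_glmm(survey, response, ch, counties = counties)
    null <- fit_presence_glmm(full$data, response, character(0))
    test <- lrt_drop_term(full, null, df = 1)
    list(channel = ch, n = full$n,
         beta = unname(full$coefficients[ch]),
         chisq = test$chisq, p = test$p,
         marginal_r2 = marginal_r2(full),
         converged = full$converged)
  })
  names(fits) <- channels
  adj <- bh_adjust(vapply(fits, `[[`, numeric(1), "p"), q = fdr)
  for (i in seq_along(fits)) {
    fits[[i]]$p_adjusted <- adj$p_adjusted[i]
    fits[[i]]$significant <- adj$significant[i]
  }
  fits
}

#' Summarise a table of choice trials
#'
#' @param trials Data frame from [generate_choice_trials()] (columns
#'   `chosen`, `metric`).
#' @return A list with `n`, `n_high`, `prop_high` and the exact two-tailed
#'   binomial `p` against 0.5.
#' @export
analyse_choice_trials <- function(trials) {
  n <- nrow(trials)
  k <- sum(trials$chosen == "high")
  list(metric = trials$metric[1], n = n, n_high = k, prop_high = k / n,
       p = exact_binomial_two_tailed(k, n, 0.5))
}

# strip model objects / data frames down to JSON-friendly structures
.jsonable <- function(x) {
  if (inherits(x, "leaf_glmm")) {
    return(list(response = x$response, fixed = x$fixed, n = x$n,
                deviance = x$deviance,
                coefficients = as.list(x$coefficients)))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, .jsonable))
  x
}

#' Plot synthetic or measured leaf spectra by archetype
#'
#' Overlays spectra, coloured by their `archetype` attribute when present.
#'
#' @param spectra List of `leaf_spectrum` objects.
#' @param normalize Normalize each spectrum to its green peak first.
#' @return Invisibly, `spectra`.
#' @export
plot_spectra <- function(spectra, normalize = TRUE) {
  if (normalize) spectra <- lapply(spectra, normalize_to_peak)
  cols <- c(bluish = "steelblue", green = "darkgreen", reddish = "firebrick")
  ymax <- max(vapply(spectra, function(s) max(s$reflectance), numeric(1)))
  graphics::plot(NULL, xlim = c(300, 700), ylim = c(0, ymax),
                 xlab = "Wavelength (nm)",
                 ylab = if (normalize) "Reflectance (peak-normalized)" else
                   "Reflectance")
  for (s in spectra) {
    a <- attr(s, "archetype")
    graphics::lines(s$wavelength_nm, s$reflectance,
                    col = if (!is.null(a)) cols[[a]] else "grey40")
  }
  graphics::legend("topleft", legend = names(cols), col = cols, lty = 1,
                   bty = "n")
  invisible(spectra)
}

#' Plot herbivore presence against a colour channel
#'
#' Scatter of presence (jittered) against the channel with the logistic
#' fit from a fixed-effect binomial GLM overlaid.
#'
#' @param survey Survey data frame (see [generate_field_survey()]).
#' @param response Presence column name.
#' @param channel Colour channel column name.
#' @return Invisibly, the fitted `glm`.
#' @export
plot_presence_colour <- function(survey, response, channel) {
  d <- survey[stats::complete.cases(survey[c(response, channel)]), ]
  fit <- stats::glm(stats::reformulate(channel, response), data = d,
                    family = stats::binomial())
  graphics::plot(d[[channel]], jitter(as.numeric(d[[response]]), 0.2),
                 pch = 16, col = grDevices::adjustcolor("grey30", 0.4),
                 xlab = channel, ylab = paste0(response, " (0/1)"))
  xs <- seq(min(d[[channel]]), max(d[[channel]]), length.out = 200)
  nd <- stats::setNames(data.frame(xs), channel)
  graphics::lines(xs, stats::predict(fit, nd, type = "response"),
                  col = "firebrick", lwd = 2)
  invisible(fit)
}
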