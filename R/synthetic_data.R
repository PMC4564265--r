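# Synthetic leaf spectra, field-survey tables and experiment tables with the
# statistical structure the analyses assume: three spectral archetypes,
# rank-correlated defence chemistry via a Gaussian copula, presence under a
# population-in-county logistic model, and paired choice/performance trials.

# Default rank-correlation targets between the four colour channels and the
# eight glucosinolates, matching the sign and scale structure typical of
# field surveys of wild cabbage: red:green channels tend to correlate
# positively with indole (and most aliphatic) glucosinolates, gluconapin
# negatively, the blue:green channel only weakly.
.default_gs_targets <- function() {
  ch <- c("bg_ratio", "prg_ratio", "drg_ratio", "brightness")
  m <- rbind(
    glucoiberin             = c(-0.08,  0.16,  0.11,  0.15),
    gluconapin              = c( 0.07, -0.17, -0.23, -0.10),
    glucoraphanin           = c(-0.06,  0.18,  0.20,  0.16),
    progoitrin              = c( 0.07, -0.07, -0.01, -0.06),
    sinigrin                = c(-0.12,  0.13,  0.00,  0.17),
    glucobrassicin          = c(-0.13,  0.23,  0.13, -0.01),
    neoglucobrassicin       = c(-0.02,  0.22,  0.27,  0.22),
    `4-methoxyglucobrassicin` = c( 0.06,  0.01,  0.12,  0.05))
  colnames(m) <- ch
  m
}

.gs_aliphatic <- c("glucoiberin", "gluconapin", "glucoraphanin",
                   "progoitrin", "sinigrin")
.gs_indole <- c("glucobrassicin", "neoglucobrassicin",
                "4-methoxyglucobrassicin")

#' Sign-pattern correlation targets for the colour-chemistry copula
#'
#' Replaces every default colour-glucosinolate correlation target of
#' magnitude at least `min_magnitude` by `sign * magnitude`, and zeroes the
#' rest. Useful for parameter-recovery checks where the question is whether
#' the analysis pipeline recovers the configured signs.
#'
#' @param magnitude Common absolute Spearman target (default 0.3).
#' @param min_magnitude Defaults below this absolute value are treated as
#'   unconfigured (set to 0); default 0.05.
#' @return A glucosinolate x channel matrix of Spearman targets.
#' @export
colour_gs_sign_targets <- function(magnitude = 0.3, min_magnitude = 0.05) {
  m <- .default_gs_targets()
  out <- sign(m) * magnitude
  out[abs(m) < min_magnitude] <- 0
  out
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic survey and experiments. Defaults
#' emulate a two-survey field design: 12 populations in 4 counties
#' (Cornwall, Devon, Dorset, Kent), 41-50 plants per population (about 548
#' in the first survey), 304 plants relocated in the second survey, 129
#' plants assayed for glucosinolates and 179 for C:N; the cabbage aphid is
#' absent from Kent. Colour effects on herbivore presence are sized so the
#' fixed effect explains about 4 percent of latent-scale variance (marginal
#' R-squared 0.04), small relative to the random population and county
#' structure.
#'
#' @param seed Integer seed; fully determines the generated tables.
#' @param plants_per_pop Length-2 integer range of plants per population.
#' @param n_relocated Plants re-found in the second survey.
#' @param n_gs_assayed Plants assayed for glucosinolates (`NA` = all).
#' @param n_cn_assayed Plants assayed for C:N (`NA` = all).
#' @param archetype_mix Named proportions of `bluish`, `green`, `reddish`
#'   leaves; must sum to 1.
#' @param gs_targets Glucosinolate x channel matrix of Spearman targets
#'   (see [colour_gs_sign_targets()]).
#' @param presence Per-species list: `channel` (driving colour channel),
#'   `r2` (target marginal R-squared of the colour effect), `sd_pop`,
#'   `sd_county` (random-intercept SDs), `base_rate`.
#' @param experiment Group means/SDs for the performance experiments.
#' @return A `leaf_sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       plants_per_pop = c(41, 50),
                       n_relocated = 304,
                       n_gs_assayed = 129,
                       n_cn_assayed = 179,
                       archetype_mix = c(bluish = 0.25, green = 0.5,
                                         reddish = 0.25),
                       gs_targets = .default_gs_targets(),
                       presence = list(
                         pieris = list(channel = "bg_ratio", r2 = 0.04,
                                       sign = +1, sd_pop = 0.5,
                                       sd_county = 0.3, base_rate = 0.45),
                         brassicae = list(channel = "brightness", r2 = 0.04,
                                          sign = -1, sd_pop = 0.5,
                                          sd_county = 0.3, base_rate = 0.5)),
                       experiment = list(
                         growth = list(high = c(mean = 12.46, sd = 3.65),
                                       low = c(mean = 10.42, sd = 3.01)),
                         pupal_mass = list(high = c(mean = 146.9, sd = 20.6),
                                           low = c(mean = 129.2, sd = 21.9)),
                         time_to_pupation = list(
                           high = c(mean = 22.25, sd = 4.0),
                           low = c(mean = 23.25, sd = 4.0)),
                         aphid_total = list(bright = c(meanlog = 7.2,
                                                       sdlog = 0.8),
                                            dull = c(meanlog = 7.3,
                                                     sdlog = 0.8)))) {
  stopifnot(length(plants_per_pop) == 2,
            plants_per_pop[1] <= plants_per_pop[2])
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    stop("archetype_mix proportions must sum to 1")
  }
  for (sp in names(presence)) {
    if (presence[[sp]]$sd_pop < 0 || presence[[sp]]$sd_county < 0) {
      stop("random-intercept SDs must be >= 0")
    }
  }
  structure(
    list(seed = as.integer(seed), n_counties = 4, n_pops_per_county = 3,
         plants_per_pop = plants_per_pop, n_relocated = n_relocated,
         n_gs_assayed = n_gs_assayed, n_cn_assayed = n_cn_assayed,
         archetype_mix = archetype_mix, gs_targets = gs_targets,
         presence = presence, experiment = experiment),
    class = "leaf_sim_config")
}

#' Generate one synthetic leaf reflectance spectrum
#'
#' Builds a leaf spectrum on 300-700 nm at 1 nm from a chlorophyll-
#' dominated base curve (absorption troughs near 430 and 662 nm, green
#' reflectance peak near 550 nm, red edge rising from about 690 nm) plus an
#' archetype component: `bluish` adds broadband 400-500 nm reflectance (a
#' waxy-epidermis term), `reddish` adds reflectance above 550 nm (a
#' long-wavelength pigment term), `green` adds neither. Plant-to-plant
#' variation enters through random component amplitudes and multiplicative
#' log-normal noise; values are clipped to [0, 1.2]. Draws from the current
#' RNG stream.
#'
#' @param archetype `"bluish"`, `"green"` or `"reddish"`.
#' @param sample_id Label for the spectrum.
#' @return A `leaf_spectrum`.
#' @export
generate_leaf_spectrum <- function(archetype = c("green", "bluish", "reddish"),
                                   sample_id = "synthetic") {
  archetype <- match.arg(archetype)
  wl <- canonical_grid()
  # every leaf carries some wax and some long-wavelength pigment; the
  # archetype shifts their means, and a shared "colourfulness" factor
  # correlates the two, as waxy and anthocyanic traits co-occur on plants
  wax_mu <- c(bluish = 0.10, green = 0.030, reddish = 0.020)
  pig_mu <- c(reddish = 0.12, green = 0.030, bluish = 0.025)
  f <- stats::rnorm(1)
  wax <- max(stats::rnorm(1, wax_mu[[archetype]], 0.02) + 0.030 * f, 0)
  pig <- max(stats::rnorm(1, pig_mu[[archetype]], 0.02) + 0.030 * f, 0)
  base_scale <- stats::rlnorm(1, 0, 0.15)
  green_amp <- 0.13 * stats::rlnorm(1, 0, 0.2)
  trough <- 0.05 * stats::rlnorm(1, 0, 0.8)     # red chlorophyll absorption
  edge_mid <- stats::rnorm(1, 702, 8)           # red-edge position
  base <- 0.06 +
    green_amp * exp(-(wl - 550)^2 / (2 * 35^2)) -
    0.025 * exp(-(wl - 430)^2 / (2 * 25^2)) -
    trough * exp(-(wl - 668)^2 / (2 * 14^2)) +
    0.45 * stats::plogis((wl - edge_mid) / 6)
  refl <- base * base_scale +
    wax * exp(-((wl - 450) / 62)^4) +
    pig * stats::plogis((wl - stats::rnorm(1, 590, 12)) / 25)
  # smooth leaf-to-leaf heterogeneity: a few random narrow bumps
  for (b in 1:4) {
    refl <- refl + stats::rnorm(1, 0, 0.015) *
      exp(-(wl - stats::runif(1, 320, 690))^2 /
            (2 * stats::runif(1, 10, 25)^2))
  }
  refl <- refl * stats::rlnorm(length(wl), 0, 0.03)
  refl <- pmin(pmax(refl, 0), 1.2)
  spectrum_new(wl, refl, sample_id = sample_id)
}

#' Generate a panel of synthetic leaf spectra
#'
#' @param n Number of spectra.
#' @param mix Named archetype proportions (default from [sim_config()]).
#' @return A list of `leaf_spectrum` objects with an `archetype` attribute
#'   on each.
#' @export
generate_spectra <- function(n, mix = c(bluish = 0.25, green = 0.5,
                                        reddish = 0.25)) {
  arch <- sample(names(mix), n, replace = TRUE, prob = mix)
  out <- lapply(seq_len(n), function(i) {
    s <- generate_leaf_spectrum(arch[i], sample_id = sprintf("plant_%04d", i))
    attr(s, "archetype") <- arch[i]
    s
  })
  names(out) <- vapply(out, `[[`, character(1), "sample_id")
  out
}

# Gaussian-copula draw: returns a variable whose Spearman correlations with
# the columns of `channels` approximate `targets`, with marginal given by
# the quantile function `qfun`. Uses normal scores of the channel ranks, so
# any channel marginal is handled.
.copula_draw <- function(channels, targets, qfun) {
  n <- nrow(channels)
  u <- apply(channels, 2, function(x) stats::qnorm((rank(x) - 0.5) / n))
  keep <- which(targets != 0)
  if (!length(keep)) {
    t_lat <- stats::rnorm(n)
  } else {
    rho_p <- 2 * sin(pi * targets[keep] / 6)  # Spearman -> Pearson (normal)
    r <- stats::cor(u[, keep, drop = FALSE])
    beta <- solve(r, rho_p)
    v <- sum(rho_p * beta)
    if (v > 2) {
      stop("infeasible correlation targets: implied latent variance ",
           round(v, 3), " > 2; targets conflict with the dependence ",
           "between the conditioning variables")
    }
    if (v > 0.95) {
      # mildly conflicting targets: honour their pattern at reduced scale
      warning("correlation targets shrunk by ", round(sqrt(0.95 / v), 3),
              " to stay feasible")
      rho_p <- rho_p * sqrt(0.95 / v)
      beta <- beta * sqrt(0.95 / v)
      v <- 0.95
    }
    t_lat <- as.vector(u[, keep, drop = FALSE] %*% beta) +
      sqrt(1 - v) * stats::rnorm(n)
  }
  qfun(stats::pnorm(t_lat))
}

# Typical constitutive concentration scales (umol/g) per glucosinolate.
.gs_meanlog <- c(glucoiberin = log(0.02), gluconapin = log(0.7),
                 glucoraphanin = log(0.05), progoitrin = log(0.08),
                 sinigrin = log(0.3), glucobrassicin = log(0.035),
                 neoglucobrassicin = log(0.1),
                 `4-methoxyglucobrassicin` = log(0.8))

#' Generate a synthetic field survey
#'
#' Hierarchical draw: counties and populations; per-plant archetype and
#' spectrum; colour channels from the pieris and aphid receptor models
#' (flat illuminant); glucosinolates rank-correlated with the colour
#' channels through a Gaussian copula with log-normal marginals; plant
#' covariates (size, density, flowering, C:N) with their own sign
#' structure; herbivore presence from a logistic model with the configured
#' colour effect and random population-in-county intercepts. The cabbage
#' aphid is generated as absent from Kent, and its presence is only scored
#' for first-survey plants, while the butterfly is only scored on the
#' relocated second-survey subset.
#'
#' @param cfg A [sim_config()].
#' @return A data frame, one row per plant: identifiers and nesting
#'   (`plant_id`, `population`, `county`, `relocated`, `archetype`), colour
#'   channels (`bg_ratio`, `prg_ratio`, `drg_ratio` from the pieris model;
#'   `bg_ratio_aphid`, `brightness` from the aphid model), eight
#'   glucosinolate columns plus `gs_total`, `gs_total_aliphatic`,
#'   `gs_total_indole` (umol/g; `NA` outside the assayed subset),
#'   covariates (`size_mm`, `density`, `flowering`, `cn_ratio`), and
#'   `presence_pieris` / `presence_brassicae` (0/1, `NA` where not
#'   surveyed).
#' @export
generate_field_survey <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "leaf_sim_config"))
  set.seed(cfg$seed)
  counties <- c("Cornwall", "Devon", "Dorset", "Kent")[seq_len(cfg$n_counties)]
  pops <- unlist(lapply(counties, function(co) {
    paste0(co, "_", seq_len(cfg$n_pops_per_county))
  }))
  pop_county <- rep(counties, each = cfg$n_pops_per_county)
  n_per_pop <- sample(seq(cfg$plants_per_pop[1], cfg$plants_per_pop[2]),
                      length(pops), replace = TRUE)
  population <- rep(pops, times = n_per_pop)
  county <- rep(pop_county, times = n_per_pop)
  n <- length(population)
  plant_id <- sprintf("plant_%04d", seq_len(n))

  spectra <- generate_spectra(n, cfg$archetype_mix)
  archetype <- vapply(spectra, attr, character(1), "archetype")
  rs_p <- receptor_set("pieris")
  rs_a <- receptor_set("aphid")
  prof_p <- catch_profiles(spectra, rs_p)
  prof_a <- catch_profiles(spectra, rs_a)

  d <- data.frame(plant_id = plant_id, population = population,
                  county = county, archetype = unname(archetype),
                  bg_ratio = prof_p$bg_ratio, prg_ratio = prof_p$prg_ratio,
                  drg_ratio = prof_p$drg_ratio,
                  bg_ratio_aphid = prof_a$bg_ratio,
                  brightness = prof_a$brightness,
                  stringsAsFactors = FALSE)

  channels <- as.matrix(d[c("bg_ratio", "prg_ratio", "drg_ratio",
                            "brightness")])
  # glucosinolates: copula per compound, then class totals by summation
  for (g in rownames(cfg$gs_targets)) {
    d[[g]] <- .copula_draw(channels, cfg$gs_targets[g, ],
                           function(p) stats::qlnorm(p, .gs_meanlog[[g]], 1))
  }
  d$gs_total_aliphatic <- rowSums(d[.gs_aliphatic])
  d$gs_total_indole <- rowSums(d[.gs_indole])
  d$gs_total <- d$gs_total_aliphatic + d$gs_total_indole

  # covariates with a field-like sign structure against the colour channels
  d$size_mm <- .copula_draw(
    channels, c(-0.09, 0.07, 0, -0.08),
    function(p) stats::qlnorm(p, log(10), 0.4))
  d$density <- .copula_draw(
    channels, c(0.08, -0.10, -0.07, 0.05),
    function(p) stats::qpois(p, 3))
  d$cn_ratio <- .copula_draw(
    channels, c(-0.29, 0.37, 0, 0.32),
    function(p) stats::qlnorm(p, log(15), 0.2))
  u <- apply(channels, 2, function(x) stats::qnorm((rank(x) - 0.5) / n))
  flower_lin <- 0.3 * (-u[, 1] + u[, 2] + u[, 3] - u[, 4])
  d$flowering <- stats::rbinom(n, 1, stats::plogis(
    stats::qlogis(0.3) + flower_lin)) == 1

  # assay subsets
  if (!is.na(cfg$n_gs_assayed) && cfg$n_gs_assayed < n) {
    assay <- .subset_per_pop(population, pops, cfg$n_gs_assayed)
    gs_cols <- c(rownames(cfg$gs_targets), "gs_total",
                 "gs_total_aliphatic", "gs_total_indole")
    d[!d$plant_id %in% assay, gs_cols] <- NA
  }
  if (!is.na(cfg$n_cn_assayed) && cfg$n_cn_assayed < n) {
    cn_sub <- sample(plant_id, cfg$n_cn_assayed)
    d$cn_ratio[!d$plant_id %in% cn_sub] <- NA
  }

  # second-survey relocation
  d$relocated <- d$plant_id %in% sample(plant_id, min(cfg$n_relocated, n))

  # presence under the logistic model with nested random intercepts
  d$presence_pieris <- .simulate_presence(d, cfg$presence$pieris,
                                          subset = d$relocated)
  aphid_sub <- d$county != "Kent"
  d$presence_brassicae <- .simulate_presence(d, cfg$presence$brassicae,
                                             subset = aphid_sub,
                                             channel_col = "brightness")
  d$presence_brassicae[d$county == "Kent"] <- 0L  # absent from Kent
  d
}

# Per-population assay subset of roughly equal size summing to n_target.
.subset_per_pop <- function(population, pops, n_target) {
  k <- length(pops)
  base <- n_target %/% k
  counts <- rep(base, k) + c(rep(1, n_target %% k), rep(0, k - n_target %% k))
  unlist(lapply(seq_along(pops), function(i) {
    ids <- which(population == pops[i])
    sample(ids, min(counts[i], length(ids)))
  })) |> (\(ix) sprintf("plant_%04d", ix))()
}

# Fixed-effect size beta for a target marginal R2 given random SDs:
# solve r2 = b^2 / (b^2 + sd_pop^2 + sd_county^2 + pi^2/3) with var(z) = 1.
.beta_for_r2 <- function(r2, sd_pop, sd_county) {
  if (r2 <= 0) return(0)
  sqrt(r2 / (1 - r2) * (sd_pop^2 + sd_county^2 + pi^2 / 3))
}

.simulate_presence <- function(d, spec, subset, channel_col = NULL) {
  ch <- if (is.null(channel_col)) spec$channel else channel_col
  out <- rep(NA_integer_, nrow(d))
  idx <- which(subset)
  z <- as.vector(scale(d[[ch]][idx]))
  beta <- spec$sign * .beta_for_r2(spec$r2, spec$sd_pop, spec$sd_county)
  cty <- unique(d$county)
  pop <- unique(d$population)
  eff_c <- stats::rnorm(length(cty), 0, spec$sd_county)
  eff_p <- stats::rnorm(length(pop), 0, spec$sd_pop)
  eta <- stats::qlogis(spec$base_rate) + beta * z +
    eff_c[match(d$county[idx], cty)] + eff_p[match(d$population[idx], pop)]
  out[idx] <- stats::rbinom(length(idx), 1, stats::plogis(eta))
  out
}

#' Generate choice trials for a paired preference experiment
#'
#' Bernoulli choices between the high and low plant of each pair, with the
#' side of the high plant randomized.
#'
#' @param n_pairs Number of plant pairs (default 30).
#' @param p_choose_high Probability the high plant is chosen.
#' @param metric Label of the paired metric (recorded, not used).
#' @param seed Optional seed for reproducibility.
#' @return A data frame: `pair_id`, `metric`, `side_of_high`, `chosen`.
#' @export
generate_choice_trials <- function(n_pairs = 30, p_choose_high = 0.5,
                                   metric = "bg_ratio", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    pair_id = seq_len(n_pairs),
    metric = metric,
    side_of_high = sample(c("left", "right"), n_pairs, replace = TRUE),
    chosen = ifelse(stats::rbinom(n_pairs, 1, p_choose_high) == 1,
                    "high", "low"),
    stringsAsFactors = FALSE)
}

#' Generate performance-experiment tables
#'
#' Emulates the two greenhouse performance designs: butterfly larvae (two
#' per plant) on plants from the high vs low blue:green groups, with
#' Normal growth-rate, pupal-mass and time-to-pupation responses at the
#' configured group means and SDs; and aphid colonies on bright vs dull
#' plants with log-normal counts. Counts and masses are positive by
#' construction (log-normal) or by truncation at a small positive floor.
#'
#' @param cfg A [sim_config()] (its `experiment` element sets the group
#'   means/SDs).
#' @param n_plants_per_group Plants per group (default 30).
#' @param n_aphid_pairs Plant pairs in the aphid experiment (default 15).
#' @param seed Optional seed.
#' @return A list of two data frames: `larvae` (one row per larva:
#'   `plant_id`, `group`, `larva`, `sex`, `growth_rate`, `pupal_mass_mg`,
#'   `time_to_pupation_days`) and `aphids` (one row per plant: `plant_id`,
#'   `group`, `total`, `alate`, `apterate`, `dead`).
#' @export
generate_performance <- function(cfg = sim_config(), n_plants_per_group = 30,
                                 n_aphid_pairs = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ex <- cfg$experiment
  groups <- rep(c("high", "low"), each = n_plants_per_group)
  plant <- sprintf("perf_%03d", seq_along(groups))
  draw <- function(spec, g, n) {
    pmax(stats::rnorm(n, spec[[g]][["mean"]], spec[[g]][["sd"]]), 0.01)
  }
  larvae <- do.call(rbind, lapply(seq_along(plant), function(i) {
    g <- groups[i]
    data.frame(plant_id = plant[i], group = g, larva = 1:2,
               sex = sample(c("F", "M"), 2, replace = TRUE),
               growth_rate = draw(ex$growth, g, 2),
               pupal_mass_mg = draw(ex$pupal_mass, g, 2),
               time_to_pupation_days = draw(ex$time_to_pupation, g, 2),
               stringsAsFactors = FALSE)
  }))
  agr <- rep(c("bright", "dull"), each = n_aphid_pairs)
  ap <- ex$aphid_total
  total <- round(stats::rlnorm(length(agr),
                               ifelse(agr == "bright", ap$bright[["meanlog"]],
                                      ap$dull[["meanlog"]]),
                               ifelse(agr == "bright", ap$bright[["sdlog"]],
                                      ap$dull[["sdlog"]])))
  total <- pmax(total, 1)
  p_alate <- stats::rbeta(length(agr), 2, 30)
  p_dead <- stats::rbeta(length(agr), 5, 12)
  alate <- stats::rbinom(length(agr), total, p_alate)
  dead <- stats::rbinom(length(agr), total - alate, p_dead)
  aphids <- data.frame(plant_id = sprintf("aphid_%03d", seq_along(agr)),
                       group = agr, total = total, alate = alate,
                       apterate = total - alate - dead, dead = dead,
                       stringsAsFactors = FALSE)
  list(larvae = larvae, aphids = aphids)
}
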