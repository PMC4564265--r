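# Photoreceptor sensitivity templates, receptor sets, quantum catches.

# Canonical measurement grid: 300-700 nm at 1 nm.
canonical_grid <- function() seq(300, 700, by = 1)

#' A1 visual-pigment sensitivity template
#'
#' Builds a full spectral sensitivity curve from a single peak wavelength
#' using the alpha-band of the A1 visual-pigment nomogram (the
#' Govardovskii-type template): with `x = lambda_max / lambda`,
#' `S = 1 / (exp(A (a - x)) + exp(B (b - x)) + exp(C (c - x)) + D)` where
#' `A = 69.7`, `B = 28`, `C = -14.9`, `D = 0.674`, `b = 0.922`, `c = 1.104`
#' and `a = 0.8795 + 0.0459 exp(-(lambda_max - 300)^2 / 11940)`. The curve
#' is peak-normalized to 1 on the grid. The beta-band is omitted: the
#' analyses here compare catches between leaves, where the small
#' short-wavelength shoulder is immaterial.
#'
#' @param lambda_max_nm Peak sensitivity wavelength, in 300-700 nm.
#' @param grid Wavelength grid (nm); default 300-700 at 1 nm.
#' @return Numeric sensitivity curve on `grid`, non-negative, max 1.
#' @export
visual_pigment_template <- function(lambda_max_nm, grid = canonical_grid()) {
  if (lambda_max_nm < 300 || lambda_max_nm > 700) {
    stop("lambda_max must lie in [300, 700] nm, got ", lambda_max_nm)
  }
  x <- lambda_max_nm / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  s / max(s)
}

#' Construct a single photoreceptor
#'
#' @param name Receptor label (`"UV"`, `"B"`, `"G"`, `"PR"` or `"DR"`).
#' @param lambda_max_nm Peak sensitivity wavelength (nm).
#' @param grid Wavelength grid; default 300-700 at 1 nm.
#' @return A `receptor` object with the peak-normalized sensitivity curve.
#' @export
receptor <- function(name, lambda_max_nm, grid = canonical_grid()) {
  structure(
    list(name = name, lambda_max_nm = lambda_max_nm, grid = grid,
         sensitivity = visual_pigment_template(lambda_max_nm, grid)),
    class = "leaf_receptor")
}

#' @export
print.leaf_receptor <- function(x, ...) {
  cat("<receptor> ", x$name, ": lambda_max ", x$lambda_max_nm, " nm\n",
      sep = "")
  invisible(x)
}

# CIE standard illuminant D65, relative spectral power 300-700 nm at 10 nm.
.d65_table <- function() {
  list(
    wl = seq(300, 700, by = 10),
    power = c(0.0341, 3.2945, 20.236, 37.0535, 39.9488, 44.9117, 46.6383,
              52.0891, 49.9755, 54.6482, 82.7549, 91.486, 93.4318, 86.6823,
              104.865, 117.008, 117.812, 114.861, 115.923, 108.811, 109.354,
              107.802, 104.79, 107.689, 104.405, 104.046, 100.0, 96.3342,
              95.788, 88.6856, 90.0062, 89.5991, 87.6987, 83.2886, 83.6992,
              80.0268, 80.2146, 82.2778, 78.2842, 69.7213, 71.6091))
}

#' Illuminant spectra
#'
#' `"flat"` is an equal-quanta spectrum (all 1); `"d65"` is CIE standard
#' daylight D65 interpolated to the grid and converted from relative energy
#' to relative quanta (multiplied by wavelength), then normalized to a
#' maximum of 1. Quantum catches use photon units, hence the conversion.
#'
#' @param type `"flat"` or `"d65"`.
#' @param grid Wavelength grid (nm).
#' @return Numeric vector of relative photon flux on `grid`, all positive.
#' @export
illuminant_spectrum <- function(type = c("flat", "d65"),
                                grid = canonical_grid()) {
  type <- match.arg(type)
  if (type == "flat") return(rep(1, length(grid)))
  tab <- .d65_table()
  e <- stats::approx(tab$wl, tab$power, xout = grid)$y
  q <- e * grid
  q / max(q)
}

# Default peak wavelengths. Aphid values follow Myzus-type eye physiology;
# pieris PR/DR are the measured pale-red/deep-red peaks. Pieris UV/B/G are
# configuration defaults sourced from pierid eye-physiology literature (not
# measured in this system) and should be overridden when better values exist.
.default_lambda_max <- list(
  aphid  = c(UV = 325, B = 460, G = 530),
  pieris = c(UV = 360, B = 450, G = 563, PR = 620, DR = 640))

#' Build a species receptor set
#'
#' @param species `"pieris"` (UV, B, G plus pale-red and deep-red receptors)
#'   or `"aphid"` (UV, B, G).
#' @param overrides Optional named numeric vector of replacement peak
#'   wavelengths, e.g. `c(G = 565)`. Names must be receptors of the species.
#' @param illuminant `"flat"`, `"d65"`, or a numeric photon spectrum on
#'   `grid`.
#' @param grid Wavelength grid; default 300-700 at 1 nm.
#' @return A `receptor_set` object.
#' @export
receptor_set <- function(species = c("pieris", "aphid"), overrides = NULL,
                         illuminant = "flat", grid = canonical_grid()) {
  if (!is.character(species) || !species[1] %in% names(.default_lambda_max)) {
    stop("unknown species '", species[1], "'; use 'pieris' or 'aphid'")
  }
  species <- species[1]
  lmax <- .default_lambda_max[[species]]
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(lmax))
    if (length(bad)) {
      stop("override names not in the ", species, " receptor set: ",
           paste(bad, collapse = ", "))
    }
    lmax[names(overrides)] <- overrides
  }
  illum <- if (is.character(illuminant)) {
    illuminant_spectrum(illuminant, grid)
  } else {
    if (length(illuminant) != length(grid)) {
      stop("illuminant length does not match the grid")
    }
    as.numeric(illuminant)
  }
  if (any(illum <= 0)) stop("illuminant must be positive on the whole grid")
  recs <- lapply(names(lmax), function(nm) receptor(nm, lmax[[nm]], grid))
  names(recs) <- names(lmax)
  structure(list(species = species, receptors = recs, illuminant = illum,
                 grid = grid),
            class = "leaf_receptor_set")
}

#' @export
print.leaf_receptor_set <- function(x, ...) {
  lm <- vapply(x$receptors, `[[`, numeric(1), "lambda_max_nm")
  cat("<receptor_set> ", x$species, ": ",
      paste(names(lm), lm, sep = "=", collapse = ", "), " nm\n", sep = "")
  invisible(x)
}

# Trapezoidal integral on an (irregular) grid.
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Quantum catch of one receptor viewing one spectrum
#'
#' The catch is the trapezoidal integral over the shared grid of
#' reflectance x illuminant x receptor sensitivity, i.e. the relative photon
#' flux absorbed by the receptor class. Linear in reflectance.
#'
#' @param s A `leaf_spectrum` on the receptor's grid (use [resample()]
#'   first if needed).
#' @param rec A `receptor`.
#' @param illuminant Numeric photon spectrum on the same grid.
#' @return A single non-negative number.
#' @export
quantum_catch <- function(s, rec, illuminant) {
  if (!isTRUE(all.equal(s$wavelength_nm, rec$grid))) {
    stop("spectrum and receptor grids differ; resample first")
  }
  if (length(illuminant) != length(rec$grid)) {
    stop("illuminant length does not match the grid")
  }
  .trapz(rec$grid, s$reflectance * illuminant * rec$sensitivity)
}

#' Quantum-catch profile of a leaf
#'
#' Computes the catch of every receptor in the set plus the derived
#' opponency channels: `bg_ratio` (blue:green catch), and for pieris also
#' `prg_ratio` (pale-red:green) and `drg_ratio` (deep-red:green).
#' `brightness` is the green-receptor catch alone, the achromatic channel.
#'
#' @param s A `leaf_spectrum` on the set's grid.
#' @param rs A `receptor_set`.
#' @return A one-row data frame: `sample_id`, `catch_<name>` per receptor,
#'   `bg_ratio`, (`prg_ratio`, `drg_ratio`,) `brightness`.
#' @export
catch_profile <- function(s, rs) {
  catches <- vapply(rs$receptors, function(r) {
    quantum_catch(s, r, rs$illuminant)
  }, numeric(1))
  if (catches[["G"]] <= 0) {
    stop("green-receptor catch is zero; opponency ratios undefined")
  }
  out <- data.frame(sample_id = s$sample_id, stringsAsFactors = FALSE)
  for (nm in names(catches)) out[[paste0("catch_", nm)]] <- catches[[nm]]
  out$bg_ratio <- catches[["B"]] / catches[["G"]]
  if (rs$species == "pieris") {
    out$prg_ratio <- catches[["PR"]] / catches[["G"]]
    out$drg_ratio <- catches[["DR"]] / catches[["G"]]
  }
  out$brightness <- catches[["G"]]
  out
}

#' Quantum-catch profiles for a list of spectra
#'
#' @param spectra A list of `leaf_spectrum` objects.
#' @param rs A `receptor_set`.
#' @return A data frame with one row per spectrum (see [catch_profile()]).
#' @export
catch_profiles <- function(spectra, rs) {
  do.call(rbind, lapply(spectra, catch_profile, rs = rs))
}
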