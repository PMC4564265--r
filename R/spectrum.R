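# Reflectance spectra: construction, I/O, normalization, resampling, smoothing.

#' Construct a reflectance spectrum
#'
#' A `leaf_spectrum` holds a reflectance curve measured against a white
#' standard (barium sulphate), so values are unitless and may exceed 1 for
#' specular leaves. Wavelengths must be strictly increasing.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param reflectance Numeric vector of reflectance values, same length as
#'   `wavelength_nm`, all `>= 0`.
#' @param sample_id Character label for the sample.
#' @param survey Optional survey label (e.g. `"first"`/`"second"`).
#' @return An object of class `leaf_spectrum` with elements `wavelength_nm`,
#'   `reflectance`, `sample_id` and `survey`.
#' @examples
#' s <- spectrum_new(300:700, rep(0.5, 401), "leaf1")
#' s
#' @export
spectrum_new <- function(wavelength_nm, reflectance, sample_id = "sample",
                         survey = NULL) {
  wavelength_nm <- as.numeric(wavelength_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelength_nm) != length(reflectance)) {
    stop("wavelength and reflectance lengths differ (",
         length(wavelength_nm), " vs ", length(reflectance), ")")
  }
  if (anyNA(wavelength_nm)) stop("wavelengths contain missing values")
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  keep <- !is.na(reflectance)
  dropped <- sum(!keep)
  wavelength_nm <- wavelength_nm[keep]
  reflectance <- reflectance[keep]
  if (any(reflectance < 0)) stop("reflectance must be >= 0")
  structure(
    list(wavelength_nm = wavelength_nm, reflectance = reflectance,
         sample_id = as.character(sample_id), survey = survey,
         n_dropped = dropped),
    class = "leaf_spectrum")
}

#' @export
print.leaf_spectrum <- function(x, ...) {
  cat("<leaf_spectrum> ", x$sample_id,
      if (!is.null(x$survey)) paste0(" (survey: ", x$survey, ")"), "\n",
      sep = "")
  cat("  ", length(x$wavelength_nm), " points, ",
      min(x$wavelength_nm), "-", max(x$wavelength_nm), " nm, reflectance ",
      signif(min(x$reflectance), 3), "-", signif(max(x$reflectance), 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.leaf_spectrum <- function(x, ...) {
  data.frame(sample_id = x$sample_id, wavelength_nm = x$wavelength_nm,
             reflectance = x$reflectance, stringsAsFactors = FALSE)
}

#' @export
plot.leaf_spectrum <- function(x, ..., col = "darkgreen") {
  graphics::plot(x$wavelength_nm, x$reflectance, type = "l", col = col,
                 xlab = "Wavelength (nm)", ylab = "Reflectance",
                 main = x$sample_id, ...)
  invisible(x)
}

#' Read reflectance spectra from CSV
#'
#' Two dialects are supported. The wide dialect has a first column
#' `wavelength_nm` followed by one column per sample; the long dialect has
#' columns `sample_id`, `wavelength_nm`, `reflectance`. Rows with missing
#' reflectance are dropped (and counted on each returned spectrum);
#' wavelengths are returned sorted ascending.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param dialect `"wide"` or `"long"`.
#' @return A named list of [spectrum_new()] objects, one per sample.
#' @export
read_spectra <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  .numcol <- function(x, name) {
    suppressWarnings(v <- as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
    if (length(bad)) {
      stop("non-numeric value in column '", name, "' at data line ",
           bad[1], ": '", x[bad[1]], "'")
    }
    v
  }
  if (dialect == "wide") {
    if (ncol(raw) < 2) stop("wide dialect needs a wavelength column plus >= 1 sample column")
    wl <- .numcol(raw[[1]], names(raw)[1])
    out <- lapply(names(raw)[-1], function(nm) {
      refl <- .numcol(raw[[nm]], nm)
      ord <- order(wl)
      w <- wl[ord]; r <- refl[ord]
      if (anyDuplicated(w[!is.na(r)])) {
        stop("duplicate wavelength for sample '", nm, "'")
      }
      spectrum_new(w, r, sample_id = nm)
    })
    names(out) <- names(raw)[-1]
  } else {
    need <- c("sample_id", "wavelength_nm", "reflectance")
    if (!all(need %in% names(raw))) {
      stop("long dialect needs columns: ", paste(need, collapse = ", "))
    }
    wl <- .numcol(raw$wavelength_nm, "wavelength_nm")
    refl <- .numcol(raw$reflectance, "reflectance")
    ids <- raw$sample_id
    out <- lapply(unique(ids), function(id) {
      sel <- ids == id
      w <- wl[sel]; r <- refl[sel]
      ord <- order(w)
      w <- w[ord]; r <- r[ord]
      if (anyDuplicated(w[!is.na(r)])) {
        stop("duplicate wavelength for sample '", id, "'")
      }
      spectrum_new(w, r, sample_id = id)
    })
    names(out) <- unique(ids)
  }
  out
}

#' Write spectra to CSV
#'
#' @param spectra A list of `leaf_spectrum` objects.
#' @param path Output path.
#' @param dialect `"wide"` (requires identical grids) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (inherits(spectra, "leaf_spectrum")) spectra <- list(spectra)
  if (dialect == "wide") {
    grids <- lapply(spectra, `[[`, "wavelength_nm")
    if (!all(vapply(grids, identical, logical(1), y = grids[[1]]))) {
      stop("wide dialect requires identical wavelength grids")
    }
    df <- data.frame(wavelength_nm = grids[[1]])
    for (s in spectra) df[[s$sample_id]] <- s$reflectance
  } else {
    df <- do.call(rbind, lapply(spectra, as.data.frame))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Normalize raw counts against a white standard
#'
#' Converts raw spectrometer counts to reflectance relative to a white
#' standard: `(raw - dark) / (white - dark)`, with the dark reading
#' defaulting to zero. All spectra must share one wavelength grid.
#'
#' @param raw,white `leaf_spectrum` objects on identical grids.
#' @param dark Optional `leaf_spectrum` dark reading; default zero.
#' @return A `leaf_spectrum` of reflectance values.
#' @export
normalize_to_white <- function(raw, white, dark = NULL) {
  if (!identical(raw$wavelength_nm, white$wavelength_nm)) {
    stop("raw and white standard wavelength grids differ")
  }
  d <- if (is.null(dark)) rep(0, length(raw$reflectance)) else {
    if (!identical(raw$wavelength_nm, dark$wavelength_nm)) {
      stop("raw and dark wavelength grids differ")
    }
    dark$reflectance
  }
  denom <- white$reflectance - d
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop("white <= dark at wavelengths: ",
         paste(utils::head(raw$wavelength_nm[bad], 5), collapse = ", "),
         if (length(bad) > 5) " ...")
  }
  spectrum_new(raw$wavelength_nm, pmax((raw$reflectance - d) / denom, 0),
               sample_id = raw$sample_id, survey = raw$survey)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; extrapolation outside the measured range is refused.
#'
#' @param s A `leaf_spectrum`.
#' @param grid Target wavelengths (nm), within the measured range.
#' @return A `leaf_spectrum` on `grid`.
#' @export
resample <- function(s, grid) {
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavelength_nm) || max(grid) > max(s$wavelength_nm)) {
    stop("resampling grid extends beyond the measured range (",
         min(s$wavelength_nm), "-", max(s$wavelength_nm), " nm); ",
         "extrapolation is not supported")
  }
  r <- stats::approx(s$wavelength_nm, s$reflectance, xout = grid)$y
  spectrum_new(grid, r, sample_id = s$sample_id, survey = s$survey)
}

#' Smooth a spectrum with a piecewise cubic least-squares fit
#'
#' Fits a cubic regression spline with knots at the boundaries of
#' `n_sections` equal sections spanning `fit_range_nm`, by minimising the
#' total squared deviation, and evaluates the fit on the input grid
#' restricted to the fit range. The spline is C2-continuous at the interior
#' knots, so the single global cubic is nested inside the model and the
#' fitted residual sum of squares can never exceed that of a global cubic.
#'
#' If the data do not span the requested fit range, the available range is
#' used with a warning.
#'
#' @param s A `leaf_spectrum`.
#' @param n_sections Number of equal sections (default 30).
#' @param fit_range_nm Length-2 numeric, the fitting interval (default
#'   `c(300, 800)`).
#' @return A `leaf_spectrum` holding the smoothed values.
#' @export
smooth_piecewise_cubic <- function(s, n_sections = 30,
                                   fit_range_nm = c(300, 800)) {
  stopifnot(n_sections >= 1, length(fit_range_nm) == 2)
  lo <- max(fit_range_nm[1], min(s$wavelength_nm))
  hi <- min(fit_range_nm[2], max(s$wavelength_nm))
  if (lo > fit_range_nm[1] || hi < fit_range_nm[2]) {
    warning("data span ", lo, "-", hi, " nm; fitting over the available range")
  }
  sel <- s$wavelength_nm >= lo & s$wavelength_nm <= hi
  x <- s$wavelength_nm[sel]
  y <- s$reflectance[sel]
  if (length(x) < 4 * n_sections) {
    stop("need at least ", 4 * n_sections, " points in the fit range, got ",
         length(x))
  }
  knots <- seq(lo, hi, length.out = n_sections + 1)
  basis <- splines::bs(x, knots = knots[-c(1, n_sections + 1)], degree = 3,
                       intercept = TRUE, Boundary.knots = c(lo, hi))
  fit <- stats::lm.fit(basis, y)
  spectrum_new(x, pmax(fit$fitted.values, 0), sample_id = s$sample_id,
               survey = s$survey)
}

#' Normalize a spectrum to its chlorophyll peak
#'
#' Divides the whole curve by the maximum reflectance within
#' `anchor_nm +/- window_nm` (default the green chlorophyll reflectance peak
#' near 550 nm), so the peak value inside the window becomes 1. Useful for
#' comparing spectral shape independent of overall intensity.
#'
#' @param s A `leaf_spectrum`.
#' @param anchor_nm Centre of the anchor window (nm).
#' @param window_nm Half-width of the anchor window (nm).
#' @return A `leaf_spectrum`.
#' @export
normalize_to_peak <- function(s, anchor_nm = 550, window_nm = 30) {
  sel <- s$wavelength_nm >= anchor_nm - window_nm &
    s$wavelength_nm <= anchor_nm + window_nm
  if (!any(sel)) stop("anchor window lies outside the spectrum range")
  peak <- max(s$reflectance[sel])
  if (peak <= 0) stop("all reflectance values in the anchor window are zero")
  spectrum_new(s$wavelength_nm, s$reflectance / peak,
               sample_id = s$sample_id, survey = s$survey)
}
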