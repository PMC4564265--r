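# Small in-code fixtures shared across tests.

flat_spectrum <- function(value = 0.5, id = "flat") {
  spectrum_new(300:700, rep(value, 401), sample_id = id)
}

# narrow Gaussian reflectance band
band_spectrum <- function(centre, width = 10, amp = 0.5, id = "band") {
  wl <- 300:700
  spectrum_new(wl, amp * exp(-(wl - centre)^2 / (2 * width^2)) + 1e-6,
               sample_id = id)
}

write_wide_csv <- function(path, wl, samples) {
  df <- data.frame(wavelength_nm = wl)
  for (nm in names(samples)) df[[nm]] <- samples[[nm]]
  write.csv(df, path, row.names = FALSE)
  path
}
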