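#' Tryptophan fluorescence emission spectrum at one denaturant concentration
#'
#' @param wavelengths Wavelength grid, nm; strictly increasing, at least 5
#'   points, inside `window`.
#' @param intensities Fluorescence intensities, arbitrary units,
#'   non-negative; same length as `wavelengths`.
#' @param denaturant_conc Denaturant concentration of the sample, M.
#' @param sample_id Sample label.
#' @param window Allowed wavelength window, nm; default `c(300, 450)` as
#'   recorded for Trp emission excited at 295 nm.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, denaturant_conc,
                              sample_id = "sample", window = c(300, 450)) {
  stopifnot(is.numeric(wavelengths), is.numeric(intensities))
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 5L) {
    stop("an emission spectrum needs at least 5 points", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(wavelengths < window[1] | wavelengths > window[2])) {
    stop(sprintf("wavelengths outside the declared window [%g, %g] nm",
                 window[1], window[2]), call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  stopifnot(is.numeric(denaturant_conc), denaturant_conc >= 0)
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities),
                 denaturant_conc = as.numeric(denaturant_conc),
                 sample_id = as.character(sample_id),
                 window = as.numeric(window)),
            class = "emission_spectrum")
}

#' Denaturant-induced transition curve
#'
#' A series of (denaturant concentration, signal) points for one sample,
#' e.g. the emission-maximum wavelength at each GdnHCl concentration.
#' Points are stored sorted by concentration.
#'
#' @param concs Denaturant concentrations, M, non-negative and unique.
#' @param signals Observed signal at each concentration.
#' @param signal_kind One of `"lambda_max_nm"`, `"intensity_au"`,
#'   `"generic"`.
#' @param sample_id Sample label.
#' @return An object of class `denaturation_curve`.
#' @export
denaturation_curve <- function(concs, signals,
                               signal_kind = c("lambda_max_nm",
                                               "intensity_au", "generic"),
                               sample_id = "sample") {
  signal_kind <- match.arg(signal_kind)
  stopifnot(is.numeric(concs), is.numeric(signals))
  if (length(concs) != length(signals)) {
    stop("concs and signals must have equal length", call. = FALSE)
  }
  if (any(concs < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (anyDuplicated(concs)) {
    stop("duplicate denaturant concentrations: ",
         paste(unique(concs[duplicated(concs)]), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(concs)
  structure(list(concs = as.numeric(concs[ord]),
                 signals = as.numeric(signals[ord]),
                 signal_kind = signal_kind,
                 sample_id = as.character(sample_id)),
            class = "denaturation_curve")
}

#' @export
print.denaturation_curve <- function(x, ...) {
  cat(sprintf("Denaturation curve '%s': %d points, %.3g-%.3g M, signal = %s\n",
              x$sample_id, length(x$concs), min(x$concs), max(x$concs),
              x$signal_kind))
  invisible(x)
}

#' @export
as.data.frame.denaturation_curve <- function(x, ...) {
  data.frame(conc_M = x$concs, signal = x$signals,
             signal_kind = x$signal_kind, sample = x$sample_id,
             stringsAsFactors = FALSE)
}

#' Extract the emission-maximum wavelength from a spectrum
#'
#' Three estimators are offered. `argmax` returns the grid wavelength with
#' maximal intensity (ties broken toward the lower wavelength). `parabolic`
#' (the default) refines the discrete maximum by fitting a quadratic through
#' it and its two neighbours and returning the vertex, giving sub-grid
#' precision without assuming a band shape. `centroid` returns the
#' intensity-weighted mean wavelength over points at or above a fraction
#' (default 0.8) of the peak intensity.
#'
#' A maximum on the first or last grid point is an error: it means the
#' recorded window clipped the emission band.
#'
#' @param s An `emission_spectrum`.
#' @param method Extraction method.
#' @param centroid_fraction Peak fraction defining the centroid region.
#' @return The emission-maximum wavelength, nm.
#' @export
extract_lambda_max <- function(s, method = c("parabolic", "argmax", "centroid"),
                               centroid_fraction = 0.8) {
  stopifnot(inherits(s, "emission_spectrum"))
  method <- match.arg(method)
  y <- s$intensities
  w <- s$wavelengths
  if (diff(range(y)) == 0) {
    stop("spectrum has no unique maximum (constant intensities)",
         call. = FALSE)
  }
  i <- which.max(y)  # which.max takes the first = lower-wavelength tie
  if (i == 1L || i == length(y)) {
    stop("intensity maximum lies on the window edge; the emission band is clipped",
         call. = FALSE)
  }
  switch(method,
    argmax = w[i],
    parabolic = {
      # quadratic through (w[i-1],y[i-1]), (w[i],y[i]), (w[i+1],y[i+1]); vertex
      x1 <- w[i - 1L]; x2 <- w[i]; x3 <- w[i + 1L]
      y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
      d <- (x1 - x2) * (x1 - x3) * (x2 - x3)
      a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / d
      b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / d
      if (a >= 0) w[i] else -b / (2 * a)
    },
    centroid = {
      keep <- y >= centroid_fraction * y[i]
      sum(w[keep] * y[keep]) / sum(y[keep])
    })
}

#' Assemble a transition curve from per-concentration spectra
#'
#' Extracts the emission maximum from each spectrum and returns the
#' (concentration, lambda max) series sorted by concentration.
#'
#' @param spectra List of `emission_spectrum` objects sharing one
#'   `sample_id`, with unique denaturant concentrations.
#' @param method Extraction method passed to [extract_lambda_max()].
#' @return A `denaturation_curve` with `signal_kind = "lambda_max_nm"`.
#' @export
build_transition_curve <- function(spectra, method = "parabolic") {
  stopifnot(is.list(spectra), length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "emission_spectrum")))
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  if (length(unique(ids)) != 1L) {
    stop("all spectra must share one sample_id (got: ",
         paste(unique(ids), collapse = ", "), ")", call. = FALSE)
  }
  concs <- vapply(spectra, `[[`, numeric(1), "denaturant_conc")
  if (anyDuplicated(concs)) {
    stop("duplicate denaturant concentrations across spectra", call. = FALSE)
  }
  lmax <- vapply(spectra, extract_lambda_max, numeric(1), method = method)
  denaturation_curve(concs, lmax, signal_kind = "lambda_max_nm",
                     sample_id = ids[1])
}
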