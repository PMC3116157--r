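#' Simulate a noisy denaturant-induced transition curve
#'
#' Forward-simulates the observable signal at each grid concentration from
#' the equilibrium model and adds iid Gaussian measurement noise. With
#' `noise_sd = 0` the exact model curve is returned. All randomness is
#' controlled by `seed`; the caller's RNG stream is left untouched.
#'
#' @param p A `three_state_params` or `two_state_params` object.
#' @param conc_grid Denaturant concentrations, M; default 31 evenly spaced
#'   points from 0 to 3 M (covering both transitions of a typical
#'   GdnHCl-induced unfolding).
#' @param noise_sd Gaussian noise standard deviation, signal units;
#'   default 0.3 (nm-scale scatter typical of emission-maximum readouts).
#' @param seed Integer seed.
#' @param signal_kind Stored on the returned curve; default
#'   `"lambda_max_nm"`.
#' @param sample_id Sample label.
#' @return A `denaturation_curve`.
#' @export
generate_curve <- function(p, conc_grid = seq(0, 3, length.out = 31),
                           noise_sd = 0.3, seed = 1L,
                           signal_kind = "lambda_max_nm",
                           sample_id = "synthetic") {
  stopifnot(is.numeric(conc_grid), all(conc_grid >= 0), noise_sd >= 0)
  y <- predicted_signal(p, conc_grid)
  if (noise_sd > 0) {
    old <- .restorable_seed(seed)
    on.exit(.restore_seed(old), add = TRUE)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  denaturation_curve(conc_grid, y, signal_kind = signal_kind,
                     sample_id = sample_id)
}

#' Simulate raw emission spectra along a denaturant titration
#'
#' Each spectrum is a population-weighted sum of Gaussian emission bands,
#' one band per conformational state, centred at that state's baseline
#' wavelength (band width `band_width_nm`, default 20 nm, typical of Trp
#' emission), sampled on a regular wavelength grid inside the recording
#' window, plus iid Gaussian intensity noise. For bands much wider than
#' their separation the peak of the mixed spectrum lies close to the
#' population-weighted mean wavelength, which is what the transition-curve
#' model assumes.
#'
#' @param p A `three_state_params` object whose baselines are wavelengths
#'   inside `window`.
#' @param conc_grid Denaturant concentrations, M.
#' @param band_width_nm Gaussian band sigma, nm.
#' @param grid_step_nm Wavelength sampling step, nm; default 1 nm.
#' @param noise_sd Intensity noise SD (arbitrary units; band peak height is
#'   ~1). The default 0.001 makes the scatter of extracted emission maxima
#'   about 0.3 nm, consistent with the curve generator's default signal
#'   noise.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param window Recording window, nm; default 300-450.
#' @return A list of `emission_spectrum` objects, one per concentration.
#' @export
generate_spectra <- function(p, conc_grid = seq(0, 3, length.out = 31),
                             band_width_nm = 20, grid_step_nm = 1,
                             noise_sd = 0.001, seed = 1L,
                             sample_id = "synthetic",
                             window = c(300, 450)) {
  stopifnot(inherits(p, "three_state_params"))
  centers <- c(p$baseline_n, p$baseline_i, p$baseline_u)
  if (any(centers < window[1] | centers > window[2])) {
    stop("state band centers must lie inside the recording window",
         call. = FALSE)
  }
  wl <- seq(window[1], window[2], by = grid_step_nm)
  old <- .restorable_seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  lapply(conc_grid, function(conc) {
    f <- state_fractions_three_state(p, conc)
    inten <- f$f_n * exp(-(wl - p$baseline_n)^2 / (2 * band_width_nm^2)) +
      f$f_i * exp(-(wl - p$baseline_i)^2 / (2 * band_width_nm^2)) +
      f$f_u * exp(-(wl - p$baseline_u)^2 / (2 * band_width_nm^2))
    if (noise_sd > 0) inten <- inten + stats::rnorm(length(wl), 0, noise_sd)
    emission_spectrum(wl, pmax(inten, 0), denaturant_conc = conc,
                      sample_id = sample_id, window = window)
  })
}

#' Published thermodynamic parameters of the HCAII Pro237 mutant panel
#'
#' Point estimates of the three-state unfolding thermodynamics (dG_NI,
#' m_NI, dG_IU, m_IU at 25 C, GdnHCl denaturation) for pseudo wild-type
#' human carbonic anhydrase II (HCAII_pwt, carrying C206S) and the five
#' position-237 substitutions with full component fits: P237A, P237T,
#' P237N, P237I, P237F. P237H is excluded: only its total ddG_NU
#' (7.3 kcal/mol, literature) is known, not its component transitions.
#'
#' The lambda-max baselines (native 336, intermediate 341, unfolded 355 nm)
#' are generator defaults typical of buried, molten-globule and
#' solvent-exposed tryptophans, not measured values; override them through
#' the returned parameter objects if needed.
#'
#' @param baseline_n,baseline_i,baseline_u Per-state lambda-max baselines,
#'   nm.
#' @param conc_grid Default simulation grid, M.
#' @param noise_sd Default signal noise SD, nm.
#' @param seed Default simulation seed.
#' @param n_replicates Default replicate count for simulation studies.
#' @return A list of class `panel_spec` with `$variants` (named list of
#'   `three_state_params`), `$conc_grid`, `$noise_sd`, `$seed`,
#'   `$n_replicates`, `$reference` (`"HCAII_pwt"`), and
#'   `$literature_ddg` (`P237H = 7.3`).
#' @export
hcaii_p237_panel <- function(baseline_n = 336, baseline_i = 341,
                             baseline_u = 355,
                             conc_grid = seq(0, 3, length.out = 31),
                             noise_sd = 0.3, seed = 1L, n_replicates = 100L) {
  tab <- list(
    # variant       dG_NI m_NI dG_IU m_IU
    HCAII_pwt   = c(5.7, 6.3, 7.8, 3.9),
    HCAII_P237A = c(6.5, 6.5, 6.0, 2.8),
    HCAII_P237T = c(4.7, 5.2, 6.4, 3.0),
    HCAII_P237N = c(5.0, 5.5, 7.3, 3.6),
    HCAII_P237I = c(5.1, 6.2, 7.5, 3.7),
    HCAII_P237F = c(5.3, 6.3, 5.3, 2.5)
  )
  variants <- lapply(tab, function(v) {
    three_state_params(transition_thermo(v[1], v[2]),
                       transition_thermo(v[3], v[4]),
                       baseline_n, baseline_i, baseline_u)
  })
  structure(list(variants = variants,
                 conc_grid = conc_grid,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 reference = "HCAII_pwt",
                 literature_ddg = c(HCAII_P237H = 7.3)),
            class = "panel_spec")
}

#' Simulate transition curves for every variant of a panel
#'
#' One curve per variant on the panel's grid; replicate `r` of variant `v`
#' uses seed `panel$seed + r` offset by the variant index so replicates and
#' variants draw independent streams.
#'
#' @param panel A `panel_spec`, e.g. from [hcaii_p237_panel()].
#' @param noise_sd Override the panel's noise SD (e.g. 0 for noiseless
#'   curves).
#' @param replicate Replicate index (shifts the seed).
#' @return Named list of `denaturation_curve`s.
#' @export
generate_panel_curves <- function(panel, noise_sd = panel$noise_sd,
                                  replicate = 0L) {
  stopifnot(inherits(panel, "panel_spec"))
  labs <- names(panel$variants)
  curves <- lapply(seq_along(labs), function(i) {
    generate_curve(panel$variants[[i]], conc_grid = panel$conc_grid,
                   noise_sd = noise_sd,
                   seed = panel$seed + as.integer(replicate) * 1000L + i,
                   sample_id = labs[i])
  })
  stats::setNames(curves, labs)
}
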