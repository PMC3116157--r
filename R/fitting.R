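#' Options controlling a denaturation-curve fit
#'
#' @param model `"three_state"` (N-I-U) or `"two_state"` (N-U).
#' @param fit_baseline_slopes If `TRUE`, linear baseline slopes are free
#'   parameters; default `FALSE` (flat per-state baselines, appropriate for
#'   emission-maximum signals).
#' @param max_iterations Maximum optimizer iterations (the underlying
#'   Levenberg-Marquardt routine caps this at 1024).
#' @param tolerance Relative convergence tolerance on the residual sum of
#'   squares.
#' @param n_bootstrap Number of case-resampling bootstrap refits for
#'   standard errors; 0 (default) uses the Jacobian-based covariance.
#' @param seed Integer seed for the multi-start fallback and bootstrap.
#' @param start Optional caller-supplied starting parameter object
#'   (`three_state_params` / `two_state_params`); default uses
#'   [initial_guess()].
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(model = c("three_state", "two_state"),
                        fit_baseline_slopes = FALSE,
                        max_iterations = 1024L,
                        tolerance = 1e-10,
                        n_bootstrap = 0L,
                        seed = 1L,
                        start = NULL) {
  model <- match.arg(model)
  stopifnot(max_iterations >= 1L, tolerance > 0, n_bootstrap >= 0L)
  structure(list(model = model,
                 fit_baseline_slopes = isTRUE(fit_baseline_slopes),
                 max_iterations = as.integer(min(max_iterations, 1024L)),
                 tolerance = tolerance,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed),
                 start = start),
            class = "fit_options")
}

# parameter-vector layout per model; slopes appended when free
.par_names <- function(model, slopes) {
  if (model == "three_state") {
    nm <- c("dg_ni", "m_ni", "dg_iu", "m_iu", "b_n", "b_i", "b_u")
    if (slopes) nm <- c(nm, "s_n", "s_i", "s_u")
  } else {
    nm <- c("dg_nu", "m_nu", "b_n", "b_u")
    if (slopes) nm <- c(nm, "s_n", "s_u")
  }
  nm
}

.params_to_par <- function(p, slopes) {
  if (inherits(p, "three_state_params")) {
    par <- c(dg_ni = p$ni$dg0, m_ni = p$ni$m, dg_iu = p$iu$dg0, m_iu = p$iu$m,
             b_n = p$baseline_n, b_i = p$baseline_i, b_u = p$baseline_u)
    if (slopes) par <- c(par, s_n = p$baseline_slope_n,
                         s_i = p$baseline_slope_i, s_u = p$baseline_slope_u)
  } else {
    par <- c(dg_nu = p$nu$dg0, m_nu = p$nu$m,
             b_n = p$baseline_n, b_u = p$baseline_u)
    if (slopes) par <- c(par, s_n = p$baseline_slope_n,
                         s_u = p$baseline_slope_u)
  }
  par
}

.par_to_params <- function(par, model, slopes,
                           temperature = DEFAULT_TEMPERATURE_K) {
  par <- as.list(par)
  z <- function(nm) if (slopes) par[[nm]] else 0
  if (model == "three_state") {
    three_state_params(transition_thermo(par$dg_ni, par$m_ni),
                       transition_thermo(par$dg_iu, par$m_iu),
                       par$b_n, par$b_i, par$b_u,
                       z("s_n"), z("s_i"), z("s_u"),
                       temperature = temperature)
  } else {
    two_state_params(transition_thermo(par$dg_nu, par$m_nu),
                     par$b_n, par$b_u, z("s_n"), z("s_u"),
                     temperature = temperature)
  }
}

#' Heuristic starting parameters for a curve fit
#'
#' Native and unfolded baselines are taken as means of the first and last
#' 15% of points; the intermediate baseline starts midway between them.
#' Transition midpoints are located where the signal crosses 25% and 75% of
#' the native-to-unfolded span; m-values start at the field-typical 6 and 4
#' kcal mol^-1 M^-1 for the N-I and I-U transitions (5 for a two-state
#' fit), and dG0 = m x midpoint.
#'
#' @param curve A `denaturation_curve`.
#' @param model `"three_state"` or `"two_state"`.
#' @return A `three_state_params` or `two_state_params` starting value.
#' @export
initial_guess <- function(curve, model = c("three_state", "two_state")) {
  stopifnot(inherits(curve, "denaturation_curve"))
  model <- match.arg(model)
  x <- curve$concs
  y <- curve$signals
  n <- length(x)
  nb <- max(2L, ceiling(0.15 * n))
  b_n <- mean(y[seq_len(nb)])
  b_u <- mean(y[seq.int(n - nb + 1L, n)])
  span <- diff(range(y))
  # noise floor from second differences (trend-insensitive)
  noise <- if (n >= 4L) stats::sd(diff(y, differences = 2L)) / sqrt(6) else 0
  if (span <= 0 || span < 5 * noise) {
    stop("curve shows no resolvable transition (signal span within noise floor)",
         call. = FALSE)
  }
  # concentration where the normalized signal first crosses level q
  cross <- function(q) {
    y01 <- (y - b_n) / (b_u - b_n)
    above <- y01 >= q
    i <- which(above)[1]
    if (is.na(i)) return(stats::quantile(x, q, names = FALSE))
    if (i == 1L) return(x[1])
    x[i - 1L] + (q - y01[i - 1L]) / (y01[i] - y01[i - 1L]) * (x[i] - x[i - 1L])
  }
  if (model == "three_state") {
    cm1 <- cross(0.25)
    cm2 <- cross(0.75)
    if (cm2 <= cm1) cm2 <- cm1 + 0.5
    three_state_params(transition_thermo(6 * cm1, 6),
                       transition_thermo(4 * cm2, 4),
                       b_n, (b_n + b_u) / 2, b_u)
  } else {
    cm <- cross(0.5)
    two_state_params(transition_thermo(5 * cm, 5), b_n, b_u)
  }
}

.residual_fun <- function(curve, model, slopes) {
  force(curve); force(model); force(slopes)
  function(par) {
    p <- .par_to_params(par, model, slopes)
    curve$signals - predicted_signal(p, curve$concs)
  }
}

.par_bounds <- function(curve, model, slopes) {
  nm <- .par_names(model, slopes)
  span <- diff(range(curve$signals))
  lo_b <- min(curve$signals) - span
  hi_b <- max(curve$signals) + span
  lower <- stats::setNames(rep(-Inf, length(nm)), nm)
  upper <- stats::setNames(rep(Inf, length(nm)), nm)
  lower[grep("^m_", nm)] <- 1e-6
  lower[grep("^b_", nm)] <- lo_b
  upper[grep("^b_", nm)] <- hi_b
  list(lower = lower, upper = upper)
}

.run_lm <- function(curve, start_par, model, slopes, options) {
  b <- .par_bounds(curve, model, slopes)
  ctrl <- minpack.lm::nls.lm.control(maxiter = options$max_iterations,
                                     ftol = options$tolerance,
                                     ptol = options$tolerance)
  start_par <- pmin(pmax(start_par, b$lower), b$upper)
  minpack.lm::nls.lm(par = start_par, lower = b$lower, upper = b$upper,
                     fn = .residual_fun(curve, model, slopes),
                     control = ctrl)
}

#' Fit a two- or three-state unfolding model to a transition curve
#'
#' Minimizes the sum of squared deviations between the observed signal and
#' the population-weighted model signal over the free thermodynamic and
#' baseline parameters, using bounded Levenberg-Marquardt least squares
#' (m-values constrained positive, baselines constrained inside the signal
#' range extended by one span). When the single start from
#' [initial_guess()] fails to converge, five seeded jittered restarts are
#' tried and the best (lowest residual sum of squares, converged preferred)
#' is returned.
#'
#' Standard errors come from the Jacobian-based covariance scaled by
#' rss/(n - p); with `n_bootstrap > 0` they are replaced by the standard
#' deviation of seeded case-resampling bootstrap refits.
#'
#' @param curve A `denaturation_curve`.
#' @param options A [fit_options()] list.
#' @return An object of class `unfold_fit`: estimated parameter object
#'   (`$params`), named estimate vector (`$par`), `$stderr`, `$covariance`,
#'   `$rss`, `$n_points`, `$aic` (small-sample corrected AIC), `$converged`,
#'   `$residuals`, `$model`, `$message`.
#' @export
fit_curve <- function(curve, options = fit_options()) {
  stopifnot(inherits(curve, "denaturation_curve"),
            inherits(options, "fit_options"))
  model <- options$model
  slopes <- options$fit_baseline_slopes
  nm <- .par_names(model, slopes)
  n <- length(curve$concs)
  p <- length(nm)
  if (n <= p + 2L) {
    stop(sprintf("curve has %d points; need more than %d for a %s fit",
                 n, p + 2L, model), call. = FALSE)
  }
  start <- if (is.null(options$start)) initial_guess(curve, model) else
    options$start
  start_par <- .params_to_par(start, slopes)[nm]

  fit <- .run_lm(curve, start_par, model, slopes, options)
  converged <- fit$info %in% 1:3
  # multi-start fallback: 5 jittered restarts, deterministic given seed
  if (!converged) {
    best <- fit
    old <- .restorable_seed(options$seed)
    on.exit(.restore_seed(old), add = TRUE)
    for (j in 1:5) {
      jit <- start_par * stats::runif(p, 0.7, 1.3) +
        stats::rnorm(p, 0, 0.01)
      cand <- tryCatch(.run_lm(curve, jit, model, slopes, options),
                       error = function(e) NULL)
      if (is.null(cand)) next
      cand_conv <- cand$info %in% 1:3
      if ((cand_conv && !(best$info %in% 1:3)) ||
          (cand_conv == (best$info %in% 1:3) &&
           cand$deviance < best$deviance)) {
        best <- cand
      }
    }
    fit <- best
    converged <- fit$info %in% 1:3
  }

  est <- stats::setNames(fit$par, nm)
  rss <- fit$deviance
  dof <- n - p
  s2 <- rss / dof
  covariance <- tryCatch(solve(fit$hessian) * s2, error = function(e) {
    warning("rank-deficient Jacobian: some parameters are unidentifiable; ",
            "standard errors unavailable", call. = FALSE)
    matrix(NA_real_, p, p)
  })
  dimnames(covariance) <- list(nm, nm)
  stderr <- sqrt(pmax(diag(covariance), 0))

  if (options$n_bootstrap > 0L) {
    stderr <- .bootstrap_stderr(curve, est, model, slopes, options)
  }

  k <- p + 1  # +1 for the residual variance
  aicc <- n * log(rss / n) + 2 * k +
    if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf

  structure(list(params = .par_to_params(est, model, slopes),
                 par = est,
                 stderr = stderr,
                 covariance = covariance,
                 rss = rss,
                 n_points = n,
                 aic = aicc,
                 converged = converged,
                 residuals = as.numeric(fit$fvec),
                 model = model,
                 niter = fit$niter,
                 message = fit$message,
                 sample_id = curve$sample_id),
            class = "unfold_fit")
}

.bootstrap_stderr <- function(curve, est, model, slopes, options) {
  old <- .restorable_seed(options$seed)
  on.exit(.restore_seed(old), add = TRUE)
  n <- length(curve$concs)
  reps <- matrix(NA_real_, options$n_bootstrap, length(est))
  for (b in seq_len(options$n_bootstrap)) {
    idx <- sort(sample.int(n, n, replace = TRUE))
    idx <- idx[!duplicated(idx)]  # curve container requires unique concs
    if (length(idx) <= length(est) + 2L) next
    bcurve <- denaturation_curve(curve$concs[idx], curve$signals[idx],
                                 signal_kind = curve$signal_kind,
                                 sample_id = curve$sample_id)
    f <- tryCatch(.run_lm(bcurve, est, model, slopes, options),
                  error = function(e) NULL)
    if (!is.null(f) && f$info %in% 1:3) reps[b, ] <- f$par
  }
  stats::setNames(apply(reps, 2, stats::sd, na.rm = TRUE), names(est))
}

#' @export
print.unfold_fit <- function(x, ...) {
  cat(sprintf("%s fit of '%s' (%d points): %s, rss = %.4g, AICc = %.4g\n",
              x$model, x$sample_id, x$n_points,
              if (x$converged) "converged" else "NOT converged",
              x$rss, x$aic))
  est <- data.frame(estimate = x$par, stderr = x$stderr)
  print(round(est, 4))
  invisible(x)
}

#' Choose between the two-state and three-state model by AICc
#'
#' Both models are fitted and the one with the lower small-sample-corrected
#' AIC is selected. When the AICc difference is below 2 the selection is
#' flagged ambiguous and the two-state model is preferred on parsimony
#' grounds. If only one fit converges it is returned with a warning.
#'
#' @param curve A `denaturation_curve`.
#' @param options A [fit_options()] list; its `model` field is ignored.
#' @return A list with `$selection` (`"two_state"` or `"three_state"`),
#'   `$ambiguous` flag, `$delta_aic` (AICc(two) - AICc(three)), and both
#'   fits under `$two_state` and `$three_state`.
#' @export
select_model <- function(curve, options = fit_options()) {
  opts2 <- options; opts2$model <- "two_state"
  opts3 <- options; opts3$model <- "three_state"
  f2 <- tryCatch(fit_curve(curve, opts2), error = function(e) NULL)
  f3 <- tryCatch(fit_curve(curve, opts3), error = function(e) NULL)
  if (is.null(f2) && is.null(f3)) {
    stop("both model fits failed", call. = FALSE)
  }
  ok2 <- !is.null(f2) && f2$converged
  ok3 <- !is.null(f3) && f3$converged
  if (ok2 && !ok3) {
    warning("only the two-state fit converged", call. = FALSE)
    return(list(selection = "two_state", ambiguous = FALSE,
                delta_aic = NA_real_, two_state = f2, three_state = f3))
  }
  if (ok3 && !ok2) {
    warning("only the three-state fit converged", call. = FALSE)
    return(list(selection = "three_state", ambiguous = FALSE,
                delta_aic = NA_real_, two_state = f2, three_state = f3))
  }
  delta <- f2$aic - f3$aic  # positive favours three-state
  ambiguous <- abs(delta) < 2
  selection <- if (ambiguous) "two_state" else
    if (delta > 0) "three_state" else "two_state"
  list(selection = selection, ambiguous = ambiguous, delta_aic = delta,
       two_state = f2, three_state = f3)
}

# save/restore .Random.seed so seeded internals do not disturb the caller's
# RNG stream
.restorable_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
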