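#' Total unfolding free energy from a three-state fit
#'
#' dG_NU0 = dG_NI0 + dG_IU0, with error propagated as
#' sqrt(var_NI + var_IU + 2 cov) from the fit covariance.
#'
#' @param fit A converged three-state `unfold_fit`.
#' @return A list with `dg_nu` (kcal/mol) and `stderr`.
#' @export
total_dg <- function(fit) {
  stopifnot(inherits(fit, "unfold_fit"))
  if (fit$model != "three_state") {
    stop("total_dg requires a three-state fit", call. = FALSE)
  }
  if (!isTRUE(fit$converged)) {
    stop("total_dg requires a converged fit", call. = FALSE)
  }
  dg <- unname(fit$par["dg_ni"] + fit$par["dg_iu"])
  v <- fit$covariance["dg_ni", "dg_ni"] + fit$covariance["dg_iu", "dg_iu"] +
    2 * fit$covariance["dg_ni", "dg_iu"]
  list(dg_nu = dg, stderr = sqrt(max(v, 0)))
}

#' Per-variant stability record
#'
#' One row of a stability table: component and total unfolding free
#' energies, m-values, and the mutation-induced stability change relative
#' to a reference variant. Literature records (no component fit) carry only
#' `ddg_nu`.
#'
#' @param variant Variant label.
#' @param dg_ni,dg_iu,dg_nu Free energies, kcal/mol.
#' @param ddg_nu Stability change vs the reference, kcal/mol;
#'   positive = destabilizing.
#' @param m_ni,m_iu m-values, kcal mol^-1 M^-1.
#' @param se_dg_ni,se_dg_iu,se_dg_nu,se_m_ni,se_m_iu Standard errors.
#' @param source `"fitted"` or `"literature"`.
#' @return A list of class `stability_record`.
#' @export
stability_record <- function(variant, dg_ni = NA_real_, dg_iu = NA_real_,
                             dg_nu = NA_real_, ddg_nu = NA_real_,
                             m_ni = NA_real_, m_iu = NA_real_,
                             se_dg_ni = NA_real_, se_dg_iu = NA_real_,
                             se_dg_nu = NA_real_, se_m_ni = NA_real_,
                             se_m_iu = NA_real_,
                             source = c("fitted", "literature")) {
  source <- match.arg(source)
  if (source == "fitted" && is.finite(dg_ni) && is.finite(dg_iu) &&
      is.finite(dg_nu) && abs(dg_nu - (dg_ni + dg_iu)) > 1e-9) {
    stop("fitted record violates dg_nu = dg_ni + dg_iu", call. = FALSE)
  }
  structure(list(variant = as.character(variant), dg_ni = dg_ni,
                 dg_iu = dg_iu, dg_nu = dg_nu, ddg_nu = ddg_nu,
                 m_ni = m_ni, m_iu = m_iu, se_dg_ni = se_dg_ni,
                 se_dg_iu = se_dg_iu, se_dg_nu = se_dg_nu,
                 se_m_ni = se_m_ni, se_m_iu = se_m_iu, source = source),
            class = "stability_record")
}

#' Mutation-induced stability change
#'
#' ddG_NU = dG_NU(reference) - dG_NU(mutant); positive values indicate a
#' destabilizing mutation. This sign convention reproduces the convention
#' under which published destabilizing mutations carry positive ddG.
#'
#' @param reference,mutant `stability_record`s with `dg_nu` set, or bare
#'   numeric dG_NU values.
#' @return ddG_NU in kcal/mol.
#' @examples
#' ddg_nu(13.5, 12.5)  # 1.0
#' @export
ddg_nu <- function(reference, mutant) {
  dg <- function(x) {
    if (inherits(x, "stability_record")) x$dg_nu else as.numeric(x)
  }
  a <- dg(reference); b <- dg(mutant)
  stopifnot(is.finite(a), is.finite(b))
  a - b
}

#' Build a stability table from per-variant fits
#'
#' Assembles one `stability_record` per variant from converged three-state
#' fits, computing each variant's ddG_NU relative to the reference variant
#' (whose ddG_NU is 0). Literature records (e.g. a variant with a published
#' ddG but no component free energies) can be appended via `literature`.
#'
#' @param fits Named list of three-state `unfold_fit` objects
#'   (names = variant labels).
#' @param reference Label of the reference variant; must be present in
#'   `fits` and converged.
#' @param literature Optional named numeric vector of literature ddG_NU
#'   values (kcal/mol) to append as `source = "literature"` records.
#' @return A list of class `stability_table` of `stability_record`s, the
#'   reference first.
#' @export
build_stability_table <- function(fits, reference, literature = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  labels <- names(fits)
  if (is.null(labels) || any(labels == "")) {
    stop("fits must be a named list (variant labels)", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate variant labels: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  if (!reference %in% labels) {
    stop("reference variant '", reference, "' not among the fits",
         call. = FALSE)
  }
  if (!isTRUE(fits[[reference]]$converged)) {
    stop("reference fit did not converge", call. = FALSE)
  }
  ref_dg <- total_dg(fits[[reference]])
  rec_of <- function(label) {
    fit <- fits[[label]]
    tot <- total_dg(fit)
    stability_record(variant = label,
                     dg_ni = unname(fit$par["dg_ni"]),
                     dg_iu = unname(fit$par["dg_iu"]),
                     dg_nu = tot$dg_nu,
                     ddg_nu = ddg_nu(ref_dg$dg_nu, tot$dg_nu),
                     m_ni = unname(fit$par["m_ni"]),
                     m_iu = unname(fit$par["m_iu"]),
                     se_dg_ni = unname(fit$stderr["dg_ni"]),
                     se_dg_iu = unname(fit$stderr["dg_iu"]),
                     se_dg_nu = tot$stderr,
                     se_m_ni = unname(fit$stderr["m_ni"]),
                     se_m_iu = unname(fit$stderr["m_iu"]),
                     source = "fitted")
  }
  ordered <- c(reference, setdiff(labels, reference))
  records <- lapply(ordered, rec_of)
  if (!is.null(literature)) {
    stopifnot(is.numeric(literature), !is.null(names(literature)))
    if (any(names(literature) %in% labels)) {
      stop("literature variant duplicates a fitted variant", call. = FALSE)
    }
    lit <- lapply(names(literature), function(v) {
      stability_record(variant = v, ddg_nu = unname(literature[[v]]),
                       source = "literature")
    })
    records <- c(records, lit)
  }
  structure(records, class = "stability_table")
}

#' @export
as.data.frame.stability_table <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(variant = r$variant, dg_ni = r$dg_ni, se_dg_ni = r$se_dg_ni,
               dg_iu = r$dg_iu, se_dg_iu = r$se_dg_iu, dg_nu = r$dg_nu,
               ddg_nu = r$ddg_nu, m_ni = r$m_ni, se_m_ni = r$se_m_ni,
               m_iu = r$m_iu, se_m_iu = r$se_m_iu, source = r$source,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.stability_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flag significantly destabilizing mutations
#'
#' Returns the variants whose ddG_NU exceeds `threshold` (default
#' 2 kcal/mol, the conventional cutoff for a clearly destabilizing
#' mutation), sorted by decreasing ddG_NU.
#'
#' @param records A `stability_table` (or list of `stability_record`s).
#' @param threshold ddG_NU cutoff, kcal/mol.
#' @return Character vector of variant labels, most destabilizing first.
#' @export
classify_destabilizing <- function(records, threshold = 2.0) {
  stopifnot(is.list(records))
  ddg <- vapply(records, function(r) r$ddg_nu, numeric(1))
  lab <- vapply(records, function(r) r$variant, character(1))
  keep <- is.finite(ddg) & ddg > threshold
  lab[keep][order(ddg[keep], decreasing = TRUE)]
}

#' Compare experimental against predicted stability changes
#'
#' Matches experimental ddG_NU records with a predictor's per-variant ddG
#' values by variant label and reports the Pearson correlation, root mean
#' squared error, and the variant with the largest absolute deviation.
#' Variants present on only one side are reported as warnings. The
#' reference variant (ddG = 0 by construction) is excluded from matching
#' unless the predictor also lists it.
#'
#' @param experimental A `stability_table` or list of `stability_record`s.
#' @param predicted Named numeric vector or list: variant -> predicted ddG
#'   (kcal/mol).
#' @return A list of class `ddg_comparison`: `$pairs` (data.frame with
#'   variant, ddg_experimental, ddg_predicted, deviation), `$pearson_r`,
#'   `$rmse`, `$max_abs_deviation`, `$max_deviation_variant`, `$n`.
#' @export
compare_predictions <- function(experimental, predicted) {
  stopifnot(is.list(experimental))
  predicted <- unlist(predicted)
  stopifnot(is.numeric(predicted), !is.null(names(predicted)))
  exp_lab <- vapply(experimental, function(r) r$variant, character(1))
  exp_ddg <- vapply(experimental, function(r) r$ddg_nu, numeric(1))
  common <- intersect(exp_lab[is.finite(exp_ddg)], names(predicted))
  miss_exp <- setdiff(names(predicted), exp_lab)
  miss_pred <- setdiff(exp_lab[is.finite(exp_ddg) & exp_ddg != 0], common)
  if (length(miss_exp)) {
    warning("predicted variants without experimental ddG: ",
            paste(miss_exp, collapse = ", "), call. = FALSE)
  }
  if (length(miss_pred)) {
    warning("experimental variants without prediction: ",
            paste(miss_pred, collapse = ", "), call. = FALSE)
  }
  if (length(common) < 2L) {
    stop("need at least 2 variants in common (got ", length(common), ")",
         call. = FALSE)
  }
  e <- exp_ddg[match(common, exp_lab)]
  p <- unname(predicted[common])
  dev <- e - p
  i_max <- which.max(abs(dev))
  pairs <- data.frame(variant = common, ddg_experimental = e,
                      ddg_predicted = p, deviation = dev,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(pairs = pairs,
                 pearson_r = stats::cor(e, p),
                 rmse = sqrt(mean(dev^2)),
                 max_abs_deviation = abs(dev[i_max]),
                 max_deviation_variant = common[i_max],
                 n = length(common)),
            class = "ddg_comparison")
}

#' @export
print.ddg_comparison <- function(x, ...) {
  cat(sprintf("Experimental vs predicted ddG over %d variants: r = %.3f, RMSE = %.2f kcal/mol\n",
              x$n, x$pearson_r, x$rmse))
  cat(sprintf("Largest deviation: %s (|ddG_exp - ddG_pred| = %.2f kcal/mol)\n",
              x$max_deviation_variant, x$max_abs_deviation))
  print(within(x$pairs, {
    ddg_experimental <- round(ddg_experimental, 3)
    ddg_predicted <- round(ddg_predicted, 3)
    deviation <- round(deviation, 3)
  }), row.names = FALSE)
  invisible(x)
}
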