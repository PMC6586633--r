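# Calibration curves over dilution series and the <20 %
# back-calculated-deviation rule for the limit of quantification.

#' Fit a calibration curve
#'
#' Weighted least-squares regression of response (L/H area ratio, or raw
#' area) on nominal amount. Default weighting is 1/x, the targeted-MS
#' convention for series spanning a wide dynamic range.
#'
#' @param levels Tibble/data frame with columns `nominal` (amol) and
#'   `response`; one row per calibration level (replicate rows allowed).
#' @param weighting `"1/x"` (default), `"none"` or `"1/x^2"`.
#' @param peptide Optional peptide identifier carried in the result.
#' @return A `prm_calibration` object: the fitted `slope`, `intercept`,
#'   `r2`, `weighting`, the per-level table with back-calculated amounts and
#'   percent deviations, and `loq` (filled by [determine_loq()], which is
#'   called automatically).
#' @export
#' @examples
#' cal <- fit_calibration(data.frame(nominal = c(1, 2, 4, 8, 16),
#'                                   response = c(2, 4, 8, 16, 32)))
#' cal$slope
fit_calibration <- function(levels, weighting = c("1/x", "none", "1/x^2"),
                            peptide = NA_character_) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("nominal", "response") %in% names(levels)))
  levels <- tibble::as_tibble(levels) |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::arrange(.data$nominal)
  nz <- levels$nominal > 0
  if (length(unique(levels$nominal[nz])) < 3) {
    stop("at least 3 distinct nonzero calibration levels are required",
         call. = FALSE)
  }
  if (stats::var(levels$nominal) == 0) {
    stop("zero variance in nominal amounts: singular fit", call. = FALSE)
  }
  w <- switch(weighting,
              `none` = rep(1, nrow(levels)),
              `1/x` = 1 / pmax(levels$nominal, .Machine$double.eps),
              `1/x^2` = 1 / pmax(levels$nominal, .Machine$double.eps)^2)
  fit <- stats::lm(response ~ nominal, data = levels, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # summary.lm warns on an exactly collinear (perfect) fit; that case is
  # legitimate here (noiseless test data)
  r2 <- suppressWarnings(summary(fit)$r.squared)

  out <- structure(list(
    peptide = peptide,
    levels = levels, slope = slope, intercept = intercept,
    weighting = weighting, r2 = r2, fit = fit, loq = NA_real_
  ), class = "prm_calibration")
  out$levels$back_calc <- (out$levels$response - intercept) / slope
  out$levels$deviation_pct <- 100 * abs(out$levels$back_calc - out$levels$nominal) /
    out$levels$nominal
  out$loq <- determine_loq(out)
  out
}

#' @export
print.prm_calibration <- function(x, ...) {
  cat(sprintf("<prm_calibration>%s slope %.4g, intercept %.4g, R2 %.4f, weighting %s\n",
              if (is.na(x$peptide)) "" else paste0(" ", x$peptide),
              x$slope, x$intercept, x$r2, x$weighting))
  cat(sprintf("  LOQ: %s amol over %d levels\n",
              if (is.na(x$loq)) "not determined" else format(x$loq),
              length(unique(x$levels$nominal))))
  invisible(x)
}

#' Back-calculated accuracy deviation at a calibration level
#'
#' `100 * |x_hat - x_nominal| / x_nominal`, with
#' `x_hat = (response - intercept) / slope`.
#'
#' @param curve A `prm_calibration`.
#' @param nominal The nominal amount of the level (must be in the curve).
#' @return Percent deviation (mean over replicate rows of the level).
#' @export
back_calc_deviation <- function(curve, nominal) {
  stopifnot(inherits(curve, "prm_calibration"))
  if (curve$slope == 0) {
    stop("slope is zero: back-calculated deviation undefined", call. = FALSE)
  }
  rows <- which(curve$levels$nominal == nominal)
  if (!length(rows)) stop("level ", nominal, " not in curve", call. = FALSE)
  mean(curve$levels$deviation_pct[rows])
}

#' Limit of quantification by the back-calculated-deviation rule
#'
#' The LOQ is the lowest nominal level whose deviation is below `max_dev`
#' percent; with `contiguous = TRUE` (default) every level above it must
#' also pass, so a noisy mid-curve level caps the LOQ from below.
#'
#' @param curve A `prm_calibration`.
#' @param max_dev Deviation threshold, percent (default 20).
#' @param contiguous Require all higher levels to pass as well.
#' @return The LOQ in amol, or `NA` (not determined) if no level qualifies.
#' @export
determine_loq <- function(curve, max_dev = 20, contiguous = TRUE) {
  stopifnot(inherits(curve, "prm_calibration"))
  lv <- curve$levels |>
    dplyr::group_by(.data$nominal) |>
    dplyr::summarise(dev = mean(.data$deviation_pct), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$nominal))
  pass <- !is.na(lv$dev) & lv$dev < max_dev
  if (!any(pass)) return(NA_real_)
  if (contiguous) {
    run <- cumprod(pass)  # 1 while every level from the top passes
    if (!run[1]) return(NA_real_)
    min(lv$nominal[run == 1])
  } else {
    min(lv$nominal[pass])
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy prm_calibration
tidy.prm_calibration <- function(x, ...) {
  x$levels |>
    dplyr::mutate(peptide = x$peptide, .before = 1)
}

#' @export
#' @method glance prm_calibration
glance.prm_calibration <- function(x, ...) {
  tibble::tibble(peptide = x$peptide, slope = x$slope,
                 intercept = x$intercept, r2 = x$r2,
                 weighting = x$weighting, loq = x$loq,
                 n_levels = length(unique(x$levels$nominal)))
}

#' Calibration curve from a simulated dilution series
#'
#' Runs the signal pipeline on every level of a [simulate_dilution_series()]
#' result and fits the curve on L/H area ratios. Levels whose pair fails QC
#' contribute no response (their row is kept with `NA`, so they can never be
#' the LOQ).
#'
#' @param series Output of [simulate_dilution_series()].
#' @param panel The panel (or the pair rows used for the series).
#' @param tol XIC tolerance, ppm.
#' @param thresholds Acceptance thresholds.
#' @param require_accept Drop responses from levels failing pair QC
#'   (default TRUE).
#' @inheritParams fit_calibration
#' @return A `prm_calibration`.
#' @export
calibrate_series <- function(series, panel, weighting = "1/x", tol = 10,
                             thresholds = acceptance_thresholds(),
                             require_accept = TRUE) {
  resp <- purrr::map_dbl(series$acquisition, function(acq) {
    ev <- evaluate_acquisition(acq, panel, tol, thresholds)
    if (!nrow(ev)) return(NA_real_)
    if (require_accept && !ev$accepted[1]) return(NA_real_)
    ev$lh_ratio[1]
  })
  levels <- tibble::tibble(nominal = series$nominal_amol, response = resp)
  if (sum(!is.na(resp) & levels$nominal > 0) < 3) {
    # too few QC-passing levels to regress: curve and LOQ undetermined
    levels$back_calc <- NA_real_
    levels$deviation_pct <- NA_real_
    return(structure(list(
      peptide = panel$peptide[1], levels = levels, slope = NA_real_,
      intercept = NA_real_, weighting = weighting, r2 = NA_real_,
      fit = NULL, loq = NA_real_
    ), class = "prm_calibration"))
  }
  cal <- fit_calibration(levels, weighting = weighting,
                         peptide = panel$peptide[1])
  # reattach levels dropped for failing QC: they count as failing the
  # deviation rule, so an undetected mid-level caps the LOQ
  missing <- setdiff(levels$nominal, cal$levels$nominal)
  if (length(missing)) {
    cal$levels <- dplyr::bind_rows(
      cal$levels,
      tibble::tibble(nominal = missing, response = NA_real_,
                     back_calc = NA_real_, deviation_pct = NA_real_)
    ) |> dplyr::arrange(.data$nominal)
    cal$loq <- determine_loq(cal)
  }
  cal
}
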