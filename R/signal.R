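# Chromatogram extraction, peak integration and the acceptance criteria
# applied to every light/heavy pair: mass deviation < 5 ppm, >= 2 detected
# transitions, Gaussian peak shape, co-elution of light and heavy, matching
# transition ratios, and library dot product.

#' Extract an ion chromatogram at ppm tolerance
#'
#' For every scheduled scan of the precursor, sums all centroids within
#' `tol` ppm of the theoretical fragment m/z; the reported m/z per point is
#' the intensity-weighted mean of the matched centroids (0 where none
#' matched).
#'
#' @param acquisition A `prm_acquisition` (or anything with `scans` and
#'   `scan_times` in the same shape).
#' @param peptide,label Precursor identity.
#' @param fragment Fragment identifier (used to name the trace).
#' @param theoretical_mz Target fragment m/z.
#' @param tol Extraction tolerance, ppm (default 10).
#' @return A tibble trace: `peptide`, `label`, `fragment`, `rt`,
#'   `intensity`, `measured_mz`, `theoretical_mz`.
#' @export
extract_xic <- function(acquisition, peptide, label, fragment,
                        theoretical_mz, tol = 10) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  st <- acquisition$scan_times
  rts <- sort(st$rt[st$peptide == peptide & st$label == label])
  if (!length(rts)) {
    stop("unknown precursor: ", peptide, " (", label, ")", call. = FALSE)
  }
  sc <- acquisition$scans
  cand <- sc[sc$peptide == peptide & sc$label == label &
               abs(sc$measured_mz - theoretical_mz) / theoretical_mz * 1e6 <= tol, ]
  inten <- numeric(length(rts))
  mzs <- numeric(length(rts))
  if (nrow(cand)) {
    grp <- match(cand$rt, rts)
    ok <- !is.na(grp)
    inten <- as.numeric(rowsum_fill(cand$intensity[ok], grp[ok], length(rts)))
    wsum <- as.numeric(rowsum_fill(cand$intensity[ok] * cand$measured_mz[ok],
                                   grp[ok], length(rts)))
    mzs <- ifelse(inten > 0, wsum / inten, 0)
  }
  tibble::tibble(peptide = peptide, label = label, fragment = fragment,
                 rt = rts, intensity = inten, measured_mz = mzs,
                 theoretical_mz = theoretical_mz)
}

rowsum_fill <- function(x, group, n) {
  out <- numeric(n)
  if (length(x)) {
    agg <- rowsum(x, group)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Extract all transitions of one precursor
#'
#' @inheritParams extract_xic
#' @param panel The `prm_panel` holding the fragment definitions.
#' @return Traces for every monitored fragment, row-bound.
#' @export
extract_precursor_xics <- function(acquisition, panel, peptide, label,
                                   tol = 10) {
  row <- panel[panel$peptide == peptide & panel$label == label, ]
  if (nrow(row) != 1) stop("precursor not in panel", call. = FALSE)
  fr <- row$fragments[[1]]
  purrr::map2_dfr(fr$fragment, fr$mz,
                  ~ extract_xic(acquisition, peptide, label, .x, .y, tol))
}

#' Normalized spectral dot product
#'
#' Similarity between a measured and a library fragment-intensity vector:
#' `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`. Ranges from 0.00 (no similarity)
#' to 1.00 (identical pattern).
#'
#' @param measured,library Nonnegative intensity vectors of equal length
#'   (>= 2).
#' @return The dot product, in `[0, 1]`.
#' @export
#' @examples
#' dot_product(c(3, 4), c(4, 3))  # 0.96
dot_product <- function(measured, library) {
  if (length(measured) != length(library) || length(measured) < 2) {
    stop("vectors must have equal length >= 2", call. = FALSE)
  }
  if (any(measured < 0) || any(library < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  na <- sum(measured^2); nb <- sum(library^2)
  if (na == 0 || nb == 0) {
    stop("dot product undefined for a zero vector", call. = FALSE)
  }
  min(1, sum(measured * library) / sqrt(na * nb))
}

#' Detect and integrate a peak over a set of transition traces
#'
#' The apex is the maximum of the 5-point moving-average of the summed trace
#' within `expected_rt +/- window/2`; boundaries extend from the apex to the
#' nearer of a local minimum or the 1 %-of-apex height crossing. Areas are
#' trapezoidal per fragment over the common boundaries. A fragment counts as
#' detected when its in-boundary signal rises at least 3-fold above its
#' off-peak baseline.
#'
#' @param traces Row-bound traces from [extract_xic()] for the fragments of
#'   one precursor.
#' @param expected_rt Expected apex retention time, min.
#' @param window Search window length, min.
#' @return A `prm_peak` list: `apex_rt`, `boundaries`, `per_fragment`
#'   (tibble of `fragment`, `area`, `mean_abs_ppm`, `snr`, `detected`),
#'   `n_detected`, `shape_r2`, `detected` (any fragment detected).
#' @export
detect_and_integrate <- function(traces, expected_rt, window = 2) {
  if (is.null(traces) || !nrow(traces)) {
    stop("at least one trace is required", call. = FALSE)
  }
  if (window <= 0) stop("window must be > 0", call. = FALSE)

  wide <- traces |>
    dplyr::select("fragment", "rt", "intensity") |>
    tidyr::pivot_wider(names_from = "fragment", values_from = "intensity",
                       values_fill = 0) |>
    dplyr::arrange(.data$rt)
  rts <- wide$rt
  mat <- as.matrix(wide[, -1, drop = FALSE])
  total <- rowSums(mat)

  if (all(total == 0)) {
    fr_names <- unique(traces$fragment)
    return(empty_peak(fr_names, expected_rt))
  }

  sm <- moving_average(total, 5L)
  in_win <- which(abs(rts - expected_rt) <= window / 2)
  if (!length(in_win)) in_win <- seq_along(rts)
  apex <- in_win[which.max(sm[in_win])]

  lo <- walk_boundary(sm, apex, -1L)
  hi <- walk_boundary(sm, apex, +1L)
  idx <- lo:hi

  per_frag <- purrr::map_dfr(colnames(mat), function(f) {
    y <- mat[, f]
    area <- trapz(rts[idx], y[idx])
    tr <- traces[traces$fragment == f, ]
    tr <- tr[order(tr$rt), ]
    inb <- tr$rt >= rts[lo] & tr$rt <= rts[hi] & tr$measured_mz > 0 &
      tr$intensity > 0
    ppm <- abs(tr$measured_mz[inb] - tr$theoretical_mz[inb]) /
      tr$theoretical_mz[inb] * 1e6
    w <- tr$intensity[inb]
    mean_ppm <- if (length(ppm)) sum(ppm * w) / sum(w) else NA_real_
    out_idx <- setdiff(seq_along(y), idx)
    baseline <- if (length(out_idx)) stats::median(y[out_idx]) else 0
    snr <- max(y[idx]) / max(baseline, 1)
    tibble::tibble(fragment = f, area = area, mean_abs_ppm = mean_ppm,
                   snr = snr,
                   detected = area > 0 & snr >= 3 & sum(y[idx] > 0) >= 3)
  })

  structure(list(
    apex_rt = rts[apex], boundaries = c(rts[lo], rts[hi]),
    per_fragment = per_frag, n_detected = sum(per_frag$detected),
    shape_r2 = gaussian_shape_score(rts[idx], total[idx]),
    detected = any(per_frag$detected)
  ), class = "prm_peak")
}

empty_peak <- function(fragments, expected_rt) {
  structure(list(
    apex_rt = NA_real_, boundaries = c(NA_real_, NA_real_),
    per_fragment = tibble::tibble(fragment = fragments, area = 0,
                                  mean_abs_ppm = NA_real_, snr = 0,
                                  detected = FALSE),
    n_detected = 0L, shape_r2 = 0, detected = FALSE
  ), class = "prm_peak")
}

#' @export
print.prm_peak <- function(x, ...) {
  cat(sprintf("<prm_peak> apex %.2f min [%.2f, %.2f], %d/%d transitions, shape R2 %.3f\n",
              x$apex_rt, x$boundaries[1], x$boundaries[2], x$n_detected,
              nrow(x$per_fragment), x$shape_r2))
  invisible(x)
}

moving_average <- function(x, k = 5L) {
  if (length(x) < k) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2) |>
               (\(v) { v[is.na(v)] <- x[is.na(v)]; v })())
}

# from the apex, step outward to the nearer of a local minimum or the
# 1%-of-apex height crossing
walk_boundary <- function(y, apex, dir) {
  thresh <- 0.01 * y[apex]
  i <- apex
  repeat {
    nxt <- i + dir
    if (nxt < 1 || nxt > length(y)) return(i)
    if (y[nxt] <= thresh) return(nxt)
    if (y[nxt] > y[i]) return(i)  # local minimum at i
    i <- nxt
  }
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Gaussian peak-shape score
#'
#' Coefficient of determination of a least-squares Gaussian fit to the
#' in-boundary points of a (summed) trace, clipped to `[0, 1]`. Fitted by
#' intensity-weighted quadratic regression on the log scale (Guo's method),
#' which is deterministic and needs no starting values. Traces with no
#' downward curvature (flat or anti-Gaussian) score 0.
#'
#' @param rt Retention times inside the peak boundaries (>= 5 points).
#' @param intensity Corresponding summed intensities.
#' @return Shape score in `[0, 1]`, or `NA` (not evaluable) for < 5 points.
#' @export
gaussian_shape_score <- function(rt, intensity) {
  stopifnot(length(rt) == length(intensity))
  pos <- intensity > 0
  if (sum(pos) < 5) return(NA_real_)
  x <- rt[pos]; y <- intensity[pos]
  w <- y^2
  X <- cbind(1, x, x^2)
  fit <- tryCatch(stats::lm.wfit(X, log(y), w), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(0)
  a2 <- fit$coefficients[3]
  if (!is.finite(a2) || a2 >= 0) return(0)
  yhat <- exp(X %*% fit$coefficients)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(0)
  max(0, min(1, 1 - ss_res / ss_tot))
}

#' Default acceptance thresholds
#'
#' @param max_ppm Mass-deviation cutoff, ppm (default 5).
#' @param min_transitions Minimum detected transitions per precursor.
#' @param min_shape_r2 Gaussian shape score cutoff.
#' @param max_rt_delta Light/heavy apex RT difference cutoff, min.
#' @param min_ratio_dotp Light-vs-heavy transition-ratio dot product cutoff.
#' @param min_library_dotp Library dot product cutoff.
#' @return Named list of thresholds.
#' @export
acceptance_thresholds <- function(max_ppm = 5, min_transitions = 2L,
                                  min_shape_r2 = 0.8, max_rt_delta = 0.05,
                                  min_ratio_dotp = 0.85,
                                  min_library_dotp = 0.85) {
  as.list(environment())
}

#' Evaluate a light/heavy peptide pair against the acceptance criteria
#'
#' A pair is accepted only if, for both light and heavy forms, the
#' intensity-weighted mean absolute mass deviation is below `max_ppm`, at
#' least `min_transitions` transitions are detected and the summed peak has
#' Gaussian shape; and, across the pair, the apexes co-elute within
#' `max_rt_delta` (or one duty cycle, whichever is larger), the light and
#' heavy transition-area patterns agree (ratio dot product) and the light
#' pattern matches the library spectrum.
#'
#' @param light,heavy `prm_peak` objects from [detect_and_integrate()] for
#'   the two labels of one peptide, computed from the same acquisition.
#' @param library Library relative intensities, in the order of the panel's
#'   fragment list.
#' @param thresholds See [acceptance_thresholds()].
#' @param cycle_time_min Optional acquisition duty cycle (min); widens the
#'   co-elution tolerance to one cycle when larger than `max_rt_delta`.
#' @return One-row tibble: apex/boundary/QC fields, `accepted` and a
#'   `rejection_reasons` list-column (character vector, empty if accepted).
#'   `mean_abs_ppm_*` covers the identified (filter-passing) transitions;
#'   `raw_abs_ppm_*` covers all signal-bearing transitions before the ppm
#'   filter.
#' @export
evaluate_pair <- function(light, heavy, library,
                          thresholds = acceptance_thresholds(),
                          cycle_time_min = NULL) {
  stopifnot(inherits(light, "prm_peak"), inherits(heavy, "prm_peak"))
  th <- thresholds
  reasons <- character(0)

  # a transition is identified only when it carries signal AND its mass
  # deviation passes the ppm filter
  qualifying <- function(pk) {
    d <- pk$per_fragment
    d$detected & !is.na(d$mean_abs_ppm) & d$mean_abs_ppm < th$max_ppm
  }
  mass_ppm <- function(pk, idx) {
    v <- pk$per_fragment$mean_abs_ppm[idx]
    if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  lq <- qualifying(light); hq <- qualifying(heavy)
  # mean deviation over signal-bearing transitions drives the mass-error
  # verdict; the reported means cover the identified (qualifying) ones
  lraw <- mass_ppm(light, light$per_fragment$detected)
  hraw <- mass_ppm(heavy, heavy$per_fragment$detected)
  lppm <- mass_ppm(light, lq)
  hppm <- mass_ppm(heavy, hq)
  if (is.na(lraw) || is.na(hraw) || lraw >= th$max_ppm || hraw >= th$max_ppm) {
    reasons <- c(reasons, "mass-error")
  }
  n_det_light <- sum(lq)
  n_det_heavy <- sum(hq)
  if (n_det_light < th$min_transitions || n_det_heavy < th$min_transitions) {
    reasons <- c(reasons, "min-transitions")
  }
  shape_ok <- function(pk) !is.na(pk$shape_r2) && pk$shape_r2 >= th$min_shape_r2
  if (!shape_ok(light) || !shape_ok(heavy)) reasons <- c(reasons, "shape")

  rt_tol <- max(th$max_rt_delta, cycle_time_min %||% 0)
  rt_delta <- abs(light$apex_rt - heavy$apex_rt)
  if (is.na(rt_delta) || rt_delta > rt_tol) {
    reasons <- c(reasons, "rt-coelution")
  }

  la <- light$per_fragment$area
  ha <- heavy$per_fragment$area
  ratio_dotp <- if (sum(la^2) > 0 && sum(ha^2) > 0) dot_product(la, ha) else 0
  if (ratio_dotp < th$min_ratio_dotp) reasons <- c(reasons, "ratio-dotp")

  lib_dotp <- if (sum(la^2) > 0 && sum(library^2) > 0) {
    dot_product(la, library)
  } else 0
  if (lib_dotp < th$min_library_dotp) reasons <- c(reasons, "library-dotp")

  tibble::tibble(
    apex_rt_light = light$apex_rt, apex_rt_heavy = heavy$apex_rt,
    rt_delta = rt_delta,
    mean_abs_ppm_light = lppm, mean_abs_ppm_heavy = hppm,
    raw_abs_ppm_light = lraw, raw_abs_ppm_heavy = hraw,
    n_detected_light = n_det_light, n_detected_heavy = n_det_heavy,
    shape_r2_light = light$shape_r2, shape_r2_heavy = heavy$shape_r2,
    ratio_dotp = ratio_dotp, library_dotp = lib_dotp,
    accepted = length(reasons) == 0L,
    rejection_reasons = list(reasons)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
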