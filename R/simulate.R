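# Seeded orbitrap-PRM acquisition simulator.
#
# Each scheduled precursor is scanned once per duty cycle inside its
# retention-time window. Per scan, the accumulated ion count is
# min(agc_target, rate * injection_time) with rate following a Gaussian
# elution profile; fragment counts are multinomial over the library pattern
# (shot noise), a constant-rate chemical baseline is added per transition,
# co-isolated interferents contribute extra counts when their precursor
# offset falls inside the isolation window, and centroid m/z values are
# drawn with the resolution- and count-dependent mass-error sigma.

# Chromatographic peak shape: Gaussian, FWHM 0.25 min.
.PEAK_FWHM_MIN <- 0.25
.PEAK_SIGMA_MIN <- .PEAK_FWHM_MIN / (2 * sqrt(2 * log(2)))
# chemical baseline, ions/ms per transition
.BASELINE_RATE <- 0.05

#' Ground truth for a simulated acquisition
#'
#' @param panel A `prm_panel`.
#' @param amounts Optional tibble `peptide`, `label`, `amol` of on-column
#'   amounts. By default light amounts are the panel's reference endogenous
#'   amounts and heavy amounts the internal-standard spikes.
#' @param interferents Optional tibble of co-isolation interferents with
#'   columns `peptide`, `label` (the targeted precursor they shadow),
#'   `mz_offset` (m/z distance of the interfering precursor from the
#'   target's), `rt` (min), `intensity` (ions/ms at apex), `peak_sigma`
#'   (min) and `fragment_mzs` (list-column of fragment m/z values).
#' @param seed Integer seed; recorded so any run is reproducible.
#' @return A `prm_truth` list.
#' @export
simulation_truth <- function(panel, amounts = NULL, interferents = NULL,
                             seed = 1L) {
  if (is.null(amounts)) {
    amounts <- tibble::tibble(
      peptide = panel$peptide, label = panel$label,
      amol = ifelse(panel$label == "light", panel$endog_amol, panel$is_amount)
    )
  }
  stopifnot(all(c("peptide", "label", "amol") %in% names(amounts)))
  if (any(amounts$amol < 0)) stop("amounts must be >= 0", call. = FALSE)
  structure(list(amounts = tibble::as_tibble(amounts),
                 interferents = interferents, seed = as.integer(seed)),
            class = "prm_truth")
}

#' Default co-isolation interferent set
#'
#' One broad interfering species per light precursor, offset from the target
#' precursor m/z so that it is co-isolated at wide isolation windows but
#' excluded at narrow ones. Its fragments are isobaric with the target's
#' (offset by a few ppm), emulating chemical noise in the extracted traces.
#'
#' @param panel A `prm_panel`.
#' @param mz_offset Precursor offset from the target, m/z (default 0.6: in
#'   window at width 1.6, out of window at 0.4).
#' @param intensity Apex ion rate, ions/ms.
#' @param fragment_ppm_shift Offset of interferent fragments from the
#'   target's fragment m/z, ppm.
#' @return Interferent tibble suitable for [simulation_truth()].
#' @export
default_interferents <- function(panel, mz_offset = 0.6, intensity = 2,
                                 fragment_ppm_shift = 4) {
  light <- dplyr::filter(panel, .data$label == "light")
  tibble::tibble(
    peptide = light$peptide, label = "light", mz_offset = mz_offset,
    rt = light$rt_true, intensity = intensity, peak_sigma = 2,
    fragment_mzs = purrr::map(light$fragments,
                              ~ .x$mz * (1 + fragment_ppm_shift * 1e-6))
  )
}

#' Simulate a scheduled PRM acquisition
#'
#' @param panel A `prm_panel` (or subset of its rows).
#' @param settings An [acquisition_settings()] object.
#' @param truth A [simulation_truth()] object; every panel precursor must
#'   have an amount entry.
#' @return A `prm_acquisition`: list with `scans` (tibble `rt`, `peptide`,
#'   `label`, `fragment`, `true_mz`, `measured_mz`, `intensity`),
#'   `scan_times` (tibble of every scheduled scan per precursor, present
#'   even where no centroid survived), `settings` and `truth`.
#' @export
#' @examples
#' panel <- build_upr_panel(1)[1:4, ]
#' acq <- simulate_acquisition(panel, acquisition_settings(),
#'                             simulation_truth(panel, seed = 7))
simulate_acquisition <- function(panel, settings = acquisition_settings(),
                                 truth = simulation_truth(panel)) {
  stopifnot(inherits(settings, "prm_settings"), inherits(truth, "prm_truth"))
  if (!nrow(panel)) stop("panel must be nonempty", call. = FALSE)
  key <- paste(panel$peptide, panel$label)
  tkey <- paste(truth$amounts$peptide, truth$amounts$label)
  if (!all(key %in% tkey)) {
    stop("truth is missing amounts for: ",
         paste(setdiff(key, tkey), collapse = ", "), call. = FALSE)
  }
  amol <- truth$amounts$amol[match(key, tkey)]

  local_rng(truth$seed, "acquisition")

  scan_times <- schedule_scan_times(panel, settings)
  per_prec <- split(scan_times$rt, scan_times$idx)

  rows <- purrr::map(seq_len(nrow(panel)), function(i) {
    rts <- per_prec[[as.character(i)]]
    if (is.null(rts)) return(NULL)
    sim_precursor_scans(panel[i, ], amol[i], sort(rts), settings,
                        truth$interferents)
  })
  scans <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$rt, .data$peptide,
                                                    .data$label, .data$fragment)
  structure(list(
    scans = scans,
    scan_times = tibble::tibble(peptide = panel$peptide[scan_times$idx],
                                label = panel$label[scan_times$idx],
                                rt = scan_times$rt),
    settings = settings, truth = truth
  ), class = "prm_acquisition")
}

#' @export
print.prm_acquisition <- function(x, ...) {
  cat(sprintf("<prm_acquisition> %d precursors, %d scans, %d centroids\n",
              nrow(dplyr::distinct(x$scan_times, .data$peptide, .data$label)),
              nrow(dplyr::distinct(x$scan_times, .data$rt)), nrow(x$scans)))
  print(x$settings)
  invisible(x)
}

# Scheduled scan times: sweep the RT axis over window breakpoints; inside
# each segment the duty cycle is (number of active precursors) * per-scan
# time, and every active precursor is scanned once per cycle, so the
# inter-scan spacing of each precursor equals the implied cycle time.
schedule_scan_times <- function(panel, settings) {
  half <- settings$rt_window / 2
  lo <- panel$rt_true - half
  hi <- panel$rt_true + half
  per_scan_ms <- max(settings$injection_time, transient_time(settings$resolution)) +
    settings$scan_overhead
  brk <- sort(unique(c(lo, hi)))
  out_idx <- integer(0); out_rt <- numeric(0)
  for (s in seq_len(length(brk) - 1L)) {
    a <- brk[s]; b <- brk[s + 1L]
    active <- which(lo <= a & hi >= b)
    if (!length(active)) next
    cycle_min <- length(active) * per_scan_ms / 60000
    times <- seq(a, b - 1e-9, by = cycle_min)
    out_idx <- c(out_idx, rep(active, each = length(times)))
    out_rt <- c(out_rt, rep(times, times = length(active)))
  }
  list(idx = out_idx, rt = out_rt)
}

# Fragment ion counts for one precursor over its scheduled scans.
sim_precursor_scans <- function(row, amol, rts, settings, interferents) {
  fr <- row$fragments[[1]]
  nf <- nrow(fr); ns <- length(rts)
  if (!ns) return(NULL)

  gauss <- exp(-(rts - row$rt_true)^2 / (2 * .PEAK_SIGMA_MIN^2))
  rate <- amol * row$response_factor * gauss            # ions/ms
  expected <- pmin(settings$agc_target, rate * settings$injection_time)
  total <- stats::rpois(ns, expected)
  total <- pmin(total, settings$agc_target)

  # shot-noise split of the accumulated ions over the fragment pattern
  sig <- matrix(0L, nrow = nf, ncol = ns)
  pos <- which(total > 0)
  if (length(pos)) {
    sig[, pos] <- draw_fragment_counts(total[pos], fr$rel_intensity)
  }

  # chemical baseline per transition
  base <- matrix(stats::rpois(nf * ns, .BASELINE_RATE * settings$injection_time),
                 nrow = nf)

  # co-isolated interference: counts land on (near-)isobaric fragment mz
  intf_counts <- matrix(0, nrow = nf, ncol = ns)
  intf_mz <- fr$mz
  if (!is.null(interferents)) {
    sel <- interferents$peptide == row$peptide &
      interferents$label == row$label &
      abs(interferents$mz_offset) <= settings$isolation_width / 2
    for (j in which(sel)) {
      g <- exp(-(rts - interferents$rt[j])^2 /
                 (2 * interferents$peak_sigma[j]^2))
      per_frag_rate <- interferents$intensity[j] * g / nf
      fmz <- interferents$fragment_mzs[[j]]
      for (k in seq_len(min(nf, length(fmz)))) {
        add <- stats::rpois(ns, per_frag_rate * settings$injection_time)
        intf_counts[k, ] <- intf_counts[k, ] + add
      }
    }
  }

  inten <- sig + base + intf_counts
  keep <- inten > 0
  if (!any(keep)) return(NULL)

  # effective centroid position: count-weighted mix of target and
  # interferent species (they are unresolved within a few ppm), then a
  # mass-error draw at the combined ion count
  frac_intf <- ifelse(inten > 0, intf_counts / inten, 0)
  true_mz <- matrix(fr$mz, nf, ns) * (1 - frac_intf) +
    outer(intf_mz, rep(1, ns)) * frac_intf
  sigma_ppm <- mass_error_sigma(settings$resolution,
                                matrix(fr$mz, nf, ns)[keep], inten[keep])
  measured <- true_mz[keep] * (1 + stats::rnorm(sum(keep), 0, sigma_ppm) * 1e-6)

  idx <- which(keep, arr.ind = TRUE)
  tibble::tibble(
    rt = rts[idx[, 2]], peptide = row$peptide, label = row$label,
    fragment = fr$fragment[idx[, 1]],
    true_mz = fr$mz[idx[, 1]], measured_mz = measured,
    intensity = as.numeric(inten[keep])
  )
}

#' Multinomial split of accumulated ions over a fragment pattern
#'
#' Exposed for property testing: for every scan the per-fragment counts sum
#' exactly to the drawn total.
#'
#' @param totals Integer vector of per-scan total ion counts.
#' @param rel Relative fragment intensities (summing to 1).
#' @return Integer matrix, `length(rel)` rows by `length(totals)` columns.
#' @keywords internal
#' @export
draw_fragment_counts <- function(totals, rel) {
  vapply(totals, function(n) stats::rmultinom(1, n, rel)[, 1],
         integer(length(rel)))
}

#' Simulate a dilution series for one peptide pair
#'
#' Emulates the calibration experiment: the light analyte is serially
#' diluted by `factor` over `steps` steps while the heavy internal standard
#' is spiked at a constant amount; level `k` has nominal amount
#' `start_conc / factor^k` (k = 0..steps, so `steps + 1` levels).
#'
#' @param pair The two panel rows (light + heavy) of one peptide.
#' @param start_conc Starting amount, amol on column (1 ul injected of an
#'   amol/ul series).
#' @param factor Dilution factor per step (> 1).
#' @param steps Number of dilution steps (>= 1).
#' @param settings Acquisition settings.
#' @param seed Integer seed.
#' @param cv Multiplicative preparation noise on the light amount per level
#'   (lognormal, coefficient of variation; default 0.10).
#' @return Tibble with `level` (0-based), `nominal_amol` and an
#'   `acquisition` list-column of `prm_acquisition` objects.
#' @export
simulate_dilution_series <- function(pair, start_conc, factor = 2, steps = 7,
                                     settings = acquisition_settings(),
                                     seed = 1L, cv = 0.10) {
  if (factor <= 1) stop("dilution factor must be > 1", call. = FALSE)
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  if (start_conc <= 0) stop("start_conc must be > 0", call. = FALSE)
  stopifnot(nrow(pair) == 2, all(c("light", "heavy") %in% pair$label))

  nominal <- start_conc / factor^(0:steps)
  local_rng(seed, "dilution")
  jitter <- exp(stats::rnorm(length(nominal), -cv^2 / 2, cv))
  sub_seeds <- sample.int(1000000L, length(nominal))

  acq <- purrr::map(seq_along(nominal), function(k) {
    amounts <- tibble::tibble(
      peptide = pair$peptide,
      label = pair$label,
      amol = ifelse(pair$label == "light", nominal[k] * jitter[k],
                    pair$is_amount)
    )
    simulate_acquisition(pair, settings,
                         simulation_truth(pair, amounts, seed = sub_seeds[k]))
  })
  tibble::tibble(level = 0:steps, nominal_amol = nominal, acquisition = acq)
}

#' Simulate a treated-vs-control condition experiment
#'
#' Light (endogenous) amounts are scaled per protein by its fold change;
#' heavy standards stay constant. Per-replicate multiplicative lognormal
#' noise with the given CV is applied and recorded in each acquisition's
#' truth.
#'
#' @param panel A `prm_panel`.
#' @param fold_changes Named numeric vector, protein -> fold change. Every
#'   name must be a panel protein.
#' @param replicates Number of replicates (>= 1).
#' @param settings Acquisition settings.
#' @param seed Integer seed.
#' @param cv Replicate coefficient of variation (default 0.10).
#' @return Tibble with `replicate` and `acquisition` list-column.
#' @export
simulate_condition_experiment <- function(panel, fold_changes, replicates = 3,
                                          settings = acquisition_settings(),
                                          seed = 1L, cv = 0.10) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  unknown <- setdiff(names(fold_changes), unique(panel$protein))
  if (length(unknown)) {
    stop("unknown protein(s) in fold_changes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  fc <- rep(1, nrow(panel))
  hit <- panel$protein %in% names(fold_changes)
  fc[hit] <- fold_changes[panel$protein[hit]]

  local_rng(seed, "condition")
  sub_seeds <- sample.int(1000000L, replicates)
  noise <- matrix(exp(stats::rnorm(replicates * nrow(panel), -cv^2 / 2, cv)),
                  nrow = replicates)
  if (cv == 0) noise[] <- 1

  acq <- purrr::map(seq_len(replicates), function(r) {
    amounts <- tibble::tibble(
      peptide = panel$peptide, label = panel$label,
      amol = ifelse(panel$label == "light",
                    panel$endog_amol * fc * noise[r, ], panel$is_amount)
    )
    simulate_acquisition(panel, settings,
                         simulation_truth(panel, amounts, seed = sub_seeds[r]))
  })
  tibble::tibble(replicate = seq_len(replicates), acquisition = acq)
}
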