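# Instrument-parameter sweeps: the simulate -> extract -> evaluate loop run
# over a grid of acquisition settings, summarised per grid point.

#' Sweep acquisition settings over a grid
#'
#' For every grid row, simulates an acquisition of the panel, runs
#' extraction and pair evaluation, and summarises mass accuracy, library
#' dot product and signal-to-noise. Optionally determines a
#' dilution-series LOQ per grid point for a chosen peptide.
#'
#' @param panel A `prm_panel` (or subset of pairs).
#' @param truth A [simulation_truth()]; its seed anchors the sweep.
#' @param grid Tibble/data frame of settings columns to vary (any of
#'   `resolution`, `injection_time`, `isolation_width`; one row per
#'   combination). Unlisted settings take [acquisition_settings()]
#'   defaults.
#' @param include_loq Also run a dilution series per grid point and report
#'   the LOQ of `loq_peptide` (default FALSE; considerably slower).
#' @param loq_peptide Peptide for the LOQ series (default: first in panel).
#' @param loq_start Starting amount for the series, amol.
#' @param tol XIC tolerance, ppm.
#' @return Tidy tibble, one row per grid point: the settings, `n_accepted`,
#'   `mean_abs_ppm`, `mean_dotp`, `mean_snr` and (optionally) `loq_amol`.
#' @export
parameter_sweep <- function(panel, truth, grid, include_loq = FALSE,
                            loq_peptide = NULL, loq_start = 500, tol = 10) {
  grid <- tibble::as_tibble(grid)
  if (!nrow(grid)) stop("settings grid must be nonempty", call. = FALSE)
  if (is.null(loq_peptide)) loq_peptide <- panel$peptide[1]

  purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    args <- as.list(grid[g, , drop = FALSE])
    settings <- do.call(acquisition_settings, args)
    acq <- simulate_acquisition(panel, settings, truth)
    ev <- evaluate_acquisition(acq, panel, tol = tol)
    out <- dplyr::bind_cols(grid[g, , drop = FALSE], tibble::tibble(
      n_pairs = nrow(ev),
      n_accepted = sum(ev$accepted),
      mean_abs_ppm = mean(c(ev$mean_abs_ppm_light, ev$mean_abs_ppm_heavy),
                          na.rm = TRUE),
      mean_dotp = mean(ev$library_dotp, na.rm = TRUE),
      mean_snr = mean(ev$snr_light, na.rm = TRUE)
    ))
    if (include_loq) {
      pair <- panel[panel$peptide == loq_peptide, ]
      series <- simulate_dilution_series(pair, loq_start, 2, 7, settings,
                                         seed = truth$seed)
      cal <- calibrate_series(series, pair, tol = tol)
      out$loq_amol <- cal$loq
    }
    out
  })
}
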