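# End-to-end convenience layer: acquisition -> XICs -> peak QC -> L/H
# ratios -> amounts -> copy numbers, per peptide pair.

#' Evaluate every light/heavy pair of an acquisition
#'
#' Runs XIC extraction, peak detection/integration and the pair acceptance
#' criteria for each peptide of the panel present in the acquisition.
#'
#' @param acquisition A `prm_acquisition`.
#' @param panel The `prm_panel` defining the targets.
#' @param tol XIC extraction tolerance, ppm.
#' @param thresholds See [acceptance_thresholds()].
#' @return Tibble with one row per peptide pair: the [evaluate_pair()]
#'   columns plus `peptide`, `protein`, `lh_ratio` (summed light / summed
#'   heavy area over fragments detected in the heavy standard; NA if no
#'   heavy signal), and `light_areas`/`heavy_areas` list-columns.
#' @export
evaluate_acquisition <- function(acquisition, panel, tol = 10,
                                 thresholds = acceptance_thresholds()) {
  present <- intersect(unique(acquisition$scan_times$peptide), panel$peptide)
  sub <- panel[panel$peptide %in% present & panel$label == "light", ]
  cyc <- median_cycle_min(acquisition)

  purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    pep <- sub$peptide[i]
    fr <- sub$fragments[[i]]
    lt <- extract_precursor_xics(acquisition, panel, pep, "light", tol)
    ht <- extract_precursor_xics(acquisition, panel, pep, "heavy", tol)
    lp <- detect_and_integrate(lt, sub$rt_true[i],
                               acquisition$settings$rt_window)
    hp <- detect_and_integrate(ht, sub$rt_true[i],
                               acquisition$settings$rt_window)
    ev <- evaluate_pair(lp, hp, fr$rel_intensity, thresholds,
                        cycle_time_min = cyc)
    la <- lp$per_fragment$area
    ha <- hp$per_fragment$area
    use <- hp$per_fragment$detected
    ratio <- if (any(use) && sum(ha[use]) > 0) {
      sum(la[use]) / sum(ha[use])
    } else NA_real_
    dplyr::bind_cols(
      tibble::tibble(peptide = pep, protein = sub$protein[i],
                     lh_ratio = ratio,
                     snr_light = mean(lp$per_fragment$snr),
                     snr_heavy = mean(hp$per_fragment$snr),
                     light_areas = list(la), heavy_areas = list(ha)),
      ev
    )
  })
}

median_cycle_min <- function(acquisition) {
  st <- acquisition$scan_times
  d <- st |>
    dplyr::group_by(.data$peptide, .data$label) |>
    dplyr::summarise(cyc = stats::median(diff(sort(.data$rt))),
                     .groups = "drop")
  stats::median(d$cyc, na.rm = TRUE)
}

#' Quantify an acquisition
#'
#' Full single-point isotope-dilution quantification: pair QC, L/H ratios,
#' absolute amounts (ratio x internal-standard spike) and copy numbers per
#' cell. Pairs failing QC are kept with `accepted = FALSE` and NA amounts.
#'
#' @inheritParams evaluate_acquisition
#' @param loaded_peptide_ug Peptide mass loaded on column, ug.
#' @param protein_per_cell_ng Total protein per cell, ng.
#' @return Tibble with `peptide`, `protein`, `accepted`, `lh_ratio`,
#'   `is_amount`, `amount_amol`, `copies_per_cell` and the QC columns.
#' @export
quantify_acquisition <- function(acquisition, panel, tol = 10,
                                 thresholds = acceptance_thresholds(),
                                 loaded_peptide_ug = 1,
                                 protein_per_cell_ng = 0.20) {
  ev <- evaluate_acquisition(acquisition, panel, tol, thresholds)
  is_amt <- panel$is_amount[match(ev$peptide, panel$peptide)]
  ev |>
    dplyr::mutate(
      is_amount = is_amt,
      amount_amol = ifelse(.data$accepted & !is.na(.data$lh_ratio),
                           pmax(0, .data$lh_ratio * .data$is_amount),
                           NA_real_),
      copies_per_cell = ifelse(is.na(.data$amount_amol), NA_real_,
                               copies_per_cell(pmax(.data$amount_amol, 0),
                                               loaded_peptide_ug,
                                               protein_per_cell_ng))
    ) |>
    dplyr::relocate("peptide", "protein", "accepted", "lh_ratio",
                    "is_amount", "amount_amol", "copies_per_cell")
}
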