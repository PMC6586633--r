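# Absolute amounts, copy numbers per cell, protein-level aggregation and
# fold-change time courses.

.AVOGADRO <- 6.022e23

#' Light-to-heavy area ratio
#'
#' @param light_areas,heavy_areas Per-fragment integrated areas over the
#'   shared accepted fragments.
#' @return `sum(light) / sum(heavy)`.
#' @export
light_heavy_ratio <- function(light_areas, heavy_areas) {
  stopifnot(length(light_areas) == length(heavy_areas),
            length(light_areas) >= 1)
  if (sum(heavy_areas) == 0) {
    stop("all heavy areas are zero: ratio undefined", call. = FALSE)
  }
  sum(light_areas) / sum(heavy_areas)
}

#' Absolute amount from ratio or calibration curve
#'
#' Two modes: single-point isotope dilution (`amount = ratio * is_amount`)
#' when a ratio and spike amount are given, or curve mode
#' (`amount = (response - intercept) / slope`) when a fitted calibration is
#' given. Negative back-calculated amounts are clamped to 0 with a warning
#' (they occur legitimately near blank levels).
#'
#' @param ratio L/H ratio (single-point mode).
#' @param is_amount Internal-standard spike, amol (single-point mode).
#' @param response Measured response (curve mode).
#' @param curve A `prm_calibration` (curve mode).
#' @return Amount in amol, with attribute `mode`.
#' @export
#' @examples
#' absolute_amount(ratio = 0.5, is_amount = 100)  # 50 amol
absolute_amount <- function(ratio = NULL, is_amount = NULL,
                            response = NULL, curve = NULL) {
  if (!is.null(ratio) && !is.null(is_amount)) {
    if (is_amount <= 0) stop("is_amount must be > 0", call. = FALSE)
    amount <- ratio * is_amount
    mode <- "single-point"
  } else if (!is.null(response) && !is.null(curve)) {
    stopifnot(inherits(curve, "prm_calibration"))
    amount <- (response - curve$intercept) / curve$slope
    mode <- "curve"
  } else {
    stop("supply either (ratio, is_amount) or (response, curve)",
         call. = FALSE)
  }
  if (any(amount < 0)) {
    warning("negative back-calculated amount clamped to 0", call. = FALSE)
    amount <- pmax(amount, 0)
  }
  structure(amount, mode = mode)
}

#' Protein copy number per cell
#'
#' The number of cells on column is `loaded_peptide / protein_per_cell`;
#' the molar amount times the Avogadro constant divided by the cell count
#' gives copies per cell.
#'
#' @param amount Peptide amount on column, amol (>= 0).
#' @param loaded_peptide_ug Total peptide loaded, ug (> 0; default 1).
#' @param protein_per_cell_ng Total protein per cell, ng (> 0; default
#'   0.20, the BCA-determined value for glioblastoma cells).
#' @param avogadro Avogadro constant (default 6.022e23 / mol).
#' @return Copies per cell.
#' @export
#' @examples
#' copies_per_cell(100, 1, 0.20)  # 12044
copies_per_cell <- function(amount, loaded_peptide_ug = 1,
                            protein_per_cell_ng = 0.20,
                            avogadro = .AVOGADRO) {
  if (any(amount < 0, na.rm = TRUE) || loaded_peptide_ug <= 0 ||
      protein_per_cell_ng <= 0) {
    stop("amount must be >= 0 and loading constants > 0", call. = FALSE)
  }
  n_cells <- loaded_peptide_ug * 1000 / protein_per_cell_ng
  amount * 1e-18 * avogadro / n_cells
}

#' Aggregate peptide-level results to one protein
#'
#' Unweighted mean across peptides (`method = "mean"`, default) or median;
#' the dispersion combines the between-peptide spread with propagated
#' replicate standard deviations where available.
#'
#' @param results Tibble with columns `peptide`, `copies_per_cell` (or
#'   `amount_amol`) and optionally `sd` (replicate sd per peptide) and
#'   `accepted`.
#' @param value Column to aggregate (default `copies_per_cell`).
#' @param method `"mean"` or `"median"`.
#' @return One-row tibble: `value`, `sd`, `n_peptides`, `quantified`.
#' @export
aggregate_protein <- function(results, value = "copies_per_cell",
                              method = c("mean", "median")) {
  method <- match.arg(method)
  if ("accepted" %in% names(results)) {
    results <- results[results$accepted %in% TRUE, ]
  }
  v <- results[[value]]
  v <- v[!is.na(v)]
  if (!length(v)) {
    return(tibble::tibble(value = NA_real_, sd = NA_real_, n_peptides = 0L,
                          quantified = FALSE))
  }
  centre <- if (method == "mean") mean(v) else stats::median(v)
  sd_between <- if (length(v) >= 2) stats::sd(v) else NA_real_
  sd_within <- if ("sd" %in% names(results)) {
    s <- results$sd[!is.na(results$sd)]
    if (length(s)) sqrt(mean(s^2)) else NA_real_
  } else NA_real_
  total_sd <- if (is.na(sd_within)) sd_between else {
    sqrt(sum(c(sd_between^2, sd_within^2), na.rm = TRUE))
  }
  tibble::tibble(value = centre, sd = total_sd, n_peptides = length(v),
                 quantified = TRUE)
}

#' Fold changes vs. control across conditions and timepoints
#'
#' @param results Tibble with columns `protein`, `condition`, `timepoint`,
#'   `copies_per_cell` (protein-level) and optionally `sd`.
#' @param control Name of the control condition (default `"control"`).
#' @return Tibble per (protein, condition, timepoint): `fold_change`
#'   (treated/control on the matched timepoint), `copies_per_cell`,
#'   `control_copies` and a `flag` column (`"ok"`, `"missing-control"`,
#'   `"zero-control"`); missing pairs are flagged, never dropped.
#' @export
fold_change_timecourse <- function(results, control = "control") {
  stopifnot(all(c("protein", "condition", "timepoint", "copies_per_cell")
                %in% names(results)))
  ctrl <- results |>
    dplyr::filter(.data$condition == control) |>
    dplyr::select("protein", "timepoint",
                  control_copies = "copies_per_cell")
  results |>
    dplyr::filter(.data$condition != control) |>
    dplyr::left_join(ctrl, by = c("protein", "timepoint")) |>
    dplyr::mutate(
      flag = dplyr::case_when(
        is.na(.data$control_copies) ~ "missing-control",
        .data$control_copies == 0 ~ "zero-control",
        TRUE ~ "ok"
      ),
      fold_change = ifelse(.data$flag == "ok",
                           .data$copies_per_cell / .data$control_copies,
                           NA_real_)
    )
}
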