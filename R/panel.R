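# The UPR quantification panel: 21 light/heavy peptide pairs covering the
# eight core unfolded-protein-response proteins (receptors IRE1, PERK, ATF6;
# effectors ATF3, ATF4, CHOP, GADD34, XBP1).

# Fixed panel definition. Four sequences are the published assay peptides
# (GGFGVVFEAK and YLTDFEPIQCLGR for PERK, AEPQPLSPASSSYSVSSPR for ATF6,
# APLSPSLLIR conventionally assigned to GADD34); the remainder are synthetic
# tryptic-like sequences standing in for the rest of the panel.
# APLSPSLLIR's protein assignment is ambiguous in the literature (GADD34 vs
# XBP1); we default to GADD34 and flag it.
.UPR_PANEL <- tibble::tribble(
  ~peptide,              ~protein, ~ambiguous_protein,
  "AVGTDLSSFLK",         "IRE1",   FALSE,
  "ELDPSVTGYR",          "IRE1",   FALSE,
  "SGIVDTLSAK",          "IRE1",   FALSE,
  "GGFGVVFEAK",          "PERK",   FALSE,
  "YLTDFEPIQCLGR",       "PERK",   FALSE,
  "TLDSEYNPVSR",         "PERK",   FALSE,
  "AEPQPLSPASSSYSVSSPR", "ATF6",   FALSE,
  "ELDSVPGTAQK",         "ATF6",   FALSE,
  "SGDLTNVFAK",          "ATF6",   FALSE,
  "ETLDSAVGPQR",         "ATF3",   FALSE,
  "ALSSDVGQLK",          "ATF3",   FALSE,
  "GLTDSVPAEFK",         "ATF4",   FALSE,
  "SEQDLVTGSPR",         "ATF4",   FALSE,
  "AVDSTLNPEGK",         "ATF4",   FALSE,
  "ELTSDFGAVQR",         "CHOP",   FALSE,
  "SDPLVTGEAK",          "CHOP",   FALSE,
  "APLSPSLLIR",          "GADD34", TRUE,
  "TGELDSVPQAK",         "GADD34", FALSE,
  "NLDSFVGTEPR",         "GADD34", FALSE,
  "SEVLDPTGAQK",         "XBP1",   FALSE,
  "GLDTESVPNAR",         "XBP1",   FALSE
)

# Reference endogenous amounts (amol on a 1 ug column load), set per protein
# so that copy numbers span the few-hundred (XBP1) to ~60,000 (ATF6) range
# typical of UPR proteins in glioblastoma cells.
.UPR_ENDOG_AMOL <- c(
  IRE1 = 50, PERK = 166, ATF6 = 498, ATF3 = 42, ATF4 = 125,
  CHOP = 66, GADD34 = 17, XBP1 = 3.3
)

#' Build the 21-pair UPR peptide panel
#'
#' Returns the panel of 21 light/heavy peptide pairs (42 precursors) covering
#' the eight core UPR proteins. Sequences, protein assignments, charge states
#' and retention times are fixed; the seed controls the library fragment
#' intensity patterns and per-peptide response factors.
#'
#' Each peptide carries up to six singly charged y ions as monitored
#' transitions. Heavy partners share sequence, retention time, fragments and
#' response factor with their light form and differ only by the C-terminal
#' SIL-label mass offset. Internal-standard spike amounts span 29.5 to
#' 490.4 amol depending on peptide response.
#'
#' @param seed Integer seed for the stochastic panel attributes.
#' @return A `prm_panel` tibble with one row per (peptide, label): columns
#'   `peptide`, `protein`, `ambiguous_protein`, `charge`, `label`,
#'   `precursor_mz`, `rt_true` (min), `is_amount` (amol, heavy spike),
#'   `endog_amol` (reference endogenous amount), `response_factor`
#'   (ions/ms/amol at peak apex) and a `fragments` list-column
#'   (tibble of `fragment`, `mz`, `rel_intensity`).
#' @export
#' @examples
#' panel <- build_upr_panel(seed = 1)
#' dplyr::count(panel, protein)
build_upr_panel <- function(seed = 1L) {
  base <- .UPR_PANEL
  n <- nrow(base)

  local_rng(seed, "panel")
  jitter <- stats::runif(n, -0.3, 0.3)
  base$rt_true <- 8 + (seq_len(n) - 1L) * (64 / (n - 1L)) + jitter
  base$charge <- 2L
  base$endog_amol <- unname(.UPR_ENDOG_AMOL[base$protein])
  base$response_factor <- exp(stats::runif(n, log(0.5), log(3)))

  # IS spike: log-spaced across the published 29.5-490.4 amol range,
  # anchored at the two documented extremes.
  base$is_amount <- round(exp(seq(log(29.5), log(490.4), length.out = n)), 1)
  base$is_amount[base$peptide == "APLSPSLLIR"] <- 29.5
  base$is_amount[base$peptide == "YLTDFEPIQCLGR"] <- 490.4

  frag_tbl <- purrr::map(base$peptide, function(seq) {
    len <- nchar(seq)
    ks <- seq(len - 1L, max(3L, len - 6L))
    mz <- y_ion_mz(seq, n = ks)
    w <- sort(stats::rgamma(length(mz), shape = 2), decreasing = TRUE)
    # put the largest weights on mid-size y ions, a typical HCD pattern
    ord <- order(abs(seq_along(mz) - (length(mz) + 1) / 2))
    rel <- numeric(length(mz)); rel[ord] <- w
    tibble::tibble(fragment = names(mz), mz = unname(mz),
                   rel_intensity = rel / sum(rel))
  })
  base$fragments <- frag_tbl

  out <- tidyr::expand_grid(base, label = c("light", "heavy")) |>
    dplyr::mutate(
      precursor_mz = purrr::map2_dbl(.data$peptide, .data$label,
                                     ~ precursor_mz(.x, 2L, .y)),
      fragments = purrr::pmap(list(.data$fragments, .data$peptide, .data$label),
        function(fr, pep, lab) {
          if (lab == "heavy") fr$mz <- fr$mz + heavy_offset(pep)
          fr
        })
    ) |>
    dplyr::select("peptide", "protein", "ambiguous_protein", "charge",
                  "label", "precursor_mz", "rt_true", "is_amount",
                  "endog_amol", "response_factor", "fragments")
  class(out) <- c("prm_panel", class(out))
  out
}

# Seeded RNG scoped to the calling function: restores the global RNG state
# on exit and decorrelates streams used for different purposes via a purpose
# string folded into the seed.
local_rng <- function(seed, purpose = "", envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  offset <- if (nzchar(purpose)) {
    sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose))) %% 100000L
  } else 0L
  set.seed((as.integer(seed) %% 2000000000L) + offset)
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  invisible(NULL)
}
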