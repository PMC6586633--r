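# Scheduled-PRM method design: in-silico tryptic digest, proteotypic
# candidate filtering, greedy target selection under a concurrency cap, and
# the cycle-time / points-per-peak model.

# Kyte-Doolittle hydropathy, used as a retention surrogate when no
# predicted RT is supplied.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' In-silico tryptic digest
#'
#' Cleaves C-terminal to K/R except before proline, enumerating peptides
#' with 0 to `max_missed` missed cleavages. Flags ragged ends (a flanking
#' K/R run making the cleavage register ambiguous) and checks uniqueness of
#' each peptide across all supplied protein sequences by exact substring
#' match.
#'
#' @param proteins Named character vector of protein sequences (names are
#'   protein identifiers), or a path to a FASTA file.
#' @param max_missed Maximum missed cleavages to enumerate (default 2).
#' @param min_length Minimum peptide length to report (default 6).
#' @param gradient_min Gradient length used to place the hydropathy-based
#'   RT surrogate (default 75 min).
#' @return Tibble of candidates: `sequence`, `protein`, `start`, `end`,
#'   `missed_cleavages`, `ragged_end`, `unique_in_proteome`,
#'   `rt_predicted`.
#' @export
#' @examples
#' tryptic_digest(c(P1 = "MAGELKADPTRVVLSEK"))
tryptic_digest <- function(proteins, max_missed = 2L, min_length = 6L,
                           gradient_min = 75) {
  if (is.character(proteins) && length(proteins) == 1L && is.null(names(proteins)) &&
      file.exists(proteins)) {
    proteins <- read_fasta(proteins)
  }
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    stop("proteins must be a named character vector or FASTA path",
         call. = FALSE)
  }
  keep <- nzchar(proteins)
  if (!all(keep)) {
    warning("skipping ", sum(!keep), " empty sequence(s)", call. = FALSE)
    proteins <- proteins[keep]
  }
  if (!length(proteins)) stop("no sequences to digest", call. = FALSE)

  digests <- purrr::imap_dfr(proteins, digest_one, max_missed = max_missed)
  digests <- digests[nchar(digests$sequence) >= min_length, ]

  # uniqueness across the supplied proteome: substring hit in exactly one
  # protein
  n_prot_hits <- vapply(digests$sequence, function(p) {
    sum(vapply(proteins, function(s) grepl(p, s, fixed = TRUE), logical(1)))
  }, numeric(1))
  digests$unique_in_proteome <- n_prot_hits == 1

  digests$rt_predicted <- hydropathy_rt(digests$sequence, gradient_min)
  tibble::as_tibble(digests)
}

digest_one <- function(seq, protein, max_missed) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  # cleavage sites: after K/R not followed by P
  site <- which(aa %in% c("K", "R") & c(aa[-1], "") != "P")
  bounds <- c(0L, site, if (!n %in% site) n)
  bounds <- unique(bounds)
  starts <- utils::head(bounds, -1) + 1L
  ends <- utils::tail(bounds, -1)

  rows <- list()
  for (mc in 0:max_missed) {
    k <- length(starts) - mc
    if (k < 1) break
    for (i in seq_len(k)) {
      s <- starts[i]; e <- ends[i + mc]
      prev1 <- if (s > 1) aa[s - 1] else ""
      prev2 <- if (s > 2) aa[s - 2] else ""
      nxt <- if (e < n) aa[e + 1] else ""
      ragged <- (prev1 %in% c("K", "R") && prev2 %in% c("K", "R")) ||
        nxt %in% c("K", "R")
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(seq, s, e), protein = protein,
        start = s, end = e, missed_cleavages = mc, ragged_end = ragged,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

hydropathy_rt <- function(sequences, gradient_min = 75) {
  h <- vapply(sequences, function(s) {
    aa <- strsplit(s, "")[[1]]
    mean(.KD[aa], na.rm = TRUE)
  }, numeric(1))
  # map mean hydropathy (~[-4.5, 4.5]) onto 5..(gradient-5) min
  5 + (h + 4.5) / 9 * (gradient_min - 10)
}

#' Select scheduled PRM targets under a concurrency cap
#'
#' Greedy selection of proteotypic candidates (unique, no missed cleavage,
#' no ragged end): proteins with the largest remaining coverage need are
#' served first, and within a protein the candidate eluting farthest from
#' already-selected targets wins, provided adding its window never pushes
#' the concurrent pair count above `max_concurrent` anywhere. Constraint
#' violations are reported, never silently committed.
#'
#' @param candidates Tibble from [tryptic_digest()] (needs `sequence`,
#'   `protein`, `rt_predicted`; filter columns are honoured when present).
#' @param rt_window Scheduling window length, min (default 2).
#' @param max_concurrent Maximum concurrent precursor pairs (default 3).
#' @param per_protein_min Minimum targets per protein (default 2).
#' @param max_per_protein Maximum targets per protein (default 3).
#' @param settings Acquisition settings used for the cycle-time estimate.
#' @return A `prm_schedule`: `targets` tibble (`sequence`, `protein`, `rt`,
#'   `window_start`, `window_end`), `rt_window`,
#'   `max_concurrency_observed`, `cycle_time_at_peak_concurrency_ms`,
#'   `est_points_per_peak`, `uncovered` (proteins below `per_protein_min`)
#'   and `excluded` (candidate count rejected by the cap).
#' @export
select_targets <- function(candidates, rt_window = 2, max_concurrent = 3L,
                           per_protein_min = 2L, max_per_protein = 3L,
                           settings = acquisition_settings()) {
  stopifnot(rt_window > 0, max_concurrent >= 1)
  cand <- tibble::as_tibble(candidates)
  if (!"rt_predicted" %in% names(cand)) {
    stop("candidates need an rt_predicted column", call. = FALSE)
  }
  for (col in c("unique_in_proteome", "ragged_end", "missed_cleavages")) {
    if (col %in% names(cand)) {
      cand <- switch(col,
        unique_in_proteome = cand[cand$unique_in_proteome, ],
        ragged_end = cand[!cand$ragged_end, ],
        missed_cleavages = cand[cand$missed_cleavages == 0, ])
    }
  }
  cand <- dplyr::distinct(cand, .data$sequence, .data$protein,
                          .keep_all = TRUE)

  half <- rt_window / 2
  sel <- integer(0)
  excluded <- 0L
  repeat {
    counts <- table(factor(cand$protein[sel], levels = unique(cand$protein)))
    # proteins still wanting targets, most-needy first
    need <- names(sort(counts[counts < max_per_protein]))
    picked <- FALSE
    for (p in need) {
      rows <- setdiff(which(cand$protein == p), sel)
      if (!length(rows)) next
      # isolation score: distance to nearest already-selected RT
      score <- if (length(sel)) {
        vapply(cand$rt_predicted[rows],
               function(r) min(abs(r - cand$rt_predicted[sel])), numeric(1))
      } else rep(Inf, length(rows))
      for (j in rows[order(-score)]) {
        trial <- c(sel, j)
        prof <- sweep_concurrency(cand$rt_predicted[trial] - half,
                                  cand$rt_predicted[trial] + half)
        if (prof$max <= max_concurrent) {
          sel <- trial; picked <- TRUE; break
        } else {
          excluded <- excluded + 1L
        }
      }
      if (picked) break
    }
    if (!picked) break
  }

  targets <- cand[sel, c("sequence", "protein", "rt_predicted")] |>
    dplyr::rename(rt = "rt_predicted") |>
    dplyr::mutate(window_start = .data$rt - half,
                  window_end = .data$rt + half) |>
    dplyr::arrange(.data$rt)

  prof <- sweep_concurrency(targets$window_start, targets$window_end)
  cyc <- estimate_cycle(settings, n_concurrent_precursors = 2L * max(1L, prof$max))
  counts <- table(factor(targets$protein, levels = unique(cand$protein)))
  structure(list(
    targets = targets, rt_window = rt_window,
    max_concurrency_observed = prof$max,
    cycle_time_at_peak_concurrency_ms = cyc$cycle_time_ms,
    est_points_per_peak = cyc$points_per_peak,
    uncovered = names(counts)[counts < per_protein_min],
    excluded = excluded
  ), class = "prm_schedule")
}

#' @export
print.prm_schedule <- function(x, ...) {
  cat(sprintf("<prm_schedule> %d targets, window %g min, max %d concurrent pairs\n",
              nrow(x$targets), x$rt_window, x$max_concurrency_observed))
  cat(sprintf("  cycle at peak concurrency %.0f ms -> ~%.1f points/peak\n",
              x$cycle_time_at_peak_concurrency_ms, x$est_points_per_peak))
  if (length(x$uncovered)) {
    cat("  under-covered proteins:", paste(x$uncovered, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Concurrency profile of a scheduled method
#'
#' Sweep-line count of concurrently scheduled precursor pairs (one pair =
#' heavy + light = one scheduled target) over the RT axis. Windows are
#' half-open `[start, end)`.
#'
#' @param method A `prm_schedule`, or a tibble with `window_start` and
#'   `window_end`.
#' @return List with `profile` (tibble `rt`, `n_pairs`: the count holding
#'   from each breakpoint to the next) and `max`.
#' @export
concurrency_profile <- function(method) {
  tg <- if (inherits(method, "prm_schedule")) method$targets else method
  if (!nrow(tg)) stop("method has no targets", call. = FALSE)
  sweep_concurrency(tg$window_start, tg$window_end)
}

sweep_concurrency <- function(starts, ends) {
  ev <- rbind(data.frame(rt = starts, d = 1L), data.frame(rt = ends, d = -1L))
  ev <- ev[order(ev$rt, ev$d), ]  # ends (-1) before starts (+1) at ties
  n <- cumsum(ev$d)
  prof <- tibble::tibble(rt = ev$rt, n_pairs = n) |>
    dplyr::group_by(.data$rt) |>
    dplyr::summarise(n_pairs = dplyr::last(.data$n_pairs), .groups = "drop")
  list(profile = prof, max = max(n))
}

#' Cycle time and points-per-peak estimate
#'
#' Per-scan time is `max(injection_time, transient(resolution)) +
#' scan_overhead`; the duty cycle is that times the number of concurrent
#' precursors (2 per pair), and points per peak follow from the peak base
#' width.
#'
#' @param settings An [acquisition_settings()].
#' @param n_concurrent_precursors Concurrent precursors (>= 1).
#' @param peak_base_width_min Chromatographic peak base width, min
#'   (default 0.5, i.e. 2x the 0.25 min FWHM).
#' @return List `cycle_time_ms`, `points_per_peak`.
#' @export
#' @examples
#' estimate_cycle(acquisition_settings(), n_concurrent_precursors = 6)
estimate_cycle <- function(settings, n_concurrent_precursors = 1L,
                           peak_base_width_min = 0.5) {
  stopifnot(n_concurrent_precursors >= 1)
  per_scan <- max(settings$injection_time, transient_time(settings$resolution)) +
    settings$scan_overhead
  cycle <- n_concurrent_precursors * per_scan
  list(cycle_time_ms = cycle,
       points_per_peak = peak_base_width_min * 60000 / cycle)
}
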