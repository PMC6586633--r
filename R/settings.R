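# Acquisition settings and the orbitrap transient-time model.

# Orbitrap transient duration (ms) by nominal resolving power at m/z 200,
# standard Q Exactive HF values.
.TRANSIENT_MS <- c(
  `15000` = 32, `30000` = 64, `60000` = 128, `120000` = 256, `240000` = 512
)

#' PRM acquisition settings
#'
#' Bundles the instrument parameters that govern a PRM acquisition. Defaults
#' are the optimized high-resolution setup: 240,000 resolving power (at m/z
#' 200), 500 ms maximum injection time, 0.4 m/z isolation width, AGC target
#' 3e6 charges, 2 min scheduling windows.
#'
#' @param resolution Resolving power at the m/z 200 reference.
#' @param injection_time Maximum ion injection (fill) time, ms.
#' @param isolation_width Quadrupole isolation window, m/z (full width).
#' @param agc_target Maximum accumulated charges per scan.
#' @param rt_window Scheduled retention-time window length, min.
#' @param scan_overhead Fixed per-scan overhead, ms.
#' @return An object of class `prm_settings`.
#' @export
#' @examples
#' acquisition_settings(resolution = 240000, injection_time = 500)
acquisition_settings <- function(resolution = 240000, injection_time = 500,
                                 isolation_width = 0.4, agc_target = 3e6,
                                 rt_window = 2, scan_overhead = 10) {
  vals <- c(resolution = resolution, injection_time = injection_time,
            isolation_width = isolation_width, agc_target = agc_target,
            rt_window = rt_window, scan_overhead = scan_overhead)
  if (any(!is.finite(vals)) || any(vals[setdiff(names(vals), "scan_overhead")] <= 0) ||
      scan_overhead < 0) {
    stop("all acquisition settings must be positive (scan_overhead >= 0)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "prm_settings")
}

#' @export
print.prm_settings <- function(x, ...) {
  cat("<prm_settings> ",
      sprintf("R=%s @ m/z 200, IT=%g ms, iso=%g m/z, AGC=%g, window=%g min",
              format(x$resolution, big.mark = ","), x$injection_time,
              x$isolation_width, x$agc_target, x$rt_window), "\n")
  invisible(x)
}

#' Orbitrap transient time for a nominal resolution
#'
#' Looks up the image-current transient duration. Resolutions not in the
#' instrument table fall back to the nearest tabulated value with a warning.
#'
#' @param resolution Resolving power at m/z 200.
#' @return Transient duration in ms.
#' @export
transient_time <- function(resolution) {
  stopifnot(resolution > 0)
  tab <- as.numeric(names(.TRANSIENT_MS))
  i <- which(tab == resolution)
  if (!length(i)) {
    i <- which.min(abs(tab - resolution))
    warning("resolution ", resolution, " not tabulated; using nearest (",
            tab[i], ")", call. = FALSE)
  }
  unname(.TRANSIENT_MS[i])
}

#' Effective orbitrap resolving power at an arbitrary m/z
#'
#' Orbitrap resolution falls off as the square root of m/z:
#' `R(mz) = R_ref * sqrt(200 / mz)` with the reference at m/z 200.
#'
#' @param resolution_at_ref Resolving power quoted at m/z 200.
#' @param mz m/z of interest.
#' @return Effective resolving power.
#' @export
effective_resolution <- function(resolution_at_ref, mz) {
  stopifnot(resolution_at_ref > 0, mz > 0)
  resolution_at_ref * sqrt(200 / mz)
}
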