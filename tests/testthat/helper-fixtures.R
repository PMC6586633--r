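# Shared fixtures, built in code.

tiny_panel <- function(seed = 1, n = 2) {
  panel <- build_upr_panel(seed)
  panel[panel$peptide %in% unique(panel$peptide)[seq_len(n)], ]
}

# A synthetic acquisition-like object with hand-placed centroids, for
# testing extraction independently of the simulator.
manual_acquisition <- function(centroids, rts, peptide = "PEP",
                               label = "light") {
  structure(list(
    scans = centroids,
    scan_times = tibble::tibble(peptide = peptide, label = label, rt = rts),
    settings = acquisition_settings(), truth = NULL
  ), class = "prm_acquisition")
}

# noiseless Gaussian trace over a fixed RT grid
gaussian_trace <- function(rts, apex_rt = 10, sigma = 0.1, height = 1000,
                           fragment = "y4", mz = 500) {
  tibble::tibble(
    peptide = "PEP", label = "light", fragment = fragment, rt = rts,
    intensity = height * exp(-(rts - apex_rt)^2 / (2 * sigma^2)),
    measured_mz = mz, theoretical_mz = mz
  )
}

# brute-force XIC oracle: plain loop over every centroid row
xic_oracle <- function(acq, peptide, label, mz, tol) {
  rts <- sort(acq$scan_times$rt[acq$scan_times$peptide == peptide &
                                  acq$scan_times$label == label])
  out <- numeric(length(rts))
  for (i in seq_along(rts)) {
    for (j in seq_len(nrow(acq$scans))) {
      row <- acq$scans[j, ]
      if (row$peptide == peptide && row$label == label &&
          row$rt == rts[i] &&
          abs(row$measured_mz - mz) / mz * 1e6 <= tol) {
        out[i] <- out[i] + row$intensity
      }
    }
  }
  out
}

# brute-force concurrency oracle: for half-open windows the maximum is
# attained at some window start, so evaluate the count there (plus a fine
# grid for good measure)
grid_concurrency_oracle <- function(starts, ends, step = 0.01) {
  pts <- sort(unique(c(starts, seq(min(starts), max(ends), by = step))))
  max(vapply(pts, function(t) sum(starts <= t & t < ends), numeric(1)))
}
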