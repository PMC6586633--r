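# In-silico digest, target selection under the concurrency cap, and the
# cycle-time model.

test_that("tryptic digest cleaves after K/R except before proline", {
  d <- tryptic_digest(c(P1 = "AAAKGGGR"), min_length = 1)
  d0 <- d[d$missed_cleavages == 0, ]
  expect_setequal(d0$sequence, c("AAAK", "GGGR"))
  # KP suppression: no cleavage after K before P
  d2 <- tryptic_digest(c(P1 = "AAKPGGK"), min_length = 1)
  expect_true("AAKPGGK" %in% d2$sequence[d2$missed_cleavages == 0])
  expect_false("AAK" %in% d2$sequence)
})

test_that("zero-missed-cleavage products reconstruct the protein exactly", {
  set.seed(5)
  aa <- c("A", "G", "S", "V", "L", "K", "R", "P", "E", "D")
  for (i in 1:20) {
    prot <- paste(sample(aa, 60, replace = TRUE), collapse = "")
    d <- tryptic_digest(setNames(prot, "X"), min_length = 1)
    d0 <- d[d$missed_cleavages == 0, ]
    d0 <- d0[order(d0$start), ]
    expect_equal(paste(d0$sequence, collapse = ""), prot)
  }
})

test_that("uniqueness flags match a brute-force substring search", {
  prots <- c(A = "MAGELKADPTRVVLSEK", B = "GGSSVKADPTRLLQEK",
             C = "MTTVLKPPLsR")
  prots <- toupper(prots)
  d <- tryptic_digest(prots, min_length = 3)
  for (i in seq_len(nrow(d))) {
    hits <- sum(vapply(prots, function(s)
      grepl(d$sequence[i], s, fixed = TRUE), logical(1)))
    expect_equal(d$unique_in_proteome[i], hits == 1)
  }
  # ADPTR appears in two proteins -> not unique
  expect_false(any(d$unique_in_proteome[d$sequence == "ADPTR"]))
})

test_that("ragged ends are flagged from flanking K/R runs", {
  # ...KK|SEQ... : N-terminal register ambiguous; SEQK|K : C-terminal
  d <- tryptic_digest(c(P = "AAKKSSSSEKGGGR"), min_length = 1)
  d0 <- d[d$missed_cleavages == 0, ]
  expect_true(d0$ragged_end[d0$sequence == "SSSSEK"])   # preceded by KK
  expect_true(d0$ragged_end[d0$sequence == "AAK"])      # followed by K
  expect_false(d0$ragged_end[d0$sequence == "GGGR"])
})

test_that("well-separated candidates are all scheduled at concurrency 1", {
  cand <- tibble::tibble(
    sequence = paste0("PEP", 1:10), protein = paste0("PROT", 1:10),
    rt_predicted = seq(5, 50, by = 5))
  m <- select_targets(cand, rt_window = 2, max_concurrent = 3,
                      per_protein_min = 1, max_per_protein = 1)
  expect_equal(nrow(m$targets), 10L)
  expect_equal(m$max_concurrency_observed, 1L)
  expect_equal(length(m$uncovered), 0L)
})

test_that("co-eluting candidates are capped at 3 concurrent pairs", {
  cand <- tibble::tibble(
    sequence = paste0("PEP", 1:8), protein = paste0("PROT", 1:8),
    rt_predicted = rep(20, 8))
  m <- select_targets(cand, rt_window = 2, max_concurrent = 3,
                      per_protein_min = 1, max_per_protein = 1)
  expect_lte(nrow(m$targets), 3L)
  expect_lte(m$max_concurrency_observed, 3L)
  expect_gt(length(m$uncovered), 0L)  # the rest reported, not silently lost
})

test_that("concurrency profile matches hand sweeps and the grid oracle", {
  w <- tibble::tibble(window_start = c(0, 1, 1.5), window_end = c(2, 3, 3.5))
  expect_equal(concurrency_profile(w)$max, 3L)
  expect_equal(concurrency_profile(w[1, , drop = FALSE])$max, 1L)
  set.seed(19)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    rt <- runif(n, 0, 20)
    m <- tibble::tibble(window_start = rt - 1, window_end = rt + 1)
    expect_equal(concurrency_profile(m)$max,
                 grid_concurrency_oracle(m$window_start, m$window_end))
  }
})

test_that("selection respects the cap on randomized candidate sets", {
  for (s in 1:20) {
    set.seed(s)
    cand <- tibble::tibble(
      sequence = paste0("PEP", 1:50),
      protein = paste0("PROT", sample(1:10, 50, replace = TRUE)),
      rt_predicted = runif(50, 0, 75))
    m <- select_targets(cand, rt_window = 2, max_concurrent = 3)
    oracle <- grid_concurrency_oracle(m$targets$window_start,
                                      m$targets$window_end)
    expect_lte(oracle, 3)
    expect_lte(m$max_concurrency_observed, 3)
  }
})

test_that("selection is deterministic for a fixed input order", {
  cand <- tibble::tibble(
    sequence = paste0("PEP", 1:30), protein = rep(paste0("PROT", 1:6), 5),
    rt_predicted = seq(2, 60, by = 2))
  m1 <- select_targets(cand)
  m2 <- select_targets(cand)
  expect_identical(m1$targets, m2$targets)
})

test_that("cycle model reproduces the transient-bound arithmetic", {
  st <- acquisition_settings(resolution = 240000, injection_time = 500,
                             scan_overhead = 10)
  cy <- estimate_cycle(st, n_concurrent_precursors = 6)
  # per scan = max(500, 512) + 10 = 522 ms; cycle = 6 * 522
  expect_equal(cy$cycle_time_ms, 3132)
  cy1 <- estimate_cycle(st, 1)
  expect_equal(cy1$cycle_time_ms, 522)
  # halving concurrency halves the cycle exactly
  expect_equal(estimate_cycle(st, 4)$cycle_time_ms,
               2 * estimate_cycle(st, 2)$cycle_time_ms)
  # injection-bound regime: at 30k the 500 ms fill dominates the 64 ms
  # transient
  st30 <- acquisition_settings(resolution = 30000, injection_time = 500,
                               scan_overhead = 10)
  expect_equal(estimate_cycle(st30, 1)$cycle_time_ms, 510)
  expect_warning(transient_time(45000), "nearest")
})
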