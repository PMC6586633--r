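# Monoisotopic peptide mass arithmetic for precursor and y-ion m/z.
# Cysteine is carried as carbamidomethyl-Cys (+57.02146), the fixed
# modification used throughout iodoacetamide-alkylated digests.

.MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919 + 57.02146, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259,
  M = 131.04049, H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333,
  W = 186.07931
)

.MASS_H2O    <- 18.0105646
.MASS_PROTON <- 1.00727646688

# Stable-isotope label mass offsets by C-terminal residue:
# 13C6,15N2-Lys and 13C6,15N4-Arg.
.HEAVY_OFFSET <- c(K = 8.014199, R = 10.008269)

#' Monoisotopic mass of a peptide
#'
#' Sums monoisotopic residue masses plus one water. Cysteines are treated as
#' carbamidomethylated.
#'
#' @param sequence Amino-acid sequence (standard one-letter codes).
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(.MONO))
  if (length(bad)) {
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  sum(.MONO[aa]) + .MASS_H2O
}

#' Precursor m/z of a peptide
#'
#' @param sequence Amino-acid sequence.
#' @param charge Positive integer charge state.
#' @param label `"light"` or `"heavy"`; heavy adds the SIL-label offset for
#'   the C-terminal residue (+8.014199 Da for Lys, +10.008269 Da for Arg).
#' @return m/z of the protonated precursor.
#' @export
precursor_mz <- function(sequence, charge = 2L, label = c("light", "heavy")) {
  label <- match.arg(label)
  stopifnot(charge >= 1)
  m <- peptide_mass(sequence)
  if (label == "heavy") m <- m + heavy_offset(sequence)
  (m + charge * .MASS_PROTON) / charge
}

heavy_offset <- function(sequence) {
  cterm <- substr(sequence, nchar(sequence), nchar(sequence))
  if (!cterm %in% names(.HEAVY_OFFSET)) {
    stop("heavy label requires a C-terminal K or R, got '", cterm, "'",
         call. = FALSE)
  }
  .HEAVY_OFFSET[[cterm]]
}

#' Singly protonated y-ion m/z values of a peptide
#'
#' @param sequence Amino-acid sequence.
#' @param n y-ion lengths to return (default y3 up to y(L-1)).
#' @param label `"light"` or `"heavy"`; y ions contain the C-terminus, so the
#'   heavy offset applies to every y ion.
#' @return Named numeric vector (`y3`, `y4`, ...) of 1+ fragment m/z.
#' @export
y_ion_mz <- function(sequence, n = NULL, label = c("light", "heavy")) {
  label <- match.arg(label)
  len <- nchar(sequence)
  if (is.null(n)) n <- seq(3L, max(3L, len - 1L))
  n <- n[n >= 1 & n < len]
  off <- if (label == "heavy") heavy_offset(sequence) else 0
  mz <- vapply(n, function(k) {
    frag <- substr(sequence, len - k + 1L, len)
    peptide_mass(frag) + off + .MASS_PROTON
  }, numeric(1))
  stats::setNames(mz, paste0("y", n))
}
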