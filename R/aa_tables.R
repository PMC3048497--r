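# Residue-level constant tables shared across the package.

# The 20 standard amino acids, alphabetical one-letter codes.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Letters legal in a stored protein sequence ('*' is stripped at parse time).
AA_LEGAL <- c(AA_STANDARD, "X")

# Average (not monoisotopic) residue masses in Da; one water is added per chain.
AA_MASS_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

WATER_MASS <- 18.0153

#' EMBOSS pKa table for isoelectric-point prediction
#'
#' The pKa values used by the EMBOSS suite: termini plus the ionizable side
#' chains (acidic: C, D, E, Y and the C-terminus; basic: H, K, R and the
#' N-terminus). [net_charge()] and [isoelectric_point()] take any table with
#' this shape, so the set is swappable.
#'
#' @return A list with numeric elements `nterm`, `cterm`, `acidic` (named
#'   vector over C, D, E, Y) and `basic` (named vector over H, K, R).
#' @export
#' @examples
#' emboss_pka()$nterm
emboss_pka <- function() {
  list(
    nterm  = 8.6,
    cterm  = 3.6,
    acidic = c(C = 8.5, D = 3.9, E = 4.1, Y = 10.1),
    basic  = c(H = 6.5, K = 10.8, R = 12.5)
  )
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used by [detect_tm_segment()]. Positive is
#' hydrophobic; a 19-residue window mean above ~1.6 is the classic indication
#' of a membrane-spanning segment.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
kyte_doolittle <- function() {
  c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  )
}

# Split sequences into a character matrix (rows = sequences). Assumes equal
# lengths; callers validate.
seq_char_matrix <- function(sequences) {
  do.call(rbind, strsplit(sequences, "", fixed = TRUE))
}
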