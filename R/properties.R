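# Physicochemical descriptors: average molecular mass and predicted
# isoelectric point (Henderson-Hasselbalch bisection under the EMBOSS pKa
# set by default).

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da). Unknown
#' residues (`X`) have no defined mass and are an error.
#'
#' @param sequence Amino-acid string over the 20 standard letters.
#' @return Mass in daltons.
#' @export
#' @examples
#' molecular_weight("G")  # 75.0672
molecular_weight <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) abort("Empty sequence has no molecular weight")
  if (grepl("[X*]", sequence)) {
    abort("Sequence contains X or *; molecular weight undefined")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  masses <- AA_MASS_AVG[chars]
  if (anyNA(masses)) {
    abort(paste0("Illegal residue '", chars[which(is.na(masses))[1]], "'"))
  }
  sum(masses) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (acidic D, E, C, Y; basic H, K, R). Strictly
#' decreasing in pH, which makes the isoelectric point a unique root.
#'
#' @param sequence Amino-acid string.
#' @param pH pH value(s); vectorized.
#' @param pka pKa table, see [emboss_pka()].
#' @return Signed charge, same length as `pH`.
#' @export
net_charge <- function(sequence, pH, pka = emboss_pka()) {
  stopifnot(nchar(sequence) > 0)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  neg_frac <- function(pk) 1 / (1 + 10^(pk - pH))
  charge <- pos_frac(pka$nterm) - neg_frac(pka$cterm)
  for (aa in names(pka$basic)) {
    n <- sum(chars == aa)
    if (n > 0) charge <- charge + n * pos_frac(pka$basic[[aa]])
  }
  for (aa in names(pka$acidic)) {
    n <- sum(chars == aa)
    if (n > 0) charge <- charge - n * neg_frac(pka$acidic[[aa]])
  }
  charge
}

#' Predicted isoelectric point
#'
#' Bisection on pH in [0, 14] down to 1e-8 pH resolution, at which point the
#' net charge magnitude is below `tol` with margin; [net_charge()] is
#' monotone decreasing in pH so the root is unique.
#'
#' @param sequence Amino-acid string.
#' @param tol Guaranteed bound on the residual charge magnitude.
#' @param pka pKa table, see [emboss_pka()].
#' @return pH at which the net charge is zero.
#' @export
#' @examples
#' isoelectric_point("GG")  # 6.10 under the EMBOSS table
isoelectric_point <- function(sequence, tol = 1e-4, pka = emboss_pka()) {
  lo <- 0; hi <- 14
  # bisect to a fixed pH resolution; the charge criterion |q| < tol is then
  # met with margin even on flat charge curves
  while ((hi - lo) > 1e-8) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical properties of a protein set
#'
#' @param proteins Tibble with `id` and `sequence`. Sequences containing `X`
#'   get `NA` mass (with a warning) but still get a pI.
#' @param config [census_config()] list (supplies the pKa table).
#' @return Tibble with `id`, `length`, `mw_kda`, `pi`.
#' @export
#' @examples
#' compute_properties(tibble::tibble(id = "p1", sequence = "MKWVTFISLLLLFSSAYS"))
compute_properties <- function(proteins, config = census_config()) {
  config <- as_census_config(config)
  mw <- map_dbl(proteins$sequence, function(s) {
    if (grepl("X", s, fixed = TRUE)) return(NA_real_)
    molecular_weight(s)
  })
  if (anyNA(mw)) {
    warn("Sequences with X residues: molecular weight reported as NA")
  }
  tibble(
    id = proteins$id,
    length = nchar(proteins$sequence),
    mw_kda = mw / 1000,
    pi = map_dbl(proteins$sequence, isoelectric_point, pka = config$pka)
  )
}
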