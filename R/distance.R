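# Pairwise-deletion p-distances and Poisson correction.

#' Poisson multiple-hit correction
#'
#' `d = -ln(1 - p)` for a proportion of differing amino-acid sites `p`.
#' Saturated pairs (`p >= 1`) have no finite corrected distance and return
#' `NA`.
#'
#' @param p Proportion(s) of differing sites in [0, 1].
#' @return Corrected distance(s); `NA` where undefined.
#' @export
#' @examples
#' poisson_correct(0.5)  # 0.6931
poisson_correct <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(is.na(p) | p >= 1, NA_real_, -log(1 - p))
}

#' Pairwise-deletion p-distances with Poisson correction
#'
#' For each sequence pair, alignment columns where either row carries a gap
#' or an `X` are excluded (pairwise deletion); `p` is the fraction of
#' differing residues over the remaining usable columns and `d = -ln(1-p)`
#' the Poisson-corrected distance. Pairs with zero usable columns or `p >= 1`
#' are flagged undefined and reject tree building.
#'
#' @param alignment Alignment tibble (`id`, `sequence`) with at least 2 rows.
#' @return An object of class `tlp_dist`: list with `labels` and symmetric
#'   matrices `d` (corrected distances), `p`, `usable` (usable-site counts)
#'   and `defined` (logical).
#' @export
pdistance_matrix <- function(alignment) {
  validate_alignment(alignment)
  if (nrow(alignment) < 2) abort("Need at least 2 sequences")
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  miss <- m == "-" | m == "X"
  p <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  usable <- matrix(ncol(m), n, n, dimnames = dimnames(p))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !miss[i, ] & !miss[j, ]
      u <- sum(ok)
      pij <- if (u == 0) NA_real_ else sum(m[i, ok] != m[j, ok]) / u
      p[i, j] <- p[j, i] <- pij
      usable[i, j] <- usable[j, i] <- u
    }
  }
  d <- matrix(poisson_correct(as.vector(p)), n, n, dimnames = dimnames(p))
  diag(d) <- 0
  defined <- !is.na(d)
  structure(
    list(labels = rownames(m), d = d, p = p, usable = usable, defined = defined),
    class = "tlp_dist"
  )
}

#' @export
print.tlp_dist <- function(x, ...) {
  cat("Poisson-corrected distance matrix,", length(x$labels), "sequences\n")
  undef <- sum(!x$defined[upper.tri(x$defined)])
  if (undef > 0) cat(undef, "undefined pair(s)\n")
  print(round(x$d, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tlp_dist <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    item1 = x$labels[idx[, 1]], item2 = x$labels[idx[, 2]],
    p = x$p[idx], usable = x$usable[idx], distance = x$d[idx],
    defined = x$defined[idx]
  )
}

#' @export
as.matrix.tlp_dist <- function(x, ...) x$d

# Coerce matrix-like input to a labelled symmetric matrix.
as_distance_matrix <- function(D) {
  if (inherits(D, "tlp_dist")) {
    if (!all(D$defined[upper.tri(D$defined)])) {
      idx <- which(!D$defined & upper.tri(D$defined), arr.ind = TRUE)
      pairs <- paste0(D$labels[idx[, 1]], "/", D$labels[idx[, 2]])
      abort(paste0("Undefined distance(s) for pair(s): ",
                   paste(pairs, collapse = ", ")))
    }
    return(D$d)
  }
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (anyNA(D)) abort("Distance matrix contains undefined entries")
  D
}
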