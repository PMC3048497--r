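# Conservation scoring on alignments: the five acidic-cleft REDDD residues
# and a coarse per-column conservation code.

REDDD_CANONICAL <- c("R", "E", "D", "D", "D")
# Charge-preserving equivalence classes per cleft position.
REDDD_CLASSES <- list(c("R", "K"), c("D", "E"), c("D", "E"), c("D", "E"), c("D", "E"))

#' Score conservation of the acidic-cleft REDDD residues
#'
#' Maps five ungapped reference positions (the Arg, Glu, Asp, Asp, Asp lining
#' the acidic cleft) to alignment columns through the reference row's gap
#' structure, then scores every row at each column: `identical` when the
#' residue equals the canonical letter, `equivalent` for a charge-preserving
#' swap (R/K at the Arg position, D/E at the acidic positions), otherwise
#' `divergent`. A gap scores `divergent`.
#'
#' @param alignment Alignment tibble (`id`, `sequence`).
#' @param reference_id Row holding the reference (cleft-bearing) sequence.
#' @param reference_positions Five 0-based ungapped residue positions on the
#'   reference sequence.
#' @return An object of class `reddd_report`: list with `columns` (0-based
#'   alignment columns), `scores` (long tibble: `id`, `position`, `column`,
#'   `residue`, `status`) and `summary` (per-id counts plus
#'   `fully_conserved`, true when no position is divergent).
#' @export
reddd_score <- function(alignment, reference_id, reference_positions) {
  validate_alignment(alignment)
  stopifnot(length(reference_positions) == 5)
  if (!reference_id %in% alignment$id) {
    abort(paste0("Reference id '", reference_id, "' not in alignment"))
  }
  m <- alignment_matrix(alignment)
  ref <- m[reference_id, ]
  nongap <- which(ref != "-")
  if (any(reference_positions < 0) || any(reference_positions >= length(nongap))) {
    abort("Reference position outside the ungapped reference sequence")
  }
  cols <- nongap[reference_positions + 1L]  # 1-based matrix columns

  scores <- list_rbind(map(seq_len(nrow(m)), function(r) {
    res <- m[r, cols]
    status <- vapply(1:5, function(p) {
      if (res[p] == "-") return("divergent")
      if (res[p] == REDDD_CANONICAL[p]) return("identical")
      if (res[p] %in% REDDD_CLASSES[[p]]) return("equivalent")
      "divergent"
    }, character(1))
    tibble(
      id = rownames(m)[r], position = 1:5, column = cols - 1L,
      residue = unname(res), status = status
    )
  }))
  summary <- scores |>
    group_by(.data$id) |>
    summarise(
      n_identical = sum(.data$status == "identical"),
      n_equivalent = sum(.data$status == "equivalent"),
      n_divergent = sum(.data$status == "divergent"),
      fully_conserved = .data$n_divergent == 0
    )
  structure(
    list(columns = cols - 1L, scores = scores, summary = summary,
         reference_id = reference_id),
    class = "reddd_report"
  )
}

#' @exportS3Method generics::tidy
tidy.reddd_report <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.reddd_report <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$summary),
    n_fully_conserved = sum(x$summary$fully_conserved),
    reference_id = x$reference_id
  )
}

#' @export
print.reddd_report <- function(x, ...) {
  cat("REDDD conservation report (reference:", x$reference_id, ")\n")
  cat("Columns (0-based):", paste(x$columns, collapse = ", "), "\n")
  cat(sum(x$summary$fully_conserved), "of", nrow(x$summary),
      "sequences carry REDDD or an equivalent at all five positions\n")
  invisible(x)
}

#' Four-level per-column conservation code
#'
#' Bins each alignment column by its count k of distinct non-gap residues:
#' k = 1 gives level 1 (invariant), 2-3 gives 2, 4-6 gives 3, 7+ gives 4
#' (highly variable). All-gap columns give `NA`.
#'
#' @param alignment Alignment tibble (`id`, `sequence`).
#' @return Integer vector of levels, one per column.
#' @export
column_conservation <- function(alignment) {
  m <- alignment_matrix(alignment)
  apply(m, 2, function(col) {
    k <- length(unique(col[col != "-"]))
    if (k == 0) return(NA_integer_)
    if (k == 1) 1L else if (k <= 3) 2L else if (k <= 6) 3L else 4L
  })
}
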