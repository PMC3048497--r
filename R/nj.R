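# Neighbour-Joining (Saitou-Nei) implemented from first principles.
#
# Determinism: when several pairs tie on the minimal Q value, the pair whose
# (sorted) subtree labels are lexicographically smallest is joined, where a
# merged node carries the smallest leaf label of its subtree. Negative branch
# estimates are clamped to zero with the deficit transferred to the sibling
# branch.

#' Build a Neighbour-Joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix: at each step the
#' pair minimizing `Q_ij = (n-2) d_ij - r_i - r_j` is joined, branch lengths
#' come from the two-point formulas, and distances to the new node are
#' `d_uk = (d_ik + d_jk - d_ij) / 2`. The final three nodes are resolved with
#' the three-point formulas, giving an unrooted tree with a basal
#' trifurcation.
#'
#' @param D A `tlp_dist` object (from [pdistance_matrix()]), a symmetric
#'   labelled matrix, or a `dist`. All entries must be defined; `n >= 3`.
#' @param trace Record the Q-selection at every join in the `"q_trace"`
#'   attribute of the result (tibble: step, joined pair, Q value).
#' @return An unrooted `ape::phylo` tree with non-negative branch lengths.
#' @export
#' @examples
#' D <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(D)$edge.length  # 0.05, 0.15, 0.25
nj_tree <- function(D, trace = FALSE) {
  D <- as_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) abort("Neighbour-Joining needs at least 3 taxa")
  labels <- rownames(D)

  # active nodes: newick fragment + smallest leaf label for tie-breaking
  repr <- as.list(labels)
  lab_min <- labels
  trace_rows <- list()
  step <- 0L

  fmt <- function(x) sprintf("%.12g", max(x, 0))

  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(ij) {
        pair <- sort(c(lab_min[ij[1]], lab_min[ij[2]]))
        paste(pair, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    step <- step + 1L
    if (trace) {
      trace_rows[[step]] <- tibble(
        step = step, left = lab_min[i], right = lab_min[j], q = qmin
      )
    }
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_repr <- paste0("(", repr[[i]], ":", fmt(bi), ",",
                       repr[[j]], ":", fmt(bj), ")")
    new_lab <- min(lab_min[i], lab_min[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    D <- D2
    repr <- c(repr[keep], new_repr)
    lab_min <- c(lab_min[keep], new_lab)
  }

  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0(
    "(", repr[[1]], ":", fmt(b1), ",", repr[[2]], ":", fmt(b2), ",",
    repr[[3]], ":", fmt(b3), ");"
  )
  phy <- ape::read.tree(text = newick)
  if (trace) attr(phy, "q_trace") <- list_rbind(trace_rows)
  phy
}
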