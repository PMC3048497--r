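# Clade assignment from anchor leaves.

#' Assign tree leaves to clades defined by anchor sets
#'
#' Each clade is seeded by a set of anchor leaves (reference sequences known
#' to belong to it). The clade comprises the anchors plus every leaf attached
#' to an internal node of the anchors' minimal spanning (Steiner) subtree.
#' When two clades' expansions overlap, the shared leaves are set to
#' `"unplaced"`; leaves claimed by no clade are `"unplaced"` as well.
#'
#' @param tree An `ape::phylo` tree.
#' @param anchors Named list of character vectors of tip labels; sets must be
#'   disjoint and all anchors present in the tree.
#' @return Tibble with columns `leaf` and `clade`.
#' @export
#' @examples
#' phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' assign_clades(phy, list(c1 = c("A", "B"), c2 = c("C", "D")))
assign_clades <- function(tree, anchors) {
  stopifnot(inherits(tree, "phylo"), is.list(anchors), !is.null(names(anchors)))
  tips <- tree$tip.label
  all_anchors <- unlist(anchors)
  missing <- setdiff(all_anchors, tips)
  if (length(missing) > 0) {
    abort(paste0("Anchor leaves not in tree: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(all_anchors)) {
    abort("Anchor sets must be disjoint")
  }
  n <- length(tips)
  edges <- tree$edge

  clade_leaves <- function(anchor_labels) {
    anchor_nodes <- match(anchor_labels, tips)
    if (length(anchor_nodes) == 1) return(anchor_labels)
    # prune non-anchor degree-1 vertices until only the Steiner tree remains
    e <- edges
    repeat {
      deg <- table(factor(c(e[, 1], e[, 2]), levels = seq_len(max(edges))))
      drop <- as.integer(names(deg)[deg == 1])
      drop <- setdiff(drop, anchor_nodes)
      if (length(drop) == 0) break
      e <- e[!(e[, 1] %in% drop | e[, 2] %in% drop), , drop = FALSE]
      if (nrow(e) == 0) break
    }
    internal <- setdiff(unique(c(e[, 1], e[, 2])), seq_len(n))
    attached <- edges[edges[, 1] %in% internal & edges[, 2] <= n, 2]
    sort(unique(c(anchor_labels, tips[attached])))
  }

  sets <- map(anchors, clade_leaves)
  assignment <- setNames(rep("unplaced", n), tips)
  claimed <- table(unlist(sets))
  shared <- names(claimed)[claimed > 1]
  for (nm in names(sets)) {
    ok <- setdiff(sets[[nm]], shared)
    assignment[ok] <- nm
  }
  tibble(leaf = tips, clade = unname(assignment[tips]))
}
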