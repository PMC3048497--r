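# Bootstrap supports for NJ trees by alignment-column resampling.

# Canonical string keys for the non-trivial bipartitions of an unrooted tree.
# Each internal edge splits the leaves in two; the side NOT containing the
# lexicographically smallest label is sorted and collapsed to a key.
tree_bipartitions <- function(phy) {
  n <- length(phy$tip.label)
  pp <- ape::prop.part(phy)
  anchor <- min(phy$tip.label)
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(pp)) {
    tips <- phy$tip.label[pp[[k]]]
    if (length(tips) >= n - 1) next  # root / trivial
    side <- if (anchor %in% tips) setdiff(phy$tip.label, tips) else tips
    if (length(side) < 2 || length(side) > n - 2) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, n + k)
  }
  tibble(node = nodes, key = keys)
}

#' Bootstrap supports for a Poisson-corrected NJ tree
#'
#' Builds the reference tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times; each replicate goes
#' through pairwise-deletion p-distances, Poisson correction and
#' Neighbour-Joining. The support of an internal edge is the fraction of
#' replicates whose tree contains the same leaf bipartition. Replicates in
#' which any pairwise distance is undefined (no usable columns, or p >= 1)
#' cannot support any split; they count against every split and are tallied
#' in the `undefined_replicates` attribute.
#'
#' @param alignment Alignment tibble (`id`, `sequence`).
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed; the same seed reproduces supports bit-identically.
#' @return The reference `ape::phylo` tree with `node.label` holding supports
#'   as fractions in [0, 1] (`""` for the basal node), and attributes
#'   `n_reps`, `undefined_replicates` and `seed`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1) {
  validate_alignment(alignment)
  ref_tree <- nj_tree(pdistance_matrix(alignment))
  bip <- tree_bipartitions(ref_tree)
  counts <- setNames(rep(0L, nrow(bip)), bip$key)
  undefined <- 0L

  m <- alignment_matrix(alignment)
  L <- ncol(m)
  ids <- rownames(m)
  withr::with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(L, L, replace = TRUE)
      sub <- tibble(id = ids, sequence = apply(m[, idx, drop = FALSE], 1, paste, collapse = ""))
      dd <- pdistance_matrix(sub)
      if (!all(dd$defined[upper.tri(dd$defined)])) {
        undefined <- undefined + 1L
        next
      }
      rep_keys <- tree_bipartitions(nj_tree(dd))$key
      hit <- intersect(rep_keys, bip$key)
      counts[hit] <- counts[hit] + 1L
    }
  })

  n_tip <- length(ref_tree$tip.label)
  labels <- rep("", ref_tree$Nnode)
  labels[bip$node - n_tip] <- format(counts[bip$key] / n_reps, digits = 15)
  ref_tree$node.label <- labels
  attr(ref_tree, "n_reps") <- n_reps
  attr(ref_tree, "undefined_replicates") <- undefined
  attr(ref_tree, "seed") <- seed
  ref_tree
}

#' Bipartition supports of a bootstrapped tree as a tibble
#'
#' @param tree Tree returned by [bootstrap_support()].
#' @return Tibble with `key` (the smaller bipartition side, `|`-joined) and
#'   `support` in [0, 1].
#' @export
support_table <- function(tree) {
  bip <- tree_bipartitions(tree)
  n_tip <- length(tree$tip.label)
  bip$support <- as.numeric(tree$node.label[bip$node - n_tip])
  bip[, c("key", "support")]
}
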