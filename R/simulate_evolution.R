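# Sequence evolution along a known tree under a Poisson substitution process.
#
# Per branch of length b, each (unfrozen) site substitutes with probability
# 1 - exp(-b); the new residue is drawn uniformly from the other 19 standard
# amino acids. Along a single branch a substituted site can never revert, so
# two sequences separated by ONE branch of length d differ at a site with
# probability exactly 1 - exp(-d) and the Poisson correction -ln(1-p) is the
# exact inverse. Across a path of several branches, independent per-branch
# draws allow back-substitution: the expected fraction of differing sites at
# path branch lengths b_1..b_k is
#     p = (19/20) * (1 - prod_k lambda(b_k)),  lambda(b) = (20 e^-b - 1)/19,
# the 19/20 factor being the chance that two independently re-drawn residues
# differ. expected_pdiff() and estimate_path_distance() document and invert
# this relation.

#' Expected fraction of differing sites across a path of branches
#'
#' @param branch_lengths Branch lengths along the path between two leaves.
#' @return Expected proportion of differing sites under the generator's
#'   substitution process (uniform redraw over the other 19 residues).
#' @export
#' @examples
#' expected_pdiff(0.5)          # single branch: 1 - exp(-0.5)
#' expected_pdiff(c(0.25, 0.25))  # two branches: slightly less, back-substitution
expected_pdiff <- function(branch_lengths) {
  lam <- (20 * exp(-branch_lengths) - 1) / 19
  (19 / 20) * (1 - prod(lam))
}

#' Invert the expected-p relation to recover a path distance
#'
#' Given an observed fraction of differing sites between two leaves separated
#' by `n_branches` equal-length branches, inverts [expected_pdiff()]'s
#' back-substitution relation. For `n_branches = 1` this reduces to the plain
#' Poisson correction `-ln(1-p)`.
#'
#' @param p Observed proportion of differing sites.
#' @param n_branches Number of equal-length branches on the path.
#' @return Estimated total path distance; `NA` when `p` exceeds the
#'   saturation level `19/20 * (1 - (-1/19)^n)`.
#' @export
estimate_path_distance <- function(p, n_branches = 1) {
  lam_tot <- 1 - 20 * p / 19
  if (lam_tot <= 0) return(NA_real_)
  lam_b <- lam_tot^(1 / n_branches)
  -n_branches * log((19 * lam_b + 1) / 20)
}

substitute_sites <- function(chars, b, frozen) {
  if (b <= 0) return(chars)
  hit <- which(runif(length(chars)) < (1 - exp(-b)))
  hit <- setdiff(hit, frozen)
  if (length(hit) == 0) return(chars)
  cur <- match(chars[hit], AA_STANDARD)
  r <- sample.int(19L, length(hit), replace = TRUE)
  chars[hit] <- AA_STANDARD[r + (r >= cur)]
  chars
}

#' Evolve a gap-free alignment along a tree
#'
#' Simulates leaf sequences from a root sequence along a tree's branches
#' under the Poisson substitution process described above. Frozen positions
#' (e.g. structural cysteines or the REDDD residues) never change, so they
#' come out identical across rows.
#'
#' @param tree An `ape::phylo` tree with branch lengths (rooted trees are
#'   simulated from their root; unrooted trees from the basal node).
#' @param root Root amino-acid sequence, or `NULL` to draw `n_columns`
#'   residues uniformly from the 20 standard letters.
#' @param n_columns Number of columns when `root` is drawn.
#' @param freeze Integer vector of frozen column indices (1-based).
#' @param seed Integer seed; output is bit-reproducible.
#' @return Alignment tibble (`id`, `sequence`) with one row per tip, carrying
#'   the tree and root as attributes `"tree"` and `"root"`.
#' @export
#' @examples
#' phy <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.2);")
#' aln <- evolve_alignment(phy, n_columns = 100, seed = 1)
evolve_alignment <- function(tree, root = NULL, n_columns = 1000,
                             freeze = integer(0), seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0))
  withr::with_seed(seed, {
    root_chars <- if (is.null(root)) {
      sample(AA_STANDARD, n_columns, replace = TRUE)
    } else {
      strsplit(toupper(root), "", fixed = TRUE)[[1]]
    }
    stopifnot(all(root_chars %in% AA_STANDARD))
    n_tip <- length(tree$tip.label)
    root_node <- n_tip + 1L
    phy <- ape::reorder.phylo(tree, "cladewise")
    seqs <- vector("list", max(phy$edge))
    seqs[[root_node]] <- root_chars
    for (e in seq_len(nrow(phy$edge))) {
      parent <- phy$edge[e, 1]
      child <- phy$edge[e, 2]
      seqs[[child]] <- substitute_sites(seqs[[parent]], phy$edge.length[e], freeze)
    }
    aln <- tibble(
      id = phy$tip.label,
      sequence = map_chr(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""))
    )
    attr(aln, "tree") <- tree
    attr(aln, "root") <- paste(root_chars, collapse = "")
    aln
  })
}
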