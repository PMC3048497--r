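# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations: character-by-character loops, per-base
# boolean arrays, grid searches, exhaustive topology enumeration.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Character-by-character sliding-window matcher for the two boundary motifs.
# Returns 0-based start positions, like scan_boundary_motifs().
brute_force_motifs <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  std <- function(ch) ch %in% AA20
  n_hits <- integer(0)
  for (i in seq_len(max(n - 7, 0))) {
    w <- chars[i:(i + 7)]
    if (w[1] == "N" && std(w[2]) && w[3] == "C" && std(w[4]) && std(w[5]) &&
        std(w[6]) && w[7] %in% c("V", "I") && w[8] == "W") {
      n_hits <- c(n_hits, i - 1L)
    }
  }
  c_hits <- integer(0)
  for (i in seq_len(max(n - 6, 0))) {
    w <- chars[i:(i + 6)]
    if (w[1] == "Y" && std(w[2]) && w[3] %in% c("I", "V") && std(w[4]) &&
        w[5] == "F" && w[6] == "C" && std(w[7])) {
      c_hits <- c(c_hits, i - 1L)
    }
  }
  list(n = n_hits, c = c_hits)
}

# Two-stage pH grid search for the isoelectric point: a 1e-3 coarse pass
# brackets the unique zero crossing (net charge is monotone in pH), then a
# 1e-5 grid resolves it. Effective resolution 1e-5.
grid_search_pi <- function(sequence, pka = emboss_pka()) {
  coarse <- seq(0, 14, by = 1e-3)
  qc <- net_charge(sequence, coarse, pka)
  k <- which.min(abs(qc))
  lo <- max(coarse[k] - 2e-3, 0)
  hi <- min(coarse[k] + 2e-3, 14)
  fine <- seq(lo, hi, by = 1e-5)
  qf <- net_charge(sequence, fine, pka)
  fine[which.min(abs(qf))]
}

# Per-base boolean-array union length on a bounded window.
per_base_union <- function(intervals, limit = 10000) {
  covered <- logical(limit)
  for (k in seq_len(nrow(intervals))) {
    covered[(intervals$start[k] + 1):intervals$end[k]] <- TRUE
  }
  sum(covered)
}

random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Additive distance matrix of a tree (the path-length metric between tips).
tree_distances <- function(phy) {
  ape::cophenetic.phylo(phy)
}

# Random tree with branch lengths in [0.01, 1].
random_tree <- function(n_tips) {
  phy <- ape::rtree(n_tips, rooted = FALSE)
  phy$edge.length <- runif(nrow(phy$edge), 0.01, 1)
  phy
}

# Ordinary least-squares fit of branch lengths for a fixed topology against
# a distance matrix; returns the residual sum of squares.
ls_topology_rss <- function(phy, D) {
  tips <- phy$tip.label
  n <- length(tips)
  pairs <- t(combn(n, 2))
  n_edge <- nrow(phy$edge)
  X <- matrix(0, nrow(pairs), n_edge)
  y <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    path_nodes <- ape::nodepath(phy, i, j)
    for (s in seq_len(length(path_nodes) - 1)) {
      a <- path_nodes[s]; b <- path_nodes[s + 1]
      e <- which((phy$edge[, 1] == a & phy$edge[, 2] == b) |
                 (phy$edge[, 1] == b & phy$edge[, 2] == a))
      X[r, e] <- 1
    }
    y[r] <- D[tips[i], tips[j]]
  }
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

# Exhaustively score every unrooted topology on n tips, return the best.
ls_best_topology <- function(D) {
  labels <- rownames(D)
  topos <- phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels)
  rss <- vapply(topos, ls_topology_rss, numeric(1), D = D)
  topos[[which.min(rss)]]
}

make_temp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}
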