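# Distances, Neighbour-Joining, bootstrap, clade assignment.

test_that("pairwise deletion excludes gap and X columns per pair", {
  aln <- tibble::tibble(id = c("a", "b"), sequence = c("ACDE", "ACDE"))
  expect_equal(pdistance_matrix(aln)$p["a", "b"], 0)

  aln <- tibble::tibble(id = c("a", "b"), sequence = c("ACDE", "ACDF"))
  expect_equal(pdistance_matrix(aln)$p["a", "b"], 0.25)

  aln <- tibble::tibble(id = c("a", "b"), sequence = c("A-DE", "ACDF"))
  d <- pdistance_matrix(aln)
  expect_equal(d$p["a", "b"], 1 / 3)
  expect_equal(d$usable["a", "b"], 3)

  aln <- tibble::tibble(id = c("a", "b"), sequence = c("AXDE", "ACDF"))
  expect_equal(pdistance_matrix(aln)$usable["a", "b"], 3)
})

test_that("saturated or empty pairs are flagged undefined and block NJ", {
  aln <- tibble::tibble(id = c("a", "b", "c"),
                        sequence = c("AAAA", "CCCC", "AACC"))
  d <- pdistance_matrix(aln)
  expect_false(d$defined["a", "b"])  # p = 1
  expect_error(nj_tree(d), "Undefined.*a/b")

  aln <- tibble::tibble(id = c("a", "b"), sequence = c("--", "AA"))
  expect_false(pdistance_matrix(aln)$defined["a", "b"])  # zero usable sites
})

test_that("Poisson correction matches its closed form", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), 0.693147, tolerance = 1e-6)
  expect_equal(poisson_correct(0.95), 2.995732, tolerance = 1e-6)
  expect_true(is.na(poisson_correct(1)))
})

test_that("three-taxon NJ reproduces the three-point formulas", {
  D <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- nj_tree(D)
  bl <- setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.05, B = 0.15, C = 0.25))
})

test_that("NJ recovers additive trees exactly", {
  set.seed(11)
  for (i in 1:60) {
    true <- random_tree(sample(4:8, 1))
    D <- tree_distances(true)
    est <- nj_tree(D)
    expect_equal(phangorn::RF.dist(est, true), 0)
    expect_lt(max(abs(tree_distances(est)[rownames(D), colnames(D)] - D)), 1e-9)
  }
})

test_that("NJ agrees with exhaustive least-squares search on perturbed matrices", {
  set.seed(12)
  n_match <- 0
  n_runs <- 40
  for (i in seq_len(n_runs)) {
    true <- random_tree(5)
    # guarantee a safely resolvable internal branch
    internal <- true$edge[, 2] > length(true$tip.label)
    true$edge.length[internal] <- pmax(true$edge.length[internal], 0.15)
    D <- tree_distances(true)
    noise <- matrix(rnorm(25, 0, 0.01), 5)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    Dp <- pmax(D + noise, 0.001)
    Dp <- (Dp + t(Dp)) / 2; diag(Dp) <- 0
    est <- nj_tree(Dp, trace = TRUE)
    best <- ls_best_topology(Dp)
    if (phangorn::RF.dist(est, best) == 0) {
      n_match <- n_match + 1
    } else {
      expect_s3_class(attr(est, "q_trace"), "tbl_df")  # trace emitted for inspection
    }
  }
  expect_gte(n_match / n_runs, 0.95)
})

test_that("Q-selection ties break deterministically on label order", {
  # perfectly symmetric 4-taxon matrix: every pair ties
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- nj_tree(D, trace = TRUE)
  t2 <- nj_tree(D, trace = TRUE)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(attr(t1, "q_trace")$left[1], "a")
  expect_equal(attr(t1, "q_trace")$right[1], "b")
})

test_that("distances estimated from simulated alignments converge to truth", {
  # single branch: p differs with probability exactly 1 - exp(-d)
  tr <- ape::read.tree(text = "(A:0.5,B:0);")
  aln <- evolve_alignment(tr, n_columns = 10000, seed = 31)
  d <- pdistance_matrix(aln)
  expect_lt(abs(d$d["A", "B"] - 0.5), 0.05)
})

test_that("bootstrap is reproducible and calibrated on a clean signal", {
  tr <- ape::read.tree(
    text = "((A:0.1,B:0.1):0.4,(C:0.1,D:0.1):0.4,(E:0.1,F:0.1):0.4);"
  )
  aln <- evolve_alignment(tr, n_columns = 2000, seed = 17)
  bt1 <- bootstrap_support(aln, n_reps = 100, seed = 99)
  bt2 <- bootstrap_support(aln, n_reps = 100, seed = 99)
  expect_identical(bt1$node.label, bt2$node.label)
  expect_identical(ape::write.tree(bt1), ape::write.tree(bt2))

  st <- support_table(bt1)
  expect_true(all(st$support >= 0 & st$support <= 1))
  # long internal branches: every true split strongly supported
  expect_true(all(st$support >= 0.95))
  expect_equal(phangorn::RF.dist(bt1, tr), 0)
  expect_equal(attr(bt1, "undefined_replicates"), 0)
})

test_that("identical sequences give a star with no supported splits", {
  aln <- tibble::tibble(id = letters[1:4], sequence = rep(strrep("ACDE", 5), 4))
  tr <- nj_tree(pdistance_matrix(aln))
  expect_true(all(tr$edge.length < 1e-12))
})

test_that("clade assignment matches hand-traced anchor expansions", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # singleton anchors claim only themselves
  cl <- assign_clades(phy, list(c1 = "A", c2 = "C"))
  expect_equal(cl$clade, c("c1", "unplaced", "c2", "unplaced"))
  # full anchor pairs give the bipartition
  cl <- assign_clades(phy, list(c1 = c("A", "B"), c2 = c("C", "D")))
  expect_equal(cl$clade, c("c1", "c1", "c2", "c2"))
  # anchors spanning the central path absorb everything attached to it
  cl <- assign_clades(phy, list(c1 = c("A", "C")))
  expect_equal(cl$clade, rep("c1", 4))
})

test_that("overlapping clade expansions yield unplaced leaves", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(assign_clades(phy, list(c1 = "Z")), "not in tree")
  expect_error(assign_clades(phy, list(c1 = "A", c2 = "A")), "disjoint")
  cl <- assign_clades(phy, list(c1 = c("A", "C"), c2 = c("B", "D")))
  # both expansions cover all leaves: everything contested, hence unplaced
  expect_true(all(cl$clade == "unplaced"))
})
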