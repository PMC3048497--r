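# Interval unions, TE coverage, tandem clusters, exon profiles.

test_that("interval union merges overlaps", {
  expect_equal(interval_union_length(data.frame(start = c(0, 5), end = c(10, 15))), 15)
  expect_equal(interval_union_length(data.frame(start = integer(0), end = integer(0))), 0L)
  expect_error(interval_union_length(data.frame(start = 5, end = 5)), "start >= end")
})

test_that("interval union equals the per-base boolean oracle", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    start <- sample(0:9900, n, replace = TRUE)
    len <- sample(1:100, n, replace = TRUE)
    df <- data.frame(start = start, end = pmin(start + len, 10000))
    expect_equal(interval_union_length(df), per_base_union(df))
  }
})

test_that("TE coverage clips, unions per class and totals correctly", {
  region <- list(chrom = "chr1", start = 0, end = 1000)
  rep1 <- tibble::tibble(chrom = "chr1", start = 0, end = 500,
                         te_class = "LTR_Gypsy", family = "g")
  cov <- te_coverage(region, rep1)
  expect_equal(cov$per_class$fraction[cov$per_class$te_class == "LTR_Gypsy"], 0.5)
  expect_equal(cov$total_fraction, 0.5)

  rep2 <- tibble::tibble(
    chrom = "chr1", start = c(0, 400), end = c(600, 800),
    te_class = c("LTR_Gypsy", "DNA_transposon"), family = c("g", "d")
  )
  cov <- te_coverage(region, rep2)
  pc <- setNames(cov$per_class$fraction, cov$per_class$te_class)
  expect_equal(unname(pc["LTR_Gypsy"]), 0.6)
  expect_equal(unname(pc["DNA_transposon"]), 0.4)
  expect_equal(cov$total_fraction, 0.8)  # union, not sum

  # repeats extending past the region are clipped
  rep3 <- tibble::tibble(chrom = "chr1", start = -200, end = 1400,
                         te_class = "other", family = "o")
  expect_equal(te_coverage(region, rep3)$total_fraction, 1)
})

test_that("enrichment is the plain ratio over supplied background", {
  region <- list(chrom = "chr1", start = 0, end = 1000)
  rep1 <- tibble::tibble(chrom = "chr1", start = 0, end = 370,
                         te_class = "LTR_Gypsy", family = "g")
  cov <- te_coverage(region, rep1, background = c(LTR_Gypsy = 0.05))
  e <- cov$per_class$enrichment[cov$per_class$te_class == "LTR_Gypsy"]
  expect_equal(e, 0.37 / 0.05)
})

test_that("cluster detection follows the gap rule", {
  genes <- tibble::tibble(
    gene_id = c("f1", "f2", "f3"), chrom = "chr1",
    start = c(0, 10000, 20000), end = c(1000, 11000, 21000),
    family = TRUE
  )
  cl <- find_clusters(genes, gap_bp = 100000, min_size = 3)
  expect_equal(cl$size, 3)
  expect_equal(cl$span_bp, 21000)
  expect_true(cl$exclusive)

  far <- tibble::tibble(
    gene_id = c("f1", "f2"), chrom = "chr1",
    start = c(0, 1e6 + 1000), end = c(1000, 1e6 + 2000), family = TRUE
  )
  expect_equal(nrow(find_clusters(far, min_size = 2)), 0)
})

test_that("an interleaved non-family gene breaks exclusivity, not the cluster", {
  genes <- tibble::tibble(
    gene_id = c("f1", "x1", "f2", "f3"), chrom = "chr1",
    start = c(0, 2000, 10000, 20000), end = c(1000, 3000, 11000, 21000),
    family = c(TRUE, FALSE, TRUE, TRUE)
  )
  cl <- find_clusters(genes)
  expect_equal(cl$size, 3)
  expect_false(cl$exclusive)
  expect_equal(cl$members[[1]], c("f1", "f2", "f3"))
})

test_that("clusters are invariant under input order and strand", {
  loc <- generate_locus(seed = 4, n_other = 2)
  tf <- tempfile(fileext = ".gff3")
  writeLines(loc$gff, tf)
  genes <- read_gff3(tf, family_ids = loc$family_ids)
  ref <- find_clusters(genes)
  shuf <- genes[rev(seq_len(nrow(genes))), ]
  shuf$strand <- "-"
  expect_equal(find_clusters(shuf), ref)
})

test_that("generator loci are recovered exactly: members, span, exclusivity", {
  for (seed in c(1, 6)) {
    interleave <- seed == 6
    loc <- generate_locus(seed = seed, interleave_other = interleave)
    tf <- tempfile(fileext = ".gff3")
    writeLines(loc$gff, tf)
    genes <- read_gff3(tf, family_ids = loc$family_ids)
    cl <- find_clusters(genes)
    expect_equal(nrow(cl), 1)
    expect_equal(cl$members[[1]], loc$truth$cluster_members)
    expect_equal(cl$start, loc$truth$cluster_start)
    expect_equal(cl$end, loc$truth$cluster_end)
    expect_equal(cl$span_bp, loc$truth$span_bp)
    expect_equal(cl$exclusive, loc$truth$exclusive)
  }
})

test_that("a locus planted at 52% total and 37% Gypsy reports those exactly", {
  loc <- generate_locus(seed = 1)
  region <- list(chrom = loc$truth$chrom, start = loc$truth$cluster_start,
                 end = loc$truth$cluster_end)
  cov <- te_coverage(region, loc$repeats)
  expect_identical(cov$total_fraction, 0.52)
  gypsy <- cov$per_class$fraction[cov$per_class$te_class == "LTR_Gypsy"]
  expect_identical(gypsy, 0.37)
  # and the total equals the union of all clipped repeats
  expect_equal(cov$total_bp, interval_union_length(loc$repeats))
})

test_that("exon profiles are literal counts", {
  loc <- generate_locus(n_cluster = 3, span_bp = 60000,
                        exon_counts = c(1, 2, 3), seed = 8)
  tf <- tempfile(fileext = ".gff3")
  writeLines(loc$gff, tf)
  genes <- read_gff3(tf, family_ids = loc$family_ids)
  prof <- exon_count_profile(genes[genes$family, ])
  expect_equal(prof$n_exons, c(1L, 2L, 3L))
})
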