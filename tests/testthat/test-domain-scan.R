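# Boundary-motif scanning, domain extraction and completeness filtering.

test_that("scan_boundary_motifs finds planted motifs at exact offsets", {
  hits <- scan_boundary_motifs("AAANQCKLMVWAAA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$kind, "N")
  expect_equal(hits$start, 3)
  expect_equal(hits$match, "NQCKLMVW")

  expect_equal(nrow(scan_boundary_motifs("AAAA")), 0)

  hits <- scan_boundary_motifs("YAIAFCKAAA")
  expect_equal(hits$kind, "C")
  expect_equal(hits$start, 0)
})

test_that("wildcard positions reject the ambiguity letter X", {
  expect_equal(nrow(scan_boundary_motifs("NXCKLMVW")), 0)
  expect_equal(nrow(scan_boundary_motifs("NACKLMVW")), 1)
})

test_that("scanner agrees with a brute-force matcher on random sequences", {
  set.seed(41)
  for (i in 1:300) {
    s <- random_protein(sample(30:80, 1))
    # plant a motif in a third of the cases
    if (i %% 3 == 0) {
      pos <- sample(nchar(s) - 8, 1)
      motif <- if (i %% 2 == 0) "NACDEFVW" else "YAIAFCK"
      substr(s, pos, pos + nchar(motif) - 1) <- motif
    }
    oracle <- brute_force_motifs(s)
    hits <- scan_boundary_motifs(s)
    expect_identical(hits$start[hits$kind == "N"], oracle$n)
    expect_identical(hits$start[hits$kind == "C"], oracle$c)
  }
})

test_that("extracted boundaries equal planted boundaries on generator output", {
  for (arch in c("typical", "small", "tlp_kinase", "small_tlp_kinase")) {
    for (seed in c(1, 19, 203)) {
      p <- generate_protein(arch, seed = seed)
      dom <- extract_domain(p$record$sequence)
      expect_equal(dom$start, p$truth$domain_start)
      expect_equal(dom$end, p$truth$domain_end)
      expect_equal(dom$n_cysteines, p$truth$n_cys)
      expect_true(dom$complete)
    }
  }
})

test_that("a protein that is exactly its domain has coverage 1", {
  p <- generate_protein("typical", seed = 8)
  core <- substr(p$record$sequence, p$truth$domain_start + 1, p$truth$domain_end)
  dom <- extract_domain(core)
  expect_equal(dom$coverage, 1.0)
  expect_equal(dom$start, 0)
})

test_that("among multiple motif pairs the longest in-bounds domain wins", {
  # two N hits, one C hit; enumerated by hand: pairs give lengths 215 and 185
  p <- generate_protein("typical", seed = 13)
  s <- p$record$sequence
  extra_at <- p$truth$domain_start + 30
  substr(s, extra_at + 1, extra_at + 8) <- "NACDEFVW"
  dom <- extract_domain(s)
  expect_equal(dom$start, p$truth$domain_start)  # leftmost N = longest
  expect_equal(dom$end - dom$start, 215)
})

test_that("validate_complete enumerates every failed criterion", {
  ok <- validate_complete(215, 16, TRUE, TRUE)
  expect_true(ok$complete)
  expect_length(ok$reasons, 0)

  v <- validate_complete(NA, 0, TRUE, FALSE)
  expect_false(v$complete)
  expect_match(v$reasons, "missing C-terminal motif")

  v <- validate_complete(215, 6, TRUE, TRUE)
  expect_false(v$complete)
  expect_match(v$reasons, "too few cysteines \\(6 < 8\\)")

  v <- validate_complete(80, 6, TRUE, TRUE)
  expect_length(v$reasons, 2)
})

test_that("a scaffold truncated before the C-motif is incomplete", {
  p <- generate_protein("typical", seed = 4)
  s <- substr(p$record$sequence, 1, p$truth$c_motif[1] - 3)
  res <- scan_domains(tibble::tibble(id = "trunc", sequence = s))
  expect_false(res$complete)
  expect_true("missing C-terminal motif" %in% res$failure_reasons[[1]])
})

test_that("completeness is monotone in the filter thresholds", {
  set.seed(7)
  for (arch in c("typical", "small")) {
    p <- generate_protein(arch, seed = sample(1000, 1))
    res <- scan_domains(p$record)
    relaxed <- scan_domains(p$record, census_config(
      domain_min_len = 60, domain_max_len = 500, domain_min_cys = 2
    ))
    # relaxing bounds never turns complete into incomplete
    expect_true(!res$complete || relaxed$complete)
  }
})
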