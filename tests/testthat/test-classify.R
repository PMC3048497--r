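# Architecture classification, kinase/TM detection, conservation scoring.

test_that("kinase detector finds the planted triad and catalytic aspartates", {
  p <- generate_protein("tlp_kinase", seed = 2)
  kin <- detect_kinase_domain(p$record$sequence,
                              offset = p$truth$domain_end)
  expect_equal(kin$start, p$truth$kinase_start)
  expect_equal(kin$catalytic_asp_positions, p$truth$asp_positions)
})

test_that("kinase motifs out of order or absent give no region", {
  expect_null(detect_kinase_domain(generate_protein("typical", 3)$record$sequence))
  # triad present but D-x-G precedes H-x-D: spacing windows cannot be met
  s <- paste0(
    "GAGAAG", strrep("A", 94), "DFG", strrep("A", 27), "HRD", strrep("A", 250)
  )
  expect_null(detect_kinase_domain(s))
})

test_that("TM detection follows Kyte-Doolittle window arithmetic", {
  # 19 Ile in a polar context: window mean 4.5 >= 1.6
  s <- paste0(strrep("D", 25), strrep("I", 19), strrep("D", 25))
  tm <- detect_tm_segment(s)
  expect_equal(tm$start, 25)
  expect_equal(tm$end, 44)
  expect_equal(tm$mean_hydropathy, 4.5)

  expect_null(detect_tm_segment(strrep("D", 60)))  # mean -3.5
  expect_null(detect_tm_segment("ILVF"))           # shorter than window
})

test_that("the fusion TM segment lies strictly between domain and kinase", {
  p <- generate_protein("small_tlp_kinase", seed = 6)
  tm <- detect_tm_segment(p$record$sequence,
                          from = p$truth$domain_end, to = p$truth$kinase_start)
  expect_equal(tm$start, p$truth$tm_start)
  expect_equal(tm$end, p$truth$tm_end)
  expect_gte(tm$start, p$truth$domain_end)
  expect_lte(tm$end, p$truth$kinase_start)
})

test_that("classifier returns the intended label for every architecture", {
  archs <- c("typical", "small", "tlp_kinase", "small_tlp_kinase")
  for (arch in archs) {
    for (seed in c(2, 77)) {
      p <- generate_protein(arch, seed = seed)
      cl <- classify_tlps(p$record)
      expect_equal(cl$label, arch)
    }
  }
  # typical ~215 aa / 16 Cys; small ~150 aa / 10 Cys
  cl <- classify_tlps(generate_protein("typical", 1)$record)
  expect_equal(cl$domain_len, 215)
  expect_equal(cl$n_cys, 16)
  cl <- classify_tlps(generate_protein("small", 1)$record)
  expect_equal(cl$domain_len, 150)
  expect_equal(cl$n_cys, 10)
})

test_that("classification is deterministic and order-invariant", {
  set <- generate_protein_set(c(typical = 3, small = 2, tlp_kinase = 2), seed = 9)
  a <- classify_tlps(set$proteins)
  b <- classify_tlps(set$proteins[sample(nrow(set$proteins)), ])
  b <- b[match(a$id, b$id), ]
  expect_equal(a$label, b$label)
  expect_equal(a$domain_start, b$domain_start)
})

test_that("proteins without a complete domain are labelled incomplete", {
  cl <- classify_tlps(tibble::tibble(id = "junk", sequence = strrep("A", 300)))
  expect_equal(cl$label, "incomplete")
})

test_that("an off-band cysteine count flags atypical evidence", {
  p <- generate_protein("typical", seed = 11, n_cys = 13)
  cl <- classify_tlps(p$record)
  expect_equal(cl$label, "typical")
  expect_true(cl$atypical_cys)
})

test_that("REDDD scoring maps reference positions through gaps", {
  aln <- tibble::tibble(
    id = c("ref", "same", "equiv", "diver"),
    sequence = c("AR-EDDDA", "AR-EDDDA", "AK-EDDEA", "AG-EDD-A")
  )
  rep <- reddd_score(aln, "ref", c(1, 2, 3, 4, 5))
  expect_equal(rep$columns, c(1, 3, 4, 5, 6))
  sc <- tidy(rep)
  expect_true(all(sc$status[sc$id == "same"] == "identical"))
  expect_equal(sc$status[sc$id == "equiv" & sc$position == 1], "equivalent")  # K at R
  expect_equal(sc$status[sc$id == "equiv" & sc$position == 5], "equivalent")  # E at D
  expect_equal(sc$status[sc$id == "diver" & sc$position == 1], "divergent")   # G at R
  expect_equal(sc$status[sc$id == "diver" & sc$position == 5], "divergent")   # gap
  expect_equal(sum(rep$summary$fully_conserved), 3)
})

test_that("REDDD of an alignment against itself is all-identical", {
  p <- generate_protein("typical", seed = 21)
  core <- substr(p$record$sequence, p$truth$domain_start + 1, p$truth$domain_end)
  aln <- tibble::tibble(id = c("a", "b"), sequence = c(core, core))
  rep <- reddd_score(aln, "a", p$truth$reddd_pos - p$truth$domain_start)
  expect_true(all(tidy(rep)$status == "identical"))
  expect_equal(unique(tidy(rep)$residue[order(tidy(rep)$position)]),
               c("R", "E", "D"))
})

test_that("REDDD errors on a bad reference", {
  aln <- tibble::tibble(id = c("a", "b"), sequence = c("ARED", "ARED"))
  expect_error(reddd_score(aln, "zz", c(0, 1, 2, 3, 3)), "not in alignment")
  expect_error(reddd_score(aln, "a", c(0, 1, 2, 3, 9)), "outside")
})

test_that("column conservation bins distinct-residue counts into 4 levels", {
  aln <- tibble::tibble(
    id = paste0("s", 1:8),
    sequence = c("CAAA", "CAGC", "CGDD", "CSEE", "CAFF", "CAGG", "CAGH", "CAII")
  )
  lev <- column_conservation(aln)
  expect_equal(lev[1], 1L)  # all C
  expect_equal(lev[2], 2L)  # {A,G,S}: 3 distinct
  expect_equal(lev[3], 3L)  # {A,G,D,E,F,I}: 6 distinct
  expect_equal(lev[4], 4L)  # 8 distinct
  expect_equal(
    column_conservation(tibble::tibble(id = c("a", "b"), sequence = c("-", "-"))),
    NA_integer_
  )
})
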