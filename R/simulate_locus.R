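# Synthetic genomic locus generator: a tandem family array with interleaved
# transposable-element intervals hitting planned coverage fractions exactly.

# GFF3 lines (1-based closed) for one gene with evenly split exons.
gene_gff_lines <- function(chrom, gene_id, start0, gene_len, n_exons, strand = "+") {
  # exons of equal length separated by fixed 300-bp introns
  intron <- if (n_exons > 1) 300L else 0L
  exon_len <- (gene_len - (n_exons - 1L) * intron) %/% n_exons
  rem <- gene_len - (n_exons - 1L) * intron - n_exons * exon_len
  lens <- rep(exon_len, n_exons)
  lens[n_exons] <- lens[n_exons] + rem
  starts <- start0 + c(0L, cumsum(head(lens, -1) + intron))
  g1 <- start0 + 1L
  g2 <- start0 + gene_len
  lines <- c(
    sprintf("%s\ttlpcensus\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, g1, g2, strand, gene_id),
    sprintf("%s\ttlpcensus\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
            chrom, g1, g2, strand, gene_id, gene_id)
  )
  for (k in seq_len(n_exons)) {
    e1 <- starts[k] + 1L
    e2 <- starts[k] + lens[k]
    lines <- c(
      lines,
      sprintf("%s\ttlpcensus\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.exon%d;Parent=%s.1",
              chrom, e1, e2, strand, gene_id, k, gene_id),
      sprintf("%s\ttlpcensus\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds%d;Parent=%s.1",
              chrom, e1, e2, strand, gene_id, k, gene_id)
    )
  }
  lines
}

#' Generate a synthetic genomic locus with a tandem family cluster
#'
#' Builds GFF3 text for a chromosome carrying a tandem array of family genes
#' spanning exactly `span_bp` (first gene start to last gene end), optional
#' far-away singleton family genes and non-family genes, and a repeat table
#' whose per-class coverage of the cluster span matches `te_fractions`
#' exactly (disjoint intervals laid down in alternating slots). Defaults
#' mirror a rosid-style TLP cluster: 11 two-exon family genes in 350 kb with
#' Gypsy retrotransposons at 37% and DNA transposons at 15% coverage (52%
#' total).
#'
#' @param n_cluster Number of family genes in the tandem cluster.
#' @param span_bp Cluster span from first gene start to last gene end.
#' @param exon_counts Exon count per cluster gene (recycled).
#' @param n_singletons Family genes placed far outside the cluster.
#' @param n_other Non-family genes placed outside the cluster.
#' @param interleave_other Insert one non-family gene inside the cluster span
#'   (makes the cluster non-exclusive).
#' @param te_fractions Named fractions of the cluster span to cover per TE
#'   class; the sum must not exceed 1.
#' @param chrom Chromosome name.
#' @param seed Integer seed (recorded; the layout is deterministic).
#' @return List with `gff` (character vector of GFF3 lines), `repeats`
#'   (repeat tibble), `family_ids`, and `truth` (planted cluster membership,
#'   span, exclusivity, exon counts, and exact per-class/total coverage
#'   fractions of the span).
#' @export
#' @examples
#' loc <- generate_locus()
#' loc$truth$te_total_fraction
generate_locus <- function(n_cluster = 11, span_bp = 350000,
                           exon_counts = 2, n_singletons = 0, n_other = 2,
                           interleave_other = FALSE,
                           te_fractions = c(LTR_Gypsy = 0.37, DNA_transposon = 0.15),
                           chrom = "chr1", seed = 1) {
  stopifnot(n_cluster >= 2, span_bp > 0)
  bad <- setdiff(names(te_fractions), TE_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("Unknown te_class in te_fractions: ", paste(bad, collapse = ", ")))
  }
  if (sum(te_fractions) > 1) {
    abort("Infeasible te_fractions: sum exceeds 1")
  }
  gene_len <- 1500L
  region_start <- 100000L
  region_end <- region_start + as.integer(span_bp)
  gap <- (span_bp - n_cluster * gene_len) %/% (n_cluster - 1L)
  starts <- region_start + (seq_len(n_cluster) - 1L) * (gene_len + gap)
  starts[n_cluster] <- region_end - gene_len  # last gene end == span end
  exon_counts <- rep_len(exon_counts, n_cluster)

  family_ids <- sprintf("FAM%02d", seq_len(n_cluster))
  gff <- c("##gff-version 3")
  for (i in seq_len(n_cluster)) {
    gff <- c(gff, gene_gff_lines(chrom, family_ids[i], starts[i], gene_len,
                                 exon_counts[i]))
  }
  if (interleave_other) {
    mid <- starts[1] + gene_len + max((gap - gene_len) %/% 2, 10L)
    gff <- c(gff, gene_gff_lines(chrom, "OTHER00", mid, 1000L, 1L))
  }
  sing_ids <- character(0)
  if (n_singletons > 0) {
    sing_ids <- sprintf("FAMS%02d", seq_len(n_singletons))
    for (k in seq_len(n_singletons)) {
      gff <- c(gff, gene_gff_lines(chrom, sing_ids[k],
                                   region_end + 500000L + k * 300000L,
                                   gene_len, 1L))
    }
  }
  if (n_other > 0) {
    for (k in seq_len(n_other)) {
      gff <- c(gff, gene_gff_lines(chrom, sprintf("OTH%02d", k),
                                   region_end + 200000L + k * 250000L,
                                   1000L, 3L))
    }
  }

  # TE intervals: partition the span into 2 * n_slots slots and drop each
  # class's chunks into its own slots, so classes are disjoint and coverage
  # of the span is exact.
  n_slots_per_class <- 10L
  classes <- names(te_fractions)
  n_slots <- max(length(classes) * n_slots_per_class, 1L)
  slot <- span_bp %/% n_slots
  rep_rows <- list()
  for (ci in seq_along(classes)) {
    bp_target <- round(te_fractions[[ci]] * span_bp)
    chunk <- bp_target %/% n_slots_per_class
    rem <- bp_target - chunk * n_slots_per_class
    for (s in seq_len(n_slots_per_class)) {
      len <- chunk + if (s == 1L) rem else 0L
      if (len <= 0) next
      if (len > slot) abort("Infeasible te_fractions: chunk exceeds slot size")
      slot_start <- region_start + ((s - 1L) * length(classes) + (ci - 1L)) * slot
      rep_rows[[length(rep_rows) + 1]] <- tibble(
        chrom = chrom, start = as.integer(slot_start),
        end = as.integer(slot_start + len),
        te_class = classes[ci], family = sprintf("%s_synth", classes[ci])
      )
    }
  }
  repeats <- if (length(rep_rows) > 0) list_rbind(rep_rows) else {
    tibble(chrom = character(0), start = integer(0), end = integer(0),
           te_class = character(0), family = character(0))
  }

  cov_bp <- vapply(TE_CLASSES, function(cl) {
    as.numeric(interval_union_length(repeats[repeats$te_class == cl, ]))
  }, numeric(1))
  truth <- list(
    chrom = chrom,
    cluster_members = family_ids,
    cluster_start = region_start, cluster_end = region_end,
    span_bp = as.integer(span_bp),
    exclusive = !interleave_other,
    exon_counts = setNames(exon_counts, family_ids),
    te_fraction = cov_bp / span_bp,
    te_total_fraction = sum(cov_bp) / span_bp,
    seed = seed
  )
  list(gff = gff, repeats = repeats,
       family_ids = c(family_ids, sing_ids), truth = truth)
}

#' Write a generated locus to disk
#'
#' @param locus Result of [generate_locus()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`gff`, `repeats`, `family_ids`).
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    gff = file.path(dir, "locus.gff3"),
    repeats = file.path(dir, "repeats.tsv"),
    family_ids = file.path(dir, "family_ids.txt")
  )
  writeLines(locus$gff, paths$gff)
  write_repeats(locus$repeats, paths$repeats)
  writeLines(locus$family_ids, paths$family_ids)
  paths
}
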