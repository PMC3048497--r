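# Tandem family-cluster detection, exon-count profiling and
# transposable-element coverage of genomic regions.
#
# All intervals are 0-based half-open. Cluster and coverage arithmetic is
# strand-agnostic: the analysis concerns loci, not transcripts.

#' Total length of a set of intervals after union
#'
#' @param intervals Data frame with `start` and `end` (0-based half-open) on
#'   a single chromosome. Overlaps are merged before summing.
#' @return Union length in bp.
#' @export
#' @examples
#' interval_union_length(data.frame(start = c(0, 5), end = c(10, 15)))  # 15
interval_union_length <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(0L)
  if (any(intervals$start >= intervals$end)) {
    abort("Interval with start >= end")
  }
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  sum(IRanges::width(IRanges::reduce(ir)))
}

#' Transposable-element coverage of a genomic region
#'
#' Clips repeat intervals to the region, unions them within each TE class
#' (overlaps are not double-counted) and reports covered bp and fractions per
#' class plus the total over all classes. When per-class genome background
#' fractions are supplied, an enrichment ratio (region fraction over
#' background fraction) is added.
#'
#' @param region List or one-row data frame with `chrom`, `start`, `end`.
#' @param repeats Repeat tibble as from [read_repeats()].
#' @param background Optional named numeric vector of genome-wide coverage
#'   fractions per TE class (and optionally `"total"`).
#' @return Object of class `te_coverage`: list with `region`, `per_class`
#'   tibble (`te_class`, `covered_bp`, `fraction`, `enrichment`), `total_bp`
#'   and `total_fraction`.
#' @export
te_coverage <- function(region, repeats, background = NULL) {
  stopifnot(region$end > region$start)
  region_len <- region$end - region$start
  rep <- repeats[repeats$chrom == region$chrom, , drop = FALSE]
  rep$start <- pmax(rep$start, region$start)
  rep$end <- pmin(rep$end, region$end)
  rep <- rep[rep$start < rep$end, , drop = FALSE]

  per_class <- list_rbind(map(TE_CLASSES, function(cl) {
    sub <- rep[rep$te_class == cl, , drop = FALSE]
    bp <- interval_union_length(sub)
    tibble(te_class = cl, covered_bp = as.numeric(bp),
           fraction = bp / region_len)
  }))
  per_class$enrichment <- NA_real_
  if (!is.null(background)) {
    bg <- background[per_class$te_class]
    per_class$enrichment <- as.numeric(ifelse(!is.na(bg) & bg > 0,
                                              per_class$fraction / bg,
                                              NA_real_))
  }
  total_bp <- interval_union_length(rep)
  structure(
    list(region = region, per_class = per_class,
         total_bp = as.numeric(total_bp),
         total_fraction = total_bp / region_len),
    class = "te_coverage"
  )
}

#' @exportS3Method generics::tidy
tidy.te_coverage <- function(x, ...) {
  bind_rows(
    x$per_class,
    tibble(te_class = "total", covered_bp = x$total_bp,
           fraction = x$total_fraction, enrichment = NA_real_)
  )
}

#' @export
print.te_coverage <- function(x, ...) {
  cat(sprintf("TE coverage of %s:%d-%d (%d bp)\n", x$region$chrom,
              x$region$start, x$region$end, x$region$end - x$region$start))
  for (i in seq_len(nrow(x$per_class))) {
    if (x$per_class$covered_bp[i] > 0) {
      cat(sprintf("  %-15s %8.0f bp  %5.1f%%\n", x$per_class$te_class[i],
                  x$per_class$covered_bp[i], 100 * x$per_class$fraction[i]))
    }
  }
  cat(sprintf("  %-15s %8.0f bp  %5.1f%%\n", "total", x$total_bp,
              100 * x$total_fraction))
  invisible(x)
}

#' Detect tandem clusters of family genes
#'
#' Scans each chromosome for maximal runs of family genes in which each next
#' family gene starts at most `gap_bp` after the previous one ends. Runs with
#' at least `min_size` members become clusters; the span runs from the first
#' gene's start to the last gene's end. A cluster is `exclusive` when no
#' non-family gene overlaps its span.
#'
#' @param genes Gene tibble as from [read_gff3()] (`gene_id`, `chrom`,
#'   `start`, `end`, `family`).
#' @param gap_bp Maximum allowed gap between successive family genes.
#' @param min_size Minimum cluster size.
#' @return Tibble with one row per cluster: `cluster_id`, `chrom`, `size`,
#'   `start`, `end`, `span_bp`, `exclusive` and list-column `members`.
#' @export
find_clusters <- function(genes, gap_bp = 100000, min_size = 3) {
  out <- list()
  for (chr in unique(genes$chrom)) {
    sub <- genes[genes$chrom == chr, ]
    sub <- sub[order(sub$start), ]
    fam <- sub[sub$family, ]
    if (nrow(fam) < min_size) next
    run_id <- cumsum(c(1, (fam$start[-1] - fam$end[-nrow(fam)]) > gap_bp))
    for (rid in unique(run_id)) {
      run <- fam[run_id == rid, ]
      if (nrow(run) < min_size) next
      span_start <- run$start[1]
      span_end <- run$end[nrow(run)]
      other <- sub[!sub$family, ]
      exclusive <- !any(other$start < span_end & other$end > span_start)
      out[[length(out) + 1]] <- tibble(
        chrom = chr, size = nrow(run), start = span_start, end = span_end,
        span_bp = span_end - span_start, exclusive = exclusive,
        members = list(run$gene_id)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      cluster_id = integer(0), chrom = character(0), size = integer(0),
      start = integer(0), end = integer(0), span_bp = integer(0),
      exclusive = logical(0), members = list()
    ))
  }
  res <- list_rbind(out)
  res <- res[order(res$chrom, res$start), ]
  bind_cols(tibble(cluster_id = seq_len(nrow(res))), res)
}

#' Exon counts per gene
#'
#' @param genes Gene tibble as from [read_gff3()].
#' @return Tibble with `gene_id` and `n_exons`, joinable with clade
#'   assignments to profile exon structure per clade.
#' @export
exon_count_profile <- function(genes) {
  tibble(gene_id = genes$gene_id, n_exons = genes$n_exons)
}
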