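# End-to-end census: scan -> classify -> properties -> phylogeny -> genomics,
# consolidated into one report object.

#' Run a full TLP family census
#'
#' Orchestrates the pipeline over a protein set and optional companion
#' inputs. Only the proteins are required; stages whose inputs are absent
#' yield empty report sections (never `NA`-riddled tables). The run is
#' deterministic for fixed inputs, config and seed.
#'
#' @param proteins Protein tibble (from [read_fasta()]) or a FASTA path.
#' @param alignment Optional alignment tibble or aligned-FASTA path; enables
#'   the phylogeny stage.
#' @param genes Optional gene tibble (from [read_gff3()]) or GFF3 path;
#'   enables cluster and exon profiling.
#' @param family_ids Gene ids of family members (used when `genes` is a
#'   path).
#' @param repeats Optional repeat tibble or path; with `genes`, enables TE
#'   coverage of each detected cluster span.
#' @param te_background Optional named per-class genome background fractions
#'   for enrichment ratios.
#' @param clade_anchors Optional named list of anchor tip sets for
#'   [assign_clades()].
#' @param boot_reps Bootstrap replicates for the tree (0 disables bootstrap).
#' @param config [census_config()] list.
#' @param seed Integer seed (bootstrap resampling).
#' @return Object of class `tlp_census`: list with tibbles `proteins`,
#'   `classification`, `properties`, `clades`, `clusters`, `exons`, a
#'   `coverage` list of `te_coverage` objects (one per cluster), the `tree`
#'   (`ape::phylo` or `NULL`), a `summary` list, plus `config` and `seed`.
#' @export
#' @examples
#' set <- generate_protein_set(c(typical = 3, tlp_kinase = 1), seed = 1)
#' cen <- run_census(set$proteins)
#' glance(cen)
run_census <- function(proteins, alignment = NULL, genes = NULL,
                       family_ids = character(), repeats = NULL,
                       te_background = NULL, clade_anchors = NULL,
                       boot_reps = 0, config = census_config(), seed = 1) {
  config <- as_census_config(config)
  if (is.character(proteins)) proteins <- read_fasta(proteins)
  if (is.character(alignment)) alignment <- read_alignment(alignment)
  if (is.character(genes)) genes <- read_gff3(genes, family_ids)
  if (is.character(repeats)) repeats <- read_repeats(repeats)

  classification <- classify_tlps(proteins, config)
  properties <- compute_properties(proteins, config)

  tree <- NULL
  clades <- tibble(leaf = character(0), clade = character(0))
  if (!is.null(alignment)) {
    tree <- if (boot_reps > 0) {
      bootstrap_support(alignment, n_reps = boot_reps, seed = seed)
    } else {
      nj_tree(pdistance_matrix(alignment))
    }
    if (!is.null(clade_anchors)) {
      clades <- assign_clades(tree, clade_anchors)
    }
  }

  clusters <- tibble(
    cluster_id = integer(0), chrom = character(0), size = integer(0),
    start = integer(0), end = integer(0), span_bp = integer(0),
    exclusive = logical(0), members = list()
  )
  exons <- tibble(gene_id = character(0), n_exons = integer(0))
  coverage <- list()
  if (!is.null(genes)) {
    clusters <- find_clusters(genes, gap_bp = config$cluster_gap_bp,
                              min_size = config$cluster_min_size)
    exons <- exon_count_profile(genes)
    if (!is.null(repeats) && nrow(clusters) > 0) {
      coverage <- map(seq_len(nrow(clusters)), function(i) {
        te_coverage(
          list(chrom = clusters$chrom[i], start = clusters$start[i],
               end = clusters$end[i]),
          repeats, background = te_background
        )
      })
    }
  }

  label_counts <- classification |> count(.data$label) |> tidyr::complete(
    label = c("typical", "small", "tlp_kinase", "small_tlp_kinase", "incomplete"),
    fill = list(n = 0L)
  )
  stopifnot(sum(label_counts$n) == nrow(proteins))

  structure(
    list(
      proteins = proteins, classification = classification,
      properties = properties, tree = tree, clades = clades,
      clusters = clusters, exons = exons, coverage = coverage,
      summary = list(
        n_proteins = nrow(proteins),
        label_counts = label_counts,
        clade_counts = if (nrow(clades) > 0) count(clades, .data$clade) else NULL,
        n_clusters = nrow(clusters)
      ),
      config = config, seed = seed
    ),
    class = "tlp_census"
  )
}

#' @export
print.tlp_census <- function(x, ...) {
  cat("TLP census:", x$summary$n_proteins, "proteins\n")
  lc <- x$summary$label_counts
  for (i in seq_len(nrow(lc))) {
    if (lc$n[i] > 0) cat(sprintf("  %-18s %d\n", lc$label[i], lc$n[i]))
  }
  if (!is.null(x$tree)) {
    cat("Tree:", length(x$tree$tip.label), "leaves")
    if (!is.null(attr(x$tree, "n_reps"))) {
      cat(",", attr(x$tree, "n_reps"), "bootstrap replicates")
    }
    cat("\n")
  }
  if (nrow(x$clusters) > 0) {
    cat("Clusters:", nrow(x$clusters), "\n")
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  %s:%d-%d  %d genes, %d bp%s\n",
                  x$clusters$chrom[i], x$clusters$start[i], x$clusters$end[i],
                  x$clusters$size[i], x$clusters$span_bp[i],
                  if (x$clusters$exclusive[i]) ", exclusive" else ""))
    }
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tlp_census <- function(x, ...) {
  out <- x$classification |>
    left_join(select(x$proteins, "id", "organism_code"), by = "id") |>
    left_join(select(x$properties, "id", "mw_kda", "pi"), by = "id") |>
    left_join(rename(x$clades, id = "leaf"), by = "id")
  if (!"clade" %in% names(out)) out$clade <- NA_character_
  member_of <- function(id) {
    for (i in seq_len(nrow(x$clusters))) {
      if (id %in% x$clusters$members[[i]]) return(x$clusters$cluster_id[i])
    }
    NA_integer_
  }
  out$cluster_id <- map_int(out$id, member_of)
  out
}

#' @exportS3Method generics::glance
glance.tlp_census <- function(x, ...) {
  lc <- setNames(x$summary$label_counts$n, x$summary$label_counts$label)
  tibble(
    n_proteins = x$summary$n_proteins,
    n_typical = lc[["typical"]], n_small = lc[["small"]],
    n_tlp_kinase = lc[["tlp_kinase"]],
    n_small_tlp_kinase = lc[["small_tlp_kinase"]],
    n_incomplete = lc[["incomplete"]],
    n_clusters = nrow(x$clusters),
    has_tree = !is.null(x$tree)
  )
}

#' Write the census report to a directory
#'
#' Emits `census.tsv` (fixed column order, see [write_census_table()]),
#' `tree.nwk` when a tree exists and `clusters.tsv` when clusters exist.
#'
#' @param census `tlp_census` object.
#' @param dir Output directory.
#' @return Named list of written paths.
#' @export
write_census <- function(census, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(census = file.path(dir, "census.tsv"))
  rows <- tidy(census)
  rows$label <- rows$label
  write_census_table(rows, paths$census)
  if (!is.null(census$tree)) {
    paths$tree <- file.path(dir, "tree.nwk")
    write_newick(census$tree, paths$tree)
  }
  if (nrow(census$clusters) > 0) {
    paths$clusters <- file.path(dir, "clusters.tsv")
    cl <- census$clusters
    cl$members <- map_chr(cl$members, paste, collapse = ",")
    readr::write_tsv(cl, paths$clusters)
  }
  paths
}
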