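# Gene-model, repeat-interval, Newick and census-table input/output.
#
# Genomic intervals are 0-based half-open everywhere inside the package; GFF3
# (1-based closed) is converted at this boundary in both directions, so
# GFF -> internal -> GFF is the identity.

TE_CLASSES <- c("LTR_Gypsy", "LTR_Copia", "LTR_other", "DNA_transposon", "other")

#' Read gene models from a GFF3 file
#'
#' Assembles one row per gene from gene/mRNA/exon/CDS features (exons may be
#' parented on the gene directly or through an mRNA; with several transcripts
#' the first mRNA is used). GFF3 1-based closed coordinates are converted to
#' 0-based half-open. Exons must be non-overlapping and every CDS interval
#' must fall inside an exon.
#'
#' @param path Path to a GFF3 file.
#' @param family_ids Character vector of gene ids belonging to the protein
#'   family under study; matching genes get `family = TRUE`.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (gene span, 0-based half-open), `n_exons`, `family`, and
#'   list-columns `exons` and `cds` of interval tibbles (`start`, `end`),
#'   sorted 5' to 3' in genome coordinates.
#' @export
read_gff3 <- function(path, family_ids = character()) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  df$parent <- vapply(
    as.list(df$Parent %||% vector("list", nrow(df))),
    function(p) if (length(p) > 0) as.character(p[[1]]) else NA_character_,
    character(1)
  )
  genes <- df[df$type == "gene", ]
  if (nrow(genes) == 0) abort(paste0("No gene features in ", path))
  mrna <- df[df$type == "mRNA", ]
  mrna_of_gene <- split(mrna$ID, mrna$parent)

  build_gene <- function(i) {
    gid <- genes$ID[i]
    owner_ids <- gid
    if (!is.null(mrna_of_gene[[gid]])) {
      owner_ids <- c(gid, mrna_of_gene[[gid]][1])
    }
    sub <- df[!is.na(df$parent) & df$parent %in% owner_ids, ]
    pick <- function(type) {
      s <- sub[sub$type == type, c("start", "end")]
      s <- s[order(s$start), ]
      tibble(start = s$start - 1L, end = s$end)
    }
    exons <- pick("exon")
    cds <- pick("CDS")
    if (nrow(exons) == 0) {
      abort(paste0("Gene '", gid, "' has no exon features"))
    }
    if (any(exons$start >= exons$end)) {
      abort(paste0("Gene '", gid, "': exon with end < start"))
    }
    if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
      abort(paste0("Gene '", gid, "': overlapping exons"))
    }
    if (nrow(cds) > 0) {
      inside <- vapply(seq_len(nrow(cds)), function(k) {
        any(cds$start[k] >= exons$start & cds$end[k] <= exons$end)
      }, logical(1))
      if (!all(inside)) {
        abort(paste0("Gene '", gid, "': CDS interval outside any exon"))
      }
    }
    tibble(
      gene_id = gid,
      chrom = as.character(genes$seqnames[i]),
      strand = as.character(genes$strand[i]),
      start = genes$start[i] - 1L,
      end = genes$end[i],
      n_exons = nrow(exons),
      family = gid %in% family_ids,
      exons = list(exons),
      cds = list(cds)
    )
  }

  list_rbind(map(seq_len(nrow(genes)), build_gene))
}

#' Read a transposable-element interval table
#'
#' Tab-delimited with a one-line header and columns `chrom`, `start`, `end`
#' (0-based half-open), `te_class`, `family`. `te_class` must be one of
#' `LTR_Gypsy`, `LTR_Copia`, `LTR_other`, `DNA_transposon`, `other`.
#'
#' @param path Path to the repeat table.
#' @return Tibble with the five columns above.
#' @export
read_repeats <- function(path) {
  stopifnot(file.exists(path))
  rep <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      te_class = readr::col_character(),
      family = readr::col_character()
    )
  )
  bad <- setdiff(unique(rep$te_class), TE_CLASSES)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown te_class value(s): ", paste(bad, collapse = ", "),
      "; allowed: ", paste(TE_CLASSES, collapse = ", ")
    ))
  }
  if (any(rep$start >= rep$end)) {
    abort("Repeat interval with start >= end")
  }
  rep
}

#' Write a transposable-element interval table
#' @param repeats Tibble as returned by [read_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeats <- function(repeats, path) {
  readr::write_tsv(repeats[, c("chrom", "start", "end", "te_class", "family")], path)
  invisible(path)
}

#' Write a tree to Newick with fixed-precision branch lengths
#'
#' Branch lengths are written with 6 decimals; internal-node bootstrap
#' supports (the tree's `node.label`, stored as fractions in [0,1]) are
#' written as integer percentages, rounded half-up.
#'
#' @param tree An `ape::phylo` tree, optionally with `node.label` supports.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  supports <- tree$node.label
  fmt_node <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      paste0(fmt_node(tree$edge[r, 2]),
             ":", sprintf("%.6f", tree$edge.length[r]))
    }, character(1))
    lab <- ""
    if (!is.null(supports) && node > root) {
      s <- supports[node - n_tip]
      if (!is.na(suppressWarnings(as.numeric(s))) && nzchar(s)) {
        lab <- as.character(floor(as.numeric(s) * 100 + 0.5))
      }
    }
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  writeLines(paste0(fmt_node(root), ";"), path)
  invisible(path)
}

CENSUS_COLUMNS <- c(
  "id", "organism_code", "label", "domain_start", "domain_end", "domain_len",
  "n_cys", "coverage", "complete", "kinase_start", "kinase_end",
  "tm_start", "tm_end", "mw_kda", "pi", "clade", "cluster_id"
)

#' Write the per-protein census table
#'
#' TSV with the fixed column order documented in [CENSUS_COLUMNS]-order:
#' id, organism_code, label, domain_start, domain_end, domain_len, n_cys,
#' coverage, complete, kinase_start, kinase_end, tm_start, tm_end, mw_kda,
#' pi, clade, cluster_id. Missing columns are filled with `NA`.
#'
#' @param rows Per-protein tibble (e.g. `tidy()` of a census object).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_table <- function(rows, path) {
  for (col in setdiff(CENSUS_COLUMNS, names(rows))) rows[[col]] <- NA
  readr::write_tsv(rows[, CENSUS_COLUMNS], path)
  invisible(path)
}
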