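#' Pipeline configuration
#'
#' Collects every tunable threshold of the census pipeline in one list, with
#' defaults chosen for the plant TLP family: the complete-domain filter admits
#' small-TLP domains (~150 aa, 10 Cys) and long ascomycete domains (~280 aa)
#' while rejecting fragments; the small/typical length cutoff splits the
#' family's ~150 vs ~215 aa bimodality; cysteine bands tolerate the 1-2
#' residue exceptions seen in divergent fungal and animal sequences.
#'
#' @param domain_min_len,domain_max_len Complete-domain length bounds (aa).
#' @param domain_min_cys Minimum cysteine count for a complete domain.
#' @param small_cutoff Domain length (aa) below which a domain is "small".
#' @param cys_typical,cys_small Inclusive cysteine-count bands for the typical
#'   (16-cysteine) and small (10-cysteine) scaffolds.
#' @param kinase_gap_gh,kinase_gap_hd Allowed start-to-start spacings between
#'   the glycine-loop and HxD motifs, and between the HxD and DxG motifs.
#' @param kinase_min_len Minimum length (aa) of a reported kinase region.
#' @param tm_window,tm_threshold Kyte-Doolittle window size and mean-hydropathy
#'   threshold for transmembrane-segment calls.
#' @param cluster_gap_bp Maximum gap (bp) between successive family genes in a
#'   tandem cluster.
#' @param cluster_min_size Minimum number of genes in a reported cluster.
#' @param pka pKa table for charge computations, see [emboss_pka()].
#' @return A list of class `tlp_config`.
#' @export
#' @examples
#' cfg <- census_config(small_cutoff = 170)
#' cfg$small_cutoff
census_config <- function(domain_min_len = 120,
                          domain_max_len = 330,
                          domain_min_cys = 8,
                          small_cutoff = 180,
                          cys_typical = c(14, 16),
                          cys_small = c(9, 11),
                          kinase_gap_gh = c(60, 140),
                          kinase_gap_hd = c(15, 45),
                          kinase_min_len = 200,
                          tm_window = 19,
                          tm_threshold = 1.6,
                          cluster_gap_bp = 100000,
                          cluster_min_size = 3,
                          pka = emboss_pka()) {
  cfg <- list(
    domain_min_len = domain_min_len,
    domain_max_len = domain_max_len,
    domain_min_cys = domain_min_cys,
    small_cutoff = small_cutoff,
    cys_typical = cys_typical,
    cys_small = cys_small,
    kinase_gap_gh = kinase_gap_gh,
    kinase_gap_hd = kinase_gap_hd,
    kinase_min_len = kinase_min_len,
    tm_window = tm_window,
    tm_threshold = tm_threshold,
    cluster_gap_bp = cluster_gap_bp,
    cluster_min_size = cluster_min_size,
    pka = pka
  )
  structure(cfg, class = "tlp_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [census_config()]; absent keys keep their
#' defaults, unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `tlp_config` list.
#' @export
read_census_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(census_config)), "pka")
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(census_config, vals)
}

as_census_config <- function(config) {
  if (inherits(config, "tlp_config")) return(config)
  if (is.null(config)) return(census_config())
  do.call(census_config, config)
}
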