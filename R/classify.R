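# Architecture classification: typical TLP, small-TLP, TLP-kinase,
# small-TLP-kinase, or incomplete.
#
# Kinase regions are recognized by a self-contained motif triad (glycine-loop
# G-x-G-x-x-G, catalytic H-x-D, activation-segment D-x-G occurring in order
# with bounded spacings) rather than a profile HMM; transmembrane segments by
# the classic Kyte-Doolittle 19-residue window heuristic.

#' Detect a protein-kinase region by its anchor-motif triad
#'
#' Searches for a glycine-rich loop (`G-x-G-x-x-G`), a catalytic `H-x-D` and
#' an activation-segment `D-x-G` occurring in that order, with start-to-start
#' spacings within the configured windows. The first (leftmost) consistent
#' triad is reported. The region runs from the glycine loop to the end of the
#' sequence and must reach the configured minimum length.
#'
#' @param sequence Amino-acid string (pass the full protein; use `offset` to
#'   restrict the search to residues at/after that 0-based position).
#' @param config [census_config()] list.
#' @param offset 0-based position from which to search (e.g. a domain end).
#' @return `NULL`, or a list with `start`, `end` (0-based half-open),
#'   `g_loop_start`, `hxd_start`, `dxg_start` and `catalytic_asp_positions`
#'   (0-based positions of the two catalytic aspartates).
#' @export
detect_kinase_domain <- function(sequence, config = census_config(), offset = 0L) {
  config <- as_census_config(config)
  sub <- substr(sequence, offset + 1, nchar(sequence))
  g <- regex_starts0(sub, paste0("(?=G", AA20_CLASS, "G", AA20_CLASS, "{2}G)"))
  h <- regex_starts0(sub, paste0("(?=H", AA20_CLASS, "D)"))
  d <- regex_starts0(sub, paste0("(?=D", AA20_CLASS, "G)"))
  if (length(g) == 0 || length(h) == 0 || length(d) == 0) return(NULL)
  for (gs in g) {
    hs_ok <- h[h - gs >= config$kinase_gap_gh[1] & h - gs <= config$kinase_gap_gh[2]]
    for (hs in hs_ok) {
      ds_ok <- d[d - hs >= config$kinase_gap_hd[1] & d - hs <= config$kinase_gap_hd[2]]
      if (length(ds_ok) > 0) {
        ds <- ds_ok[1]
        start <- offset + gs
        end <- nchar(sequence)
        if (end - start < config$kinase_min_len) next
        return(list(
          start = start, end = end,
          g_loop_start = offset + gs,
          hxd_start = offset + hs,
          dxg_start = offset + ds,
          catalytic_asp_positions = c(offset + hs + 2L, offset + ds)
        ))
      }
    }
  }
  NULL
}

#' Detect a transmembrane segment by Kyte-Doolittle hydropathy
#'
#' Slides a window over the (optionally restricted) sequence and returns the
#' maximal mean-hydropathy window if its mean reaches the threshold. Ties are
#' broken by smallest start.
#'
#' @param sequence Amino-acid string.
#' @param window Window size in residues.
#' @param threshold Minimum window-mean hydropathy.
#' @param from,to Optional 0-based half-open bounds restricting the search
#'   (e.g. the inter-domain region between thaumatin and kinase domains).
#' @return `NULL`, or a list with `start`, `end` (0-based half-open, absolute
#'   protein coordinates) and `mean_hydropathy`.
#' @export
#' @examples
#' detect_tm_segment(paste0(strrep("D", 10), strrep("I", 19), strrep("D", 10)))
detect_tm_segment <- function(sequence, window = 19, threshold = 1.6,
                              from = 0L, to = nchar(sequence)) {
  stopifnot(to <= nchar(sequence), from >= 0, from <= to)
  sub <- substr(sequence, from + 1, to)
  if (nchar(sub) < window) return(NULL)
  kd <- kyte_doolittle()
  vals <- unname(kd[strsplit(sub, "", fixed = TRUE)[[1]]])
  vals[is.na(vals)] <- 0  # X scores neutral
  cs <- c(0, cumsum(vals))
  means <- (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
  best <- which.max(means)
  if (means[best] < threshold) return(NULL)
  list(
    start = from + best - 1L,
    end = from + best - 1L + as.integer(window),
    mean_hydropathy = means[best]
  )
}

classify_one <- function(id, sequence, config) {
  dom <- extract_domain(sequence, config)
  base <- tibble(
    id = id,
    label = NA_character_,
    domain_start = NA_integer_, domain_end = NA_integer_,
    domain_len = NA_integer_, n_cys = NA_integer_, coverage = NA_real_,
    complete = FALSE,
    kinase_start = NA_integer_, kinase_end = NA_integer_,
    asp1 = NA_integer_, asp2 = NA_integer_,
    tm_start = NA_integer_, tm_end = NA_integer_,
    atypical_cys = FALSE
  )
  if (is.null(dom) || !dom$complete) {
    base$label <- "incomplete"
    if (!is.null(dom)) {
      base$domain_start <- dom$start; base$domain_end <- dom$end
      base$domain_len <- dom$end - dom$start
      base$n_cys <- dom$n_cysteines; base$coverage <- dom$coverage
    }
    return(base)
  }
  base$domain_start <- dom$start; base$domain_end <- dom$end
  base$domain_len <- dom$end - dom$start
  base$n_cys <- dom$n_cysteines; base$coverage <- dom$coverage
  base$complete <- TRUE

  is_small <- base$domain_len < config$small_cutoff &&
    base$n_cys >= config$cys_small[1] && base$n_cys <= config$cys_small[2]
  is_typical_band <- base$n_cys >= config$cys_typical[1] &&
    base$n_cys <= config$cys_typical[2]

  kin <- detect_kinase_domain(sequence, config, offset = dom$end)
  if (!is.null(kin)) {
    base$kinase_start <- kin$start; base$kinase_end <- kin$end
    base$asp1 <- kin$catalytic_asp_positions[1]
    base$asp2 <- kin$catalytic_asp_positions[2]
    tm <- detect_tm_segment(sequence, config$tm_window, config$tm_threshold,
                            from = dom$end, to = kin$start)
    if (!is.null(tm)) {
      base$tm_start <- tm$start; base$tm_end <- tm$end
    }
    base$label <- if (is_small) "small_tlp_kinase" else "tlp_kinase"
    return(base)
  }
  if (is_small) {
    base$label <- "small"
  } else if (is_typical_band) {
    base$label <- "typical"
  } else {
    base$label <- "typical"
    base$atypical_cys <- TRUE
  }
  base
}

#' Classify TLP architectures
#'
#' Assigns each protein one of the labels `typical`, `small`, `tlp_kinase`,
#' `small_tlp_kinase` or `incomplete` by the decision tree: no complete
#' thaumatin domain gives `incomplete`; a kinase motif triad downstream of the
#' domain gives `tlp_kinase` (or `small_tlp_kinase` when the domain meets the
#' small criteria); otherwise a domain below the small cutoff with 9-11
#' cysteines is `small`, a 14-16-cysteine domain is `typical`, and anything
#' else is `typical` with `atypical_cys = TRUE`.
#'
#' @param proteins Tibble with `id` and `sequence`.
#' @param config [census_config()] list.
#' @return Tibble with one row per protein: `id`, `label`, domain coordinates
#'   and metrics, kinase/TM coordinates (NA when absent), catalytic-aspartate
#'   positions `asp1`/`asp2`, and the `atypical_cys` evidence flag.
#' @export
#' @examples
#' set <- generate_protein_set(c(typical = 1, small = 1), seed = 7)
#' classify_tlps(set$proteins)[, c("id", "label", "domain_len", "n_cys")]
classify_tlps <- function(proteins, config = census_config()) {
  config <- as_census_config(config)
  list_rbind(map(seq_len(nrow(proteins)), function(i) {
    classify_one(proteins$id[[i]], proteins$sequence[[i]], config)
  }))
}
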