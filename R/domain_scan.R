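# Motif-delimited thaumatin-domain extraction and completeness filtering.
#
# The thaumatin domain is delimited by two conserved boundary motifs:
# N-x-C-x(3)-V/I-W at the N-terminal end (8 residues) and Y-x-I/V-x-F-C-x at
# the C-terminal end (7 residues), where x is any of the 20 standard amino
# acids (the ambiguity letter X cannot certify a boundary).

AA20_CLASS <- "[ACDEFGHIKLMNPQRSTVWY]"

N_MOTIF_LEN <- 8L
C_MOTIF_LEN <- 7L

n_motif_regex <- function() {
  paste0("(?=N", AA20_CLASS, "C", AA20_CLASS, "{3}[VI]W)")
}

c_motif_regex <- function() {
  paste0("(?=Y", AA20_CLASS, "[IV]", AA20_CLASS, "FC", AA20_CLASS, ")")
}

# All (overlapping) match start positions, 0-based.
regex_starts0 <- function(sequence, lookahead_regex) {
  m <- gregexpr(lookahead_regex, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Scan a protein for thaumatin-domain boundary motifs
#'
#' Reports every (possibly overlapping) occurrence of the N-terminal
#' (`N-x-C-x(3)-V/I-W`) and C-terminal (`Y-x-I/V-x-F-C-x`) boundary motifs.
#'
#' @param sequence Amino-acid string.
#' @return Tibble with columns `kind` (`"N"`/`"C"`), `start`, `end` (0-based
#'   half-open on the protein) and `match` (the matched residues). Empty when
#'   nothing matches.
#' @export
#' @examples
#' scan_boundary_motifs("AAANQCKLMVWAAA")
scan_boundary_motifs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  n_start <- regex_starts0(sequence, n_motif_regex())
  c_start <- regex_starts0(sequence, c_motif_regex())
  out <- tibble(
    kind = c(rep("N", length(n_start)), rep("C", length(c_start))),
    start = c(n_start, c_start),
    end = c(n_start + N_MOTIF_LEN, c_start + C_MOTIF_LEN)
  )
  out$match <- substr(rep(sequence, nrow(out)), out$start + 1, out$end)
  out
}

#' Completeness verdict for a delimited thaumatin domain
#'
#' A domain is complete when both boundary motifs were found, its length lies
#' within the configured bounds and it carries at least the configured
#' minimum number of cysteines. Reasons enumerate every failed criterion.
#'
#' @param domain_len Domain length in residues (NA when no domain).
#' @param n_cys Cysteine count inside the domain.
#' @param has_n_motif,has_c_motif Whether each boundary motif was found.
#' @param config [census_config()] list.
#' @return List with `complete` (logical) and `reasons` (character vector,
#'   empty when complete).
#' @export
validate_complete <- function(domain_len, n_cys, has_n_motif, has_c_motif,
                              config = census_config()) {
  config <- as_census_config(config)
  reasons <- character(0)
  if (!isTRUE(has_n_motif)) reasons <- c(reasons, "missing N-terminal motif")
  if (!isTRUE(has_c_motif)) reasons <- c(reasons, "missing C-terminal motif")
  if (isTRUE(has_n_motif) && isTRUE(has_c_motif)) {
    if (is.na(domain_len)) {
      reasons <- c(reasons, "no compatible motif pair")
    } else {
      if (domain_len < config$domain_min_len) {
        reasons <- c(reasons, sprintf("domain too short (%d < %d)",
                                      domain_len, config$domain_min_len))
      }
      if (domain_len > config$domain_max_len) {
        reasons <- c(reasons, sprintf("domain too long (%d > %d)",
                                      domain_len, config$domain_max_len))
      }
      if (n_cys < config$domain_min_cys) {
        reasons <- c(reasons, sprintf("too few cysteines (%d < %d)",
                                      n_cys, config$domain_min_cys))
      }
    }
  }
  list(complete = length(reasons) == 0, reasons = reasons)
}

#' Extract the thaumatin domain from one protein sequence
#'
#' Scans both boundary motifs and chooses the (N-hit, C-hit) pair yielding
#' the longest domain whose length lies within the configured bounds, ties
#' broken by smallest start. When no pair satisfies the bounds, the longest
#' compatible pair is kept so completeness checking can report why it fails;
#' when no compatible pair exists at all, `NULL` is returned.
#'
#' @param sequence Amino-acid string.
#' @param config [census_config()] list.
#' @return `NULL`, or a list with `start`, `end` (0-based half-open),
#'   `sequence`, `n_cysteines`, `coverage` (domain length over protein
#'   length), `complete`, `failure_reasons`, `has_n_motif`, `has_c_motif`.
#' @export
extract_domain <- function(sequence, config = census_config()) {
  config <- as_census_config(config)
  hits <- scan_boundary_motifs(sequence)
  n_hits <- hits[hits$kind == "N", ]
  c_hits <- hits[hits$kind == "C", ]
  if (nrow(n_hits) == 0 || nrow(c_hits) == 0) {
    return(NULL)
  }
  pairs <- tidyr::expand_grid(n = seq_len(nrow(n_hits)), c = seq_len(nrow(c_hits)))
  pairs$start <- n_hits$start[pairs$n]
  pairs$end <- c_hits$end[pairs$c]
  # compatible: C motif begins at or after the N motif's end
  pairs <- pairs[c_hits$start[pairs$c] >= n_hits$end[pairs$n], ]
  if (nrow(pairs) == 0) return(NULL)
  pairs$len <- pairs$end - pairs$start
  in_bounds <- pairs$len >= config$domain_min_len & pairs$len <= config$domain_max_len
  pool <- if (any(in_bounds)) pairs[in_bounds, ] else pairs
  pool <- pool[order(-pool$len, pool$start), ]
  best <- pool[1, ]

  dom_seq <- substr(sequence, best$start + 1, best$end)
  n_cys <- str_count(dom_seq, "C")
  verdict <- validate_complete(best$len, n_cys, TRUE, TRUE, config)
  list(
    start = best$start,
    end = best$end,
    sequence = dom_seq,
    n_cysteines = n_cys,
    coverage = best$len / nchar(sequence),
    complete = verdict$complete,
    failure_reasons = verdict$reasons,
    has_n_motif = TRUE,
    has_c_motif = TRUE
  )
}

#' Scan a set of proteins for thaumatin domains
#'
#' Tidy wrapper over [extract_domain()]: one row per input protein, with
#' completeness verdicts per the configured filter.
#'
#' @param proteins Tibble with `id` and `sequence` (e.g. from [read_fasta()]).
#' @param config [census_config()] list.
#' @return Tibble with columns `id`, `has_n_motif`, `has_c_motif`,
#'   `domain_start`, `domain_end`, `domain_len`, `n_cys`, `coverage`,
#'   `complete`, `failure_reasons` (list-column).
#' @export
#' @examples
#' set <- generate_protein_set(c(typical = 2), seed = 1)
#' scan_domains(set$proteins)
scan_domains <- function(proteins, config = census_config()) {
  config <- as_census_config(config)
  rows <- map(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[[i]]
    dom <- extract_domain(s, config)
    if (is.null(dom)) {
      hits <- scan_boundary_motifs(s)
      has_n <- any(hits$kind == "N")
      has_c <- any(hits$kind == "C")
      verdict <- validate_complete(NA_integer_, 0L, has_n, has_c, config)
      return(tibble(
        id = proteins$id[[i]], has_n_motif = has_n, has_c_motif = has_c,
        domain_start = NA_integer_, domain_end = NA_integer_,
        domain_len = NA_integer_, n_cys = NA_integer_, coverage = NA_real_,
        complete = FALSE, failure_reasons = list(verdict$reasons)
      ))
    }
    tibble(
      id = proteins$id[[i]], has_n_motif = TRUE, has_c_motif = TRUE,
      domain_start = dom$start, domain_end = dom$end,
      domain_len = dom$end - dom$start, n_cys = dom$n_cysteines,
      coverage = dom$coverage, complete = dom$complete,
      failure_reasons = list(dom$failure_reasons)
    )
  })
  list_rbind(rows)
}
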