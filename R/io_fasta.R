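# Protein FASTA and alignment input/output.
#
# All sequence collections travel through the package as tibbles with one row
# per sequence (columns `id`, `description`, `organism_code`, `sequence`,
# `stop_stripped` for proteins; `id`, `sequence` for alignment rows).

# Locate the 1-based file line of the first offending character within a
# record, for error messages.
locate_bad_line <- function(path, record_idx, bad_regex) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (record_idx > length(hdr)) return(NA_integer_)
  from <- hdr[record_idx] + 1L
  to <- if (record_idx < length(hdr)) hdr[record_idx + 1L] - 1L else length(lines)
  if (from > to) return(hdr[record_idx])
  body <- toupper(lines[from:to])
  hit <- which(grepl(bad_regex, body))
  if (length(hit) == 0) from else from + hit[1L] - 1L
}

# Parse the 5-letter organism code (3 letters genus + 2 species, e.g. "Poptr")
# from an id of the form "Poptr-1234" or "Poptr_0001s09570".
parse_organism_code <- function(id) {
  m <- regmatches(id, regexec("^([A-Za-z]{5})[-_]", id))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

#' Read a protein FASTA file
#'
#' Sequences are uppercased and validated against the 20 standard amino-acid
#' letters plus `X`. A single trailing `*` (stop codon) is stripped and
#' flagged in the `stop_stripped` column; an internal `*` or any other illegal
#' character is an error naming the offending line.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with columns `id`, `description`, `organism_code`
#'   (5-letter genus+species code parsed from the id, `NA` when absent),
#'   `sequence` and `stop_stripped`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">Poptr-1 a thaumatin", "MNCAV*"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) abort(paste0("No FASTA records in ", path))
  full <- names(aas)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- toupper(as.character(aas))

  if (anyDuplicated(id)) {
    abort(paste0(
      "Duplicate sequence id(s) in ", path, ": ",
      paste(unique(id[duplicated(id)]), collapse = ", ")
    ))
  }

  stop_stripped <- rep(FALSE, length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) == 0) {
      abort(paste0("Empty sequence for record '", id[i], "' (line ",
                   locate_bad_line(path, i, "."), ")"))
    }
    n_stop <- str_count(s, "\\*")
    if (n_stop > 0) {
      if (n_stop > 1 || !endsWith(s, "*")) {
        abort(paste0("Internal stop codon '*' in record '", id[i], "' (line ",
                     locate_bad_line(path, i, "\\*"), ")"))
      }
      s <- substr(s, 1, nchar(s) - 1)
      stop_stripped[i] <- TRUE
      if (nchar(s) == 0) {
        abort(paste0("Record '", id[i], "' contains only a stop codon"))
      }
    }
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", s)) {
      bad <- regmatches(s, regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", s))
      abort(paste0(
        "Illegal character '", bad, "' in record '", id[i], "' (line ",
        locate_bad_line(path, i, paste0("[^ACDEFGHIKLMNPQRSTVWYX*]")), ")"
      ))
    }
    seqs[[i]] <- s
  }

  tibble(
    id = id,
    description = desc,
    organism_code = parse_organism_code(id),
    sequence = unname(seqs),
    stop_stripped = stop_stripped
  )
}

#' Write protein records to FASTA
#'
#' @param proteins Tibble with `id`, `sequence` and optionally `description`.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  hdr <- paste0(
    ">", proteins$id,
    ifelse(!is.null(proteins$description) & nzchar(proteins$description %||% ""),
           paste0(" ", proteins$description), "")
  )
  lines <- unlist(map2(hdr, proteins$sequence, function(h, s) {
    c(h, substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

validate_alignment <- function(aln) {
  stopifnot(is.data.frame(aln), all(c("id", "sequence") %in% names(aln)))
  if (nrow(aln) == 0) abort("Empty alignment")
  if (anyDuplicated(aln$id)) {
    abort(paste0("Duplicate alignment ids: ",
                 paste(unique(aln$id[duplicated(aln$id)]), collapse = ", ")))
  }
  len <- nchar(aln$sequence)
  if (length(unique(len)) != 1) {
    ref <- as.integer(names(which.max(table(len))))
    bad <- aln$id[len != ref]
    abort(paste0("Ragged alignment rows (length != ", ref, "): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(aln)
}

#' Number of columns of an alignment tibble
#' @param aln Alignment tibble (`id`, `sequence`).
#' @return Integer column count.
#' @export
n_columns <- function(aln) {
  validate_alignment(aln)
  nchar(aln$sequence[[1]])
}

#' Read a protein multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal block format. Gap characters `.` are
#' normalized to `-`; residues are uppercased. Rows of unequal length are an
#' error listing the offending ids.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return Alignment tibble with columns `id` and `sequence` (gapped).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "fasta") {
    aas <- Biostrings::readAAStringSet(path)
    aln <- tibble(id = sub("\\s.*$", "", names(aas)),
                  sequence = unname(toupper(as.character(aas))))
  } else {
    ma <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(Biostrings::unmasked(ma))
    aln <- tibble(id = names(seqs), sequence = toupper(unname(seqs)))
  }
  aln$sequence <- gsub(".", "-", aln$sequence, fixed = TRUE)
  validate_alignment(aln)
  aln
}

#' Write an alignment to FASTA or Clustal format
#'
#' @param aln Alignment tibble (`id`, `sequence`).
#' @param path Output path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  validate_alignment(aln)
  if (format == "fasta") {
    return(write_fasta(aln, path))
  }
  w <- max(nchar(aln$id)) + 3
  ncol <- nchar(aln$sequence[[1]])
  # header followed by exactly two blank lines, blocks separated by one
  lines <- c("CLUSTAL W multiple sequence alignment", "", "")
  for (from in seq(1, ncol, 60)) {
    to <- min(from + 59, ncol)
    block <- paste0(formatC(aln$id, width = -w), substr(aln$sequence, from, to))
    lines <- c(lines, block, "")
  }
  writeLines(lines, path)
  invisible(path)
}

# Convert an alignment tibble to a character matrix with row names = ids.
alignment_matrix <- function(aln) {
  validate_alignment(aln)
  m <- seq_char_matrix(aln$sequence)
  rownames(m) <- aln$id
  m
}
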