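# Seeded protein scaffold generator with recorded ground truth.
#
# Scaffolds emulate the four family architectures: typical (~215-aa thaumatin
# domain, 16 cysteines), small (~150 aa, 10 cysteines), and the kinase
# fusions which append a hydrophobic transmembrane stretch and a kinase
# region (ordered G-x-G-x-x-G / H-x-D / D-x-G anchor motifs with two
# catalytic aspartates), reaching ~650 aa for the typical-domain fusion.
# Filler residues are drawn uniformly from the standard letters minus the
# motif anchor letters {C, G, H, N, W, Y}, so planted motifs are provably the
# only matches and recorded coordinates are exact for every seed.

FILLER_AA <- setdiff(AA_STANDARD, c("C", "G", "H", "N", "W", "Y"))
# linkers flanking the transmembrane stretch are polar, so the planted TM is
# the unique maximal hydropathy window
LINKER_AA <- c("D", "E", "K", "R", "S", "T", "Q", "P")
TM_STRETCH <- "ILVFILVFILVFILVFILV"  # 19 hydrophobic residues, mean KD 3.825

# Fixed canonical template of internal cysteine positions (1-based within the
# domain), evenly spread between the boundary motifs so coordinates are
# stable across seeds.
internal_cys_template <- function(domain_len, n_internal) {
  unique(round(seq(N_MOTIF_LEN + 4, domain_len - C_MOTIF_LEN - 3,
                   length.out = n_internal)))
}

# Default REDDD offsets (1-based within the domain), at fixed fractions of
# the domain length, shifted off any cysteine-template position.
default_reddd_offsets <- function(domain_len, cys_pos) {
  pos <- round(domain_len * c(0.30, 0.40, 0.47, 0.55, 0.62))
  for (k in seq_along(pos)) {
    while (pos[k] %in% c(cys_pos, pos[seq_len(k - 1)])) pos[k] <- pos[k] + 1
  }
  pos
}

rand_filler <- function(n) {
  if (n == 0) return(character(0))
  sample(FILLER_AA, n, replace = TRUE)
}

# Build a domain of given length: boundary motifs at the two ends, n_cys
# total cysteines (two sit inside the boundary motifs), REDDD letters at the
# given offsets. Returns list(chars, cys_pos, reddd_pos) (1-based).
build_domain <- function(domain_len, n_cys, reddd_offsets = NULL) {
  if (n_cys < 2) abort("A delimited domain carries at least its 2 motif cysteines")
  n_internal <- n_cys - 2L
  cys_int <- internal_cys_template(domain_len, n_internal)
  if (length(cys_int) < n_internal) {
    abort(sprintf("Domain of %d aa cannot hold %d cysteines", domain_len, n_cys))
  }
  if (is.null(reddd_offsets)) {
    reddd_offsets <- default_reddd_offsets(domain_len, cys_int)
  }
  stopifnot(length(reddd_offsets) == 5)
  if (any(reddd_offsets <= N_MOTIF_LEN) ||
      any(reddd_offsets > domain_len - C_MOTIF_LEN)) {
    abort("REDDD offsets fall outside the domain interior")
  }

  chars <- rand_filler(domain_len)
  chars[1:N_MOTIF_LEN] <- c("N", sample(FILLER_AA, 1), "C",
                            sample(FILLER_AA, 3, replace = TRUE),
                            sample(c("V", "I"), 1), "W")
  cpos <- domain_len - C_MOTIF_LEN + 1L
  chars[cpos:domain_len] <- c("Y", sample(FILLER_AA, 1), sample(c("I", "V"), 1),
                              sample(FILLER_AA, 1), "F", "C",
                              sample(FILLER_AA, 1))
  chars[cys_int] <- "C"
  chars[reddd_offsets] <- REDDD_CANONICAL
  list(
    chars = chars,
    cys_pos = sort(c(3L, cys_int, domain_len - 1L)),
    reddd_pos = reddd_offsets
  )
}

# Kinase region of given length: glycine loop at its start, H-x-D at +100,
# D-x-G at +130 (spacings inside the detector's windows).
build_kinase_region <- function(region_len = 374) {
  stopifnot(region_len >= 200)
  chars <- rand_filler(region_len)
  chars[1:6] <- c("G", sample(FILLER_AA, 1), "G",
                  sample(FILLER_AA, 2, replace = TRUE), "G")
  chars[101:103] <- c("H", "R", "D")
  chars[131:133] <- c("D", "F", "G")
  list(chars = chars, g_loop = 1L, hxd = 101L, dxg = 131L,
       asp = c(103L, 131L))
}

#' Generate one synthetic TLP protein with ground truth
#'
#' Deterministic under `seed`. The sequence satisfies exactly the criteria of
#' its architecture: boundary motifs at recorded positions, the requested
#' cysteine count inside the domain, R/E/D/D/D at the REDDD offsets, and for
#' kinase architectures a 19-residue hydrophobic transmembrane stretch
#' followed by a kinase region with ordered anchor motifs.
#'
#' @param architecture One of `"typical"`, `"small"`, `"tlp_kinase"`,
#'   `"small_tlp_kinase"`.
#' @param seed Integer seed.
#' @param id Sequence id (default derived from architecture and seed).
#' @param domain_len,n_cys Domain length and cysteine count; defaults 215/16
#'   for typical-domain and 150/10 for small-domain architectures.
#' @param reddd_offsets Optional 5 custom REDDD positions (1-based within
#'   the domain).
#' @return List with `record` (one-row protein tibble) and `truth` (list of
#'   planted coordinates, all 0-based half-open on the protein: `label`,
#'   `domain_start`, `domain_end`, `n_motif`, `c_motif`, `n_cys`, `cys_pos`,
#'   `reddd_pos`, and for fusions `tm_start`, `tm_end`, `kinase_start`,
#'   `kinase_end`, `asp_positions`).
#' @export
#' @examples
#' p <- generate_protein("typical", seed = 1)
#' nchar(p$record$sequence)
generate_protein <- function(architecture = c("typical", "small", "tlp_kinase",
                                              "small_tlp_kinase"),
                             seed = 1, id = NULL,
                             domain_len = NULL, n_cys = NULL,
                             reddd_offsets = NULL) {
  architecture <- match.arg(architecture)
  small_domain <- architecture %in% c("small", "small_tlp_kinase")
  has_kinase <- architecture %in% c("tlp_kinase", "small_tlp_kinase")
  domain_len <- domain_len %||% if (small_domain) 150L else 215L
  n_cys <- n_cys %||% if (small_domain) 10L else 16L
  id <- id %||% sprintf("Synth-%s-%d", architecture, seed)

  withr::with_seed(seed, {
    dom <- build_domain(domain_len, n_cys, reddd_offsets)
    if (has_kinase) {
      prefix <- rand_filler(22)
      linker1 <- sample(LINKER_AA, 10, replace = TRUE)
      tm <- strsplit(TM_STRETCH, "")[[1]]
      linker2 <- sample(LINKER_AA, 10, replace = TRUE)
      kin <- build_kinase_region(374)
      chars <- c(prefix, dom$chars, linker1, tm, linker2, kin$chars)
      dstart <- length(prefix)
      kstart <- dstart + domain_len + 10L + 19L + 10L
      truth <- list(
        label = architecture,
        domain_start = dstart, domain_end = dstart + domain_len,
        n_motif = c(dstart, dstart + N_MOTIF_LEN),
        c_motif = c(dstart + domain_len - C_MOTIF_LEN, dstart + domain_len),
        n_cys = n_cys, cys_pos = dstart + dom$cys_pos - 1L,
        reddd_pos = dstart + dom$reddd_pos - 1L,
        tm_start = dstart + domain_len + 10L,
        tm_end = dstart + domain_len + 10L + 19L,
        kinase_start = kstart, kinase_end = length(chars),
        asp_positions = kstart + kin$asp - 1L
      )
    } else {
      prefix <- rand_filler(5)
      suffix <- rand_filler(2)
      chars <- c(prefix, dom$chars, suffix)
      dstart <- length(prefix)
      truth <- list(
        label = architecture,
        domain_start = dstart, domain_end = dstart + domain_len,
        n_motif = c(dstart, dstart + N_MOTIF_LEN),
        c_motif = c(dstart + domain_len - C_MOTIF_LEN, dstart + domain_len),
        n_cys = n_cys, cys_pos = dstart + dom$cys_pos - 1L,
        reddd_pos = dstart + dom$reddd_pos - 1L
      )
    }
    record <- tibble(
      id = id, description = paste0("synthetic ", architecture, " scaffold"),
      organism_code = "Synth", sequence = paste(chars, collapse = ""),
      stop_stripped = FALSE
    )
    list(record = record, truth = truth)
  })
}

#' Generate a set of synthetic TLP proteins
#'
#' @param counts Named integer vector of per-architecture counts, e.g.
#'   `c(typical = 38, tlp_kinase = 4)` to mirror a typical dicot genome
#'   complement.
#' @param seed Integer seed; protein `i` uses `seed + i`.
#' @return List with `proteins` (tibble of records) and `truth` (tibble with
#'   one row per protein: `id`, `label`, `domain_start`, `domain_end`,
#'   `n_cys`).
#' @export
generate_protein_set <- function(counts, seed = 1) {
  stopifnot(!is.null(names(counts)))
  plan <- rep(names(counts), counts)
  out <- imap(plan, function(arch, i) {
    generate_protein(arch, seed = seed + i,
                     id = sprintf("Synth-%s-%03d", arch, i))
  })
  list(
    proteins = list_rbind(map(out, "record")),
    truth = list_rbind(map(out, function(o) {
      tibble(
        id = o$record$id, label = o$truth$label,
        domain_start = o$truth$domain_start, domain_end = o$truth$domain_end,
        n_cys = o$truth$n_cys
      )
    }))
  )
}
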