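# IUPAC consensus scanning of promoters for cis-regulatory elements and
# overlap of predicted TFBSs with methylated cytosines.
#
# Matching is exact IUPAC consensus (no position-weight scores): the
# elements come from consensus-style catalogs, and a score model would
# invent information the consensus does not carry. Low-affinity variants
# are separate catalog entries, not score thresholds.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Built-in cis-regulatory element catalog
#'
#' IUPAC consensus patterns for the core-promoter and hormone-responsive
#' elements scanned in taxane-pathway promoters: transcription initiators
#' (TATA-box, Inr, DPE), facilitators (CAAT-box, Y-patch), MeJA-responsive
#' motifs (CGTCA/TGACG, G-box, E-box), the ethylene-responsive GCC-box,
#' and consensus TF binding sites (W-box/WRKY, MYC, LHY, AP2/ERF). The
#' MYC, LHY and AP2/ERF consensi are documented assumptions -- exact
#' strings vary between prediction databases -- and every entry can be
#' overridden or extended via [read_motif_catalog()].
#'
#' @return A data.frame: `name`, `pattern` (IUPAC), `category`
#'   (`core_element`, `MeJA_responsive`, `ethylene_responsive`,
#'   `TF_binding`), `both_strands` (logical).
#' @examples
#' builtin_catalog()[builtin_catalog()$name == "G-box", ]
#' @export
builtin_catalog <- function() {
  df <- utils::read.table(header = TRUE, text = "
name            pattern    category            both_strands
TATA-box        TATAAA     core_element        TRUE
CAAT-box        CCAAT      core_element        TRUE
Inr             YYCANTYY   core_element        FALSE
DPE             RGWYV      core_element        FALSE
Y-patch         TCTCTCTTC  core_element        FALSE
CGTCA-motif     CGTCA      MeJA_responsive     FALSE
TGACG-motif     TGACG      MeJA_responsive     FALSE
G-box           CACGTG     MeJA_responsive     TRUE
E-box           CANNTG     MeJA_responsive     TRUE
GCC-box         GCCGCC     ethylene_responsive TRUE
W-box           TTGACY     TF_binding          TRUE
MYC-site        CACATG     TF_binding          TRUE
LHY-site        AAAATATCT  TF_binding          TRUE
ERF-site        GCCGGC     TF_binding          TRUE
")
  validate_catalog(df)
}

validate_catalog <- function(df) {
  need <- c("name", "pattern", "category", "both_strands")
  if (!all(need %in% names(df)))
    stop("catalog needs columns ", paste(need, collapse = ", "))
  df$pattern <- toupper(df$pattern)
  bad <- !vapply(strsplit(df$pattern, ""),
                 function(b) length(b) > 0L && all(b %in% IUPAC_LETTERS),
                 logical(1))
  if (any(bad))
    stop("non-IUPAC pattern(s): ", paste(df$name[bad], collapse = ", "))
  if (anyDuplicated(df$name)) stop("duplicate motif names in catalog")
  df$both_strands <- as.logical(df$both_strands)
  rownames(df) <- NULL
  df[need]
}

#' Read a motif catalog from a YAML config
#'
#' The file holds a list of entries with fields `name`, `pattern`,
#' `category`, `both_strands`. With `extend = TRUE` the entries override
#' (by name) or extend the built-in catalog; otherwise they replace it.
#'
#' @param path YAML file path.
#' @param extend Merge with [builtin_catalog()]?
#' @return A validated catalog data.frame.
#' @export
read_motif_catalog <- function(path, extend = TRUE) {
  entries <- yaml::read_yaml(path)
  if (length(entries) == 0L) stop("empty motif catalog: ", path)
  df <- do.call(rbind, lapply(entries, function(e) {
    data.frame(name = e$name, pattern = e$pattern, category = e$category,
               both_strands = isTRUE(e$both_strands))
  }))
  if (extend) {
    base <- builtin_catalog()
    base <- base[!base$name %in% df$name, , drop = FALSE]
    df <- rbind(base, df)
  }
  validate_catalog(df)
}

#' Write a motif catalog as YAML
#' @param catalog Catalog data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_catalog <- function(catalog, path) {
  catalog <- validate_catalog(catalog)
  entries <- lapply(seq_len(nrow(catalog)), function(i)
    list(name = catalog$name[i], pattern = catalog$pattern[i],
         category = catalog$category[i],
         both_strands = catalog$both_strands[i]))
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Scan a reference for IUPAC consensus motif hits
#'
#' All plus-strand matches of each pattern are reported; for
#' `both_strands` entries the reverse complement of the pattern is also
#' matched and reported on the minus strand in plus coordinates.
#' Overlapping hits are all kept.
#'
#' @param ref A `ReferenceRegion` or DNA string.
#' @param catalog Catalog data.frame (default [builtin_catalog()]), or a
#'   single-row subset for one motif.
#' @return A data.frame: `motif_name`, `start`, `end` (1-based closed),
#'   `strand`, `matched_text` (plus-strand sequence of the interval).
#' @examples
#' scan_motifs("TTCACGTGAA", builtin_catalog()[5:9, ])
#' @export
scan_motifs <- function(ref, catalog = builtin_catalog()) {
  seq <- if (inherits(ref, "ReferenceRegion")) ref$sequence
         else normalize_sequence(ref)
  subject <- Biostrings::DNAString(seq)
  catalog <- validate_catalog(catalog)
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    pat <- catalog$pattern[i]
    if (nchar(pat) > nchar(seq)) return(NULL)
    hits <- Biostrings::matchPattern(pat, subject, fixed = "subject")
    rows <- if (length(hits))
      data.frame(motif_name = catalog$name[i],
                 start = Biostrings::start(hits), end = Biostrings::end(hits),
                 strand = "+",
                 matched_text = as.character(hits)) else NULL
    if (catalog$both_strands[i]) {
      rcpat <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pat)))
      mh <- Biostrings::matchPattern(rcpat, subject, fixed = "subject")
      if (length(mh))
        rows <- rbind(rows, data.frame(
          motif_name = catalog$name[i],
          start = Biostrings::start(mh), end = Biostrings::end(mh),
          strand = "-",
          matched_text = as.character(mh)))
    }
    rows
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(motif_name = character(), start = integer(),
                      end = integer(), strand = character(),
                      matched_text = character())
  res <- res[order(res$start, res$end, res$motif_name, res$strand,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Overlap predicted TFBSs with methylated cytosines
#'
#' A hit is "affected by methylation" when at least one methylated
#' cytosine (strict >threshold call, either strand) lies within its span.
#'
#' @param hits Output of [scan_motifs()].
#' @param calls Site table with `position` and `is_methylated`.
#' @return A list with `reports` (one row per hit: `motif_name`, `start`,
#'   `end`, `strand`, `n_methylated_in_span`, `methylated_positions`
#'   (comma-separated), `affected`) and `summary` (per motif: `n_hits`,
#'   `n_affected`).
#' @export
overlap_with_methylation <- function(hits, calls) {
  mpos <- sort(unique(calls$position[!is.na(calls$is_methylated) &
                                     calls$is_methylated]))
  reports <- hits
  inside <- lapply(seq_len(nrow(hits)), function(i)
    mpos[mpos >= hits$start[i] & mpos <= hits$end[i]])
  reports$n_methylated_in_span <- vapply(inside, length, integer(1))
  reports$methylated_positions <- vapply(inside, paste, character(1),
                                         collapse = ",")
  reports$affected <- reports$n_methylated_in_span > 0L
  reports$matched_text <- NULL
  agg <- split(reports, reports$motif_name)
  summary <- do.call(rbind, lapply(names(agg), function(nm)
    data.frame(motif_name = nm, n_hits = nrow(agg[[nm]]),
               n_affected = sum(agg[[nm]]$affected))))
  if (is.null(summary))
    summary <- data.frame(motif_name = character(), n_hits = integer(),
                          n_affected = integer())
  list(reports = reports, summary = summary)
}

#' Write motif hits as BED
#' @param hits Output of [scan_motifs()].
#' @param path Output path.
#' @param chrom First BED column value.
#' @return `path`, invisibly.
#' @export
hits_to_bed <- function(hits, path, chrom = "ref") {
  df <- data.frame(chrom = chrom, start = hits$start - 1L, end = hits$end,
                   name = hits$motif_name, score = 0L, strand = hits$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
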