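# Reference promoter sequences, coordinate conventions, and the
# distal/proximal/core partition around the TSS.
#
# All coordinates in this package are 1-based closed intervals on the plus
# strand; BED export converts to 0-based half-open at the boundary only.

#' Construct an annotated reference promoter region
#'
#' A `ReferenceRegion` holds a promoter (or promoter + early CDS) sequence
#' together with its transcription start site (TSS) and CDS start landmarks.
#' The sequence is normalized to uppercase `{A,C,G,T}` (U is read as T);
#' IUPAC ambiguity codes are rejected because cytosine-context
#' classification and nucleotide composition counting are undefined on them.
#'
#' @param sequence Character scalar, the DNA sequence.
#' @param id Record identifier.
#' @param origin_offset Position of base 1 of `sequence` in the source
#'   record (1 when the whole record is used).
#' @param tss 1-based TSS position within `sequence`, or `NULL`.
#' @param cds_start 1-based CDS start position within `sequence`, or `NULL`.
#' @return An object of class `ReferenceRegion`: a list with fields
#'   `id`, `sequence`, `origin_offset`, `tss`, `cds_start`.
#' @examples
#' ref <- reference_region("acgtACGT", id = "demo", tss = 3)
#' nchar(ref$sequence)
#' @export
reference_region <- function(sequence, id = "ref", origin_offset = 1L,
                             tss = NULL, cds_start = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- normalize_sequence(sequence)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence in record '", id, "'")
  if (!is.null(tss)) {
    tss <- as.integer(tss)
    if (tss < 1L || tss > n) stop("tss outside the reference [1, ", n, "]")
  }
  if (!is.null(cds_start)) {
    cds_start <- as.integer(cds_start)
    if (cds_start < 1L || cds_start > n)
      stop("cds_start outside the reference [1, ", n, "]")
  }
  if (!is.null(tss) && !is.null(cds_start) && tss > cds_start)
    stop("tss (", tss, ") must not lie downstream of cds_start (", cds_start, ")")
  structure(
    list(id = as.character(id), sequence = seq,
         origin_offset = as.integer(origin_offset),
         tss = tss, cds_start = cds_start),
    class = "ReferenceRegion")
}

# Uppercase, U->T, and reject anything outside {A,C,G,T}, naming the first
# offending position.
normalize_sequence <- function(sequence) {
  seq <- chartr("u", "T", toupper(sequence))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L)
    stop("non-ACGT character '", substr(seq, bad, bad),
         "' at position ", as.integer(bad))
  seq
}

#' @export
print.ReferenceRegion <- function(x, ...) {
  cat("ReferenceRegion '", x$id, "': ", nchar(x$sequence), " nt",
      if (!is.null(x$tss)) paste0("; TSS at ", x$tss),
      if (!is.null(x$cds_start)) paste0("; CDS start at ", x$cds_start),
      "\n", sep = "")
  invisible(x)
}

#' Load a reference sequence from FASTA or GenBank
#'
#' Reads the first (or only) record of the file and returns it as a
#' [reference_region()]. FASTA parsing is delegated to
#' [Biostrings::readDNAStringSet()]; GenBank flat files are read from their
#' ORIGIN block. Landmarks (TSS, CDS start) are configuration, not file
#' content, and are supplied through the arguments.
#'
#' @param path File path.
#' @param format `"fasta"` or `"genbank"`.
#' @param tss,cds_start Optional landmark positions (see [reference_region()]).
#' @return A `ReferenceRegion`.
#' @export
load_reference <- function(path, format = c("fasta", "genbank"),
                           tss = NULL, cds_start = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) stop("no records in ", path)
    id <- sub("\\s.*$", "", names(set)[1L])
    seq <- as.character(set[[1L]])
  } else {
    rec <- read_genbank_flat(path)
    id <- rec$id
    seq <- rec$sequence
  }
  reference_region(seq, id = id, tss = tss, cds_start = cds_start)
}

#' Write a reference sequence as FASTA or GenBank
#'
#' @param ref A `ReferenceRegion`.
#' @param path Output path.
#' @param format `"fasta"` or `"genbank"`.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  stopifnot(inherits(ref, "ReferenceRegion"))
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(ref$sequence)
    names(set) <- ref$id
    Biostrings::writeXStringSet(set, path)
  } else {
    write_genbank_flat(ref, path)
  }
  invisible(path)
}

# Minimal GenBank flat-file reader: LOCUS line for the id, ORIGIN block for
# the sequence. Feature tables are ignored (landmarks are config).
read_genbank_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
  o <- grep("^ORIGIN", lines)
  if (length(o) == 0L) stop("no ORIGIN block in ", path)
  body <- lines[(o[1L] + 1L):length(lines)]
  end <- grep("^//", body)
  if (length(end) > 0L) body <- body[seq_len(end[1L] - 1L)]
  seq <- gsub("[0-9 ]", "", paste(body, collapse = ""))
  if (nchar(seq) == 0L) stop("empty record in ", path)
  list(id = id, sequence = seq)
}

write_genbank_flat <- function(ref, path) {
  n <- nchar(ref$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNA",
                     ref$id, n), con)
  writeLines(sprintf("DEFINITION  %s.", ref$id), con)
  writeLines("ORIGIN", con)
  seq <- tolower(ref$sequence)
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Partition a promoter into distal, proximal, and core sub-regions
#'
#' The core promoter is taken as TSS +/- `core_halfwidth` (default 35 nt,
#' the conventional -35..+35 window), the proximal promoter as the
#' `proximal_extent` nucleotides immediately upstream of the core, and the
#' distal promoter as everything further upstream. Intervals are clipped to
#' the sequence; clipped-to-empty intervals are kept and flagged.
#'
#' @param ref A `ReferenceRegion` with `tss` set.
#' @param core_halfwidth Half-width of the core window, nt.
#' @param proximal_extent Upstream extent of the proximal promoter, nt.
#' @return An object of class `RegionPartition`: a list of closed 1-based
#'   intervals `distal`, `proximal`, `core` (each `c(start, end)` or marked
#'   empty), plus `clipped`, a character vector naming clipped regions.
#' @examples
#' ref <- reference_region(strrep("ACGT", 50), tss = 100)
#' partition_regions(ref)
#' @export
partition_regions <- function(ref, core_halfwidth = 35L, proximal_extent = 200L) {
  stopifnot(inherits(ref, "ReferenceRegion"))
  if (is.null(ref$tss)) stop("partition_regions() requires a TSS")
  n <- nchar(ref$sequence)
  tss <- ref$tss
  raw <- list(
    distal   = c(1L, tss - proximal_extent - 1L),
    proximal = c(tss - proximal_extent, tss - core_halfwidth - 1L),
    core     = c(tss - core_halfwidth, tss + core_halfwidth))
  clipped <- character()
  out <- lapply(names(raw), function(nm) {
    iv <- raw[[nm]]
    cl <- c(max(1L, iv[1L]), min(n, iv[2L]))
    if (!identical(as.integer(cl), as.integer(iv)))
      clipped <<- c(clipped, nm)
    if (cl[1L] > cl[2L]) return(NULL)   # empty after clipping
    as.integer(cl)
  })
  names(out) <- names(raw)
  structure(list(distal = out$distal, proximal = out$proximal,
                 core = out$core, y_region = NULL,
                 clipped = clipped, tss = tss, ref_length = n),
            class = "RegionPartition")
}

#' @export
print.RegionPartition <- function(x, ...) {
  fmt <- function(iv) if (is.null(iv)) "(empty)" else
    sprintf("[%d, %d]", iv[1L], iv[2L])
  cat("RegionPartition (TSS at ", x$tss, "):\n",
      "  distal   ", fmt(x$distal), "\n",
      "  proximal ", fmt(x$proximal), "\n",
      "  core     ", fmt(x$core), "\n", sep = "")
  if (!is.null(x$y_region)) cat("  Y-region ", fmt(x$y_region), "\n", sep = "")
  if (length(x$clipped))
    cat("  clipped: ", paste(x$clipped, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a region partition as BED
#'
#' BED is 0-based half-open; the conversion happens here and only here.
#'
#' @param partition A `RegionPartition`.
#' @param path Output path.
#' @param chrom Chromosome/record name for the first BED column.
#' @return `path`, invisibly.
#' @export
partition_to_bed <- function(partition, path, chrom = "ref") {
  stopifnot(inherits(partition, "RegionPartition"))
  rows <- Filter(Negate(is.null),
                 partition[c("distal", "proximal", "core", "y_region")])
  df <- data.frame(
    chrom = chrom,
    start = vapply(rows, function(iv) iv[1L] - 1L, integer(1)),
    end   = vapply(rows, function(iv) iv[2L], integer(1)),
    name  = names(rows))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Regions of a partition as a named list of intervals (used by reports).
partition_intervals <- function(partition, whole = TRUE) {
  iv <- list()
  if (whole) iv$Promoter <- c(1L, partition$ref_length)
  if (!is.null(partition$proximal)) iv[["Proximal promoter"]] <- partition$proximal
  if (!is.null(partition$core)) iv[["Core promoter"]] <- partition$core
  if (!is.null(partition$y_region)) iv[["Y-region"]] <- partition$y_region
  iv
}
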