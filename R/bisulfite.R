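# In-silico bisulfite conversion, cytosine-context annotation on both
# strands, and degenerate (Y/R) primer / amplicon design.

#' Annotate every cytosine of both strands with its methylation context
#'
#' Emits one row per cytosine: plus-strand cytosines are the C positions of
#' the sequence; minus-strand cytosines lie opposite the G positions
#' (coordinates stay on the plus strand). The context is read 5'->3' on the
#' strand carrying the cytosine: next base G gives CG; next base H
#' (A, C or T) followed by G gives CHG; anything else is CHH. Cytosines
#' whose 2-nt context window runs off the sequence end are kept, classified
#' as far as determinable, and flagged `truncated` -- dropping them would
#' silently change the denominators of the methylation summaries.
#'
#' @param ref A `ReferenceRegion` or a plain DNA string.
#' @return A data.frame with columns `position` (1-based, plus strand),
#'   `strand` (`"+"`/`"-"`), `context` (`"CG"`, `"CHG"`, `"CHH"`),
#'   `truncated` (logical), sorted by position then strand.
#' @examples
#' annotate_contexts("AACGTA")
#' @export
annotate_contexts <- function(ref) {
  seq <- if (inherits(ref, "ReferenceRegion")) ref$sequence
         else normalize_sequence(ref)
  b <- strsplit(seq, "")[[1L]]
  n <- length(b)
  at <- function(i) ifelse(i >= 1L & i <= n, b[pmax(pmin(i, n), 1L)], NA)

  classify <- function(n1, n2) {
    # n1, n2: next two bases 5'->3' on the cytosine's strand (NA = off-end)
    ctx <- ifelse(!is.na(n1) & n1 == "G", "CG",
           ifelse(!is.na(n1) & !is.na(n2) & n2 == "G", "CHG",
           ifelse(!is.na(n1) & !is.na(n2), "CHH",
           ifelse(is.na(n1), "CHH",          # nothing determinable: default CHH
           "CHH"))))                          # n1 known H, n2 off-end
    ctx
  }

  plus_pos <- which(b == "C")
  plus_n1 <- at(plus_pos + 1L)
  plus_n2 <- at(plus_pos + 2L)
  plus_ctx <- classify(plus_n1, plus_n2)
  # truncated: the classification needed a base beyond the end
  plus_trunc <- is.na(plus_n1) | (plus_n1 != "G" & is.na(plus_n2))

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  minus_pos <- which(b == "G")
  # 5'->3' on the minus strand runs leftwards on the plus strand
  minus_n1 <- unname(comp[at(minus_pos - 1L)])
  minus_n2 <- unname(comp[at(minus_pos - 2L)])
  minus_ctx <- classify(minus_n1, minus_n2)
  minus_trunc <- is.na(minus_n1) | (minus_n1 != "G" & is.na(minus_n2))

  df <- data.frame(
    position = c(plus_pos, minus_pos),
    strand = rep(c("+", "-"), c(length(plus_pos), length(minus_pos))),
    context = c(plus_ctx, minus_ctx),
    truncated = c(plus_trunc, minus_trunc))
  df <- df[order(df$position, df$strand, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' In-silico bisulfite conversion of the plus strand
#'
#' Unmethylated cytosines deaminate to uracil, read out as T after PCR;
#' 5-methylcytosine resists conversion. Positions listed in
#' `methylated_plus_positions` keep their C; every other plus-strand C
#' becomes T. Non-C bases are untouched.
#'
#' @param sequence DNA string.
#' @param methylated_plus_positions Integer positions (1-based) of protected
#'   cytosines; each must carry a C.
#' @return The converted sequence.
#' @examples
#' convert_in_silico("ACGCT", 2)   # "ACGTT"
#' @export
convert_in_silico <- function(sequence, methylated_plus_positions = integer()) {
  seq <- normalize_sequence(sequence)
  b <- strsplit(seq, "")[[1L]]
  mp <- as.integer(methylated_plus_positions)
  if (length(mp)) {
    bad <- mp[mp < 1L | mp > length(b) | b[pmax(pmin(mp, length(b)), 1L)] != "C"]
    if (length(bad))
      stop("methylated position(s) not carrying C: ", paste(bad, collapse = ", "))
  }
  conv <- b == "C" & !(seq_along(b) %in% mp)
  b[conv] <- "T"
  paste(b, collapse = "")
}

#' Bisulfite conversion efficiency from a demethylated control
#'
#' The control is PCR-amplified (hence fully demethylated) DNA; any
#' apparent methylation on it is residual unconverted cytosine. Efficiency
#' is `100 - mean(specific percents)`. A warning fires below `warn_floor`
#' and an error below `hard_floor`, mirroring the usual wet-lab QC gate.
#'
#' @param control_percents Per-site specific methylation percents measured
#'   on the control.
#' @param warn_floor,hard_floor QC floors in percent.
#' @return Efficiency in percent.
#' @export
conversion_efficiency <- function(control_percents, warn_floor = 95,
                                  hard_floor = 90) {
  p <- control_percents[!is.na(control_percents)]
  if (length(p) == 0L) stop("empty control call set")
  if (any(p < 0 | p > 100)) stop("control percents must lie in [0, 100]")
  eff <- 100 - mean(p)
  if (eff < hard_floor)
    stop(sprintf("conversion efficiency %.2f%% below hard floor %.1f%%",
                 eff, hard_floor))
  if (eff < warn_floor)
    warning(sprintf("conversion efficiency %.2f%% below %.1f%%",
                    eff, warn_floor))
  eff
}

# IUPAC degeneration of bisulfite PCR primers: on the forward primer every
# C may read C or T after conversion, hence Y; on the reverse primer
# (reverse complement of the plus strand) every G may read G or A, hence R.
degenerate_forward <- function(site) chartr("C", "Y", normalize_sequence(site))
degenerate_reverse <- function(site) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(normalize_sequence(site))))
  chartr("G", "R", rc)
}

#' Design degenerate primers tiling a target with overlapping amplicons
#'
#' Tiles `target` with amplicons of `min_len`--`max_len` nt whose
#' consecutive products overlap by at least `min_overlap` nt, the layout
#' used for direct bisulfite sequencing of promoter walks. The forward
#' primer is the plus-strand prefix of the product with C replaced by Y;
#' the reverse primer is the reverse complement of the product's 3' end
#' with G replaced by R, so each primer anneals to the converted template
#' regardless of the template's methylation state. Within a small jitter
#' window each primer start is chosen to minimise the degenerate-base
#' count, then the distance of the non-degenerate GC fraction from 0.5 (a
#' crude melting-temperature proxy).
#'
#' @param ref A `ReferenceRegion` or DNA string.
#' @param target Closed interval `c(start, end)` to cover.
#' @param primer_length Primer length, nt.
#' @param min_len,max_len Allowed product lengths, nt.
#' @param min_overlap Minimum overlap between consecutive products, nt.
#' @param jitter Primer-placement search half-window, nt.
#' @return A data.frame with one row per amplicon: `amplicon`, `start`,
#'   `end`, `length`, `forward_primer`, `reverse_primer`,
#'   `fwd_degenerate_frac`, `rev_degenerate_frac`.
#' @export
design_degenerate_primers <- function(ref, target = NULL, primer_length = 25L,
                                      min_len = 150L, max_len = 300L,
                                      min_overlap = 30L, jitter = 10L) {
  seq <- if (inherits(ref, "ReferenceRegion")) ref$sequence
         else normalize_sequence(ref)
  n <- nchar(seq)
  if (is.null(target)) target <- c(1L, n)
  target <- as.integer(target)
  if (target[1L] < 1L || target[2L] > n || target[1L] >= target[2L])
    stop("target interval outside the reference")
  span <- target[2L] - target[1L] + 1L
  if (span <= min_len)
    stop("target (", span, " nt) not longer than min_len (", min_len, " nt)")
  if (min_overlap >= min_len)
    stop("target uncoverable: min_overlap >= min_len")

  score_site <- function(s, reverse) {
    site <- substr(seq, s, s + primer_length - 1L)
    primer <- if (reverse) degenerate_reverse(site) else degenerate_forward(site)
    deg <- sum(strsplit(primer, "")[[1L]] %in% c("Y", "R"))
    keep <- strsplit(site, "")[[1L]]
    keep <- keep[keep != (if (reverse) "G" else "C")]
    gc <- if (length(keep)) mean(keep %in% c("G", "C")) else 0
    list(start = s, primer = primer, deg = deg, tm_pen = abs(gc - 0.5))
  }
  # choose the best primer start from a candidate window (all within target)
  pick <- function(starts, reverse) {
    cand <- lapply(unique(starts), score_site, reverse = reverse)
    ord <- order(vapply(cand, `[[`, 0, "deg"),
                 vapply(cand, `[[`, 0, "tm_pen"))
    cand[[ord[1L]]]
  }

  if (span <= max_len) {
    prod_len <- span
    starts0 <- target[1L]
    jit <- 0L
  } else {
    # reserve the jitter budget on both sides so jittered products
    # never exceed max_len
    prod_len <- max(min_len, max_len - 2L * jitter)
    step <- prod_len - min_overlap
    n_amp <- ceiling((span - prod_len) / step) + 1L
    starts0 <- target[1L] + (seq_len(n_amp) - 1L) * step
    jit <- as.integer(jitter)
  }

  rows <- lapply(seq_along(starts0), function(i) {
    e0 <- min(starts0[i] + prod_len - 1L, target[2L])
    s0 <- max(target[1L], e0 - prod_len + 1L)
    # forward primer may slide left (grows product and overlap, never shrinks)
    fwd <- pick(seq(max(target[1L], s0 - jit), s0), reverse = FALSE)
    # reverse primer may slide right within the target
    rev_s0 <- e0 - primer_length + 1L
    rev_hi <- min(rev_s0 + jit, target[2L] - primer_length + 1L)
    rev <- pick(seq(rev_s0, max(rev_s0, rev_hi)), reverse = TRUE)
    s <- fwd$start
    e <- rev$start + primer_length - 1L
    data.frame(
      amplicon = sprintf("amp%02d", i),
      start = s, end = e, length = e - s + 1L,
      forward_primer = fwd$primer, reverse_primer = rev$primer,
      fwd_degenerate_frac = fwd$deg / primer_length,
      rev_degenerate_frac = rev$deg / primer_length)
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  cov <- rep(FALSE, span)
  for (i in seq_len(nrow(out)))
    cov[(out$start[i]:out$end[i]) - target[1L] + 1L] <- TRUE
  if (!all(cov))
    stop("target uncoverable under the length constraints (gap at ",
         which(!cov)[1L] + target[1L] - 1L, ")")
  if (any(out$length > max_len))
    stop("amplicon length constraint violated")
  out
}

#' Export annotated cytosine sites as BED
#'
#' One BED line per cytosine (0-based half-open single-base interval), with
#' the context in the name field and the strand column set.
#'
#' @param sites Output of [annotate_contexts()].
#' @param path Output path.
#' @param chrom First BED column value.
#' @return `path`, invisibly.
#' @export
sites_to_bed <- function(sites, path, chrom = "ref") {
  df <- data.frame(chrom = chrom, start = sites$position - 1L,
                   end = sites$position, name = sites$context,
                   score = 0L, strand = sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
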