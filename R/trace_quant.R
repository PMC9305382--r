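# Chromatogram signal model: reading four-channel traces, bisulfite-aware
# read alignment, and the peak-ratio methylation estimator
#   mC = 100 * C/(C+T)  (forward reads, plus-strand cytosines)
#   mC = 100 * G/(G+A)  (reverse reads, minus-strand cytosines)
#
# Trace channels are recorded at plus-strand reference coordinates using
# plus-strand base labels; the `orientation` tag says which sequencing
# direction produced them (reads are never reverse-complemented silently).

#' Construct a trace record
#'
#' @param positions 1-based reference positions, strictly increasing.
#' @param channels Numeric matrix, one row per position, columns
#'   `A`, `C`, `G`, `T`; finite, non-negative intensities.
#' @param sample_id,amplicon_id Identifiers.
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `TraceRecord`.
#' @export
trace_record <- function(positions, channels, sample_id = "sample",
                         amplicon_id = "amp", orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  positions <- as.integer(positions)
  channels <- as.matrix(channels)
  if (length(positions) == 0L) stop("no positions in trace")
  if (is.null(colnames(channels))) colnames(channels) <- c("A", "C", "G", "T")
  channels <- channels[, c("A", "C", "G", "T"), drop = FALSE]
  if (nrow(channels) != length(positions))
    stop("channels/positions length mismatch")
  if (any(!is.finite(channels)) || any(channels < 0))
    stop("channel intensities must be finite and >= 0")
  structure(list(sample_id = sample_id, amplicon_id = amplicon_id,
                 orientation = orientation, positions = positions,
                 channels = channels),
            class = "TraceRecord")
}

#' @export
print.TraceRecord <- function(x, ...) {
  cat("TraceRecord ", x$sample_id, "/", x$amplicon_id, " (", x$orientation,
      "): positions ", min(x$positions), "-", max(x$positions),
      " (", length(x$positions), " called)\n", sep = "")
  invisible(x)
}

#' Read a four-channel trace file
#'
#' The canonical dialect is `trace_tsv`: a tab-separated file with a header
#' line `position A C G T`, one row per base-called position, intensities
#' at the called-base location. AB1 binary chromatograms are not parsed by
#' this package; export peak heights to `trace_tsv` upstream.
#'
#' @param path File path.
#' @param sample_id,amplicon_id,orientation Metadata for the record.
#' @param format Only `"trace_tsv"` is supported.
#' @return A `TraceRecord`.
#' @export
read_trace <- function(path, sample_id = "sample", amplicon_id = "amp",
                       orientation = c("forward", "reverse"),
                       format = c("trace_tsv", "ab1")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "ab1")
    stop("AB1 binary parsing is not implemented; export peak heights to ",
         "trace_tsv (columns: position, A, C, G, T)")
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    stop("malformed trace_tsv ", path, ": need columns ",
         paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("no positions in ", path)
  trace_record(df$position, as.matrix(df[, c("A", "C", "G", "T")]),
               sample_id = sample_id, amplicon_id = amplicon_id,
               orientation = orientation)
}

#' Write a trace record as trace_tsv
#'
#' @param trace A `TraceRecord`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "TraceRecord"))
  df <- data.frame(position = trace$positions, trace$channels,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a bisulfite-converted read to an unconverted reference
#'
#' Global (Needleman--Wunsch) alignment with affine gaps and a
#' bisulfite-aware asymmetric match rule: in forward orientation a read T
#' aligned to a reference C scores as a match (the read derives from a
#' converted template), and read C to reference C is of course also a
#' match; in reverse orientation a read A to a reference G is a match.
#' The asymmetry is one-directional only -- a read C against a reference T
#' is still a mismatch. Off-the-shelf symmetric-substitution aligners
#' cannot express this rule, hence the built-in implementation.
#'
#' @param read Base-called read sequence (plus-strand base labels).
#' @param ref A `ReferenceRegion` or DNA string.
#' @param orientation `"forward"` or `"reverse"`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (gap
#'   penalties positive).
#' @param min_identity Identity floor below which the read is rejected
#'   as unmappable.
#' @return A list with `map` (integer vector: read position ->
#'   reference position, `NA` at read insertions), `identity` (fraction of
#'   aligned read bases scoring as matches), and `score`.
#' @export
align_bisulfite_read <- function(read, ref, orientation = c("forward", "reverse"),
                                 match = 2, mismatch = -3,
                                 gap_open = 10, gap_extend = 1,
                                 min_identity = 0.8) {
  orientation <- match.arg(orientation)
  r <- strsplit(normalize_sequence(read), "")[[1L]]
  s <- strsplit(if (inherits(ref, "ReferenceRegion")) ref$sequence
                else normalize_sequence(ref), "")[[1L]]
  n <- length(r); m <- length(s)
  if (n < 20L) stop("read shorter than 20 nt")

  is_match <- function(a, b) {
    a == b ||
      (orientation == "forward" && a == "T" && b == "C") ||
      (orientation == "reverse" && a == "A" && b == "G")
  }

  NEG <- -1e15
  # Three-state affine DP. M: r[i] aligned to s[j]; X: gap in ref (read
  # insertion, consumes r[i]); Y: gap in read (deletion, consumes s[j]).
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  tbM <- matrix(0L, n + 1L, m + 1L)  # predecessor state: 1=M, 2=X, 3=Y
  tbX <- matrix(0L, n + 1L, m + 1L)
  tbY <- matrix(0L, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -gap_open - (i - 1L) * gap_extend
  for (j in seq_len(m)) Y[1L, j + 1L] <- -gap_open - (j - 1L) * gap_extend
  tbX[-1L, 1L] <- 2L
  tbY[1L, -1L] <- 3L

  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (is_match(r[i], s[j])) match else mismatch
      cand <- c(M[i, j], X[i, j], Y[i, j])
      w <- which.max(cand)
      M[i + 1L, j + 1L] <- cand[w] + sc
      tbM[i + 1L, j + 1L] <- w
      candX <- c(M[i, j + 1L] - gap_open, X[i, j + 1L] - gap_extend,
                 Y[i, j + 1L] - gap_open)
      w <- which.max(candX)
      X[i + 1L, j + 1L] <- candX[w]
      tbX[i + 1L, j + 1L] <- w
      candY <- c(M[i + 1L, j] - gap_open, X[i + 1L, j] - gap_open,
                 Y[i + 1L, j] - gap_extend)
      w <- which.max(candY)
      Y[i + 1L, j + 1L] <- candY[w]
      tbY[i + 1L, j + 1L] <- w
    }
  }
  ends <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- which.max(ends)
  score <- ends[state]

  map <- rep(NA_integer_, n)
  i <- n; j <- m
  matches <- 0L; aligned <- 0L
  while (i > 0L || j > 0L) {
    if (state == 1L) {          # M: r[i] ~ s[j]
      prev <- tbM[i + 1L, j + 1L]
      map[i] <- j
      aligned <- aligned + 1L
      if (is_match(r[i], s[j])) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {   # X: insertion in read
      prev <- tbX[i + 1L, j + 1L]
      i <- i - 1L
    } else {                    # Y: deletion from read
      prev <- tbY[i + 1L, j + 1L]
      j <- j - 1L
    }
    state <- prev
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  identity <- if (aligned > 0L) matches / aligned else 0
  if (identity < min_identity)
    stop(sprintf("unmappable read: alignment identity %.1f%% below %.1f%%",
                 100 * identity, 100 * min_identity))
  list(map = map, identity = identity, score = unname(score))
}

#' Per-site methylation percent from chromatogram channel intensities
#'
#' The direct-bisulfite estimator: the amplicon pools many template
#' molecules, so the mixed peak at a cytosine position carries the
#' population methylation fraction. Forward reads use `100*C/(C+T)`,
#' reverse reads `100*G/(G+A)`; the other two channels are ignored. A site
#' where both formula-relevant channels are zero carries no information
#' and is an error here (report it as no-data, never as 0%).
#'
#' @param signal Named numeric vector with elements `A`, `C`, `G`, `T`.
#' @param orientation `"forward"` or `"reverse"`.
#' @return Percent in `[0, 100]`.
#' @examples
#' site_methylation(c(A = 0, C = 250, G = 2, T = 750), "forward")  # 25
#' @export
site_methylation <- function(signal, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("channel intensities must be finite and >= 0")
  num <- if (orientation == "forward") signal[["C"]] else signal[["G"]]
  den <- num + if (orientation == "forward") signal[["T"]] else signal[["A"]]
  if (den <= 0)
    stop("undefined site: both formula-relevant channels are zero (no-data)")
  100 * num / den
}

#' Quantify every covered cytosine site of a trace
#'
#' Forward traces carry information on plus-strand cytosines (C/T peaks at
#' the C position); reverse traces on minus-strand cytosines (G/A peaks at
#' the plus-strand G position). Sites of the other strand are skipped;
#' covered sites whose two relevant channels are both zero are emitted
#' with `percent = NA` and `flag = "no_data"` so they can be excluded from
#' denominators but still counted by QC.
#'
#' @param trace A `TraceRecord`.
#' @param sites Cytosine annotation from [annotate_contexts()].
#' @return A data.frame: `sample_id`, `amplicon_id`, `orientation`,
#'   `position`, `strand`, `context`, `percent`, `flag`.
#' @export
quantify_trace <- function(trace, sites) {
  stopifnot(inherits(trace, "TraceRecord"))
  want_strand <- if (trace$orientation == "forward") "+" else "-"
  sub <- sites[sites$strand == want_strand &
               sites$position %in% trace$positions, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(sample_id = character(), amplicon_id = character(),
                      orientation = character(), position = integer(),
                      strand = character(), context = character(),
                      percent = numeric(), flag = character()))
  idx <- match(sub$position, trace$positions)
  ch <- trace$channels[idx, , drop = FALSE]
  if (trace$orientation == "forward") {
    num <- ch[, "C"]; den <- ch[, "C"] + ch[, "T"]
  } else {
    num <- ch[, "G"]; den <- ch[, "G"] + ch[, "A"]
  }
  pct <- ifelse(den > 0, 100 * num / den, NA_real_)
  data.frame(sample_id = trace$sample_id, amplicon_id = trace$amplicon_id,
             orientation = trace$orientation, position = sub$position,
             strand = sub$strand, context = sub$context,
             percent = pct,
             flag = ifelse(is.na(pct), "no_data", "ok"))
}

#' Merge replicate measurements of one site
#'
#' Overlapping amplicons (and the forward/reverse read pair) measure some
#' sites more than once; the merged estimate is the unweighted mean
#' (every read is one pooled-template measurement of the same population).
#'
#' @param percents Per-read percents at one site.
#' @return Named list: `percent` (mean), `n` (measurements), `sd`
#'   (dispersion, `NA` for a singleton).
#' @export
merge_replicate_measurements <- function(percents) {
  p <- percents[!is.na(percents)]
  if (length(p) == 0L) stop("no measurements to merge")
  list(percent = mean(p), n = length(p),
       sd = if (length(p) > 1L) stats::sd(p) else NA_real_)
}

#' Quantify and merge a whole sample
#'
#' Runs [quantify_trace()] over all traces of one sample and merges
#' replicate measurements per site.
#'
#' @param traces List of `TraceRecord`s belonging to one sample.
#' @param sites Cytosine annotation from [annotate_contexts()].
#' @param sample_id Sample label for the output.
#' @return A data.frame with one row per measured site: `sample_id`,
#'   `position`, `strand`, `context`, `percent`, `n_reads`, `sd`, `flag`
#'   (`"ok"` or `"no_data"`), sorted by position.
#' @export
quantify_sample <- function(traces, sites, sample_id = NULL) {
  per_read <- do.call(rbind, lapply(traces, quantify_trace, sites = sites))
  if (is.null(per_read) || nrow(per_read) == 0L)
    stop("no cytosine site covered by any trace")
  if (is.null(sample_id)) sample_id <- per_read$sample_id[1L]
  key <- paste(per_read$position, per_read$strand)
  merged <- lapply(split(per_read, key), function(g) {
    ok <- g$percent[!is.na(g$percent)]
    if (length(ok) == 0L)
      return(data.frame(position = g$position[1L], strand = g$strand[1L],
                        context = g$context[1L], percent = NA_real_,
                        n_reads = 0L, sd = NA_real_, flag = "no_data"))
    m <- merge_replicate_measurements(ok)
    data.frame(position = g$position[1L], strand = g$strand[1L],
               context = g$context[1L], percent = m$percent,
               n_reads = m$n, sd = m$sd, flag = "ok")
  })
  out <- do.call(rbind, merged)
  out <- cbind(sample_id = sample_id, out)
  out <- out[order(out$position, out$strand, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
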