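# Nucleotide composition tables, sliding-window pyrimidine (%Y)
# profiling, and detection of the pyrimidine-rich Y-region upstream of
# the CDS.

#' Pyrimidine percentage from nucleotide counts
#'
#' `100 * (C + T) / (A + C + G + T)`; its complement is the purine (AG)
#' percentage.
#'
#' @param counts Named numeric vector with elements `A`, `C`, `G`, `T`.
#' @return Percent in `[0, 100]`, full precision (round to one decimal for
#'   report display).
#' @examples
#' pyrimidine_percent(c(A = 25, C = 4, G = 31, T = 54))  # 50.877...
#' @export
pyrimidine_percent <- function(counts) {
  counts <- counts[c("A", "C", "G", "T")]
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be named non-negative values for A, C, G, T")
  total <- sum(counts)
  if (total == 0) stop("empty region: total count is zero")
  100 * (counts[["C"]] + counts[["T"]]) / total
}

#' Count nucleotides in a region of a reference
#'
#' @param ref A `ReferenceRegion` or DNA string.
#' @param region Closed 1-based interval `c(start, end)`; `NULL` for the
#'   whole sequence.
#' @param label Region label carried into the output.
#' @return A data.frame row: `region_label`, counts `A`, `C`, `G`, `T`,
#'   `ct_percent`, `ag_percent` (full precision).
#' @export
count_nucleotides <- function(ref, region = NULL, label = "region") {
  seq <- if (inherits(ref, "ReferenceRegion")) ref$sequence
         else normalize_sequence(ref)
  n <- nchar(seq)
  if (is.null(region)) region <- c(1L, n)
  region <- as.integer(region)
  if (region[1L] < 1L || region[2L] > n || region[1L] > region[2L])
    stop("empty or out-of-range region [", region[1L], ", ", region[2L], "]")
  sub <- substr(seq, region[1L], region[2L])
  b <- strsplit(sub, "")[[1L]]
  cnt <- c(A = sum(b == "A"), C = sum(b == "C"),
           G = sum(b == "G"), T = sum(b == "T"))
  ct <- pyrimidine_percent(cnt)
  data.frame(region_label = label, A = cnt[["A"]], C = cnt[["C"]],
             G = cnt[["G"]], T = cnt[["T"]],
             ct_percent = ct, ag_percent = 100 - ct)
}

#' Sliding-window pyrimidine profile
#'
#' Percentage of pyrimidines (C or T) in each window of `window_size` nt
#' (default 30, the standard promoter-profiling width), advanced by
#' `step`. Computed with a cumulative-sum trick; each value equals the
#' `ct_percent` of the window substring.
#'
#' @param ref A `ReferenceRegion` or DNA string.
#' @param window_size Window width, nt.
#' @param step Window advance, nt.
#' @return An object of class `WindowProfile`: a data.frame with `start`
#'   (1-based window start) and `y_percent`, plus attributes `window_size`
#'   and `ref_length`.
#' @examples
#' window_profile("CCCCAAAA", window_size = 4)$y_percent  # 100 75 50 25 0
#' @export
window_profile <- function(ref, window_size = 30L, step = 1L) {
  seq <- if (inherits(ref, "ReferenceRegion")) ref$sequence
         else normalize_sequence(ref)
  n <- nchar(seq)
  window_size <- as.integer(window_size)
  if (window_size > n) stop("window (", window_size, ") longer than sequence (", n, ")")
  b <- strsplit(seq, "")[[1L]]
  cum <- c(0L, cumsum(b %in% c("C", "T")))
  starts <- seq.int(1L, n - window_size + 1L, by = as.integer(step))
  y <- 100 * (cum[starts + window_size] - cum[starts]) / window_size
  structure(data.frame(start = starts, y_percent = y),
            window_size = window_size, ref_length = n,
            class = c("WindowProfile", "data.frame"))
}

#' Detect the pyrimidine-rich Y-region upstream of the CDS
#'
#' Windows at or above `threshold` %Y are merged (gaps up to `merge_gap`
#' nt bridged); a merged block qualifies when it spans at least `min_span`
#' nt and its 3' end lies within `anchor_distance` nt of the anchor
#' (normally the CDS start -- the Y-patch region involves at least 100 nt
#' immediately upstream of the CDS). Among qualifying blocks the widest is
#' returned. Returns `NULL` when nothing qualifies.
#'
#' @param profile A `WindowProfile`.
#' @param threshold %Y threshold for a window to count as pyrimidine-rich.
#' @param min_span Minimum block span, nt.
#' @param anchor 1-based anchor position (CDS start).
#' @param anchor_distance Maximum distance of the block's 3' end from the
#'   anchor, nt.
#' @param merge_gap Maximum sub-threshold gap bridged when merging, nt.
#' @return Closed interval `c(start, end)` or `NULL`.
#' @export
detect_y_region <- function(profile, threshold = 55, min_span = 100L,
                            anchor = NULL, anchor_distance = 50L,
                            merge_gap = 10L) {
  stopifnot(inherits(profile, "WindowProfile"))
  w <- attr(profile, "window_size")
  n <- attr(profile, "ref_length")
  if (is.null(anchor)) anchor <- n
  if (anchor < 1L || anchor > n) stop("anchor outside the reference")
  hit <- profile$start[profile$y_percent >= threshold]
  if (length(hit) == 0L) return(NULL)
  # nucleotide coverage of super-threshold windows
  covered <- rep(FALSE, n)
  for (s in hit) covered[s:(s + w - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  blocks <- cbind(starts[r$values], ends[r$values])
  # bridge short gaps
  if (nrow(blocks) > 1L) {
    merged <- blocks[1L, , drop = FALSE]
    for (i in 2L:nrow(blocks)) {
      if (blocks[i, 1L] - merged[nrow(merged), 2L] - 1L <= merge_gap)
        merged[nrow(merged), 2L] <- blocks[i, 2L]
      else merged <- rbind(merged, blocks[i, ])
    }
    blocks <- merged
  }
  span <- blocks[, 2L] - blocks[, 1L] + 1L
  near <- abs(blocks[, 2L] - anchor) <= anchor_distance |
    (blocks[, 1L] <= anchor & blocks[, 2L] >= anchor)
  ok <- which(span >= min_span & near)
  if (length(ok) == 0L) return(NULL)
  best <- ok[which.max(span[ok])]
  c(blocks[best, 1L], blocks[best, 2L])
}

#' Composition table over a region partition
#'
#' One [count_nucleotides()] row per partition region (whole promoter,
#' proximal, core, and the Y-region when present), the layout of the
#' classic promoter-composition table.
#'
#' @param ref A `ReferenceRegion`.
#' @param partition A `RegionPartition` (optionally with `y_region` set).
#' @return A data.frame of composition rows.
#' @export
composition_table <- function(ref, partition) {
  iv <- partition_intervals(partition)
  do.call(rbind, lapply(names(iv), function(nm)
    count_nucleotides(ref, iv[[nm]], label = nm)))
}

#' Write a composition table as TSV in report column order
#'
#' Column order CT%, AG%, C, T, A, G with one-decimal rounding of the
#' percentages (display only; `composition_table()` retains full
#' precision).
#'
#' @param tab Output of [composition_table()] / [count_nucleotides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(tab, path) {
  out <- data.frame(region = tab$region_label,
                    `CT%` = formatC(tab$ct_percent, format = "f", digits = 1),
                    `AG%` = formatC(tab$ag_percent, format = "f", digits = 1),
                    C = tab$C, T = tab$T, A = tab$A, G = tab$G,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published promoter composition counts
#'
#' Single-nucleotide counts and printed CT%/AG% values for the taxane
#' biosynthesis promoters (*GGPPS*, *TXS*, *DBTNBT*) as published for the
#' whole promoter, proximal promoter, core promoter, and Y-region. Some
#' printed rows are not self-consistent (their printed percentages
#' disagree with their own counts); those carry `self_consistent = FALSE`
#' and should be excluded from numeric reproduction.
#'
#' @return A data.frame: `gene`, `region`, printed `ct_percent` and
#'   `ag_percent`, counts `C`, `T`, `A`, `G`, and `self_consistent`.
#' @export
published_composition_counts <- function() {
  df <- utils::read.table(header = TRUE, text = "
gene   region     ct_percent ag_percent C   T   A   G
GGPPS  Promoter   52.3       47.7       178 471 403 188
GGPPS  Proximal   49.0       51.0       27  120 78  25
GGPPS  Core       50.7       49.3       2   34  17  18
GGPPS  Y-region   50.9       49.1       4   54  25  31
TXS    Promoter   48.0       52.0       197 389 434 201
TXS    Proximal   45.0       55.0       46  89  116 49
TXS    Core       54.1       41.9       8   35  24  7
TXS    Y-region   52.3       47.6       15  53  44  18
DBTNBT Promoter   54.4       45.6       458 569 466 398
DBTNBT Proximal   50.5       50.5       65  84  119 32
DBTNBT Core       50.7       49.3       12  27  31  7
DBTNBT Y-region   57.3       42.7       35  28  33  14
")
  recomputed <- vapply(seq_len(nrow(df)), function(i)
    pyrimidine_percent(c(A = df$A[i], C = df$C[i], G = df$G[i], T = df$T[i])),
    numeric(1))
  df$self_consistent <- abs(round(recomputed, 1) - df$ct_percent) < 0.05 &
    abs(round(100 - recomputed, 1) - df$ag_percent) < 0.05
  df
}
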