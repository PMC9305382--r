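# General / specific methylation statistics per context, methylation
# calling, hotspot detection, cell-line comparison, and the text diagram.

CONTEXTS <- c("CG", "CHG", "CHH")

#' Call cytosines as methylated or not
#'
#' A cytosine is called methylated when its specific methylation percent is
#' strictly greater than the threshold (default 50%): exactly 50% is NOT
#' methylated. Sites with `NA` percent (no-data) keep `NA` calls and are
#' excluded from all denominators downstream.
#'
#' @param site_table Per-site table from [quantify_sample()], or a bare
#'   numeric vector of percents.
#' @param threshold Calling threshold in percent.
#' @return The table with an `is_methylated` logical column appended (or,
#'   for a bare vector, the logical vector itself).
#' @examples
#' call_sites(c(0, 50, 50.1))   # FALSE FALSE TRUE
#' @export
call_sites <- function(site_table, threshold = 50) {
  if (is.numeric(site_table)) {
    p <- site_table
    if (any(p < 0 | p > 100, na.rm = TRUE)) stop("percents must lie in [0, 100]")
    return(p > threshold)
  }
  stopifnot(is.data.frame(site_table), "percent" %in% names(site_table))
  site_table$is_methylated <- call_sites(site_table$percent, threshold)
  site_table
}

#' Per-context general and specific methylation summary of one sample
#'
#' General methylation is the percentage of cytosines called methylated
#' (binary, >50% rule); specific methylation is the mean of the per-site
#' percent signals, i.e. the average methylation level across the pooled
#' cell population. One row per context plus a `Total` row pooling all
#' sites. A context with no measured sites is reported with `NA` values
#' (rendered "-" in text reports), never as 0.
#'
#' @param calls Output of [call_sites()] applied to a site table.
#' @return A data.frame: `sample_id`, `context` (`CG`, `CHG`, `CHH`,
#'   `Total`), `n_sites`, `n_methylated`, `general_percent`,
#'   `specific_percent`. Full precision; round only for display.
#' @export
summarize_sample <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("context", "percent", "is_methylated") %in% names(calls)))
  ok <- calls[!is.na(calls$percent), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no measured sites to summarize")
  sample_id <- if ("sample_id" %in% names(calls)) calls$sample_id[1L] else "sample"
  one <- function(sub) {
    if (nrow(sub) == 0L)
      return(c(n_sites = 0, n_methylated = NA, general = NA, specific = NA))
    c(n_sites = nrow(sub), n_methylated = sum(sub$is_methylated),
      general = 100 * mean(sub$is_methylated), specific = mean(sub$percent))
  }
  rows <- rbind(
    t(vapply(CONTEXTS, function(cx) one(ok[ok$context == cx, , drop = FALSE]),
             numeric(4))),
    Total = one(ok))
  data.frame(sample_id = sample_id,
             context = c(CONTEXTS, "Total"),
             n_sites = as.integer(rows[, "n_sites"]),
             n_methylated = as.integer(rows[, "n_methylated"]),
             general_percent = rows[, "general"],
             specific_percent = rows[, "specific"],
             row.names = NULL)
}

#' Star code for a p-value
#'
#' `*` for p < 0.05, `**` for p < 0.005, `***` for p < 0.001 (the most
#' extreme applicable), `ns` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of codes.
#' @export
star_code <- function(p) {
  ifelse(is.na(p), "ns",
  ifelse(p < 0.001, "***",
  ifelse(p < 0.005, "**",
  ifelse(p < 0.05, "*", "ns"))))
}

#' Compare per-site specific methylation between two cell lines
#'
#' Welch's (unequal-variance) two-sample t-test on the per-site specific
#' percents of one context; sites are the statistical units. Degenerate
#' zero-variance inputs, which `t.test()` refuses, are resolved explicitly:
#' both groups constant and equal means gives p = 1; constant groups with
#' different means give the smallest positive representable p with a flag.
#'
#' @param line_a_percents,line_b_percents Per-site specific percents.
#' @param context Context label carried into the result.
#' @return A data.frame row: `context`, `mean_a`, `mean_b`, `t`,
#'   `p_value`, `stars`, `flag` (`"ok"`, `"zero_variance"`, or
#'   `"not_computable"`).
#' @export
compare_lines <- function(line_a_percents, line_b_percents, context = "Total") {
  a <- line_a_percents[!is.na(line_a_percents)]
  b <- line_b_percents[!is.na(line_b_percents)]
  if (length(a) < 2L || length(b) < 2L)
    return(data.frame(context = context, mean_a = mean(a), mean_b = mean(b),
                      t = NA_real_, p_value = NA_real_, stars = "ns",
                      flag = "not_computable"))
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      p <- 1; tval <- 0; flag <- "zero_variance"
    } else {
      p <- .Machine$double.xmin; tval <- Inf * sign(mean(a) - mean(b))
      flag <- "zero_variance"
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    p <- tt$p.value; tval <- unname(tt$statistic); flag <- "ok"
  }
  data.frame(context = context, mean_a = mean(a), mean_b = mean(b),
             t = tval, p_value = p, stars = star_code(p), flag = flag)
}

#' Detect methylation hotspots (runs of consecutive methylated cytosines)
#'
#' A hotspot is a maximal run of at least `min_run` methylated cytosines
#' that are consecutive in the ordered site list, irrespective of the
#' nucleotide distance between neighbouring sites. The default of 4
#' reflects the clustered groups of 4-5 methylated cytosines seen in
#' heavily methylated promoter stretches.
#'
#' @param calls Site table with `position` and `is_methylated`, sorted by
#'   position; `NA` calls break runs.
#' @param min_run Minimum run length.
#' @return A data.frame of intervals: `start`, `end` (positions of the
#'   first and last site of the run), `n_sites`.
#' @export
find_hotspots <- function(calls, min_run = 4L) {
  stopifnot(is.data.frame(calls),
            all(c("position", "is_methylated") %in% names(calls)))
  if (is.unsorted(calls$position)) stop("calls must be sorted by position")
  meth <- !is.na(calls$is_methylated) & calls$is_methylated
  r <- rle(meth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = calls$position[starts[keep]],
             end = calls$position[ends[keep]],
             n_sites = r$lengths[keep])
}

#' Write hotspot intervals as BED
#' @param hotspots Output of [find_hotspots()].
#' @param path Output path.
#' @param chrom First BED column value.
#' @return `path`, invisibly.
#' @export
hotspots_to_bed <- function(hotspots, path, chrom = "ref") {
  df <- data.frame(chrom = chrom, start = hotspots$start - 1L,
                   end = hotspots$end,
                   name = paste0("hotspot_", seq_len(nrow(hotspots))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Glyphs for the text methylation diagram, one per cytosine:
# filled = methylated, empty = unmethylated, "." = no data.
DIAGRAM_GLYPHS <- list(
  CG  = c(meth = "\u25cf", unmeth = "\u25cb"),   # filled / open circle
  CHG = c(meth = "\u25a0", unmeth = "\u25a1"),   # filled / open square
  CHH = c(meth = "\u25b2", unmeth = "\u25b3"))   # filled / open triangle

#' Plain-text per-cytosine methylation diagram
#'
#' One glyph per cytosine in positional order, per sample: circles for CG,
#' squares for CHG, triangles for CHH; filled when methylated, open when
#' not, `.` for no-data sites. An approximate text rendering of the
#' classic per-cytosine methylation diagram.
#'
#' @param call_tables Named list of site tables (one per sample) with
#'   `position`, `context`, `is_methylated`.
#' @param width Glyphs per line.
#' @return Character vector of diagram lines, invisibly printed with
#'   `cat()` when `print = TRUE`.
#' @param print Print the diagram to the console.
#' @export
methylation_diagram <- function(call_tables, width = 60L, print = FALSE) {
  lines <- character()
  for (nm in names(call_tables)) {
    tab <- call_tables[[nm]]
    tab <- tab[order(tab$position), , drop = FALSE]
    glyph <- vapply(seq_len(nrow(tab)), function(i) {
      if (is.na(tab$is_methylated[i])) return(".")
      g <- DIAGRAM_GLYPHS[[tab$context[i]]]
      unname(g[if (tab$is_methylated[i]) "meth" else "unmeth"])
    }, character(1))
    lines <- c(lines, paste0("## ", nm))
    starts <- seq(1L, length(glyph), by = width)
    for (s in starts) {
      chunk <- glyph[s:min(s + width - 1L, length(glyph))]
      lines <- c(lines, paste0(sprintf("%6d ", tab$position[s]),
                               paste(chunk, collapse = "")))
    }
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a two-line methylation summary report
#'
#' Text table mirroring the classic layout: one row per sample, general
#' and specific percentages for CG / CHG / CHH / Total, "-" for contexts
#' with no measured sites, and star codes from the line comparison
#' appended to the specific columns. Percentages are rounded to 2 decimals
#' for display only.
#'
#' @param summaries List of per-sample summaries from [summarize_sample()].
#' @param comparisons Optional data.frame of [compare_lines()] rows
#'   (one per context) whose stars annotate the specific columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_summary <- function(summaries, path, comparisons = NULL) {
  fmt <- function(x, stars = "") {
    ifelse(is.na(x), "-", paste0(formatC(x, format = "f", digits = 2), stars))
  }
  star_of <- function(cx) {
    if (is.null(comparisons)) return("")
    hit <- comparisons$stars[comparisons$context == cx]
    if (length(hit) == 1L && hit != "ns") hit else ""
  }
  rows <- lapply(summaries, function(s) {
    g <- s$general_percent[match(c(CONTEXTS, "Total"), s$context)]
    sp <- s$specific_percent[match(c(CONTEXTS, "Total"), s$context)]
    data.frame(sample = s$sample_id[1L],
               gen_CG = fmt(g[1L]), gen_CHG = fmt(g[2L]),
               gen_CHH = fmt(g[3L]), gen_Total = fmt(g[4L]),
               spec_CG = fmt(sp[1L], star_of("CG")),
               spec_CHG = fmt(sp[2L], star_of("CHG")),
               spec_CHH = fmt(sp[3L], star_of("CHH")),
               spec_Total = fmt(sp[4L], star_of("Total")))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
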