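# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

# Enumerate cytosine sites and contexts by extracting each cytosine's
# downstream 3-mer on its own strand with plain string ops.
oracle_contexts <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  rows <- list()
  for (i in seq_len(n)) {
    for (strand in c("+", "-")) {
      base <- if (strand == "+") b[i] else chartr("ACGT", "TGCA", b[i])
      if (base != "C") next
      nxt <- if (strand == "+") {
        c(if (i + 1 <= n) b[i + 1] else NA,
          if (i + 2 <= n) b[i + 2] else NA)
      } else {
        c(if (i - 1 >= 1) chartr("ACGT", "TGCA", b[i - 1]) else NA,
          if (i - 2 >= 1) chartr("ACGT", "TGCA", b[i - 2]) else NA)
      }
      ctx <- if (!is.na(nxt[1]) && nxt[1] == "G") "CG"
             else if (!is.na(nxt[2]) && nxt[2] == "G") "CHG"
             else "CHH"
      trunc <- is.na(nxt[1]) || (nxt[1] != "G" && is.na(nxt[2]))
      rows[[length(rows) + 1]] <- data.frame(
        position = i, strand = strand, context = ctx, truncated = trunc)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$strand, method = "radix"), ]
  rownames(out) <- NULL
  out
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# Position-by-position IUPAC consensus matcher (plus strand only).
oracle_iupac_match <- function(seq, pattern) {
  sb <- strsplit(seq, "")[[1]]
  pb <- strsplit(pattern, "")[[1]]
  k <- length(pb)
  hits <- integer()
  for (s in seq_len(length(sb) - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k))
      if (!(sb[s + j - 1] %in% IUPAC_SETS[[pb[j]]])) { ok <- FALSE; break }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Recount %Y of one window by direct substring counting.
oracle_window_y <- function(seq, start, w) {
  sub <- strsplit(substr(seq, start, start + w - 1), "")[[1]]
  100 * sum(sub %in% c("C", "T")) / w
}

# Recount a methylation summary from raw calls.
oracle_summary <- function(context, percent, is_meth, cx) {
  keep <- if (cx == "Total") !is.na(percent) else context == cx & !is.na(percent)
  list(n = sum(keep),
       general = 100 * sum(is_meth[keep]) / sum(keep),
       specific = mean(percent[keep]))
}

# Small default-free simulation config for fast tests.
tiny_config <- function(seed = 11, ...) {
  simulation_config(
    seed = seed, ref_length = 700L, tss = 430L, cds_start = 630L,
    planted_features = list(
      list(kind = "cytosine_poor_core", interval = c(395L, 465L), max_c = 2L),
      list(kind = "y_region", interval = c(500L, 629L)),
      list(kind = "hotspot", interval = c(470L, 669L), line = "old"),
      list(kind = "motif", interval = c(480L, 485L), pattern = "CACATG"),
      list(kind = "motif", interval = c(101L, 106L), pattern = "CACGTG")),
    ...)
}
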