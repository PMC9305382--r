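# Seeded synthetic-data generator: reference promoters with planted
# features, two-cell-line methylomes with known ground truth, and noisy
# four-channel Sanger traces -- so every pipeline stage is testable
# without chromatogram downloads.

#' Simulation configuration
#'
#' Defaults emulate the study design this package supports: one old
#' (~14-year) cell line with heavy CG/CHG methylation and elevated CHH in
#' the distal block plus a fully methylated ~200 bp hotspot between TSS
#' and CDS, contrasted with a lightly methylated young line over the same
#' reference. The default per-context true means are the published
#' specific-methylation levels of the most heavily methylated promoter
#' (old line CG 0.92, CHG 0.96, CHH 0.60; new line CG 0.60, CHG 0.53,
#' CHH 0.14).
#'
#' @param seed Integer RNG seed; every draw of the bundle derives from it.
#' @param ref_length Reference length, nt.
#' @param gc_fraction Background GC fraction.
#' @param tss,cds_start Landmark positions.
#' @param planted_features List of features, each
#'   `list(kind, interval, ...)` with kind one of `motif` (field
#'   `pattern`), `y_region`, `cytosine_poor_core` (field `max_c`),
#'   `hotspot` (field `line`).
#' @param line_profiles Per line, per context, `c(mean, sd)` of true
#'   methylation fractions.
#' @param conversion_efficiency Bisulfite conversion probability of an
#'   unmethylated cytosine.
#' @param channel_noise_sd Additive Gaussian channel noise, intensity
#'   units.
#' @param signal_total Total polymorphic-channel intensity per position.
#' @param reads_per_amplicon Forward/reverse read pairs per amplicon.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L,
                              ref_length = 2000L,
                              gc_fraction = 0.40,
                              tss = 1689L,
                              cds_start = 1891L,
                              planted_features = NULL,
                              line_profiles = list(
                                old = list(CG = c(0.92, 0.05),
                                           CHG = c(0.96, 0.05),
                                           CHH = c(0.60, 0.05)),
                                new = list(CG = c(0.60, 0.05),
                                           CHG = c(0.53, 0.05),
                                           CHH = c(0.14, 0.05))),
                              conversion_efficiency = 0.99,
                              channel_noise_sd = 5,
                              signal_total = 300,
                              reads_per_amplicon = 1L) {
  if (is.null(planted_features))
    planted_features <- list(
      list(kind = "cytosine_poor_core", interval = c(tss - 35L, tss + 35L),
           max_c = 2L),
      list(kind = "y_region", interval = c(cds_start - 130L, cds_start - 1L)),
      list(kind = "hotspot", interval = c(tss + 41L, tss + 240L), line = "old"),
      list(kind = "motif", interval = c(tss - 60L, tss - 55L),
           pattern = "CACGTG"),
      list(kind = "motif", interval = c(tss + 61L, tss + 66L),
           pattern = "CACATG"),
      list(kind = "motif", interval = c(501L, 505L), pattern = "CGTCA"))
  cfg <- list(seed = as.integer(seed), ref_length = as.integer(ref_length),
              gc_fraction = gc_fraction, tss = as.integer(tss),
              cds_start = as.integer(cds_start),
              planted_features = planted_features,
              line_profiles = line_profiles,
              conversion_efficiency = conversion_efficiency,
              channel_noise_sd = channel_noise_sd,
              signal_total = signal_total,
              reads_per_amplicon = as.integer(reads_per_amplicon))
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$ref_length > 0L,
            cfg$gc_fraction >= 0, cfg$gc_fraction <= 1,
            cfg$conversion_efficiency >= 0, cfg$conversion_efficiency <= 1,
            cfg$channel_noise_sd >= 0, cfg$signal_total > 0,
            cfg$reads_per_amplicon >= 1L)
  for (f in cfg$planted_features) {
    iv <- f$interval
    if (iv[1L] < 1L || iv[2L] > cfg$ref_length || iv[1L] > iv[2L])
      stop("planted feature interval outside [1, ", cfg$ref_length, "]")
  }
  for (line in cfg$line_profiles)
    for (p in line)
      if (p[1L] < 0 || p[1L] > 1 || p[2L] < 0)
        stop("line profile means must lie in [0,1], sds >= 0")
  structure(cfg, class = c("SimulationConfig", "list"))
}

# Sequence-level planted features must not overlap one another
# (methylome-level hotspots may overlap anything).
check_feature_conflicts <- function(features) {
  seq_kinds <- c("motif", "y_region", "cytosine_poor_core")
  iv <- Filter(function(f) f$kind %in% seq_kinds, features)
  if (length(iv) < 2L) return(invisible(NULL))
  conflicts <- character()
  for (i in seq_len(length(iv) - 1L))
    for (j in (i + 1L):length(iv)) {
      a <- iv[[i]]$interval; b <- iv[[j]]$interval
      if (a[1L] <= b[2L] && b[1L] <= a[2L])
        conflicts <- c(conflicts,
                       sprintf("%s[%d,%d] vs %s[%d,%d]", iv[[i]]$kind,
                               a[1L], a[2L], iv[[j]]$kind, b[1L], b[2L]))
    }
  if (length(conflicts))
    stop("planted features overlap: ", paste(conflicts, collapse = "; "))
  invisible(NULL)
}

# Resolve one concrete instance of an IUPAC pattern (used when planting
# motifs into the reference).
sample_iupac_instance <- function(pattern) {
  amb <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(toupper(pattern), "")[[1L]],
               function(ch) sample(amb[[ch]], 1L), character(1)),
        collapse = "")
}

#' Generate a reference promoter with planted features
#'
#' Pseudo-random background at the requested GC fraction, then planted
#' features overwrite their intervals: concrete motif instances; a
#' pyrimidine-rich, cytosine-dense Y-region block; and a cytosine-poor
#' core window (at most `max_c` cytosines). Deterministic under
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List: `ref` (a `ReferenceRegion` with TSS/CDS set) and `truth`
#'   (a skeleton carrying the planted-feature registry).
#' @export
generate_reference <- function(config) {
  config <- validate_simulation_config(config)
  check_feature_conflicts(config$planted_features)
  set.seed(config$seed)
  gc <- config$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  b <- sample(names(probs), config$ref_length, replace = TRUE, prob = probs)
  for (f in config$planted_features) {
    iv <- f$interval
    idx <- iv[1L]:iv[2L]
    if (f$kind == "motif") {
      inst <- strsplit(sample_iupac_instance(f$pattern), "")[[1L]]
      if (length(inst) != length(idx))
        stop("motif interval length != pattern length")
      b[idx] <- inst
    } else if (f$kind == "y_region") {
      # cytosine-dense pyrimidine block: C 35%, T 35%, A 20%, G 10%
      b[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE,
                       prob = c(0.20, 0.35, 0.10, 0.35))
    } else if (f$kind == "cytosine_poor_core") {
      max_c <- if (is.null(f$max_c)) 2L else f$max_c
      b[idx] <- sample(c("A", "G", "T"), length(idx), replace = TRUE)
      keep_c <- sample(idx, min(max_c, length(idx)))
      b[keep_c] <- "C"
    }
  }
  ref <- reference_region(paste(b, collapse = ""), id = "synthetic_promoter",
                          tss = config$tss, cds_start = config$cds_start)
  list(ref = ref,
       truth = list(features = config$planted_features, methylome = NULL))
}

#' Draw per-site true methylation fractions for each cell line
#'
#' Each cytosine gets one true methylation fraction `m` per line, drawn
#' from the line's per-context normal profile truncated to `[0, 1]`.
#' Symmetric CG pairs share `m` within a line (maintenance methylation
#' acts on both strands of a CpG); CHG/CHH strands are independent. Sites
#' inside a planted hotspot are set to `m = 1` for the designated line.
#' Deterministic under `config$seed` (offset so the reference and the
#' methylome draws are independent streams).
#'
#' @param ref A `ReferenceRegion` from [generate_reference()].
#' @param truth Truth skeleton from [generate_reference()].
#' @param config The [simulation_config()].
#' @return The completed truth list; `truth$methylome` is a data.frame
#'   with `position`, `strand`, `context`, `truncated`, and one `m_<line>`
#'   column per line.
#' @export
generate_methylome <- function(ref, truth, config) {
  config <- validate_simulation_config(config)
  sites <- annotate_contexts(ref)
  set.seed(config$seed + 104729L)  # separate stream from the reference draw
  for (line in names(config$line_profiles)) {
    prof <- config$line_profiles[[line]]
    m <- numeric(nrow(sites))
    for (cx in names(prof)) {
      sel <- sites$context == cx
      m[sel] <- pmin(1, pmax(0, stats::rnorm(sum(sel), prof[[cx]][1L],
                                             prof[[cx]][2L])))
    }
    # symmetric CG pairs share m: copy the plus member onto its partner
    plus_cg <- which(sites$context == "CG" & sites$strand == "+")
    partner <- match(paste(sites$position[plus_cg] + 1L, "-"),
                     paste(sites$position, sites$strand))
    ok <- !is.na(partner)
    m[partner[ok]] <- m[plus_cg[ok]]
    for (f in truth$features)
      if (f$kind == "hotspot" && identical(f$line, line)) {
        sel <- sites$position >= f$interval[1L] & sites$position <= f$interval[2L]
        m[sel] <- 1
      }
    sites[[paste0("m_", line)]] <- m
  }
  truth$methylome <- sites
  truth
}

# Expected retained-C fraction read out at a cytosine with true
# methylation m under conversion efficiency e: methylated templates keep
# C; unmethylated ones convert with probability e.
retained_c_fraction <- function(m, efficiency) m + (1 - m) * (1 - efficiency)

#' Simulate four-channel traces for every line and a demethylated control
#'
#' The reference is tiled into overlapping amplicons
#' ([design_degenerate_primers()]); each amplicon yields
#' `reads_per_amplicon` forward/reverse trace pairs per sample. Channel
#' intensities are mixture-proportional (Sanger pools templates, so peak
#' height tracks population fractions, not read counts): at a plus-strand
#' cytosine the forward trace puts `signal_total * c_frac` on C and the
#' rest on T, where `c_frac = m + (1-m)(1-e)`; reverse traces do the same
#' on G/A at minus-strand cytosine positions. Non-polymorphic positions
#' put all mass on the reference base channel. Independent Gaussian noise
#' (sd `channel_noise_sd`) is added to all four channels and clipped at
#' zero. The control sample is fully demethylated (`m = 0` everywhere).
#' Deterministic under `config$seed`.
#'
#' @param ref A `ReferenceRegion`.
#' @param truth Completed truth from [generate_methylome()].
#' @param config The [simulation_config()].
#' @return Named list of trace lists (`old`, `new`, ..., `control`), each
#'   a list of `TraceRecord`s.
#' @export
simulate_traces <- function(ref, truth, config) {
  config <- validate_simulation_config(config)
  sites <- truth$methylome
  amps <- design_degenerate_primers(ref, c(1L, nchar(ref$sequence)))
  refb <- strsplit(ref$sequence, "")[[1L]]
  e <- config$conversion_efficiency
  S <- config$signal_total
  set.seed(config$seed + 224737L)  # separate stream from methylome draw

  samples <- c(names(config$line_profiles), "control")
  out <- lapply(samples, function(sample) {
    m_col <- if (sample == "control") NULL else paste0("m_", sample)
    traces <- list()
    for (i in seq_len(nrow(amps))) {
      pos <- amps$start[i]:amps$end[i]
      for (rep_i in seq_len(config$reads_per_amplicon)) {
        for (orient in c("forward", "reverse")) {
          ch <- matrix(0, nrow = length(pos), ncol = 4L,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
          ch[cbind(seq_along(pos), match(refb[pos], colnames(ch)))] <- S
          strand <- if (orient == "forward") "+" else "-"
          sel <- sites$strand == strand & sites$position %in% pos
          if (any(sel)) {
            sp <- sites$position[sel]
            m <- if (is.null(m_col)) rep(0, sum(sel)) else sites[[m_col]][sel]
            cf <- retained_c_fraction(m, e)
            row <- match(sp, pos)
            if (orient == "forward") {
              ch[row, "C"] <- S * cf
              ch[row, "T"] <- S * (1 - cf)
              ch[row, "A"] <- 0; ch[row, "G"] <- 0
            } else {
              ch[row, "G"] <- S * cf
              ch[row, "A"] <- S * (1 - cf)
              ch[row, "C"] <- 0; ch[row, "T"] <- 0
            }
          }
          if (config$channel_noise_sd > 0)
            ch <- pmax(ch + stats::rnorm(length(ch),
                                         sd = config$channel_noise_sd), 0)
          traces[[length(traces) + 1L]] <- trace_record(
            pos, ch, sample_id = sample,
            amplicon_id = sprintf("%s_r%d", amps$amplicon[i], rep_i),
            orientation = orient)
        }
      }
    }
    traces
  })
  names(out) <- samples
  out
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Produces `reference.fasta`, `regions.yaml` (landmarks + thresholds),
#' `traces/<line>/<amplicon>_<orientation>.tsv`, `control/...tsv`, and
#' `truth.tsv` in `dir`. Running the pipeline on the bundle must recover
#' the planted truth.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return List: `dir`, `ref`, `truth`, `traces`, `config_path`.
#' @export
end_to_end_fixture <- function(config, dir) {
  config <- validate_simulation_config(config)
  gen <- generate_reference(config)
  truth <- generate_methylome(gen$ref, gen$truth, config)
  traces <- simulate_traces(gen$ref, truth, config)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  write_reference(gen$ref, file.path(dir, "reference.fasta"))
  utils::write.table(truth$methylome, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sample_dirs <- character()
  for (sample in names(traces)) {
    sdir <- if (sample == "control") file.path(dir, "control")
            else file.path(dir, "traces", sample)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    sample_dirs[sample] <- sdir
    for (tr in traces[[sample]])
      write_trace(tr, file.path(sdir, sprintf("%s_%s.tsv", tr$amplicon_id,
                                              tr$orientation)))
  }
  lines <- setdiff(names(traces), "control")
  run_cfg <- list(
    reference = "reference.fasta",
    tss = config$tss, cds_start = config$cds_start,
    samples = as.list(stats::setNames(file.path("traces", lines), lines)),
    control = "control",
    seed = config$seed)
  cfg_path <- file.path(dir, "regions.yaml")
  yaml::write_yaml(run_cfg, cfg_path)
  list(dir = dir, ref = gen$ref, truth = truth, traces = traces,
       config_path = cfg_path)
}
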