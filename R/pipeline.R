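# End-to-end pipeline: load reference -> partition -> annotate contexts ->
# read traces -> quantify -> control QC -> summarize -> compare lines ->
# composition / %Y profile / Y-region -> motif scan -> methylation overlap
# -> reports. A machine-readable manifest is always written.

# Recognised config keys and their defaults. Unknown keys are rejected so
# typos cannot silently disable an option.
RUN_CONFIG_DEFAULTS <- list(
  reference = NULL,            # path to FASTA (required)
  tss = NULL,                  # 1-based TSS position (required)
  cds_start = NULL,            # optional CDS start
  samples = NULL,              # named list: sample id -> trace directory
  control = NULL,              # demethylated-control trace directory
  call_threshold = 50,         # methylation call threshold, percent
  conversion_warn_floor = 95,  # control QC warning floor, percent
  conversion_hard_floor = 90,  # control QC abort floor, percent
  hotspot_min_run = 4L,
  window_size = 30L,
  y_threshold = 55,
  y_min_span = 100L,
  y_anchor_distance = 50L,
  y_merge_gap = 10L,
  core_halfwidth = 35L,
  proximal_extent = 200L,
  motif_catalog = NULL,        # optional YAML overriding the built-in catalog
  orientation_policy = "average",  # "average", "forward", or "reverse"
  seed = 1L)

#' Validate a pipeline run configuration
#'
#' Reads a YAML file (or takes a list), applies defaults, rejects unknown
#' keys, checks threshold ranges, and verifies that every referenced path
#' exists. Relative paths are resolved against the config file's
#' directory.
#'
#' @param config Path to a YAML config, or a named list.
#' @return A fully defaulted, validated `RunConfig` list.
#' @export
validate_config <- function(config) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  unknown <- setdiff(names(config), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(RUN_CONFIG_DEFAULTS, config)
  # modifyList drops NULL-valued keys; keep the full schema so validation
  # is idempotent
  for (k in setdiff(names(RUN_CONFIG_DEFAULTS), names(cfg)))
    cfg[k] <- list(NULL)
  cfg <- cfg[names(RUN_CONFIG_DEFAULTS)]
  for (key in c("reference", "tss", "samples"))
    if (is.null(cfg[[key]])) stop("config field '", key, "' is required")
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  cfg$reference <- resolve(cfg$reference)
  if (!file.exists(cfg$reference))
    stop("config field 'reference': file not found: ", cfg$reference)
  cfg$samples <- lapply(cfg$samples, resolve)
  for (nm in names(cfg$samples))
    if (!dir.exists(cfg$samples[[nm]]))
      stop("config field 'samples.", nm, "': directory not found: ",
           cfg$samples[[nm]])
  if (!is.null(cfg$control)) {
    cfg$control <- resolve(cfg$control)
    if (!dir.exists(cfg$control))
      stop("config field 'control': directory not found: ", cfg$control)
  }
  if (!is.null(cfg$motif_catalog)) {
    cfg$motif_catalog <- resolve(cfg$motif_catalog)
    if (!file.exists(cfg$motif_catalog))
      stop("config field 'motif_catalog': file not found: ", cfg$motif_catalog)
  }
  if (cfg$call_threshold < 0 || cfg$call_threshold > 100)
    stop("config field 'call_threshold': must lie in [0, 100]")
  if (cfg$y_threshold < 0 || cfg$y_threshold > 100)
    stop("config field 'y_threshold': must lie in [0, 100]")
  if (!cfg$orientation_policy %in% c("average", "forward", "reverse"))
    stop("config field 'orientation_policy': must be average/forward/reverse")
  cfg$tss <- as.integer(cfg$tss)
  if (!is.null(cfg$cds_start)) cfg$cds_start <- as.integer(cfg$cds_start)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("RunConfig", "list"))
}

read_trace_dir <- function(dir, sample_id) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no trace_tsv files in ", dir)
  lapply(files, function(f) {
    base <- sub("\\.tsv$", "", basename(f))
    orient <- if (grepl("reverse", base)) "reverse" else "forward"
    read_trace(f, sample_id = sample_id,
               amplicon_id = sub("_(forward|reverse)$", "", base),
               orientation = orient)
  })
}

#' Run the full promoter-methylation pipeline
#'
#' Executes every stage on the configured inputs and writes the report
#' bundle into `out_dir`: per-site percents, two-line methylation summary
#' with star codes, per-context comparisons, composition table, %Y window
#' profile, Y-region and hotspot BEDs, motif hits and methylation-overlap
#' tables, the plain-text methylation diagram, stage-level QC counters,
#' and a JSON manifest (inputs, parameters, output checksums). The run is
#' a pure function of (inputs, config, seed): repeated runs are
#' byte-identical.
#'
#' @param config A `RunConfig` from [validate_config()] (or a path/list,
#'   validated on the fly).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "RunConfig")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qc <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ref <- stage("load", load_reference(config$reference, "fasta",
                                      tss = config$tss,
                                      cds_start = config$cds_start))
  part <- stage("partition", partition_regions(ref, config$core_halfwidth,
                                               config$proximal_extent))
  sites <- stage("annotate_contexts", annotate_contexts(ref))
  qc$n_cytosine_sites <- nrow(sites)

  site_tables <- list()
  for (sample in names(config$samples)) {
    traces <- stage(paste0("read_traces[", sample, "]"),
                    read_trace_dir(config$samples[[sample]], sample))
    if (config$orientation_policy != "average")
      traces <- Filter(function(t) t$orientation == config$orientation_policy,
                       traces)
    tab <- stage(paste0("quantify[", sample, "]"),
                 quantify_sample(traces, sites, sample_id = sample))
    qc[[paste0("n_reads_", sample)]] <- length(traces)
    qc[[paste0("n_sites_no_data_", sample)]] <- sum(tab$flag == "no_data")
    site_tables[[sample]] <- tab
  }

  if (!is.null(config$control)) {
    ctrl_traces <- stage("read_traces[control]",
                         read_trace_dir(config$control, "control"))
    ctrl <- stage("quantify[control]",
                  quantify_sample(ctrl_traces, sites, sample_id = "control"))
    eff <- stage("control_qc",
                 conversion_efficiency(ctrl$percent,
                                       warn_floor = config$conversion_warn_floor,
                                       hard_floor = config$conversion_hard_floor))
    qc$conversion_efficiency_percent <- eff
  }

  calls <- lapply(site_tables, call_sites, threshold = config$call_threshold)
  summaries <- lapply(calls, function(x)
    stage("summarize", summarize_sample(x)))

  comparisons <- NULL
  if (length(calls) == 2L) {
    a <- calls[[1L]]; b <- calls[[2L]]
    comparisons <- do.call(rbind, lapply(c(CONTEXTS, "Total"), function(cx) {
      pa <- if (cx == "Total") a$percent else a$percent[a$context == cx]
      pb <- if (cx == "Total") b$percent else b$percent[b$context == cx]
      compare_lines(pa, pb, context = cx)
    }))
  }

  hotspots <- lapply(calls, find_hotspots, min_run = config$hotspot_min_run)

  comp_prof <- stage("window_profile",
                     window_profile(ref, window_size = config$window_size))
  anchor <- if (!is.null(ref$cds_start)) ref$cds_start else nchar(ref$sequence)
  yreg <- stage("detect_y_region",
                detect_y_region(comp_prof, threshold = config$y_threshold,
                                min_span = config$y_min_span, anchor = anchor,
                                anchor_distance = config$y_anchor_distance,
                                merge_gap = config$y_merge_gap))
  if (!is.null(yreg)) part$y_region <- yreg
  comp_tab <- stage("composition", composition_table(ref, part))

  catalog <- if (is.null(config$motif_catalog)) builtin_catalog()
             else read_motif_catalog(config$motif_catalog)
  hits <- stage("motif_scan", scan_motifs(ref, catalog))
  overlaps <- lapply(calls, function(cl)
    stage("overlap", overlap_with_methylation(hits, cl)))

  # ---- reports -------------------------------------------------------
  out <- function(f) file.path(out_dir, f)
  per_site <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  utils::write.table(per_site, out("per_site.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_methylation_summary(summaries, out("summary.tsv"),
                            comparisons = comparisons)
  if (!is.null(comparisons))
    utils::write.table(comparisons, out("comparisons.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_composition_tsv(comp_tab, out("composition.tsv"))
  utils::write.table(as.data.frame(comp_prof), out("window_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  partition_to_bed(part, out("regions.bed"), chrom = ref$id)
  sites_to_bed(sites, out("sites.bed"), chrom = ref$id)
  for (sample in names(hotspots))
    hotspots_to_bed(hotspots[[sample]],
                    out(sprintf("hotspots_%s.bed", sample)), chrom = ref$id)
  hits_to_bed(hits, out("motif_hits.bed"), chrom = ref$id)
  for (sample in names(overlaps))
    utils::write.table(overlaps[[sample]]$reports,
                       out(sprintf("overlap_%s.tsv", sample)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  writeLines(methylation_diagram(calls), out("diagram.txt"))
  qc_df <- data.frame(counter = names(qc),
                      value = vapply(qc, function(v) as.character(v),
                                     character(1)))
  utils::write.table(qc_df, out("qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    inputs = list(reference = basename(config$reference),
                  samples = lapply(config$samples, basename),
                  control = if (!is.null(config$control))
                    basename(config$control)),
    parameters = config[setdiff(names(RUN_CONFIG_DEFAULTS),
                                c("reference", "samples", "control",
                                  "motif_catalog"))],
    input_md5 = as.list(tools::md5sum(config$reference)),
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$input_md5) <- basename(names(manifest$input_md5))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(ref = ref, partition = part, sites = sites,
                 site_tables = site_tables, calls = calls,
                 summaries = summaries, comparisons = comparisons,
                 hotspots = hotspots, profile = comp_prof,
                 y_region = yreg, composition = comp_tab, hits = hits,
                 overlaps = overlaps, qc = qc, manifest = manifest))
}
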