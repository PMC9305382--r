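test_that("generation is deterministic under the seed", {
  cfg <- tiny_config(seed = 91)
  a <- generate_reference(cfg)
  b <- generate_reference(cfg)
  expect_equal(a$ref$sequence, b$ref$sequence)
  ta <- generate_methylome(a$ref, a$truth, cfg)
  tb <- generate_methylome(b$ref, b$truth, cfg)
  expect_equal(ta$methylome, tb$methylome)
  tra <- simulate_traces(a$ref, ta, cfg)
  trb <- simulate_traces(b$ref, tb, cfg)
  expect_equal(tra$old[[1]]$channels, trb$old[[1]]$channels)
})

test_that("planted sequence features materialize as constructed", {
  cfg <- tiny_config(seed = 47)
  gen <- generate_reference(cfg)
  # planted G-box instance at [101,106]
  gbox <- builtin_catalog()[builtin_catalog()$name == "G-box", ]
  hits <- scan_motifs(gen$ref, gbox)
  expect_true(any(hits$start == 101 & hits$end == 106))
  # cytosine-poor core: at most 2 C over [395,465]
  core <- count_nucleotides(gen$ref, c(395, 465))
  expect_lte(core$C, 2)
  # Y-region block is pyrimidine-rich
  y <- count_nucleotides(gen$ref, c(500, 629))
  expect_gt(y$ct_percent, 55)
})

test_that("overlapping sequence features are rejected with the conflict listed", {
  cfg <- tiny_config(seed = 3)
  cfg$planted_features <- list(
    list(kind = "motif", interval = c(100L, 105L), pattern = "CACGTG"),
    list(kind = "y_region", interval = c(103L, 220L)))
  expect_error(generate_reference(cfg), "overlap.*motif")
})

test_that("methylome draws honour hotspots, degenerate profiles, and CG symmetry", {
  cfg <- tiny_config(seed = 53,
                     line_profiles = list(
                       old = list(CG = c(0.92, 0.05), CHG = c(0.96, 0.05),
                                  CHH = c(0.60, 0.05)),
                       new = list(CG = c(0.60, 0.05), CHG = c(0.53, 0.05),
                                  CHH = c(0.10, 0))))
  gen <- generate_reference(cfg)
  truth <- generate_methylome(gen$ref, gen$truth, cfg)
  m <- truth$methylome
  # hotspot sites fully methylated in the designated line only
  hot <- m$position >= 470 & m$position <= 669
  expect_true(all(m$m_old[hot] == 1))
  expect_false(all(m$m_new[hot] == 1))
  # sd = 0 profile collapses to its mean
  expect_true(all(m$m_new[m$context == "CHH"] == 0.10))
  # symmetric CG pairs share m
  plus <- m[m$context == "CG" & m$strand == "+", ]
  for (i in seq_len(nrow(plus))) {
    p <- m[m$position == plus$position[i] + 1 & m$strand == "-", ]
    if (nrow(p) == 1 && p$context == "CG")
      expect_equal(plus$m_old[i], p$m_old)
  }
  expect_true(all(m$m_old >= 0 & m$m_old <= 1))
})

test_that("per-context means of drawn m track the profile (law of large numbers)", {
  cfg <- simulation_config(seed = 61, ref_length = 12000L, tss = 11000L,
                           cds_start = 11500L, planted_features = list())
  gen <- generate_reference(cfg)
  truth <- generate_methylome(gen$ref, gen$truth, cfg)
  m <- truth$methylome
  for (cx in c("CG", "CHG", "CHH")) {
    sel <- m$context == cx
    expect_gte(sum(sel), 500)
    prof <- cfg$line_profiles$new[[cx]]
    # truncation to [0,1] shifts the mean by < 1 sd/sqrt(n) here
    se <- prof[2] / sqrt(sum(sel))
    expect_lt(abs(mean(m$m_new[sel]) - prof[1]), 3 * se + 0.01)
  }
})

test_that("the trace measurement model reproduces its closed forms", {
  # m = 0.7, perfect conversion, no noise -> exactly 70
  cfg <- tiny_config(seed = 67, channel_noise_sd = 0,
                     conversion_efficiency = 1,
                     line_profiles = list(
                       old = list(CG = c(0.7, 0), CHG = c(0.7, 0),
                                  CHH = c(0.7, 0)),
                       new = list(CG = c(0, 0), CHG = c(0, 0),
                                  CHH = c(0, 0))))
  cfg$planted_features <- cfg$planted_features[
    !vapply(cfg$planted_features, function(f) f$kind == "hotspot", TRUE)]
  gen <- generate_reference(cfg)
  truth <- generate_methylome(gen$ref, gen$truth, cfg)
  traces <- simulate_traces(gen$ref, truth, cfg)
  sites <- annotate_contexts(gen$ref)
  old <- quantify_sample(traces$old, sites, "old")
  expect_true(all(abs(old$percent - 70) < 1e-9))
  # m = 0 with efficiency 1 -> exactly 0
  new <- quantify_sample(traces$new, sites, "new")
  expect_true(all(new$percent == 0))
})

test_that("incomplete conversion appears as the expected artifact on unmethylated DNA", {
  # m = 0, efficiency 0.95, no noise -> estimate exactly 5.0
  cfg <- tiny_config(seed = 71, channel_noise_sd = 0,
                     conversion_efficiency = 0.95,
                     line_profiles = list(
                       old = list(CG = c(0, 0), CHG = c(0, 0), CHH = c(0, 0)),
                       new = list(CG = c(0, 0), CHG = c(0, 0), CHH = c(0, 0))))
  cfg$planted_features <- cfg$planted_features[
    !vapply(cfg$planted_features, function(f) f$kind == "hotspot", TRUE)]
  gen <- generate_reference(cfg)
  truth <- generate_methylome(gen$ref, gen$truth, cfg)
  traces <- simulate_traces(gen$ref, truth, cfg)
  sites <- annotate_contexts(gen$ref)
  tab <- quantify_sample(traces$new, sites, "new")
  expect_true(all(abs(tab$percent - 5) < 1e-9))
})

test_that("the fixture bundle is complete, reproducible, and self-describing", {
  cfg <- tiny_config(seed = 83)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- end_to_end_fixture(cfg, d1)
  b2 <- end_to_end_fixture(cfg, d2)
  expect_true(file.exists(file.path(d1, "reference.fasta")))
  expect_true(file.exists(file.path(d1, "regions.yaml")))
  expect_true(file.exists(file.path(d1, "truth.tsv")))
  expect_gt(length(list.files(file.path(d1, "traces", "old"))), 0)
  expect_gt(length(list.files(file.path(d1, "control"))), 0)
  # byte-identical bundles under the same seed
  files <- list.files(d1, recursive = TRUE)
  expect_equal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
})

test_that("estimator calibration: mean bias within 1 point at default noise", {
  cfg <- simulation_config(seed = 89, ref_length = 4000L, tss = 3500L,
                           cds_start = 3800L, planted_features = list())
  gen <- generate_reference(cfg)
  truth <- generate_methylome(gen$ref, gen$truth, cfg)
  traces <- simulate_traces(gen$ref, truth, cfg)
  sites <- annotate_contexts(gen$ref)
  tab <- quantify_sample(traces$old, sites, "old")
  key <- paste(tab$position, tab$strand)
  m <- truth$methylome$m_old[
    match(key, paste(truth$methylome$position, truth$methylome$strand))]
  expect_gte(nrow(tab), 1000)
  expect_lt(abs(mean(tab$percent - 100 * m)), 1)
})

test_that("calls are correct for sites clearly away from the threshold", {
  cfg <- simulation_config(seed = 97, ref_length = 3000L, tss = 2500L,
                           cds_start = 2800L, planted_features = list(),
                           line_profiles = list(
                             old = list(CG = c(0.65, 0), CHG = c(0.70, 0),
                                        CHH = c(0.60, 0)),
                             new = list(CG = c(0.35, 0), CHG = c(0.30, 0),
                                        CHH = c(0.40, 0))))
  gen <- generate_reference(cfg)
  truth <- generate_methylome(gen$ref, gen$truth, cfg)
  traces <- simulate_traces(gen$ref, truth, cfg)
  sites <- annotate_contexts(gen$ref)
  for (line in c("old", "new")) {
    calls <- call_sites(quantify_sample(traces[[line]], sites, line))
    want <- line == "old"   # all true m >= 0.6 (old) or <= 0.4 (new)
    expect_gte(mean(calls$is_methylated == want, na.rm = TRUE), 0.99)
  }
})
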