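test_that("the built-in catalog carries the canonical elements", {
  cat <- builtin_catalog()
  expect_equal(cat$pattern[cat$name == "G-box"], "CACGTG")
  expect_equal(cat$pattern[cat$name == "TATA-box"], "TATAAA")
  expect_equal(cat$pattern[cat$name == "E-box"], "CANNTG")
  expect_equal(cat$pattern[cat$name == "W-box"], "TTGACY")
  expect_true(all(c("CGTCA-motif", "TGACG-motif", "CAAT-box", "Y-patch",
                    "MYC-site", "LHY-site", "ERF-site") %in% cat$name))
  expect_true(all(cat$category %in% c("core_element", "MeJA_responsive",
                                      "ethylene_responsive", "TF_binding")))
})

test_that("catalog round-trips through YAML and overrides by name", {
  cat <- builtin_catalog()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_motif_catalog(cat, path)
  back <- read_motif_catalog(path, extend = FALSE)
  expect_equal(back, cat)

  ov <- withr::local_tempfile(fileext = ".yaml")
  write_motif_catalog(data.frame(name = "E-box", pattern = "CATTTG",
                                 category = "MeJA_responsive",
                                 both_strands = FALSE), ov)
  merged <- read_motif_catalog(ov, extend = TRUE)
  expect_equal(merged$pattern[merged$name == "E-box"], "CATTTG")
  expect_equal(sum(merged$name == "E-box"), 1)
  hits <- scan_motifs("GGCATTTGGG", merged[merged$name == "E-box", ])
  expect_equal(nrow(hits), 1)
})

test_that("scanning reports palindromes on both strands and IUPAC wildcards", {
  gbox <- builtin_catalog()[builtin_catalog()$name == "G-box", ]
  hits <- scan_motifs("TTCACGTGAA", gbox)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(3L, 3L))
  expect_equal(hits$end, c(8L, 8L))
  expect_setequal(hits$strand, c("+", "-"))

  ebox <- builtin_catalog()[builtin_catalog()$name == "E-box", ]
  h2 <- scan_motifs("CATTTG", ebox)
  expect_true(any(h2$start == 1 & h2$end == 6 & h2$strand == "+"))
})

test_that("hit sets equal the brute-force IUPAC matcher on random sequences", {
  set.seed(404)
  cat <- builtin_catalog()
  for (i in 1:100) {
    seq <- random_dna(sample(100:400, 1), gc = runif(1, 0.3, 0.7))
    motif <- cat[sample(nrow(cat), 1), ]
    hits <- scan_motifs(seq, motif)
    expect_equal(sort(hits$start[hits$strand == "+"]),
                 oracle_iupac_match(seq, motif$pattern),
                 info = motif$name)
    if (motif$both_strands) {
      rc_hits <- oracle_iupac_match(revcomp_chr(seq), motif$pattern)
      minus <- sort(nchar(seq) - (rc_hits + nchar(motif$pattern) - 1) + 1)
      expect_equal(sort(hits$start[hits$strand == "-"]), minus,
                   info = motif$name)
    }
  }
})

test_that("scanning the reverse complement mirrors the hit set", {
  set.seed(19)
  cat <- builtin_catalog()
  both <- cat[cat$both_strands, ]
  for (i in 1:20) {
    seq <- random_dna(300)
    motif <- both[sample(nrow(both), 1), ]
    fwd <- scan_motifs(seq, motif)
    rev <- scan_motifs(revcomp_chr(seq), motif)
    n <- nchar(seq)
    mirrored <- sort(n - rev$end + 1)
    expect_equal(sort(fwd$start), mirrored, info = motif$name)
  }
})

test_that("a length-1 N pattern hits every position", {
  seq <- random_dna(50)
  hits <- scan_motifs(seq, data.frame(name = "any", pattern = "N",
                                      category = "core_element",
                                      both_strands = FALSE))
  expect_equal(hits$start, 1:50)
})

test_that("methylation overlap uses closed-interval containment", {
  hits <- data.frame(motif_name = "m", start = 10L, end = 15L, strand = "+",
                     matched_text = "ACGTAC")
  calls <- data.frame(position = c(12L, 16L),
                      is_methylated = c(TRUE, TRUE))
  ov <- overlap_with_methylation(hits, calls)
  expect_true(ov$reports$affected)
  expect_equal(ov$reports$n_methylated_in_span, 1L)
  expect_equal(ov$reports$methylated_positions, "12")

  calls2 <- data.frame(position = 16L, is_methylated = TRUE)
  expect_false(overlap_with_methylation(hits, calls2)$reports$affected)
})

test_that("overlap counts are order-invariant and match a planted layout", {
  cfg <- tiny_config(
    seed = 37, channel_noise_sd = 0, conversion_efficiency = 1,
    line_profiles = list(old = list(CG = c(0.1, 0), CHG = c(0.1, 0),
                                    CHH = c(0.1, 0)),
                         new = list(CG = c(0.1, 0), CHG = c(0.1, 0),
                                    CHH = c(0.1, 0))))
  gen <- generate_reference(cfg)
  truth <- generate_methylome(gen$ref, gen$truth, cfg)
  traces <- simulate_traces(gen$ref, truth, cfg)
  sites <- annotate_contexts(gen$ref)
  calls <- call_sites(quantify_sample(traces$old, sites, "old"))
  myc <- builtin_catalog()[builtin_catalog()$name == "MYC-site", ]
  gbox <- builtin_catalog()[builtin_catalog()$name == "G-box", ]
  hits <- rbind(scan_motifs(gen$ref, myc), scan_motifs(gen$ref, gbox))
  ov <- overlap_with_methylation(hits, calls)
  # the MYC instance planted at [480,485] sits inside the hotspot [470,669]
  planted_myc <- ov$reports[ov$reports$start == 480, ]
  expect_true(all(planted_myc$affected))
  # the G-box planted at [101,106] lies outside it (background m = 0.1)
  planted_gbox <- ov$reports[ov$reports$start == 101, ]
  expect_false(any(planted_gbox$affected))

  shuf <- overlap_with_methylation(hits[sample(nrow(hits)), ],
                                   calls[sample(nrow(calls)), ])
  a <- ov$summary[order(ov$summary$motif_name), ]
  b <- shuf$summary[order(shuf$summary$motif_name), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
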