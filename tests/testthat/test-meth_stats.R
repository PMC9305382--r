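test_that("methylation calling is strictly greater-than the threshold", {
  expect_equal(call_sites(c(50, 50.1, 0, 100)), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(call_sites(c(-1, 50)), "\\[0, 100\\]")
  tab <- data.frame(percent = c(50, 50.0001, NA))
  out <- call_sites(tab)
  expect_equal(out$is_methylated, c(FALSE, TRUE, NA))
})

test_that("summaries reproduce the worked general/specific arithmetic", {
  tab <- data.frame(
    sample_id = "s",
    context = c("CG", "CG", "CHH", "CHH", "CHH"),
    percent = c(80, 20, 60, 55, 10))
  s <- summarize_sample(call_sites(tab))
  expect_equal(s$general_percent[s$context == "CG"], 50)
  expect_equal(s$general_percent[s$context == "CHH"], 200 / 3)
  expect_equal(s$general_percent[s$context == "Total"], 60)
  expect_equal(s$specific_percent[s$context == "CG"], 50)
  expect_equal(s$specific_percent[s$context == "CHH"], 125 / 3)
  expect_equal(s$specific_percent[s$context == "Total"], 45)
  # absent context reported NA (rendered "-"), never 0
  expect_true(is.na(s$general_percent[s$context == "CHG"]))

  zero <- data.frame(sample_id = "z", context = c("CG", "CHH"),
                     percent = c(0, 0))
  sz <- summarize_sample(call_sites(zero))
  expect_equal(sz$general_percent[sz$context == "Total"], 0)
  expect_equal(sz$specific_percent[sz$context == "Total"], 0)
})

test_that("summaries equal a brute-force recount on random inputs", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(5:80, 1)
    tab <- data.frame(
      sample_id = "r",
      context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
      percent = round(runif(n, 0, 100), 2))
    calls <- call_sites(tab)
    s <- summarize_sample(calls)
    for (cx in c("CG", "CHG", "CHH", "Total")) {
      o <- oracle_summary(tab$context, tab$percent, calls$is_methylated, cx)
      row <- s[s$context == cx, ]
      expect_equal(row$n_sites, o$n)
      if (o$n > 0) {
        expect_equal(row$general_percent, o$general)
        expect_equal(row$specific_percent, o$specific)
      } else {
        expect_true(is.na(row$general_percent))
      }
    }
    # Total specific = site-count-weighted mean of context specifics
    ctx <- s[s$context != "Total" & s$n_sites > 0, ]
    expect_equal(s$specific_percent[s$context == "Total"],
                 sum(ctx$specific_percent * ctx$n_sites) / sum(ctx$n_sites))
  }
})

test_that("general percent ignores perturbations that do not cross the threshold", {
  set.seed(8)
  tab <- data.frame(sample_id = "p", context = rep("CHH", 30),
                    percent = runif(30, 0, 100))
  base <- summarize_sample(call_sites(tab))
  jit <- tab
  eps <- pmin(abs(jit$percent - 50) / 2, 1)
  jit$percent <- jit$percent + ifelse(jit$percent > 50, -eps, eps)
  pert <- summarize_sample(call_sites(jit))
  expect_equal(pert$general_percent, base$general_percent)
})

test_that("line comparison is Welch's t-test with explicit degenerate rules", {
  same <- compare_lines(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")

  sep <- compare_lines(c(0, 0, 0, 0), c(100, 100, 100, 100))
  expect_equal(sep$p_value, .Machine$double.xmin)
  expect_equal(sep$stars, "***")
  expect_equal(sep$flag, "zero_variance")

  set.seed(12)
  a <- rnorm(20, 40, 10); b <- rnorm(25, 55, 20)
  got <- compare_lines(a, b, "CHH")
  want <- t.test(a, b, var.equal = FALSE)
  expect_equal(got$p_value, want$p.value)
  expect_equal(got$t, unname(want$statistic))

  expect_equal(compare_lines(5, c(1, 2, 3))$flag, "not_computable")
})

test_that("star coding follows the <0.05/<0.005/<0.001 thresholds", {
  expect_equal(star_code(c(0.5, 0.049, 0.0049, 0.0009, 0.05, 0.005, 0.001)),
               c("ns", "*", "**", "***", "ns", "*", "**"))
})

test_that("hotspots are maximal runs of >= min_run consecutive methylated sites", {
  tab <- data.frame(position = c(10, 14, 17, 30, 42),
                    is_methylated = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  h <- find_hotspots(tab)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 10)
  expect_equal(h$end, 30)
  expect_equal(h$n_sites, 4L)

  alt <- data.frame(position = 1:5,
                    is_methylated = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(nrow(find_hotspots(alt)), 0)

  # runs are broken by no-data sites
  nd <- data.frame(position = 1:9,
                   is_methylated = c(TRUE, TRUE, NA, TRUE, TRUE, TRUE, TRUE,
                                     TRUE, FALSE))
  h2 <- find_hotspots(nd)
  expect_equal(h2$start, 4)
  expect_equal(h2$end, 8)
})

test_that("a planted fully methylated block yields exactly one covering hotspot", {
  # low-background methylome: only the planted block exceeds the threshold
  cfg <- tiny_config(
    seed = 19, channel_noise_sd = 0, conversion_efficiency = 1,
    line_profiles = list(old = list(CG = c(0.2, 0), CHG = c(0.2, 0),
                                    CHH = c(0.2, 0)),
                         new = list(CG = c(0.1, 0), CHG = c(0.1, 0),
                                    CHH = c(0.1, 0))))
  gen <- generate_reference(cfg)
  truth <- generate_methylome(gen$ref, gen$truth, cfg)
  traces <- simulate_traces(gen$ref, truth, cfg)
  sites <- annotate_contexts(gen$ref)
  calls <- call_sites(quantify_sample(traces$old, sites, "old"))
  h <- find_hotspots(calls)
  expect_equal(nrow(h), 1)
  planted <- c(470L, 669L)
  site_in <- sites$position[sites$position >= planted[1] &
                            sites$position <= planted[2]]
  expect_lte(h$start, min(site_in))
  expect_gte(h$end, max(site_in))
})

test_that("the text diagram encodes context and state one glyph per cytosine", {
  tabs <- list(old = data.frame(position = c(3, 5, 9),
                                context = c("CG", "CHG", "CHH"),
                                is_methylated = c(TRUE, FALSE, NA)))
  lines <- methylation_diagram(tabs)
  expect_equal(lines[1], "## old")
  row <- sub("^\\s*\\d+ ", "", lines[2])
  expect_equal(nchar(row), 3)
  expect_equal(substr(row, 1, 1), "\u25cf")  # methylated CG: filled circle
  expect_equal(substr(row, 2, 2), "\u25a1")  # unmethylated CHG: open square
  expect_equal(substr(row, 3, 3), ".")       # no data
})

test_that("the summary report renders '-' for absent contexts and stars", {
  tab <- data.frame(sample_id = "TXS_like",
                    context = c("CG", "CHH", "CHH"),
                    percent = c(80, 10, 20))
  s <- summarize_sample(call_sites(tab))
  cmp <- data.frame(context = "CG", stars = "**")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_methylation_summary(list(s), path, comparisons = cmp)
  txt <- readLines(path)
  expect_match(txt[2], "\t-\t")      # CHG column rendered as "-"
  expect_match(txt[2], "80.00\\*\\*")
})
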