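# Read filtering, classification and library metrics.

test_that("expected errors follow the closed form sum of 10^(-Q/10)", {
  expect_equal(expected_errors(strrep("5", 10)), 0.1)            # 10 x Q20
  expect_equal(expected_errors(strrep("?", 100)), 0.1)           # 100 x Q30
  expect_equal(expected_errors("$"), 10^(-0.3))                  # one Q3 base
  expect_gt(expected_errors("$"), 0.5)                           # fails <0.5 alone
  expect_equal(expected_errors(""), 0)
  expect_equal(expected_errors(c(20, 20, 30)), 2 * 0.01 + 0.001)
  expect_equal(expected_errors(c(strrep("5", 10), strrep("?", 100))),
               c(0.1, 0.1))
  expect_error(expected_errors(c(-1, 10)), ">= 0")
})

test_that("adapter gating extracts the inner window and counts failures", {
  p <- read_filter_params(left_adapter = "ACGTAC", right_adapter = "TTGGCC")
  reads <- c("ACGTACAAATTTCCCTTGGCC",   # exact
             "ACGTACAAATTTCCC",         # right missing
             "GGGTACAAATTTCCCTTGGCC",   # left broken
             "ACGTA")                   # shorter than both adapters
  got <- gate_adapters(reads, p)
  expect_identical(got$status,
                   c("kept", "right_fail", "left_fail", "left_fail"))
  expect_identical(got$window[1], "AAATTTCCC")
  # one mismatch tolerated when allowed
  p1 <- read_filter_params(left_adapter = "ACGTAC", right_adapter = "TTGGCC",
                           adapter_max_mismatches = 1L)
  got1 <- gate_adapters("ACTTACAAATTTCCCTTGGCC", p1)
  expect_identical(got1$status, "kept")
  expect_identical(gate_adapters("ACTTACAAATTTCCCTTGGCC", p)$status,
                   "left_fail")
})

test_that("pair merging recovers the molecule and takes the higher-quality base", {
  mol <- withr::with_seed(19, paste(sample(c("A", "C", "G", "T"), 150,
                                           replace = TRUE), collapse = ""))
  fwd <- substr(mol, 1, 95)
  rev <- revcomp(substring(mol, 56))            # 95 nt, 40 nt overlap
  q <- strrep("I", 95)
  m <- merge_pairs(fwd, rev, q, q)
  expect_true(m$merged)
  expect_identical(m$seq, mol)
  # disagreement resolved toward the higher quality, quality |Q1-Q2|
  fwd2 <- "AAAAAAAAAAAAAAAAAAAAC"  # last base disagrees inside overlap
  rev2 <- revcomp("AAAAAAAAAAAAAAAAAAAAT")
  fq <- paste0(strrep("I", 20), intToUtf8(35 + 33))  # Q35 at the clash
  rq <- strrep(intToUtf8(10 + 33), 21)               # Q10 mate
  m2 <- merge_pairs(fwd2, rev2, fq, rq)
  expect_identical(substr(m2$seq, 21, 21), "C")
  expect_identical(utf8ToInt(substr(m2$qual, 21, 21)) - 33L, 25L)
})

test_that("simulated error-free pairs all merge back to their molecules", {
  tg <- random_template(10L, gc = 0.5, seed = 23)
  cfg <- sim_config(n_reads = 1000L, paired = TRUE, read_length = 60L,
                    seed = 23)
  sim <- simulate_library(tg, "suni", cfg)
  m <- merge_pairs(sim$reads$seq, sim$reads2$seq,
                   sim$reads$qual, sim$reads2$qual)
  expect_true(all(m$merged))
  # consensus must equal the original molecules: rebuild them via single-end
  cfg1 <- sim_config(n_reads = 1000L, paired = FALSE, seed = 23)
  sim1 <- simulate_library(tg, "suni", cfg1)
  expect_identical(m$seq, sim1$reads$seq)
})

test_that("expected variant sets have the right size and never contain WT", {
  tg <- fixture_target()
  es_nnk <- build_expected_set(tg, "NNK")
  wt <- wt_codons(tg)
  sizes <- table(es_nnk$variants$codon_index)
  expected_sizes <- ifelse(substr(wt$wt_codon, 3, 3) %in% c("G", "T"),
                           31L, 32L)
  expect_identical(as.integer(sizes), expected_sizes)
  expect_false(es_nnk$wt_window %in% es_nnk$variants$seq)
  # every variant differs from WT in exactly one codon
  es <- build_expected_set(tg, "suni")
  codon_of <- function(s, j) substr(s, 3 * j + 1, 3 * j + 3)
  idx <- sample(seq_len(nrow(es$variants)), 50)
  for (i in idx) {
    v <- es$variants[i, ]
    diffs <- vapply(seq_len(nchar(es$wt_window) / 3) - 1L, function(j) {
      codon_of(v$seq, j) != codon_of(es$wt_window, j)
    }, logical(1))
    expect_identical(sum(diffs), 1L)
    expect_identical(which(diffs) - 1L, v$codon_index)
  }
  expect_error(build_expected_set(tg, data.frame(codon_index = 0L,
                                                 scheme = "NNK")),
               "missing codon indices")
})

test_that("classification is a perfect-match partition", {
  tg <- fixture_target()
  es <- build_expected_set(tg, "suni")
  wt <- es$wt_window
  v1 <- es$variants$seq[10]
  two <- paste0("TTT", "TTT", substring(wt, 7)) # two codons changed
  got <- classify_reads(c(wt, v1, two, "ACGT"), es)
  expect_identical(got$class, c("wild_type", "programmed", "other", "other"))
  expect_identical(got$codon, c(NA, es$variants$codon[10], NA, NA))
  tab <- tally_variants(got, es)
  expect_identical(tab$total_retained,
                   tab$wt_count + tab$other_count + sum(tab$counts$count))
})

test_that("metrics match a spreadsheet-checked hand computation", {
  tab <- hand_count_table()
  m <- compute_metrics(tab)
  expect_equal(m$pct_programmed, 76.7441860465, tolerance = 1e-9)
  expect_equal(m$pct_wt, 17.4418604651, tolerance = 1e-9)
  expect_equal(m$logdiff, 0.8481139860, tolerance = 1e-9)
  expect_equal(m$screening_efficiency, 0.1088758349, tolerance = 1e-9)
  expect_identical(m$n_zero_count_variants, 1L)
  expect_equal(m$per_position_median_freq$median_freq,
               c(0.0116279069767, 0.0203488372093, 0.0392441860465),
               tolerance = 1e-9)
  # percentage partition and definitional identity
  expect_equal(m$pct_programmed + m$pct_wt + m$pct_other, 100,
               tolerance = 1e-9)
  expect_equal(m$screening_efficiency * 10^m$logdiff * 100,
               m$pct_programmed, tolerance = 1e-9)
})

test_that("uniform counts give LogDiff 0 and efficiency = programmed fraction", {
  tab <- hand_count_table()
  tab$counts$count <- rep(12L, nrow(tab$counts))
  tab$total_retained <- sum(tab$counts$count) + tab$wt_count + tab$other_count
  m <- compute_metrics(tab)
  expect_equal(m$logdiff, 0)
  expect_equal(m$screening_efficiency, m$pct_programmed / 100)
})

test_that("adding WT reads lowers %programmed and efficiency, not LogDiff", {
  tab <- hand_count_table()
  m0 <- compute_metrics(tab)
  # frequencies change but their ratios do not, so LogDiff is invariant
  tab2 <- tab
  tab2$wt_count <- tab$wt_count + 500L
  tab2$total_retained <- tab$total_retained + 500L
  m1 <- compute_metrics(tab2)
  expect_lt(m1$pct_programmed, m0$pct_programmed)
  expect_lt(m1$screening_efficiency, m0$screening_efficiency)
  expect_equal(m1$logdiff, m0$logdiff, tolerance = 1e-9)
})

test_that("too few nonzero variants is a metrics error", {
  tab <- hand_count_table()
  tab$counts <- tab$counts[1:9, ]
  expect_error(compute_metrics(tab), "percentiles unstable")
})

test_that("zero-count handling is explicit and switchable", {
  tab <- hand_count_table()
  m_ex <- compute_metrics(tab, zero_policy = "exclude")
  m_ps <- compute_metrics(tab, zero_policy = "pseudo")
  expect_identical(m_ex$n_zero_count_variants, 1L)
  expect_gt(m_ps$logdiff, m_ex$logdiff) # pseudo-count widens the spread here
})

test_that("the QC pipeline conserves reads across stages and is deterministic", {
  tg <- random_template(10L, gc = 0.5, seed = 29)
  cfg <- sim_config(n_reads = 20000L, wt_fraction = 0.25,
                    other_fraction = 0.1, seed = 29)
  sim <- simulate_library(tg, "suni", cfg)
  fp <- read_filter_params(left_adapter = sim$adapters[1],
                           right_adapter = sim$adapters[2])
  qc1 <- run_qc(sim$reads, NULL, tg, "suni", fp)
  qc2 <- run_qc(sim$reads, NULL, tg, "suni", fp)
  expect_identical(qc1$table$counts, qc2$table$counts)
  rep1 <- qc1$report
  n_raw <- rep1$n_out[rep1$stage == "input"]
  expect_identical(n_raw, sum(rep1$n_discarded) + qc1$table$total_retained)
  # recovered composition close to the generator's
  expect_lt(abs(qc1$metrics$pct_wt / 100 - 0.25),
            3 * sqrt(0.25 * 0.75 / 20000))
  # reads flipped to the reverse strand classify identically
  flipped <- sim$reads
  flipped$seq <- revcomp(flipped$seq)
  qc3 <- run_qc(flipped, NULL, tg, "suni", fp)
  expect_identical(qc3$table$counts, qc1$table$counts)
})

test_that("low-quality reads are removed by the expected-error filter", {
  tg <- random_template(10L, gc = 0.5, seed = 37)
  cfg <- sim_config(n_reads = 500L, quality = 12L, seed = 37) # EE >> 0.5
  sim <- simulate_library(tg, "suni", cfg)
  fp <- read_filter_params(left_adapter = sim$adapters[1],
                           right_adapter = sim$adapters[2])
  expect_error(run_qc(sim$reads, NULL, tg, "suni", fp), "Empty library")
})

test_that("QC results serialize to counts TSV and metrics JSON", {
  tg <- random_template(10L, gc = 0.5, seed = 29)
  cfg <- sim_config(n_reads = 5000L, seed = 29)
  sim <- simulate_library(tg, "suni", cfg)
  fp <- read_filter_params(left_adapter = sim$adapters[1],
                           right_adapter = sim$adapters[2])
  qc <- run_qc(sim$reads, NULL, tg, "suni", fp)
  prefix <- withr::local_tempfile()
  paths <- write_qc(qc, prefix, seed = 29)
  counts <- readr::read_tsv(paths[["counts"]], show_col_types = FALSE)
  expect_identical(nrow(counts), nrow(qc$table$counts))
  js <- jsonlite::read_json(paths[["metrics"]], simplifyVector = TRUE)
  expect_equal(js$logdiff, qc$metrics$logdiff, tolerance = 1e-12)
  expect_identical(js$provenance$package, "suni")
  expect_identical(js$provenance$seed, 29L)
})
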