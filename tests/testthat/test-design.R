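# opt1 / SUNi primer design.

test_that("arm enumeration yields one candidate per length, abutting the codon", {
  tg <- fixture_target()
  for (side in c("left", "right")) {
    cand <- enumerate_arm_candidates(tg, 5L, side)
    expect_identical(nrow(cand), 21L)
    expect_identical(cand$length, 20:40)
    expect_identical(nchar(cand$seq), cand$length)
  }
  # hand-sliced substrings: left arm ends right before the codon, right arm
  # starts right after it
  left <- enumerate_arm_candidates(tg, 5L, "left")
  end1 <- tg$cds_offset + 3L * 5L
  expect_identical(left$seq,
                   substring(tg$template, end1 - (20:40) + 1L, end1))
  right <- enumerate_arm_candidates(tg, 5L, "right")
  start1 <- tg$cds_offset + 3L * 5L + 4L
  expect_identical(right$seq,
                   substring(tg$template, start1, start1 + (20:40) - 1L))
})

test_that("closest-Tm selection minimizes |Tm - target|, shorter on ties", {
  cand <- tibble::tibble(side = "left", length = c(20L, 22L, 31L),
                         seq = "x", tm = c(58, 60.9, 63.5))
  expect_equal(select_arm_closest_tm(cand, 61)$tm, 60.9)
  tie <- tibble::tibble(side = "left", length = c(31L, 22L),
                        seq = "x", tm = c(62.5, 59.5))
  expect_identical(select_arm_closest_tm(tie, 61)$length, 22L)
  expect_error(select_arm_closest_tm(tie[0, ], 61), "non-empty")
  # brute-force scan agreement on random candidate sets
  withr::with_seed(9, {
    for (i in 1:500) {
      n <- sample(3:21, 1)
      cc <- tibble::tibble(side = "left",
                           length = sample(20:40, n), seq = "x",
                           tm = runif(n, 50, 72))
      tgt <- runif(1, 55, 68)
      pick <- select_arm_closest_tm(cc, tgt)
      d <- abs(cc$tm - tgt)
      expect_equal(abs(pick$tm - tgt), min(d))
      expect_identical(pick$length,
                       min(cc$length[d == min(d)]))
    }
  })
})

test_that("strong/weak terminal classes follow S=G/C, W=A/T", {
  expect_identical(sw_class(c("GCATT", "CAGGG", "ATTAA")),
                   c("SSW", "SWS", "WWW"))
  expect_identical(sw_class("AAGCC", end = "3prime"), "SSS")
  expect_error(sw_class("AT"), ">= 3")
  expect_equal(terminal_gc("GCATC", k = 4), 0.5)
  expect_equal(terminal_gc("GCATC", k = 2), 1)
})

test_that("SUNi left-arm cascade walks SSS, then SSW/SWS, then 64-degree fallback", {
  base <- function(tm, seq, len = nchar(seq)) {
    tibble::tibble(side = "left", length = len, seq = seq, tm = tm)
  }
  # SSS in window beats longer/better-Tm alternatives
  cand <- dplyr::bind_rows(
    base(60.2, strrep("G", 24)),                 # SSS, in window
    base(61.0, paste0("GCA", strrep("T", 19))),  # SSW, in window, shorter
    base(64.0, strrep("A", 30))                  # WWW
  )
  got <- select_left_arm_suni(cand)
  expect_identical(got$length, 24L)
  expect_false(got$fallback_used)
  # no SSS: shortest over the union of SSW and SWS
  cand2 <- dplyr::bind_rows(
    base(60.5, paste0("GCA", strrep("T", 23))),  # SSW 26-mer
    base(62.0, paste0("CAG", strrep("T", 19))),  # SWS 22-mer
    base(61.0, strrep("A", 21))
  )
  got2 <- select_left_arm_suni(cand2)
  expect_identical(got2$length, 22L)
  expect_false(got2$fallback_used)
  # no compliant terminus in window -> Tm closest to 64 over all arms
  cand3 <- dplyr::bind_rows(
    base(58.0, paste0("GGG", strrep("T", 17))),  # SSS but below window
    base(60.0, strrep("A", 25)),
    base(63.1, strrep("T", 30)),
    base(67.5, paste0("GGC", strrep("T", 37), ""), 40L)
  )
  got3 <- select_left_arm_suni(cand3)
  expect_identical(got3$tm, 63.1)
  expect_true(got3$fallback_used)
})

test_that("degenerate codon is NNK except NNS for SUNi when WT ends in T", {
  expect_identical(degenerate_codon_for("GAT", "suni"), "NNS")
  expect_identical(degenerate_codon_for("GAG", "suni"), "NNK")
  expect_identical(degenerate_codon_for("GAT", "opt1"), "NNK")
  expect_identical(degenerate_codon_for(c("AAA", "TTT"), "suni"),
                   c("NNK", "NNS"))
  expect_error(degenerate_codon_for("GA", "suni"), "codon")
  expect_error(degenerate_codon_for("GAX", "suni"), "codon")
})

test_that("designed pools satisfy the SUNi rules on random templates", {
  params <- design_params()
  withr::with_seed(17, {
    for (rep in 1:10) {
      tg <- random_template(12L, gc = runif(1, 0.3, 0.7))
      suni_pool <- design_pool(tg, "suni")
      opt1_pool <- design_pool(tg, "opt1")
      expect_identical(nrow(suni_pool), 12L)
      # one primer per codon, in codon order
      expect_identical(suni_pool$codon_index, 0:11)
      # arm length and full-sequence length bounds
      expect_true(all(suni_pool$left_len %in% 20:40))
      expect_true(all(suni_pool$right_len %in% 20:40))
      expect_true(all(nchar(suni_pool$full_seq) >= 43 &
                        nchar(suni_pool$full_seq) <= 83))
      # non-fallback primers: left Tm in window and compliant clamp
      ok <- !suni_pool$fallback_used
      expect_true(all(suni_pool$left_tm[ok] >= 59 &
                        suni_pool$left_tm[ok] <= 66))
      expect_true(all(suni_pool$terminal_class[ok] %in%
                        c("SSS", "SSW", "SWS")))
      expect_identical(suni_pool$replicate_count,
                       ifelse(suni_pool$fallback_used, 2L, 1L))
      # opt1: always NNK, never duplicated
      expect_true(all(opt1_pool$degenerate_codon == "NNK"))
      expect_true(all(opt1_pool$replicate_count == 1L))
      # right arms identical between modes, and globally Tm-closest to 61
      expect_identical(suni_pool$right_arm, opt1_pool$right_arm)
      for (i in c(1L, 7L)) {
        cand <- enumerate_arm_candidates(tg, suni_pool$codon_index[i], "right")
        d <- abs(cand$tm - params$opt1_target_tm)
        expect_equal(abs(suni_pool$right_tm[i] - params$opt1_target_tm),
                     min(d))
      }
      # NNS exactly where the WT codon ends in T
      expect_identical(suni_pool$degenerate_codon,
                       ifelse(substr(suni_pool$wt_codon, 3, 3) == "T",
                              "NNS", "NNK"))
      # full_seq is the stated concatenation
      expect_identical(suni_pool$full_seq,
                       paste0(suni_pool$left_arm, suni_pool$degenerate_codon,
                              suni_pool$right_arm))
    }
  })
})

test_that("design is a pure function: identical bytes on re-export", {
  tg <- random_template(8L, gc = 0.45, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pool(design_pool(tg, "suni"), f1)
  write_pool(design_pool(tg, "suni"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a low-GC template forces at least one duplicated fallback primer", {
  tg <- random_template(20L, gc = 0.12, seed = 31)
  pool <- design_pool(tg, "suni")
  expect_gt(sum(pool$fallback_used), 0)
  expect_true(all(pool$replicate_count[pool$fallback_used] == 2L))
})

test_that("pool CSV round-trips and FASTA mirrors molar composition", {
  tg <- random_template(20L, gc = 0.2, seed = 31)
  pool <- design_pool(tg, "suni")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pool(pool, csv, "csv")
  back <- read_pool(csv)
  expect_equal(as.data.frame(back), as.data.frame(pool), tolerance = 1e-12,
               ignore_attr = TRUE)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_pool(pool, fa, "fasta")
  recs <- read_fasta(fa, single = FALSE)
  expect_identical(nrow(recs), sum(pool$replicate_count))
  # degenerate IUPAC letters survive in the codon slot
  expect_true(all(grepl("[KS]", recs$seq)))
  expect_error(write_pool(pool[0, ], csv), "Empty")
})

test_that("targets without enough flank are rejected at construction", {
  tpl <- paste(rep("ACGT", 30), collapse = "") # 120 nt
  expect_error(
    mutagenesis_target(tpl, cds_offset = 10, codon_start = 0, codon_end = 10),
    "flank"
  )
  expect_error(
    mutagenesis_target(substr(tpl, 1, 50), cds_offset = 45,
                       codon_start = 0, codon_end = 10),
    "short"
  )
})
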