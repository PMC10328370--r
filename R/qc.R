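# Library quality control: read filtering, exact-match variant classification,
# uniformity (LogDiff) and screening-efficiency metrics.

.DNA_BASES <- c("A", "C", "G", "T")
.IUPAC_SETS <- list(N = c("A", "C", "G", "T"), K = c("G", "T"),
                    S = c("G", "C"))

#' Read filtering parameters
#'
#' @param max_expected_errors Reads with expected errors (sum of per-base
#'   error probabilities) at or above this value are discarded; the retained
#'   set satisfies `expected_errors < max_expected_errors`. Default 0.5.
#' @param left_adapter,right_adapter Constant sequence required at the 5' and
#'   3' end of each (merged) read; the inner window between them is what gets
#'   classified.
#' @param adapter_max_mismatches Mismatches tolerated in each adapter match
#'   (default 0: exact).
#' @param min_overlap Minimum overlap (nt) for merging read pairs.
#' @param max_mismatch_frac Maximum mismatch fraction in the best overlap for
#'   a pair to be merged (default 0.1).
#' @param orient `"forward"` classifies reads as given; `"both"` (default)
#'   additionally reverse-complements reads whose reverse complement, but not
#'   the read itself, starts with the left adapter.
#' @return An object of class `read_filter_params`.
#' @export
read_filter_params <- function(max_expected_errors = 0.5,
                               left_adapter = NULL, right_adapter = NULL,
                               adapter_max_mismatches = 0L,
                               min_overlap = 20L, max_mismatch_frac = 0.1,
                               orient = c("both", "forward")) {
  if (!is.numeric(max_expected_errors) || max_expected_errors <= 0) {
    abort("`max_expected_errors` must be positive.")
  }
  orient <- match.arg(orient)
  chk <- function(x, nm) {
    if (!is.null(x)) {
      x <- toupper(x)
      if (!is.character(x) || length(x) != 1L || grepl("[^ACGT]", x) ||
          nchar(x) < 1L) {
        abort(sprintf("`%s` must be a non-empty A/C/G/T string.", nm))
      }
    }
    x
  }
  structure(
    list(max_expected_errors = max_expected_errors,
         left_adapter = chk(left_adapter, "left_adapter"),
         right_adapter = chk(right_adapter, "right_adapter"),
         adapter_max_mismatches = as.integer(adapter_max_mismatches),
         min_overlap = as.integer(min_overlap),
         max_mismatch_frac = max_mismatch_frac,
         orient = orient),
    class = "read_filter_params"
  )
}

#' Expected errors of reads from their Phred qualities
#'
#' The expected number of erroneous bases in a read is
#' \eqn{\sum_i 10^{-Q_i/10}} over its per-base Phred scores. This is the
#' standard statistic behind "expected error" read filtering.
#'
#' @param qual Character vector of Phred+33-encoded quality strings, or a
#'   single numeric vector of Phred scores.
#' @return Numeric vector of expected-error values (0 for empty reads).
#' @examples
#' expected_errors(strrep("5", 10)) # ten Q20 bases -> 0.1
#' @export
expected_errors <- function(qual) {
  if (is.numeric(qual)) {
    if (any(qual < 0)) abort("Phred scores must be >= 0.")
    return(sum(10^(-qual / 10)))
  }
  if (!is.character(qual)) abort("`qual` must be character or numeric.")
  uq <- unique(qual)
  ee <- vapply(uq, function(q) {
    if (nchar(q) == 0L) return(0)
    sc <- utf8ToInt(q) - 33L
    if (any(sc < 0L)) abort("Quality string below Phred+33 '!' encountered.")
    sum(10^(-sc / 10))
  }, numeric(1), USE.NAMES = FALSE)
  ee[match(qual, uq)]
}

# Hamming distance between equal-length strings x and a single reference.
.hamming <- function(x, ref) {
  r <- utf8ToInt(ref)
  vapply(x, function(s) sum(utf8ToInt(s) != r), integer(1), USE.NAMES = FALSE)
}

#' Gate reads on flanking adapters and extract the inner window
#'
#' Requires the left adapter at the very 5' end and the right adapter at the
#' very 3' end of each read (within `adapter_max_mismatches` each, default
#' exact) and returns the window between them. Reads failing the left check
#' are counted as `left_fail`, then the right check as `right_fail`.
#'
#' @param seqs Character vector of read sequences.
#' @param params A [read_filter_params()] with both adapters set.
#' @return Tibble with `window` (NA where rejected) and `status`
#'   (`kept` / `left_fail` / `right_fail`).
#' @export
gate_adapters <- function(seqs, params) {
  stopifnot(inherits(params, "read_filter_params"))
  if (is.null(params$left_adapter) || is.null(params$right_adapter)) {
    abort("Both adapters must be set in `read_filter_params()`.")
  }
  la <- params$left_adapter
  ra <- params$right_adapter
  nl <- nchar(la)
  nr <- nchar(ra)
  len <- nchar(seqs)
  long_enough <- len >= nl + nr
  pre <- substr(seqs, 1L, nl)
  suf <- substring(seqs, len - nr + 1L)
  if (params$adapter_max_mismatches == 0L) {
    left_ok <- long_enough & pre == la
    right_ok <- long_enough & suf == ra
  } else {
    left_ok <- right_ok <- rep(FALSE, length(seqs))
    left_ok[long_enough] <- .hamming(pre[long_enough], la) <=
      params$adapter_max_mismatches
    right_ok[long_enough] <- .hamming(suf[long_enough], ra) <=
      params$adapter_max_mismatches
  }
  status <- ifelse(!left_ok, "left_fail",
                   ifelse(!right_ok, "right_fail", "kept"))
  window <- ifelse(status == "kept",
                   substr(seqs, nl + 1L, len - nr), NA_character_)
  tibble(window = window, status = status)
}

#' Merge overlapping read pairs
#'
#' Reverse-complements the reverse mate, scans all overlap offsets of at
#' least `min_overlap` nt for the one with the most matching bases, and
#' builds a consensus: at agreeing positions the base is kept with quality
#' `max(Q)`; at disagreements the higher-quality base wins with quality
#' `|Q_fwd - Q_rev|`. Pairs whose best overlap exceeds `max_mismatch_frac`
#' mismatches, or admit no overlap, are rejected (counted, not fatal). This
#' is a deliberately simple merger validated against the in-package
#' simulator; bit-parity with external read mergers is not promised.
#'
#' @param fwd,rev Character vectors of mate sequences.
#' @param fwd_qual,rev_qual Phred+33 quality strings.
#' @param params A [read_filter_params()].
#' @return Tibble with `seq`, `qual` (NA where rejected) and `merged`.
#' @export
merge_pairs <- function(fwd, rev, fwd_qual, rev_qual,
                        params = read_filter_params()) {
  stopifnot(length(fwd) == length(rev),
            length(fwd) == length(fwd_qual),
            length(fwd) == length(rev_qual))
  rc <- revcomp(rev)
  rcq <- vapply(rev_qual, function(q) {
    intToUtf8(rev(utf8ToInt(q)))
  }, character(1), USE.NAMES = FALSE)
  out_seq <- rep(NA_character_, length(fwd))
  out_qual <- rep(NA_character_, length(fwd))
  for (i in seq_along(fwd)) {
    f <- utf8ToInt(fwd[i]); r <- utf8ToInt(rc[i])
    fq <- utf8ToInt(fwd_qual[i]) - 33L; rq <- utf8ToInt(rcq[i]) - 33L
    nf <- length(f); nr <- length(r)
    if (nf == 0L || nr == 0L) next
    best_o <- NA_integer_; best_m <- -1L
    for (o in seq(params$min_overlap, min(nf, nr))) {
      m <- sum(f[(nf - o + 1L):nf] == r[1:o])
      if (m > best_m) { best_m <- m; best_o <- o }
    }
    if (is.na(best_o)) next
    o <- best_o
    if ((o - best_m) / o > params$max_mismatch_frac) next
    fo <- f[(nf - o + 1L):nf]; ro <- r[1:o]
    fqo <- fq[(nf - o + 1L):nf]; rqo <- rq[1:o]
    agree <- fo == ro
    cons <- ifelse(agree | fqo >= rqo, fo, ro)
    consq <- ifelse(agree, pmax(fqo, rqo), abs(fqo - rqo))
    out_seq[i] <- intToUtf8(c(f[seq_len(nf - o)], cons, r[-(1:o)]))
    out_qual[i] <- intToUtf8(c(fq[seq_len(nf - o)], consq,
                               rq[-(1:o)]) + 33L)
  }
  tibble(seq = out_seq, qual = out_qual, merged = !is.na(out_seq))
}

.expand_degenerate_codon <- function(scheme) {
  third <- switch(scheme,
                  NNN = .DNA_BASES,
                  NNK = .IUPAC_SETS$K,
                  NNS = .IUPAC_SETS$S,
                  abort(sprintf("Unknown scheme '%s'.", scheme)))
  as.vector(t(outer(
    as.vector(t(outer(.DNA_BASES, .DNA_BASES, paste0))), third, paste0
  )))
}

.translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Build the expected single-codon variant set
#'
#' For each codon of the target window, enumerates every codon matching the
#' codon's degeneracy scheme (NNN, NNK or NNS) substituted into the wild-type
#' window sequence. Sequences equal to the wild-type window (i.e. the
#' wild-type codon itself, when it matches the scheme) are excluded from the
#' variant set — downstream they classify as wild type, not programmed.
#'
#' @param target A [mutagenesis_target()].
#' @param schemes Degeneracy scheme per codon: a single string (`"NNN"`,
#'   `"NNK"`, `"NNS"` recycled over the window, or `"suni"` for the SUNi rule
#'   NNS-iff-WT-ends-in-T), or a data frame with columns `codon_index`,
#'   `scheme` covering the window.
#' @return An object of class `expected_variant_set`: the wild-type window,
#'   a `variants` tibble (`seq`, `codon_index`, `codon`, `aa`) and the
#'   per-codon scheme table.
#' @export
build_expected_set <- function(target, schemes = "suni") {
  stopifnot(inherits(target, "mutagenesis_target"))
  wt <- wt_codons(target)
  if (is.character(schemes) && length(schemes) == 1L) {
    if (schemes == "suni") {
      sch <- ifelse(substr(wt$wt_codon, 3L, 3L) == "T", "NNS", "NNK")
    } else {
      sch <- rep(match.arg(schemes, c("NNN", "NNK", "NNS")), nrow(wt))
    }
    scheme_tbl <- tibble(codon_index = wt$codon_index, scheme = sch)
  } else if (is.data.frame(schemes)) {
    scheme_tbl <- as_tibble(schemes[, c("codon_index", "scheme")])
    miss <- setdiff(wt$codon_index, scheme_tbl$codon_index)
    if (length(miss)) {
      abort(paste0("`schemes` missing codon indices: ",
                   paste(miss, collapse = ", ")))
    }
    scheme_tbl <- scheme_tbl[match(wt$codon_index, scheme_tbl$codon_index), ]
    if (!all(scheme_tbl$scheme %in% c("NNN", "NNK", "NNS"))) {
      abort("Schemes must be NNN, NNK or NNS.")
    }
  } else {
    abort("`schemes` must be a string or a data frame.")
  }
  wt_window <- window_sequence(target)
  per <- lapply(seq_len(nrow(wt)), function(j) {
    codons <- .expand_degenerate_codon(scheme_tbl$scheme[j])
    codons <- codons[codons != wt$wt_codon[j]]
    off <- 3L * (wt$codon_index[j] - target$codon_start)
    seqs <- paste0(substr(wt_window, 1L, off),
                   codons,
                   substring(wt_window, off + 4L))
    tibble(seq = seqs, codon_index = wt$codon_index[j], codon = codons,
           aa = .translate_codons(codons))
  })
  structure(
    list(wt_window = wt_window,
         variants = bind_rows(per),
         schemes = left_join(wt, scheme_tbl, by = "codon_index"),
         target_name = target$name,
         codon_start = target$codon_start),
    class = "expected_variant_set"
  )
}

#' @export
print.expected_variant_set <- function(x, ...) {
  cat("<expected_variant_set> ", x$target_name, "\n", sep = "")
  cat("  window: ", nchar(x$wt_window), " nt, ", nrow(x$schemes),
      " codons, ", nrow(x$variants), " programmed variants\n", sep = "")
  invisible(x)
}

#' Classify read windows against the expected variant set
#'
#' Perfect-match classification: a window equal to the wild-type window is
#' `wild_type`; a window equal to one of the enumerated single-codon variants
#' is `programmed` (with its codon identity); everything else — length
#' mismatches, multi-codon changes, synthesis or sequencing errors — is
#' `other`.
#'
#' @param windows Character vector of gated read windows.
#' @param expected An [build_expected_set()] object.
#' @return Tibble with `class` (`programmed`/`wild_type`/`other`),
#'   `codon_index` and `codon` (NA unless programmed).
#' @export
classify_reads <- function(windows, expected) {
  stopifnot(inherits(expected, "expected_variant_set"))
  hit <- match(windows, expected$variants$seq)
  cls <- ifelse(windows == expected$wt_window, "wild_type",
                ifelse(is.na(hit), "other", "programmed"))
  tibble(
    class = cls,
    codon_index = ifelse(cls == "programmed",
                         expected$variants$codon_index[hit], NA_integer_),
    codon = ifelse(cls == "programmed",
                   expected$variants$codon[hit], NA_character_)
  )
}

#' Tally classified reads into a variant count table
#'
#' @param classified Tibble from [classify_reads()].
#' @param expected The [build_expected_set()] used for classification; the
#'   count table covers every expected variant (zero counts included).
#' @return An object of class `variant_counts`: per-variant `counts` tibble
#'   plus `wt_count`, `other_count` and `total_retained`.
#' @export
tally_variants <- function(classified, expected) {
  stopifnot(inherits(expected, "expected_variant_set"))
  prog <- classified[classified$class == "programmed", ]
  key <- paste(prog$codon_index, prog$codon)
  all_key <- paste(expected$variants$codon_index, expected$variants$codon)
  counts <- expected$variants %>%
    select("codon_index", "codon", "aa") %>%
    mutate(count = as.integer(tabulate(match(key, all_key),
                                       nbins = length(all_key))))
  structure(
    list(counts = counts,
         wt_count = sum(classified$class == "wild_type"),
         other_count = sum(classified$class == "other"),
         total_retained = nrow(classified)),
    class = "variant_counts"
  )
}

#' @export
print.variant_counts <- function(x, ...) {
  cat("<variant_counts> ", x$total_retained, " retained reads: ",
      sum(x$counts$count), " programmed / ", x$wt_count, " WT / ",
      x$other_count, " other\n", sep = "")
  invisible(x)
}

#' Screening efficiency of a variant library
#'
#' Composite library-quality score combining the programmed fraction and the
#' uniformity of programmed variants:
#' \deqn{\mathrm{screening\ efficiency} =
#'   \frac{\%\mathrm{programmed}/100}{10^{\mathrm{LogDiff}}}}
#' where LogDiff is the log10 difference between the 90th and 10th percentile
#' of programmed-variant frequencies. Higher is better; a perfectly uniform,
#' fully programmed library scores 1.
#'
#' @param pct_programmed Percent of retained reads carrying a programmed
#'   variant (on the 0-100 scale).
#' @param logdiff LogDiff in log10 units.
#' @return Numeric vector of screening efficiencies.
#' @examples
#' screening_efficiency(77.5, 0.65)
#' @export
screening_efficiency <- function(pct_programmed, logdiff) {
  (pct_programmed / 100) / 10^logdiff
}

#' Library uniformity and efficiency metrics from a count table
#'
#' Per-variant frequencies are counts over total retained reads. LogDiff is
#' `log10(P90) - log10(P10)` over the programmed-variant frequencies
#' (linearly interpolated percentiles); zero-count variants are excluded from
#' the percentile population by default (their number is reported) or mapped
#' to a pseudo-frequency of `0.5 / total_retained`. Per-position medians are
#' the median frequency of each codon's programmed variants, zeros included.
#'
#' @param tab A [tally_variants()] object.
#' @param zero_policy `"exclude"` (default) or `"pseudo"`.
#' @param per_position If `TRUE`, the LogDiff percentile population is the
#'   per-position median frequencies instead of per-variant frequencies.
#' @return An object of class `library_metrics`; see [glance.library_metrics()]
#'   for the one-row summary and [tidy.library_metrics()] for per-position
#'   medians.
#' @export
compute_metrics <- function(tab, zero_policy = c("exclude", "pseudo"),
                            per_position = FALSE) {
  stopifnot(inherits(tab, "variant_counts"))
  zero_policy <- match.arg(zero_policy)
  if (tab$total_retained <= 0L) abort("No retained reads.")
  total <- tab$total_retained
  freq <- tab$counts$count / total
  n_zero <- sum(tab$counts$count == 0L)
  pct_programmed <- 100 * sum(tab$counts$count) / total
  pct_wt <- 100 * tab$wt_count / total
  pct_other <- 100 * tab$other_count / total

  per_pos <- tab$counts %>%
    mutate(freq = .data$count / total) %>%
    group_by(.data$codon_index) %>%
    summarise(median_freq = median(.data$freq), .groups = "drop")

  pop <- if (zero_policy == "exclude") freq[freq > 0] else {
    ifelse(freq > 0, freq, 0.5 / total)
  }
  if (per_position) pop <- per_pos$median_freq[per_pos$median_freq > 0]
  if (length(pop) < 10L) {
    abort("Fewer than 10 nonzero programmed variants: percentiles unstable.")
  }
  qs <- quantile(pop, c(0.1, 0.9), type = 7, names = FALSE)
  logdiff <- log10(qs[2]) - log10(qs[1])
  structure(
    list(pct_programmed = pct_programmed, pct_wt = pct_wt,
         pct_other = pct_other, logdiff = logdiff,
         screening_efficiency = screening_efficiency(pct_programmed, logdiff),
         per_position_median_freq = per_pos,
         n_zero_count_variants = n_zero,
         n_variants = nrow(tab$counts), total_retained = total,
         zero_policy = zero_policy, per_position = per_position),
    class = "library_metrics"
  )
}

#' @export
print.library_metrics <- function(x, ...) {
  cat("<library_metrics>\n")
  cat(sprintf("  %% programmed / WT / other: %.1f / %.1f / %.1f\n",
              x$pct_programmed, x$pct_wt, x$pct_other))
  cat(sprintf("  LogDiff (P90-P10, log10): %.3f\n", x$logdiff))
  cat(sprintf("  screening efficiency:     %.3f\n", x$screening_efficiency))
  cat(sprintf("  zero-count variants:      %d of %d\n",
              x$n_zero_count_variants, x$n_variants))
  invisible(x)
}

#' Run the full library-QC pipeline
#'
#' merge (if paired) -> expected-error filter -> adapter gate -> perfect-match
#' classification -> count table -> metrics, with a per-stage discard report.
#'
#' @param reads A tibble with columns `seq` and `qual` (e.g. from
#'   [simulate_library()] or [read_fastq()]), or a FASTQ file path.
#' @param reads2 Optional reverse mates (tibble or FASTQ path) for paired
#'   input.
#' @param target A [mutagenesis_target()].
#' @param schemes Passed to [build_expected_set()].
#' @param params A [read_filter_params()] with adapters set.
#' @param zero_policy,per_position Passed to [compute_metrics()].
#' @return An object of class `qc_result`: `table` ([tally_variants()]),
#'   `metrics` ([compute_metrics()]), and a per-stage `report` tibble.
#' @export
run_qc <- function(reads, reads2 = NULL, target, schemes = "suni",
                   params = read_filter_params(),
                   zero_policy = "exclude", per_position = FALSE) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (is.character(reads2)) reads2 <- read_fastq(reads2)
  stopifnot(is.data.frame(reads), all(c("seq", "qual") %in% names(reads)))
  n_raw <- nrow(reads)
  report <- tibble(stage = "input", n_out = n_raw, n_discarded = 0L)

  if (!is.null(reads2)) {
    m <- merge_pairs(reads$seq, reads2$seq, reads$qual, reads2$qual, params)
    keep <- m$merged
    reads <- tibble(seq = m$seq[keep], qual = m$qual[keep])
    report <- bind_rows(report, tibble(
      stage = "merge", n_out = nrow(reads), n_discarded = sum(!keep)
    ))
  }

  ee <- expected_errors(reads$qual)
  keep <- ee < params$max_expected_errors
  reads <- reads[keep, ]
  report <- bind_rows(report, tibble(
    stage = "expected_error_filter", n_out = nrow(reads),
    n_discarded = sum(!keep)
  ))

  seqs <- reads$seq
  if (params$orient == "both" && !is.null(params$left_adapter)) {
    la <- params$left_adapter
    fwd_ok <- startsWith(seqs, la)
    flip <- !fwd_ok & startsWith(revcomp(seqs), la)
    seqs[flip] <- revcomp(seqs[flip])
  }
  gated <- gate_adapters(seqs, params)
  report <- bind_rows(report, tibble(
    stage = c("adapter_left", "adapter_right"),
    n_out = c(sum(gated$status != "left_fail"), sum(gated$status == "kept")),
    n_discarded = c(sum(gated$status == "left_fail"),
                    sum(gated$status == "right_fail"))
  ))
  windows <- gated$window[gated$status == "kept"]
  if (length(windows) == 0L) {
    abort("Empty library: no reads survived filtering and adapter gating.")
  }

  expected <- build_expected_set(target, schemes)
  classified <- classify_reads(windows, expected)
  tab <- tally_variants(classified, expected)
  metrics <- compute_metrics(tab, zero_policy = zero_policy,
                             per_position = per_position)
  report <- bind_rows(report, tibble(
    stage = "retained", n_out = tab$total_retained, n_discarded = 0L
  ))
  structure(list(table = tab, metrics = metrics, report = report,
                 params = params),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$report, n = Inf)
  print(x$metrics)
  invisible(x)
}

#' Write QC outputs to files
#'
#' Writes the per-variant counts as TSV and all metrics plus the stage report
#' as JSON with a provenance block (package version, timestamp, seed if
#' given).
#'
#' @param qc A [run_qc()] result.
#' @param prefix Output path prefix; writes `<prefix>_counts.tsv` and
#'   `<prefix>_metrics.json`.
#' @param seed Optional seed recorded in provenance.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_qc <- function(qc, prefix, seed = NULL) {
  stopifnot(inherits(qc, "qc_result"))
  counts_path <- paste0(prefix, "_counts.tsv")
  metrics_path <- paste0(prefix, "_metrics.json")
  total <- qc$table$total_retained
  readr::write_tsv(
    qc$table$counts %>% mutate(frequency = .data$count / total),
    counts_path
  )
  m <- qc$metrics
  payload <- list(
    provenance = .provenance(seed),
    pct_programmed = m$pct_programmed, pct_wt = m$pct_wt,
    pct_other = m$pct_other, logdiff = m$logdiff,
    screening_efficiency = m$screening_efficiency,
    n_zero_count_variants = m$n_zero_count_variants,
    n_variants = m$n_variants, total_retained = m$total_retained,
    per_position_median_freq = m$per_position_median_freq,
    stage_report = qc$report
  )
  jsonlite::write_json(payload, metrics_path, auto_unbox = TRUE, digits = NA)
  invisible(c(counts = counts_path, metrics = metrics_path))
}

.provenance <- function(seed = NULL, inputs = character()) {
  list(
    package = "suni",
    version = as.character(utils::packageVersion("suni")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    input_md5 = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else NULL
  )
}
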