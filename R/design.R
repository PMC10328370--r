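# Mutagenic primer design: opt1 (Tm-optimized arms) and SUNi (Tm window +
# 5' GC clamp + per-codon NNK/NNS choice).

#' Primer design parameters
#'
#' Tunable parameters of the opt1 and SUNi design procedures. The defaults are
#' the published procedure: homology arms between 20 and 40 nt; opt1 arms (and
#' all right arms) chosen closest to 61 degC; SUNi left arms restricted to a
#' 59-66 degC window and preferred by 5'-terminal strong/weak class (SSS
#' first, then SSW or SWS); when no arm in the window carries an acceptable
#' clamp, the fallback arm is the one closest to 64 degC irrespective of
#' terminus, and that primer is encoded twice in the pool.
#'
#' @param arm_min_len,arm_max_len Homology-arm length bounds in nt.
#' @param opt1_target_tm Target melting temperature (degC) for opt1 arms and
#'   for every right arm.
#' @param suni_left_tm_low,suni_left_tm_high Admissible Tm window (degC) for
#'   SUNi left arms in the clamp-preference steps.
#' @param suni_fallback_tm Target Tm (degC) of the fallback left arm.
#' @param fallback_ignores_window If `TRUE` (default) the fallback step
#'   considers all enumerated arms irrespective of the Tm window; if `FALSE`
#'   it re-applies the window first (falling back to all arms only when the
#'   window is empty).
#' @param clamp_preference Ordered list of character vectors of 5'-terminal
#'   strong/weak classes; earlier groups are preferred. Default: `"SSS"`,
#'   then `c("SSW", "SWS")`.
#' @return An object of class `design_params`.
#' @export
design_params <- function(arm_min_len = 20L, arm_max_len = 40L,
                          opt1_target_tm = 61, suni_left_tm_low = 59,
                          suni_left_tm_high = 66, suni_fallback_tm = 64,
                          fallback_ignores_window = TRUE,
                          clamp_preference = list("SSS", c("SSW", "SWS"))) {
  arm_min_len <- as.integer(arm_min_len)
  arm_max_len <- as.integer(arm_max_len)
  if (arm_min_len < 8L || arm_min_len > arm_max_len) {
    abort("Need 8 <= arm_min_len <= arm_max_len.")
  }
  if (!(suni_left_tm_low < suni_left_tm_high)) {
    abort("Need suni_left_tm_low < suni_left_tm_high.")
  }
  stopifnot(is.list(clamp_preference))
  structure(
    list(arm_min_len = arm_min_len, arm_max_len = arm_max_len,
         opt1_target_tm = opt1_target_tm,
         suni_left_tm_low = suni_left_tm_low,
         suni_left_tm_high = suni_left_tm_high,
         suni_fallback_tm = suni_fallback_tm,
         fallback_ignores_window = isTRUE(fallback_ignores_window),
         clamp_preference = clamp_preference),
    class = "design_params"
  )
}

#' Enumerate homology-arm candidates for one codon
#'
#' Lists every arm of length `arm_min_len` to `arm_max_len` abutting the
#' mutated codon on the given side, with its predicted melting temperature.
#' The left arm's 3' end sits immediately before the codon; the right arm's
#' 5' end immediately after it. All sequences are reported 5'->3' on the
#' coding strand.
#'
#' @param target A [mutagenesis_target()].
#' @param codon_index 0-based codon index inside the target window.
#' @param side `"left"` or `"right"`.
#' @param params A [design_params()].
#' @param thermo A [thermo_params()].
#' @return Tibble with columns `side`, `length`, `seq`, `tm`, ordered by
#'   increasing length.
#' @export
enumerate_arm_candidates <- function(target, codon_index,
                                     side = c("left", "right"),
                                     params = design_params(),
                                     thermo = thermo_params()) {
  stopifnot(inherits(target, "mutagenesis_target"))
  side <- match.arg(side)
  codon_index <- as.integer(codon_index)
  if (codon_index < target$codon_start || codon_index >= target$codon_end) {
    abort(sprintf("codon_index %d is outside the target window.", codon_index))
  }
  lens <- seq(params$arm_min_len, params$arm_max_len)
  n <- nchar(target$template)
  if (side == "left") {
    end1 <- target$cds_offset + 3L * codon_index # 1-based end position
    if (end1 - max(lens) < 0L) {
      abort(sprintf("Insufficient left flank for codon %d.", codon_index))
    }
    seqs <- substring(target$template, end1 - lens + 1L, end1)
  } else {
    start1 <- target$cds_offset + 3L * codon_index + 4L # 1-based start
    if (start1 + max(lens) - 1L > n) {
      abort(sprintf("Insufficient right flank for codon %d.", codon_index))
    }
    seqs <- substring(target$template, start1, start1 + lens - 1L)
  }
  tibble(side = side, length = lens, seq = seqs, tm = tm_nn(seqs, thermo))
}

#' Pick the arm with melting temperature closest to a target
#'
#' Returns the candidate minimizing `|tm - target_tm|`; on an exact tie in
#' the absolute difference the shorter arm wins (lower synthesis cost; the
#' published procedure does not specify a tie-break).
#'
#' @param candidates Tibble from [enumerate_arm_candidates()].
#' @param target_tm Target melting temperature in degC.
#' @return One-row tibble (the selected candidate).
#' @export
select_arm_closest_tm <- function(candidates, target_tm) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    abort("`candidates` must be a non-empty data frame.")
  }
  d <- abs(candidates$tm - target_tm)
  hit <- which(d == min(d))
  if (length(hit) > 1L) hit <- hit[which.min(candidates$length[hit])]
  candidates[hit, , drop = FALSE]
}

#' Strong/weak terminal class of a primer arm
#'
#' Classifies the `k` terminal bases of each sequence in strong/weak notation
#' (S = G or C, W = A or T), read 5'->3'. For a left homology arm the relevant
#' terminus is the 5' end (the primer's own 5' terminus); for a right arm the
#' 3' end.
#'
#' @param seq Character vector of DNA sequences.
#' @param end `"5prime"` (default) or `"3prime"`.
#' @param k Number of terminal bases to classify (default 3).
#' @return Character vector of classes such as `"SSW"`.
#' @examples
#' sw_class(c("GCATT", "CAGGG", "ATT"))
#' @export
sw_class <- function(seq, end = c("5prime", "3prime"), k = 3L) {
  end <- match.arg(end)
  if (any(nchar(seq) < k)) abort(sprintf("Sequences must be >= %d nt.", k))
  term <- if (end == "5prime") substr(seq, 1L, k) else {
    substring(seq, nchar(seq) - k + 1L, nchar(seq))
  }
  chartr("GCAT", "SSWW", toupper(term))
}

#' GC fraction of the k terminal bases
#'
#' @inheritParams sw_class
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
terminal_gc <- function(seq, end = c("5prime", "3prime"), k = 3L) {
  cls <- sw_class(seq, end = end, k = k)
  stringr::str_count(cls, "S") / k
}

#' SUNi left-arm selection cascade
#'
#' Applies the published decision cascade to the enumerated left-arm
#' candidates: (1) among arms with Tm in the admissible window whose three
#' 5'-terminal bases are all strong (class SSS), take the shortest; (2)
#' otherwise among in-window arms of class SSW or SWS, take the shortest;
#' (3) otherwise take the arm with Tm closest to the fallback target
#' irrespective of terminus, and flag it so the caller duplicates that primer
#' in the pool.
#'
#' @param candidates Tibble of enumerated left-arm candidates.
#' @param params A [design_params()].
#' @return One-row tibble: the selected candidate plus a `fallback_used`
#'   logical column.
#' @export
select_left_arm_suni <- function(candidates, params = design_params()) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    abort("`candidates` must be a non-empty data frame.")
  }
  cls <- sw_class(candidates$seq, end = "5prime", k = 3L)
  in_window <- candidates$tm >= params$suni_left_tm_low &
    candidates$tm <= params$suni_left_tm_high
  for (group in params$clamp_preference) {
    ok <- in_window & cls %in% group
    if (any(ok)) {
      sub <- candidates[ok, , drop = FALSE]
      pick <- sub[which.min(sub$length), , drop = FALSE]
      pick$fallback_used <- FALSE
      return(pick)
    }
  }
  pool <- if (params$fallback_ignores_window || !any(in_window)) {
    candidates
  } else {
    candidates[in_window, , drop = FALSE]
  }
  pick <- select_arm_closest_tm(pool, params$suni_fallback_tm)
  pick$fallback_used <- TRUE
  pick
}

#' Degenerate mutagenic codon for a wild-type codon
#'
#' opt1 always uses NNK. SUNi uses NNK unless the wild-type codon ends in T,
#' in which case NNS is used so that the wild-type sequence can never be a
#' member of the degenerate primer pool (K covers G and T; S covers G and C).
#'
#' @param wt_codon Character vector of wild-type codons (A/C/G/T, length 3).
#' @param mode `"suni"` or `"opt1"`.
#' @return Character vector of `"NNK"` / `"NNS"`.
#' @examples
#' degenerate_codon_for(c("GAT", "GAG"), mode = "suni")
#' @export
degenerate_codon_for <- function(wt_codon, mode = c("suni", "opt1")) {
  mode <- match.arg(mode)
  wt_codon <- toupper(wt_codon)
  if (any(nchar(wt_codon) != 3L) || any(grepl("[^ACGT]", wt_codon))) {
    abort("`wt_codon` must be 3-letter A/C/G/T codons.")
  }
  if (mode == "opt1") {
    rep("NNK", length(wt_codon))
  } else {
    ifelse(substr(wt_codon, 3L, 3L) == "T", "NNS", "NNK")
  }
}

#' Design a mutagenic primer pool
#'
#' Produces one mutagenic primer per codon of the target window. In both
#' modes the right homology arm is the candidate with Tm closest to
#' `opt1_target_tm`. In `opt1` mode the left arm is chosen the same way and
#' the degenerate codon is always NNK. In `suni` mode the left arm is chosen
#' by the GC-clamp cascade ([select_left_arm_suni()]), the degenerate codon is
#' NNS when the wild-type codon ends in T (NNK otherwise), and primers that
#' needed the no-clamp fallback are assigned `replicate_count = 2` so the
#' synthesized pool compensates for their expected lower efficiency.
#'
#' @param target A [mutagenesis_target()].
#' @param mode `"suni"` or `"opt1"`.
#' @param params A [design_params()].
#' @param thermo A [thermo_params()].
#' @return A tibble of class `suni_pool`, one row per codon, with the primer
#'   sequence (`full_seq`, IUPAC letters in the codon slot), both arms and
#'   their lengths/Tm, the 5'-terminal class of the left arm, and
#'   `replicate_count`. `codon_index` is 0-based; primer names carry 1-based
#'   codon numbers.
#' @export
design_pool <- function(target, mode = c("suni", "opt1"),
                        params = design_params(), thermo = thermo_params()) {
  stopifnot(inherits(target, "mutagenesis_target"))
  mode <- match.arg(mode)
  idx <- seq(target$codon_start, target$codon_end - 1L)
  wt <- wt_codons(target)$wt_codon
  rows <- lapply(seq_along(idx), function(j) {
    i <- idx[j]
    left_cand <- enumerate_arm_candidates(target, i, "left", params, thermo)
    right_cand <- enumerate_arm_candidates(target, i, "right", params, thermo)
    right <- select_arm_closest_tm(right_cand, params$opt1_target_tm)
    if (mode == "opt1") {
      left <- select_arm_closest_tm(left_cand, params$opt1_target_tm)
      fallback <- FALSE
    } else {
      left <- select_left_arm_suni(left_cand, params)
      fallback <- left$fallback_used
    }
    codon <- degenerate_codon_for(wt[j], mode)
    tibble(
      name = sprintf("%s_codon%03d_%s", target$name, i + 1L, mode),
      codon_index = i,
      wt_codon = wt[j],
      degenerate_codon = codon,
      left_arm = left$seq, left_len = left$length, left_tm = left$tm,
      right_arm = right$seq, right_len = right$length, right_tm = right$tm,
      terminal_class = sw_class(left$seq, "5prime", 3L),
      fallback_used = fallback,
      replicate_count = if (mode == "suni" && fallback) 2L else 1L,
      full_seq = paste0(left$seq, codon, right$seq),
      design_mode = mode
    )
  })
  pool <- bind_rows(rows)
  class(pool) <- c("suni_pool", class(pool))
  attr(pool, "target_name") <- target$name
  pool
}

#' Write a primer pool to CSV or FASTA
#'
#' CSV keeps one row per primer with design annotations and round-trips
#' through [read_pool()]. FASTA writes each primer `replicate_count` times so
#' the record multiset mirrors the molar composition of the ordered pool;
#' degenerate codon letters are IUPAC (K, S).
#'
#' @param pool A `suni_pool` tibble from [design_pool()].
#' @param path Output file path.
#' @param format `"csv"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path, format = c("csv", "fasta")) {
  format <- match.arg(format)
  if (!is.data.frame(pool) || nrow(pool) == 0L) abort("Empty primer pool.")
  if (format == "csv") {
    out <- pool %>%
      mutate(sequence = .data$full_seq, mode = .data$design_mode) %>%
      select("name", "sequence", "replicate_count", "codon_index", "mode",
             "wt_codon", "degenerate_codon", "left_len", "right_len",
             "left_tm", "right_tm", "terminal_class", "fallback_used")
    readr::write_csv(out, path)
  } else {
    reps <- rep(seq_len(nrow(pool)), pool$replicate_count)
    copy <- unlist(lapply(pool$replicate_count, seq_len))
    recs <- Biostrings::DNAStringSet(pool$full_seq[reps])
    names(recs) <- sprintf("%s/%d", pool$name[reps], copy)
    Biostrings::writeXStringSet(recs, path)
  }
  invisible(path)
}

#' Read a primer pool written by [write_pool()]
#'
#' @param path CSV file written by `write_pool(..., format = "csv")`.
#' @return A `suni_pool` tibble equivalent to the one written.
#' @export
read_pool <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("name", "sequence", "replicate_count", "codon_index", "mode",
            "wt_codon", "degenerate_codon", "left_len", "right_len",
            "left_tm", "right_tm", "terminal_class", "fallback_used")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("Pool CSV is missing columns: ", paste(miss, collapse = ", ")))
  }
  pool <- raw %>%
    mutate(
      left_arm = substr(.data$sequence, 1L, .data$left_len),
      right_arm = substring(.data$sequence, .data$left_len + 4L),
      full_seq = .data$sequence,
      design_mode = .data$mode,
      codon_index = as.integer(.data$codon_index),
      left_len = as.integer(.data$left_len),
      right_len = as.integer(.data$right_len),
      replicate_count = as.integer(.data$replicate_count)
    ) %>%
    select("name", "codon_index", "wt_codon", "degenerate_codon",
           "left_arm", "left_len", "left_tm",
           "right_arm", "right_len", "right_tm",
           "terminal_class", "fallback_used", "replicate_count",
           "full_seq", "design_mode")
  class(pool) <- c("suni_pool", class(pool))
  pool
}
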