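# broom-style tidiers for fitted/computed result objects.

#' Tidy a library_metrics object into per-position medians
#'
#' @param x A `library_metrics` object.
#' @param ... Unused.
#' @return Tibble with `codon_index` and `median_freq`.
#' @export
tidy.library_metrics <- function(x, ...) {
  as_tibble(x$per_position_median_freq)
}

#' One-row summary of library metrics
#'
#' @param x A `library_metrics` object.
#' @param ... Unused.
#' @return One-row tibble with `pct_programmed`, `pct_wt`, `pct_other`,
#'   `logdiff`, `screening_efficiency`, `n_zero_count_variants`,
#'   `n_variants`, `total_retained`.
#' @export
glance.library_metrics <- function(x, ...) {
  tibble(
    pct_programmed = x$pct_programmed, pct_wt = x$pct_wt,
    pct_other = x$pct_other, logdiff = x$logdiff,
    screening_efficiency = x$screening_efficiency,
    n_zero_count_variants = x$n_zero_count_variants,
    n_variants = x$n_variants, total_retained = x$total_retained
  )
}

#' Tidy a qc_result into the per-variant count table
#'
#' @param x A `qc_result` object.
#' @param ... Unused.
#' @return Tibble with `codon_index`, `codon`, `aa`, `count`, `frequency`.
#' @export
tidy.qc_result <- function(x, ...) {
  x$table$counts %>%
    mutate(frequency = .data$count / x$table$total_retained)
}

#' One-row summary of a qc_result
#'
#' @inheritParams tidy.qc_result
#' @return One-row tibble (see [glance.library_metrics()]) plus raw-read and
#'   retained-read counts.
#' @export
glance.qc_result <- function(x, ...) {
  glance(x$metrics) %>%
    mutate(n_input_reads = x$report$n_out[x$report$stage == "input"])
}

#' @export
tidy.spearman_cor <- function(x, ...) as_tibble(unclass(x))

#' @export
tidy.feature_scan <- function(x, ...) as_tibble(unclass(x))
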