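# Primer-feature analysis: melting-temperature and terminal-GC features per
# position, Spearman correlation against mutagenesis efficiency, and the
# strong/weak terminal-class comparison that motivates the 5' GC-clamp rule.

#' Build the per-position primer feature table
#'
#' Joins the design features of each primer (arm melting temperatures and
#' their min/max/sum/difference; GC fraction of the 1-5 terminal bases of
#' the left arm's 5' end and of the right arm's 3' end; the 5'-terminal
#' strong/weak class) with the measured mutagenesis efficiency of its
#' position (the median frequency of all programmed mutations at that
#' codon).
#'
#' @param pool A `suni_pool` tibble from [design_pool()] (or several
#'   row-bound pools, e.g. from multiple target regions).
#' @param metrics A `library_metrics` object from [compute_metrics()] /
#'   [run_qc()], or a data frame with columns `codon_index` and
#'   `median_freq`. Several regions can be combined by row-binding their
#'   tidied metrics.
#' @return A tibble of class `primer_features`, one row per codon.
#' @export
featurize_pool <- function(pool, metrics) {
  stopifnot(is.data.frame(pool))
  eff <- if (inherits(metrics, "library_metrics")) {
    metrics$per_position_median_freq
  } else if (is.data.frame(metrics)) {
    as_tibble(metrics[, c("codon_index", "median_freq")])
  } else {
    abort("`metrics` must be a library_metrics object or a data frame.")
  }
  miss <- setdiff(pool$codon_index, eff$codon_index)
  if (length(miss)) {
    abort(paste0("No efficiency for codon indices: ",
                 paste(sort(miss), collapse = ", ")))
  }
  rows <- pool %>%
    left_join(eff, by = "codon_index") %>%
    mutate(
      tm_min = pmin(.data$left_tm, .data$right_tm),
      tm_max = pmax(.data$left_tm, .data$right_tm),
      tm_sum = .data$left_tm + .data$right_tm,
      tm_diff = .data$left_tm - .data$right_tm,
      efficiency = .data$median_freq
    )
  for (k in 1:5) {
    rows[[paste0("gc5_k", k)]] <- terminal_gc(rows$left_arm, "5prime", k)
    rows[[paste0("gc3_k", k)]] <- terminal_gc(rows$right_arm, "3prime", k)
  }
  rows <- rows %>%
    select("codon_index", "left_tm", "right_tm", "tm_min", "tm_max",
           "tm_sum", "tm_diff", dplyr::starts_with("gc5_k"),
           dplyr::starts_with("gc3_k"), "terminal_class", "efficiency")
  class(rows) <- c("primer_features", class(rows))
  rows
}

# All permutations of 1..n as an n! x n matrix (n <= 10).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    shifted <- sub + (sub >= i)
    out[[i]] <- cbind(rep.int(i, nrow(sub)), shifted, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation with a size-adapted p-value
#'
#' Tie-corrected Spearman rho (Pearson correlation of mid-ranks) with a
#' two-sided p-value computed by the method suited to the sample size:
#' exhaustive permutation enumeration for n <= `exact_max` (default 10),
#' seeded Monte-Carlo permutation (`n_mc` draws) for n up to `mc_max`
#' (default 30), and the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} above that.
#'
#' @param x,y Numeric vectors of equal length, n >= 5.
#' @param exact_max Largest n for exhaustive enumeration.
#' @param mc_max Largest n for Monte-Carlo permutation.
#' @param n_mc Number of Monte-Carlo permutations.
#' @param mc_seed Seed for the Monte-Carlo substream (isolated from the
#'   caller's RNG state).
#' @return A one-row tibble of class `spearman_cor`: `rho`, `p_value`, `n`,
#'   `method`.
#' @export
spearman_cor <- function(x, y, exact_max = 10L, mc_max = 30L, n_mc = 1e5L,
                         mc_seed = 1L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5L) abort("Need at least 5 complete observations.")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("Correlation undefined: one input is constant.")
  }
  rho <- cor(rx, ry)
  rx0 <- rx - mean(rx)
  ry0 <- ry - mean(ry)
  denom <- sqrt(sum(rx0^2)) * sqrt(sum(ry0^2))
  eps <- 1e-12
  if (n <= exact_max) {
    perms <- .permutations(n)
    s <- matrix(ry0[perms], nrow = nrow(perms)) %*% rx0
    rho_perm <- as.numeric(s) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - eps)
    method <- "exact_permutation"
  } else if (n <= mc_max) {
    rho_perm <- .with_seed(mc_seed, {
      vapply(seq_len(n_mc), function(i) {
        sum(rx0 * ry0[sample.int(n)]) / denom
      }, numeric(1))
    })
    p <- (1 + sum(abs(rho_perm) >= abs(rho) - eps)) / (n_mc + 1)
    method <- "monte_carlo_permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- eps
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t_approximation"
  }
  out <- tibble(rho = rho, p_value = p, n = n, method = method)
  class(out) <- c("spearman_cor", class(out))
  out
}

#' Median mutagenesis efficiency by 5'-terminal strong/weak class
#'
#' @param features A `primer_features` tibble from [featurize_pool()].
#' @return Tibble with `terminal_class`, `n` and `median_efficiency`, in
#'   fixed lexical class order (SSS, SSW, SWS, SWW, WSS, WSW, WWS, WWW);
#'   classes with no rows are omitted.
#' @export
class_medians <- function(features) {
  stopifnot(is.data.frame(features))
  order_ref <- c("SSS", "SSW", "SWS", "SWW", "WSS", "WSW", "WWS", "WWW")
  features %>%
    group_by(.data$terminal_class) %>%
    summarise(n = dplyr::n(),
              median_efficiency = median(.data$efficiency),
              .groups = "drop") %>%
    arrange(match(.data$terminal_class, order_ref))
}

#' Correlate every numeric primer feature with mutagenesis efficiency
#'
#' Runs [spearman_cor()] of each numeric feature column against
#' `efficiency` and sorts the results by decreasing `|rho|`. No
#' multiple-testing correction is applied (the scan is exploratory; the
#' `adjusted` attribute is `FALSE` to make that explicit).
#'
#' @param features A `primer_features` tibble from [featurize_pool()].
#' @param feature_cols Character vector of feature columns to scan; defaults
#'   to every numeric column except `codon_index` and `efficiency`.
#' @param ... Passed to [spearman_cor()] (e.g. `mc_seed`).
#' @return A tibble of class `feature_scan`: `feature`, `rho`, `p_value`,
#'   `n`, `method`, sorted by `|rho|` descending.
#' @export
feature_scan <- function(features, feature_cols = NULL, ...) {
  stopifnot(is.data.frame(features), nrow(features) > 0L)
  if (is.null(feature_cols)) {
    num <- vapply(features, is.numeric, logical(1))
    feature_cols <- setdiff(names(features)[num],
                            c("codon_index", "efficiency"))
  }
  n_complete <- function(v) sum(is.finite(v) & is.finite(features$efficiency))
  res <- purrr::map_dfr(feature_cols, function(f) {
    v <- features[[f]]
    if (length(unique(v[is.finite(v)])) < 2L) {
      # a constant feature (e.g. gc5_k1 on an all-compliant SUNi pool) has
      # no defined rank correlation; keep the row so the scan stays complete
      return(tibble(feature = f, rho = NA_real_, p_value = NA_real_,
                    n = n_complete(v), method = "undefined_constant"))
    }
    r <- spearman_cor(v, features$efficiency, ...)
    dplyr::bind_cols(tibble(feature = f), as_tibble(r))
  })
  res <- res %>% arrange(desc(abs(.data$rho)))
  class(res) <- c("feature_scan", class(res))
  attr(res, "adjusted") <- FALSE
  res
}
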