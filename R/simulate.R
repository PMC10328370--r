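# Synthetic mutagenesis-library read simulator with analytic ground truth.

#' Simulation configuration
#'
#' Defines the composition and noise model of a simulated mutagenesis
#' library. Per-variant abundances are lognormal on the log10 scale: each
#' position draws a multiplier with s.d. `position_sigma` and each variant an
#' independent multiplier with s.d. `variant_sigma`; abundances are
#' renormalized over the programmed mass `1 - wt_fraction - other_fraction`.
#' The defaults emulate a high-quality SUNi-style library: ~77% programmed
#' reads, ~15% wild-type carryover, ~8% other, and a total log10 spread
#' giving LogDiff near 0.65.
#'
#' @param n_reads Number of reads (pairs, if `paired`).
#' @param wt_fraction Fraction of wild-type carryover reads.
#' @param other_fraction Fraction of unclassifiable reads (simulated as
#'   windows with two or more codon substitutions, so they can never match a
#'   programmed single-codon variant or the wild type).
#' @param position_sigma,variant_sigma Lognormal s.d. (log10 scale) of the
#'   per-position and per-variant abundance multipliers.
#' @param base_error_rate Per-base substitution probability applied to every
#'   read after composition sampling.
#' @param quality Constant Phred score for every base (single number), or a
#'   length-2 range for uniform per-base integer draws.
#' @param paired If `TRUE`, each molecule is split into overlapping mates of
#'   `read_length` nt.
#' @param read_length Mate length for paired mode (ignored otherwise).
#' @param seed Integer seed governing all draws; per-stage substreams are
#'   derived from it deterministically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reads = 1e5, wt_fraction = 0.15,
                       other_fraction = 0.08, position_sigma = 0.18,
                       variant_sigma = 0.18, base_error_rate = 0,
                       quality = 30L, paired = FALSE, read_length = 150L,
                       seed = 1L) {
  if (wt_fraction < 0 || other_fraction < 0 ||
      wt_fraction + other_fraction > 1) {
    abort("Need wt_fraction, other_fraction >= 0 and their sum <= 1.")
  }
  if (position_sigma < 0 || variant_sigma < 0) abort("Sigmas must be >= 0.")
  if (n_reads < 1) abort("`n_reads` must be positive.")
  if (base_error_rate < 0 || base_error_rate >= 1) {
    abort("`base_error_rate` must be in [0, 1).")
  }
  structure(
    list(n_reads = as.integer(n_reads), wt_fraction = wt_fraction,
         other_fraction = other_fraction, position_sigma = position_sigma,
         variant_sigma = variant_sigma, base_error_rate = base_error_rate,
         quality = as.integer(quality), paired = isTRUE(paired),
         read_length = as.integer(read_length), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Analytic LogDiff of the generating abundance distribution
#'
#' The per-variant log10 abundances are normal with total s.d.
#' \eqn{\sigma_t = \sqrt{\sigma_{pos}^2 + \sigma_{var}^2}}; normalization
#' shifts all log-frequencies by a constant, so the log10 ratio of the 90th
#' to the 10th percentile of the generating frequency distribution is
#' \eqn{(z_{0.9} - z_{0.1})\,\sigma_t = 2 \times 1.28155\,\sigma_t}.
#'
#' @param config A [sim_config()], or a single number taken as
#'   \eqn{\sigma_t} directly.
#' @return The analytic LogDiff in log10 units.
#' @examples
#' analytic_logdiff(0.5)
#' @export
analytic_logdiff <- function(config) {
  sigma_t <- if (inherits(config, "sim_config")) {
    sqrt(config$position_sigma^2 + config$variant_sigma^2)
  } else {
    as.numeric(config)
  }
  (qnorm(0.9) - qnorm(0.1)) * sigma_t
}

# Run `expr` under a deterministic substream seed, restoring the caller's RNG.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a mutagenesis-library sequencing run
#'
#' Draws per-variant abundances from the configured lognormal model, samples
#' read classes and identities multinomially, assembles each read as
#' `left_adapter + window + right_adapter`, applies per-base substitution
#' errors, attaches Phred qualities, and (in paired mode) splits molecules
#' into overlapping mates. "Other" reads carry two codon substitutions so
#' they are unclassifiable by construction. Fully reproducible from
#' `config$seed`.
#'
#' @param target A [mutagenesis_target()].
#' @param schemes Passed to [build_expected_set()].
#' @param config A [sim_config()].
#' @param adapters Length-2 character vector `c(left, right)`; defaults to
#'   the 20 nt of template flanking the codon window on each side.
#' @param out Optional path prefix: writes `<out>_R1.fastq` (and `_R2`),
#'   plus `<out>_truth.json`.
#' @return A list with `reads` (tibble `id`, `seq`, `qual`; in paired mode
#'   also `reads2`), `truth` (true per-variant frequencies, class fractions
#'   and the analytic LogDiff), `adapters`, and the file paths if written.
#' @export
simulate_library <- function(target, schemes = "suni", config = sim_config(),
                             adapters = NULL, out = NULL) {
  stopifnot(inherits(target, "mutagenesis_target"),
            inherits(config, "sim_config"))
  expected <- build_expected_set(target, schemes)
  nvar <- nrow(expected$variants)
  b <- .window_bounds(target)
  if (is.null(adapters)) {
    adapters <- c(substr(target$template, b[["start"]] - 20L, b[["start"]] - 1L),
                  substr(target$template, b[["end"]] + 1L, b[["end"]] + 20L))
  }
  stopifnot(length(adapters) == 2L, all(nchar(adapters) > 0L))

  stage_seeds <- .with_seed(config$seed, sample.int(2^31 - 2L, 5L))

  # --- per-variant abundances -------------------------------------------
  pos_idx <- match(expected$variants$codon_index,
                   sort(unique(expected$variants$codon_index)))
  log_a <- .with_seed(stage_seeds[1], {
    pos_eff <- rnorm(max(pos_idx), 0, config$position_sigma)
    pos_eff[pos_idx] + rnorm(nvar, 0, config$variant_sigma)
  })
  prog_mass <- 1 - config$wt_fraction - config$other_fraction
  a <- 10^log_a
  p_variant <- a / sum(a) * prog_mass

  # --- read class / identity sampling -----------------------------------
  probs <- c(p_variant, config$wt_fraction, config$other_fraction)
  draw <- .with_seed(stage_seeds[2], {
    sample.int(nvar + 2L, config$n_reads, replace = TRUE, prob = probs)
  })
  is_wt <- draw == nvar + 1L
  is_other <- draw == nvar + 2L

  windows <- character(config$n_reads)
  windows[!is_wt & !is_other] <- expected$variants$seq[draw[!is_wt & !is_other]]
  windows[is_wt] <- expected$wt_window
  n_other <- sum(is_other)
  if (n_other > 0L) {
    windows[is_other] <- .with_seed(stage_seeds[3], {
      .make_other_windows(expected, target, n_other)
    })
  }

  mol <- paste0(adapters[1], windows, adapters[2])

  # --- sequencing errors -------------------------------------------------
  if (config$base_error_rate > 0) {
    mol <- .with_seed(stage_seeds[4], {
      .apply_base_errors(mol, config$base_error_rate)
    })
  }

  truth <- list(
    variant_freq = expected$variants %>%
      select("codon_index", "codon") %>%
      mutate(freq = p_variant),
    wt_fraction = config$wt_fraction,
    other_fraction = config$other_fraction,
    pct_programmed = 100 * prog_mass,
    analytic_logdiff = analytic_logdiff(config),
    n_reads = config$n_reads,
    seed = config$seed
  )

  qual_for <- function(lens) {
    if (length(config$quality) == 1L) {
      strrep(intToUtf8(config$quality + 33L), lens)
    } else {
      vapply(lens, function(L) {
        intToUtf8(sample(seq(config$quality[1], config$quality[2]), L,
                         replace = TRUE) + 33L)
      }, character(1))
    }
  }

  ids <- sprintf("sim_%07d", seq_len(config$n_reads))
  if (!config$paired) {
    reads <- tibble(id = ids, seq = mol, qual = qual_for(nchar(mol)))
    result <- list(reads = reads, truth = truth, adapters = adapters)
  } else {
    rl <- config$read_length
    lens <- nchar(mol)
    if (any(2L * rl - lens < 20L)) {
      abort("read_length leaves < 20 nt of mate overlap for some molecules.")
    }
    fwd <- substr(mol, 1L, rl)
    rev_ <- revcomp(substring(mol, lens - rl + 1L))
    qual <- .with_seed(stage_seeds[5], qual_for(rep(rl, length(mol))))
    result <- list(
      reads = tibble(id = ids, seq = fwd, qual = qual),
      reads2 = tibble(id = ids, seq = rev_, qual = qual),
      truth = truth, adapters = adapters
    )
  }

  if (!is.null(out)) {
    r1 <- paste0(out, "_R1.fastq")
    write_fastq(result$reads, r1)
    paths <- c(r1 = r1)
    if (config$paired) {
      r2 <- paste0(out, "_R2.fastq")
      write_fastq(result$reads2, r2)
      paths <- c(paths, r2 = r2)
    }
    tj <- paste0(out, "_truth.json")
    jsonlite::write_json(
      c(list(provenance = .provenance(config$seed)), truth),
      tj, auto_unbox = TRUE, digits = NA
    )
    result$paths <- c(paths, truth = tj)
  }
  result
}

# Windows with exactly two codon substitutions: never wild type, never a
# single-codon programmed variant.
.make_other_windows <- function(expected, target, n) {
  wt <- expected$schemes
  ncod <- nrow(wt)
  if (ncod < 2L) abort("Need >= 2 window codons to simulate 'other' reads.")
  vapply(seq_len(n), function(i) {
    at <- sample.int(ncod, 2L)
    w <- expected$wt_window
    for (j in at) {
      alt <- sample(setdiff(.DNA_BASES_CODONS, wt$wt_codon[j]), 1L)
      off <- 3L * (wt$codon_index[j] - target$codon_start)
      w <- paste0(substr(w, 1L, off), alt, substring(w, off + 4L))
    }
    w
  }, character(1))
}

.DNA_BASES_CODONS <- as.vector(outer(
  as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
  c("A", "C", "G", "T"), paste0
))

.apply_base_errors <- function(seqs, rate) {
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}
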