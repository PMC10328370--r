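# Nearest-neighbor melting temperature engine.
#
# Unified NN parameters of Allawi & SantaLucia (1997): stacking enthalpies
# (kcal/mol) and entropies (cal/mol/K) for the ten unique dinucleotide duplex
# steps, expanded here to all 16 top-strand dinucleotides (a step and its
# reverse complement share parameters).
.NN_TABLES <- list(
  allawi1997 = list(
    dh = c(
      AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
      CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
      CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
      CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
    ),
    ds = c(
      AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
      CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
      CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
      CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
    ),
    # duplex initiation at a terminal A:T or G:C pair (applied to both ends)
    init_AT = c(dh = 2.3, ds = 4.1),
    init_GC = c(dh = 0.1, ds = -2.8)
  )
)

.GAS_CONSTANT <- 1.987 # cal / (mol K)

#' Thermodynamic parameters for melting-temperature prediction
#'
#' Bundles the nearest-neighbor parameter set, salt and strand concentrations,
#' and the salt-correction formula used by [tm_nn()]. The defaults reproduce
#' the documented defaults of the widely used Biopython
#' `Bio.SeqUtils.MeltingTemp.Tm_NN` routine: the unified Allawi & SantaLucia
#' (1997) table, 25 nM of each strand, 50 mM monovalent sodium, and the
#' SantaLucia (1998) entropic salt correction
#' \eqn{\Delta S += 0.368 (N-1) \ln[\mathrm{Na}^+]}.
#'
#' @param nn_table Identifier of the nearest-neighbor parameter set. Currently
#'   `"allawi1997"` (the unified DNA parameter set).
#' @param na_mM Monovalent sodium concentration in mM. Must be positive.
#' @param primer_nM Concentration of each strand in nM. Must be positive.
#' @param salt_correction Identifier of the salt-correction formula. Currently
#'   `"santalucia1998"` (entropy correction).
#' @return An object of class `thermo_params`.
#' @examples
#' thermo_params()
#' tm_nn("ACGTACGTACGTACGTACGT")
#' @export
thermo_params <- function(nn_table = "allawi1997", na_mM = 50,
                          primer_nM = 25, salt_correction = "santalucia1998") {
  nn_table <- match.arg(nn_table, names(.NN_TABLES))
  salt_correction <- match.arg(salt_correction, "santalucia1998")
  if (!is.numeric(na_mM) || length(na_mM) != 1L || !is.finite(na_mM) || na_mM <= 0) {
    abort("`na_mM` must be a single positive number.")
  }
  if (!is.numeric(primer_nM) || length(primer_nM) != 1L ||
      !is.finite(primer_nM) || primer_nM <= 0) {
    abort("`primer_nM` must be a single positive number.")
  }
  structure(
    list(nn_table = nn_table, na_mM = na_mM, primer_nM = primer_nM,
         salt_correction = salt_correction),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>\n")
  cat("  nn_table:        ", x$nn_table, "\n", sep = "")
  cat("  na_mM:           ", x$na_mM, "\n", sep = "")
  cat("  primer_nM:       ", x$primer_nM, " (each strand)\n", sep = "")
  cat("  salt_correction: ", x$salt_correction, "\n", sep = "")
  invisible(x)
}

#' Nearest-neighbor duplex melting temperature
#'
#' Predicts the melting temperature of a DNA sequence paired with its perfect
#' complement, by summing nearest-neighbor stacking enthalpies and entropies
#' plus terminal initiation penalties, applying an entropic salt correction,
#' and solving the two-state melting equation
#' \deqn{T_m = \frac{1000\,\Delta H}{\Delta S + R \ln C_T/4} - 273.15}
#' where the effective strand concentration for a non-self-complementary
#' duplex at equal strand concentrations \eqn{c} is \eqn{c - c/2}.
#' Self-complementary sequences are deliberately treated as ordinary
#' hetero-duplexes, and no dangling-end or mismatch terms are applied: primer
#' homology arms are assumed fully complementary to template.
#'
#' @param seq Character vector of DNA sequences (A/C/G/T only, length >= 8).
#' @param params A [thermo_params()] object.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' tm_nn(c("ACGTACGTACGTACGTACGT", "GCGCGCGCGCGCGCGCGCGC"))
#' @export
tm_nn <- function(seq, params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  if (!is.character(seq)) abort("`seq` must be a character vector.")
  seq <- toupper(seq)
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    abort(sprintf(
      "Sequence contains non-ACGT characters (first offender: %s). Degenerate bases are not accepted.",
      seq[which(bad)[1]]
    ))
  }
  if (any(nchar(seq) < 8L)) {
    abort("Sequences shorter than 8 nt are too short for a nearest-neighbor Tm.")
  }
  tab <- .NN_TABLES[[params$nn_table]]
  log_k <- log((params$primer_nM - params$primer_nM / 2) * 1e-9)
  log_na <- log(params$na_mM * 1e-3)
  vapply(seq, function(s) {
    n <- nchar(s)
    ends <- c(substr(s, 1L, 1L), substr(s, n, n))
    n_at <- sum(ends %in% c("A", "T"))
    dh <- n_at * tab$init_AT[["dh"]] + (2L - n_at) * tab$init_GC[["dh"]]
    ds <- n_at * tab$init_AT[["ds"]] + (2L - n_at) * tab$init_GC[["ds"]]
    steps <- substring(s, 1:(n - 1L), 2:n)
    dh <- dh + sum(tab$dh[steps])
    ds <- ds + sum(tab$ds[steps])
    ds <- ds + 0.368 * (n - 1L) * log_na
    1000 * dh / (ds + .GAS_CONSTANT * log_k) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Reverse complement of DNA sequences
#'
#' Thin vectorized wrapper around [chartr()]/[Biostrings] semantics for plain
#' A/C/G/T (+ IUPAC) character vectors.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
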