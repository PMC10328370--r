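# Mutagenesis target: a template with a window of codons to saturate.

#' Define a mutagenesis target
#'
#' A mutagenesis target is a template DNA sequence (coding strand), the offset
#' at which its reading frame starts, and a half-open window of codon indices
#' to mutagenize. Every codon in the window must have enough template flank on
#' both sides to accommodate the longest homology arm (40 nt by default);
#' violating that is an error at construction time because no primer could be
#' designed for such a codon.
#'
#' @param template DNA string (coding strand, A/C/G/T). May contain flanking
#'   vector/UTR sequence around the coding region.
#' @param cds_offset 0-based position in `template` where the reading frame
#'   starts.
#' @param codon_start,codon_end Half-open 0-based codon window
#'   `[codon_start, codon_end)` to mutagenize; codon 0 is the first codon of
#'   the reading frame.
#' @param name Label used in primer names and reports.
#' @param flank_required Minimum template flank (nt) required on each side of
#'   every window codon. Defaults to 40, the longest homology arm.
#' @return An object of class `mutagenesis_target`.
#' @examples
#' tpl <- paste(rep("ACGT", 60), collapse = "")
#' mutagenesis_target(tpl, cds_offset = 45, codon_start = 0, codon_end = 10,
#'                    name = "demo")
#' @export
mutagenesis_target <- function(template, cds_offset, codon_start, codon_end,
                               name = "target", flank_required = 40L) {
  if (!is.character(template) || length(template) != 1L) {
    abort("`template` must be a single DNA string.")
  }
  template <- toupper(template)
  if (grepl("[^ACGT]", template)) {
    abort("`template` must contain only A/C/G/T.")
  }
  cds_offset <- as.integer(cds_offset)
  codon_start <- as.integer(codon_start)
  codon_end <- as.integer(codon_end)
  if (cds_offset < 0L) abort("`cds_offset` must be >= 0.")
  if (codon_start < 0L || codon_end <= codon_start) {
    abort("Codon window must satisfy 0 <= codon_start < codon_end.")
  }
  n <- nchar(template)
  if (n - cds_offset < 3L * codon_end) {
    abort(sprintf(
      "Template too short: %d nt after cds_offset, but codon window needs %d.",
      n - cds_offset, 3L * codon_end
    ))
  }
  left_flank <- cds_offset + 3L * codon_start
  right_flank <- n - (cds_offset + 3L * codon_end)
  if (left_flank < flank_required || right_flank < flank_required) {
    abort(sprintf(
      paste0("Every window codon needs >= %d nt of template flank on each ",
             "side; got %d (left) and %d (right)."),
      flank_required, left_flank, right_flank
    ))
  }
  structure(
    list(template = template, cds_offset = cds_offset,
         codon_start = codon_start, codon_end = codon_end, name = name),
    class = "mutagenesis_target"
  )
}

#' @export
print.mutagenesis_target <- function(x, ...) {
  cat("<mutagenesis_target> ", x$name, "\n", sep = "")
  cat("  template: ", nchar(x$template), " nt, cds_offset ", x$cds_offset,
      "\n", sep = "")
  cat("  codon window: [", x$codon_start, ", ", x$codon_end, ") — ",
      x$codon_end - x$codon_start, " codons\n", sep = "")
  invisible(x)
}

#' Wild-type codons of a target window
#'
#' @param target A [mutagenesis_target()].
#' @param codon_index Integer vector of 0-based codon indices; defaults to the
#'   whole window.
#' @return Tibble with `codon_index` and `wt_codon`.
#' @export
wt_codons <- function(target, codon_index = NULL) {
  stopifnot(inherits(target, "mutagenesis_target"))
  if (is.null(codon_index)) {
    codon_index <- seq(target$codon_start, target$codon_end - 1L)
  }
  start <- target$cds_offset + 3L * codon_index + 1L
  tibble(
    codon_index = as.integer(codon_index),
    wt_codon = substring(target$template, start, start + 2L)
  )
}

# 1-based substring coordinates of the codon window within the template
.window_bounds <- function(target) {
  c(start = target$cds_offset + 3L * target$codon_start + 1L,
    end = target$cds_offset + 3L * target$codon_end)
}

#' Wild-type sequence of the codon window
#'
#' @inheritParams wt_codons
#' @return DNA string covering exactly the codon window.
#' @export
window_sequence <- function(target) {
  b <- .window_bounds(target)
  substr(target$template, b[["start"]], b[["end"]])
}
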