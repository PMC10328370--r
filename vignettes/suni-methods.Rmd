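---
title: "Methods: primer design rules, library metrics and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primer design rules, library metrics and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the models, parameter choices and numerical decisions
behind the package, in the spirit of a methods section: what is computed,
under which assumptions, and what the validation suite does and does not
demonstrate.

## The problem

Nicking saturation mutagenesis builds a variant library by annealing, for
each codon of a target region, a mutagenic primer consisting of a left
homology arm, a degenerate codon (NNK/NNS) and a right homology arm, then
degrading and resynthesizing the plasmid strands around it. Library quality
is limited by (i) wild-type carryover, (ii) synthesis/sequencing artifacts,
and (iii) position-to-position differences in mutagenesis efficiency, which
make variant representation non-uniform and inflate the sequencing and
screening effort needed per variant. The package implements the design
rules that address these failure modes and the sequencing QC that
quantifies them.

## Melting-temperature model

Arm selection is driven entirely by a nearest-neighbor duplex model
(`tm_nn()`), with the arm assumed perfectly complementary to template:

* **Parameter set** — the unified DNA nearest-neighbor table of Allawi &
  SantaLucia (1997): ten unique dinucleotide stacking terms plus terminal
  initiation penalties for A:T (ΔH = 2.3 kcal/mol, ΔS = 4.1 cal/mol/K) and
  G:C (0.1, −2.8) ends.
* **Salt correction** — the SantaLucia (1998) entropic form,
  ΔS += 0.368 (N−1) ln[Na⁺], with [Na⁺] = 50 mM by default.
* **Strand concentration** — 25 nM each strand; for a hetero-duplex at
  equal concentrations the effective concentration in the two-state
  equation is c − c/2.
* **Self-complementary sequences** are deliberately treated as ordinary
  hetero-duplexes, and no dangling-end or mismatch corrections are applied.
  These are the documented defaults of the widely used nearest-neighbor
  routine that this engine reproduces, so designs selected by this package
  match designs selected with that routine at its defaults.

All defaults are visible and overridable through `thermo_params()` and the
CLI's `--show-config`. The frozen fixture `tests/testthat/tm-oracle.tsv`
pins 206 sequences to reference values from an independent published
implementation of the same parameter set; the suite requires agreement
within 0.01 °C (observed agreement is at numerical precision) and exact
reverse-complement symmetry, which holds because every stacking term is
shared with its reverse complement.

Predicted secondary-structure free energy (hairpins, self-dimers) is
intentionally **not** modeled: it adds a dependency and was not informative
for mutagenesis efficiency in the analyses this design follows.

## Design rules and their open choices

Both modes enumerate, per codon and side, the 21 arms of length 20–40 nt
abutting the codon (`enumerate_arm_candidates()`).

* **Right arm (both modes) and opt1 left arm**: the |T_m − 61 °C|
  minimizer. On an exact tie the shorter arm wins — the published procedure
  is silent on ties; shorter arms cost less to synthesize, and since each
  length yields exactly one candidate, ties can only occur across lengths.
* **SUNi left arm**: restrict to T_m ∈ [59, 66] °C; prefer arms whose three
  5′-terminal bases are all strong (S = G/C, class SSS), then class SSW or
  SWS, shortest first within the admissible group; if no in-window arm has
  an acceptable clamp, take the arm with T_m closest to 64 °C *irrespective
  of terminus and of the window*, and encode that primer twice
  (`replicate_count = 2`). Whether the fallback re-applies the 59–66 °C
  window is genuinely open; we read "irrespective" as lifting all
  restrictions, and expose `fallback_ignores_window = FALSE` for the other
  reading.
* **Degenerate codon**: NNK everywhere in opt1. In SUNi, NNS when the
  wild-type codon ends in T — K covers G and T, so an NNK pool at such a
  codon would contain the exact wild-type primer, which outcompetes
  mutation-bearing primers and inflates wild-type carryover; S covers G and
  C, excluding it. The expected-variant logic mirrors this: under NNK a
  wild-type codon ending in G or T leaves 31 programmed codons, otherwise
  32.
* **Orientation**: primers are reported on the coding strand of the
  supplied template (`--revcomp` emits the antisense complement; arm T_m is
  strand-symmetric, so selection is unaffected). Coordinates are 0-based
  half-open internally; primer names carry 1-based codon numbers.

## Library metrics

With retained reads classified by perfect match into programmed /
wild-type / other, `compute_metrics()` reports:

* per-variant frequency = count / retained reads;
* **LogDiff** = log10(P90) − log10(P10) over the programmed-variant
  frequencies. Percentiles use linear interpolation between order
  statistics (R's type 7, the common scientific-computing default) — fixed
  and documented because LogDiff is sensitive to the interpolation rule.
  The percentile population is per-variant frequencies by default
  (`per_position = TRUE` computes the per-position alternative for
  comparison).
* **Zero-count variants** are excluded from the percentile population
  (log10 of zero is undefined) and their number is reported;
  `zero_policy = "pseudo"` substitutes 0.5/total instead. Fewer than 10
  nonzero variants is an error, as the 10th/90th percentiles are then
  meaningless.
* **Screening efficiency** = (%programmed/100) / 10^LogDiff, the composite
  score used to compare construction methods; it satisfies the identity
  efficiency × 10^LogDiff × 100 = %programmed by construction, which the
  suite asserts to 1e−9.
* Per-position medians (the "mutagenesis efficiency" of the feature
  analysis) are medians over *all* of a codon's programmed variants,
  zeros included, regardless of `zero_policy` — zeros there are real
  estimates, not percentile pathologies.

The read-processing stages are deliberately simple, documented equivalents
of the usual external tools: expected-error filtering at < 0.5 expected
errors (Σ 10^(−Q/10)), exact adapter gating at both read ends (mismatch
tolerance opt-in), and a maximal-match overlap merger for read pairs
(consensus takes the higher-quality base, quality |Q₁ − Q₂| at
disagreements, max(Q) at agreements; pairs with > 10% overlap mismatches
are rejected). Bit-parity with any external merger/trimmer is not promised;
the mergers are validated against the in-package simulator. Reads arriving
on the opposite strand are recognized by their reverse complement starting
with the left adapter and are flipped before gating (`orient = "forward"`
disables this).

## Simulator and ground truth

`simulate_library()` generates reads whose composition is known exactly:
per-variant abundances are lognormal on the log10 scale (a per-position
multiplier with s.d. σ_pos shared by the codon's variants, times an
independent per-variant multiplier with s.d. σ_var), renormalized over the
programmed mass 1 − wt_fraction − other_fraction; read identities are
multinomial; "other" reads carry exactly two codon substitutions, which
makes them unclassifiable by construction — a modeling shortcut that
exercises the classifier without imitating real error spectra. Qualities
default to constant Q30 so that expected-error filtering is exercised by
explicit low-quality configurations rather than by accident. A single seed
drives deterministic per-stage substreams, so outputs are byte-identical
across runs.

Because normalization only shifts log-frequencies by a constant, the
generating distribution's LogDiff has the closed form
(z₀.₉ − z₀.₁)·σ_t = 2 × 1.28155 × σ_t with σ_t = √(σ_pos² + σ_var²)
(`analytic_logdiff()`), which anchors the round-trip tests.

The defaults (15% wild-type, 8% other, σ_pos = σ_var = 0.18, hence
σ_t ≈ 0.25 and analytic LogDiff ≈ 0.65) emulate the composition of a
high-quality SUNi-style library. The simulator does **not** model
realistic Illumina error profiles, PCR jackpotting, chimeras, indels or
barcode structure — so passing round-trip tests demonstrates the internal
consistency of the pipeline and metrics, not performance on real
sequencing data.

### Validation problem sizes

The round-trip check compares measured LogDiff with the closed form at
10⁶ reads for σ_t ∈ {0, 0.3, 0.5}. Problem size matters here for
statistical, not computational, reasons: with V variants sharing the
programmed read mass N_p, multinomial counting noise alone contributes
about 2.563 × 0.434/√(N_p/V) of apparent LogDiff, and the finite draw of V
lognormal abundances makes the realized 10th/90th percentile gap deviate
from the asymptotic closed form by O(σ_t/√V). A 30-codon window (~945
variants) at 10⁶ reads keeps the first term near 0.04 — inside the 0.05
comparison band — while the 5-seed average suppresses the second; the
equal-abundance unit test uses a 6-codon window where the counting-noise
floor is ~0.015, comfortably under its 0.02 bound. Design-rule compliance
is checked on 100 random 60-codon templates spanning 30–70% GC, the range
bracketing the high- and low-GC regions the method was developed on.

## Correlation engine

The feature analysis (`featurize_pool()`, `feature_scan()`,
`class_medians()`) pairs each position's design features — left/right arm
T_m, their min/max/sum/difference, and the GC fraction of the k = 1..5
terminal bases at the left arm's 5′ end and the right arm's 3′ end — with
its measured efficiency, and computes tie-corrected Spearman ρ (Pearson
correlation of mid-ranks). Because no published method is stated for the
p-values, the package fixes its own, split by sample size: exhaustive
permutation enumeration for n ≤ 10 (exact, two-sided on |ρ|), seeded
Monte-Carlo permutation with 10⁵ draws for n ≤ 30 (reported p is the
add-one estimate, never zero), and the t approximation
t = ρ√((n−2)/(1−ρ²)) above. The suite checks the exact branch against an
independent enumeration oracle, the Monte-Carlo branch against the exact
one, and the t branch against the exact one at n = 10 (agreement within
0.01 on random data). Feature columns that are constant in a given pool —
e.g. the 1-base 5′ GC fraction of a fully clamp-compliant SUNi pool — have
no defined rank correlation and are reported with ρ = NA and method
`"undefined_constant"` rather than dropped, so a scan always returns one
row per feature. No multiple-testing correction is applied; the scan is
exploratory and flagged as unadjusted.

The planted-signal check generates 80 positions with random arms and
efficiency = 5×10⁻⁴ + 6×10⁻⁴·gc5_k3 + N(0, 10⁻⁴): the slope spans roughly
six noise standard deviations across the feature's range, a clearly
detectable but not degenerate signal, chosen once so that the scan must
rank the planted feature above its strongly correlated neighbors (gc5_k2,
gc5_k4 share two of its three bases) in at least 95 of 100 seeded runs.

## Known limitations

* Classification is exact-match only: indels, multi-codon events and reads
  with any sequencing error in the window all land in "other"; there is no
  alignment-based rescue, barcode or UMI handling.
* The QC denominators are retained reads (post merge, expected-error and
  adapter filters); comparisons against pipelines using other denominators
  need care.
* The T_m engine rejects degenerate bases by design — it scores homology
  arms, not the degenerate codon.
* Exhaustive permutation at n = 10 allocates a 3.6M-row matrix
  (~300 MB transiently); above n = 10 the engine switches to sampling
  precisely to avoid this.
* The CLI takes all configuration through flags (printed by
  `--show-config`); there is no configuration-file parser.
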