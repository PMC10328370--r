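# Shared fixture builders. Everything is generated in code from fixed seeds;
# the only stored fixture is tm-oracle.tsv (reference melting temperatures
# from an independent published nearest-neighbor implementation).

# Random template with a given GC content and enough flank for 40-mer arms.
random_template <- function(n_codons, gc = 0.5, flank = 60L, seed = NULL) {
  draw <- function() {
    n <- flank * 2L + 3L * n_codons
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  tpl <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  mutagenesis_target(tpl, cds_offset = flank, codon_start = 0L,
                     codon_end = n_codons,
                     name = sprintf("rnd%dgc%02.0f", n_codons, 100 * gc))
}

# Fixed 200-nt template used for hand-sliced arm checks.
fixture_target <- function() {
  tpl <- paste0(
    "GATTACAGATTACAGATTACAGATTACAGATTACAGATTACA",      # 42 nt left flank
    "ATGGCCGGCTGGACTTTCGCCGATAAGCCCGGATTACTGCAT",      # codons 0..13
    "GCTGGCAAGTAA",                                    # codons 14..17
    "GATTACAGATTACAGATTACAGATTACAGATTACAGATTACAGATTACAGATTACAGATTACAGATTACAGATTACAGATTACAGATTACAGATTACAGATTAC"
  )
  mutagenesis_target(tpl, cds_offset = 42L, codon_start = 0L,
                     codon_end = 18L, name = "fix200")
}

# Independent Spearman oracle: exhaustive enumeration with a different
# permutation algorithm (Heap's) and per-permutation cor() calls.
heap_permutations <- function(n) {
  a <- seq_len(n)
  out <- matrix(NA_integer_, factorial(n), n)
  k <- 0L
  gen <- function(m) {
    if (m == 1L) {
      k <<- k + 1L
      out[k, ] <<- a
      return(invisible())
    }
    for (i in seq_len(m)) {
      gen(m - 1L)
      j <- if (m %% 2L == 0L) i else 1L
      tmp <- a[j]; a[j] <<- a[m]; a[m] <<- tmp
    }
  }
  gen(n)
  out
}

spearman_exact_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- heap_permutations(length(x))
  rhos <- apply(perms, 1L, function(p) cor(rx, ry[p]))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# Synthetic primer-feature rows with a monotone signal planted on one
# feature (plus independent noise); arms are random so correlated gc
# features arise naturally.
planted_features <- function(n = 80, planted = "gc5_k3", slope = 6e-4,
                             noise_sd = 1e-4) {
  left <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(20:40, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  right <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(20:40, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  rows <- tibble::tibble(
    codon_index = seq_len(n) - 1L,
    left_tm = tm_nn(left), right_tm = tm_nn(right)
  )
  rows$tm_min <- pmin(rows$left_tm, rows$right_tm)
  rows$tm_max <- pmax(rows$left_tm, rows$right_tm)
  rows$tm_sum <- rows$left_tm + rows$right_tm
  rows$tm_diff <- rows$left_tm - rows$right_tm
  for (k in 1:5) {
    rows[[paste0("gc5_k", k)]] <- terminal_gc(left, "5prime", k)
    rows[[paste0("gc3_k", k)]] <- terminal_gc(right, "3prime", k)
  }
  rows$terminal_class <- sw_class(left, "5prime", 3L)
  rows$efficiency <- 5e-4 + slope * rows[[planted]] + rnorm(n, 0, noise_sd)
  rows
}

# Small variant_counts object with hand-written counts (3 codons x 11
# variants) for spreadsheet-checked metric values.
hand_count_table <- function() {
  counts <- c(5, 8, 12, 0, 7, 15, 22, 3, 9, 11, 6,
              14, 18, 2, 10, 13, 4, 16, 20, 1, 19,
              17, 21, 23, 25, 24, 26, 27, 28, 30, 29, 31, 32)
  structure(
    list(
      counts = tibble::tibble(
        codon_index = rep(0:2, each = 11L),
        codon = sprintf("C%02d", seq_along(counts)),
        aa = "X",
        count = as.integer(counts)
      ),
      wt_count = 120L, other_count = 40L,
      total_retained = sum(counts) + 160L
    ),
    class = "variant_counts"
  )
}
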