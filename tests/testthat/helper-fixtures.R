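## Shared fixture builders. Everything is generated in code; no files
## beyond what individual tests write to tempdir().

## tiny handcrafted population: 3 progeny, one marker of each class
tiny_loci <- function() {
  data.frame(marker_id = c("mA", "mB", "mC"),
             chromosome = c("chr01", "chr01", "chr02"),
             genetic_pos = c(0, 10, 5),
             physical_pos = c(0, 12.5, NA),
             seg_class = c("maternal", "paternal", "biparental"),
             phase_maternal = c(0L, NA, 1L),
             phase_paternal = c(NA, 0L, 0L),
             stringsAsFactors = FALSE)
}

tiny_codes <- function() {
  matrix(c("ll", "lm", "lm",
           "np", "nn", "np",
           "hh", "hk", "kk"),
         nrow = 3, ncol = 3,
         dimnames = list(c("p1", "p2", "p3"), c("mA", "mB", "mC")))
}

tiny_matrix <- function() genotype_matrix(tiny_loci(), tiny_codes())

## a small multi-chromosome simulated population (paternal-only by default)
small_sim <- function(n = 60, n_chr = 2, length_cM = 60, markers = 31,
                      classes = "paternal", selections = list(), seed = 7) {
  maps <- lapply(seq_len(n_chr), function(i)
    chromosome_map(sprintf("chr%02d", i), length_cM, length_cM * 0.8,
                   n_markers = markers))
  simulate_population(cross_design(maps, n, marker_classes = classes,
                                   selections = selections, seed = seed))
}

## build a distortion-results-like data.frame directly (for sdr tests)
fake_results <- function(chromosome, genetic_pos, p_value,
                         seg_class = "paternal", physical_pos = NULL,
                         ratio = 2) {
  n <- length(genetic_pos)
  data.frame(marker_id = sprintf("%s_f%03d", chromosome, seq_len(n)),
             chromosome = chromosome,
             genetic_pos = genetic_pos,
             physical_pos = physical_pos %||% genetic_pos * 0.9,
             seg_class = seg_class,
             n1 = NA, n2 = NA, n3 = NA, n = 96,
             chi2 = stats::qchisq(p_value, 1, lower.tail = FALSE),
             df = 1L,
             p_value = p_value,
             neg_log10_p = -log10(p_value),
             distortion_ratio = ratio,
             favored_class = "nn",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## independent closed-form chi-square upper-tail oracles (df 1, 2, 3)
oracle_tail <- function(x, df) {
  switch(as.character(df),
         "1" = 2 * stats::pnorm(sqrt(x), lower.tail = FALSE),
         "2" = exp(-x / 2),
         "3" = 2 * stats::pnorm(sqrt(x), lower.tail = FALSE) +
           sqrt(2 * x / pi) * exp(-x / 2),
         stop("no oracle for df ", df))
}

## brute-force longest non-decreasing subsequence (n <= 20)
brute_lnds_len <- function(v) {
  n <- length(v)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    if (!is.unsorted(v[idx])) best <- length(idx)
  }
  best
}
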