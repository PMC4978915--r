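#' Configuration for segregation-distortion testing
#'
#' @param alpha_levels Strictly decreasing significance levels at which
#'   distortion is classified; defaults to the 5, 1, 0.1 and 0.001 percent
#'   levels used throughout the package.
#' @param ratio_threshold_1to1 A 1:1 locus is dropped by the ratio filter
#'   when the larger:smaller class ratio exceeds this (default 10, i.e.
#'   worse than 1:10).
#' @param ratio_threshold_1to2to1 A 1:2:1 locus is dropped when one
#'   homozygote class is more than this many times under-represented
#'   relative to the other homozygote (default 5, i.e. worse than 1:5:5).
#' @return A `distortion_config` list.
#' @export
distortion_config <- function(alpha_levels = c(0.05, 0.01, 0.001, 0.00001),
                              ratio_threshold_1to1 = 10,
                              ratio_threshold_1to2to1 = 5) {
  if (is.unsorted(rev(alpha_levels), strictly = TRUE))
    stop("alpha_levels must be strictly decreasing")
  if (any(c(ratio_threshold_1to1, ratio_threshold_1to2to1) <= 1))
    stop("ratio thresholds must exceed 1")
  structure(list(alpha_levels = alpha_levels,
                 ratio_threshold_1to1 = ratio_threshold_1to1,
                 ratio_threshold_1to2to1 = ratio_threshold_1to2to1[1]),
            class = "distortion_config")
}

#' Chi-square goodness-of-fit test against a Mendelian segregation ratio
#'
#' Plain Pearson chi-square, `sum((O - E)^2 / E)`, with expected counts
#' from the stated ratio (1:1 for single-parent segregation, 1:2:1 for
#' biparental) and no continuity correction; the p-value is the upper tail
#' of the chi-square distribution with `classes - 1` degrees of freedom.
#'
#' @param counts Non-negative observed class counts: length 2 for `"1:1"`
#'   (homozygote, heterozygote), length 3 for `"1:2:1"` (homozygote,
#'   heterozygote, homozygote).
#' @param expected_ratio `"1:1"` or `"1:2:1"` (inferred from the length of
#'   `counts` when omitted).
#' @return A list with `chi2`, `df`, `p_value` and `neg_log10_p`.
#' @export
#' @examples
#' chi_square_segregation(c(25, 71))
#' chi_square_segregation(c(20, 60, 50), "1:2:1")
chi_square_segregation <- function(counts,
                                   expected_ratio = c("1:1", "1:2:1")) {
  ratio <- ratio_weights(counts, expected_ratio)
  if (any(counts < 0)) stop("class counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("no observations (n = 0)")
  e <- n * ratio / sum(ratio)
  chi2 <- sum((counts - e)^2 / e)
  df <- length(counts) - 1L
  p <- chisq_upper_tail(chi2, df)
  list(chi2 = chi2, df = df, p_value = p, neg_log10_p = -log10(p))
}

ratio_weights <- function(counts, expected_ratio) {
  if (length(expected_ratio) > 1)
    expected_ratio <- if (length(counts) == 2) "1:1" else "1:2:1"
  switch(expected_ratio,
         "1:1" = {
           if (length(counts) != 2) stop("1:1 needs two class counts")
           c(1, 1)
         },
         "1:2:1" = {
           if (length(counts) != 3) stop("1:2:1 needs three class counts")
           c(1, 2, 1)
         },
         stop("expected_ratio must be '1:1' or '1:2:1'"))
}

#' Distortion ratio and favored class at a locus
#'
#' The ratio of the over- to the under-represented genotypic class,
#' reported in the field's `1:x` convention as a number `>= 1`. For 1:1
#' loci it is the larger over the smaller of the two class counts; for
#' 1:2:1 loci it is taken over the two homozygote classes only (the
#' heterozygote is ambiguous about parental origin). A zero class count
#' yields an infinite ratio.
#'
#' @inheritParams chi_square_segregation
#' @return A list with `ratio` (>= 1, possibly `Inf`), `favored_class`
#'   (name or index of the over-represented class) and the two `counts`
#'   the ratio was computed from.
#' @export
#' @examples
#' distortion_ratio(c(5, 91))  # the 1:18.2 worked example
distortion_ratio <- function(counts, expected_ratio = c("1:1", "1:2:1")) {
  ratio_weights(counts, expected_ratio)  # validates the shape
  if (any(counts < 0)) stop("class counts must be non-negative")
  idx <- if (length(counts) == 2) c(1L, 2L) else c(1L, 3L)
  pair <- counts[idx]
  nm <- names(counts)[idx] %||% paste0("class", idx)
  hi <- which.max(pair)
  lo <- 3L - hi
  list(ratio = if (pair[lo] == 0) Inf else unname(pair[hi] / pair[lo]),
       favored_class = nm[hi],
       counts = stats::setNames(unname(pair), nm))
}

#' Ratio-threshold filter for heavily distorted loci
#'
#' Mirrors the pre-mapping filter that excludes markers whose segregation
#' is worse than 1:10 (single-parent loci) or 1:5:5 (biparental loci,
#' judged between the two homozygote classes).
#'
#' @inheritParams chi_square_segregation
#' @param config A [distortion_config()].
#' @return `TRUE` to keep the locus, `FALSE` to drop it.
#' @export
ratio_threshold_filter <- function(counts,
                                   expected_ratio = c("1:1", "1:2:1"),
                                   config = distortion_config()) {
  r <- distortion_ratio(counts, expected_ratio)$ratio
  thr <- if (length(counts) == 2) config$ratio_threshold_1to1
  else config$ratio_threshold_1to2to1
  r <= thr
}

#' Per-locus segregation-distortion tests for a whole population
#'
#' Runs [chi_square_segregation()] and [distortion_ratio()] on every
#' marker of a genotype matrix. Class counts are `(ll, lm)`, `(nn, np)` or
#' `(hh, hk, kk)` according to the marker's segregation class. Loci with
#' missing codes are excluded before testing (default policy, matching a
#' dataset cleaned at the source); set `drop_missing = FALSE` to test them
#' on their non-missing codes instead.
#'
#' @param g A [genotype_matrix()].
#' @param config A [distortion_config()].
#' @param drop_missing Exclude loci containing missing codes (default).
#' @return A data.frame with one row per tested locus: map columns, class
#'   counts (`n1`, `n2`, `n3`; `n3` is `NA` for 1:1 loci), `n`,
#'   `expected_ratio`, `chi2`, `df`, `p_value`, `neg_log10_p`,
#'   `distortion_ratio`, `favored_class`, `significance_level` (the
#'   strictest configured alpha with `p < alpha`, `NA` when none) and
#'   `keep_ratio_threshold`.
#' @export
test_distortion <- function(g, config = distortion_config(),
                            drop_missing = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  codes <- g$codes
  loci <- g$loci
  has_missing <- colSums(codes == MISSING_CODE) > 0
  if (drop_missing && any(has_missing)) {
    message("excluding ", sum(has_missing), " locus/loci with missing codes")
    codes <- codes[, !has_missing, drop = FALSE]
    loci <- loci[!has_missing, , drop = FALSE]
  }
  m <- nrow(loci)
  if (m == 0) stop("no loci to test")

  bi <- loci$seg_class == "biparental"
  first <- ifelse(loci$seg_class == "maternal", "ll",
                  ifelse(loci$seg_class == "paternal", "nn", "hh"))
  second <- ifelse(loci$seg_class == "maternal", "lm",
                   ifelse(loci$seg_class == "paternal", "np", "hk"))
  n1 <- colSums(codes == matrix(first, nrow(codes), m, byrow = TRUE))
  n2 <- colSums(codes == matrix(second, nrow(codes), m, byrow = TRUE))
  n3 <- ifelse(bi, colSums(codes == "kk"), NA_real_)
  n <- n1 + n2 + ifelse(bi, n3, 0)
  if (any(n == 0)) stop("locus with zero informative progeny")

  ## vectorised chi-square
  chi2 <- numeric(m)
  e1 <- ifelse(bi, n / 4, n / 2)
  e2 <- ifelse(bi, n / 2, n / 2)
  chi2 <- (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  chi2[bi] <- chi2[bi] + (n3[bi] - e1[bi])^2 / e1[bi]
  df <- ifelse(bi, 2L, 1L)
  p <- chisq_upper_tail(chi2, df)

  hom_hi <- ifelse(bi, pmax(n1, n3), pmax(n1, n2))
  hom_lo <- ifelse(bi, pmin(n1, n3), pmin(n1, n2))
  ratio <- ifelse(hom_lo == 0, Inf, hom_hi / hom_lo)
  fav_first <- ifelse(bi, n1 >= n3, n1 >= n2)
  favored <- ifelse(fav_first, first,
                    ifelse(bi, "kk", second))

  lev <- rep(NA_real_, m)
  for (a in sort(config$alpha_levels, decreasing = TRUE))
    lev[p < a] <- a
  thr <- ifelse(bi, config$ratio_threshold_1to2to1,
                config$ratio_threshold_1to1)

  out <- data.frame(marker_id = loci$marker_id,
                    chromosome = loci$chromosome,
                    genetic_pos = loci$genetic_pos,
                    physical_pos = loci$physical_pos,
                    seg_class = loci$seg_class,
                    expected_ratio = ifelse(bi, "1:2:1", "1:1"),
                    n1 = n1, n2 = n2, n3 = n3, n = n,
                    chi2 = chi2, df = df, p_value = p,
                    neg_log10_p = -log10(p),
                    distortion_ratio = ratio,
                    favored_class = favored,
                    significance_level = lev,
                    keep_ratio_threshold = ratio <= thr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize distortion by significance level, chromosome and class
#'
#' Proportion of loci with `p < alpha` at each configured level, reported
#' per chromosome (across classes), per segregation class (genome-wide)
#' and genome-wide overall. Levels are nested: every locus counted at a
#' stricter level is also counted at the looser ones.
#'
#' @param results A data.frame from [test_distortion()].
#' @param config A [distortion_config()].
#' @return A long data.frame with columns `scope` (`"chromosome"`,
#'   `"seg_class"` or `"genome"`), `group`, `alpha`, `n_loci`,
#'   `n_distorted` and `proportion`.
#' @export
summarize_distortion <- function(results, config = distortion_config()) {
  stopifnot(nrow(results) >= 1)
  one <- function(scope, group, idx) {
    p <- results$p_value[idx]
    do.call(rbind, lapply(config$alpha_levels, function(a)
      data.frame(scope = scope, group = group, alpha = a,
                 n_loci = length(p), n_distorted = sum(p < a),
                 proportion = mean(p < a), stringsAsFactors = FALSE)))
  }
  out <- rbind(
    do.call(rbind, lapply(unique(results$chromosome), function(chr)
      one("chromosome", chr, results$chromosome == chr))),
    do.call(rbind, lapply(intersect(SEG_CLASSES, results$seg_class),
                          function(cl)
      one("seg_class", cl, results$seg_class == cl))),
    one("genome", "all", rep(TRUE, nrow(results))))
  rownames(out) <- NULL
  out
}
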