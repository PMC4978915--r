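#' Configuration for the unlinked-locus interaction scan
#'
#' @param p_threshold Significance threshold for reported interactions
#'   (default 0.005).
#' @param linked_cutoff_cM Two loci on the same chromosome count as
#'   unlinked when at least this far apart (default 50 cM); loci on
#'   different chromosomes are always unlinked.
#' @return An `epistasis_config` list.
#' @export
epistasis_config <- function(p_threshold = 0.005, linked_cutoff_cM = 50) {
  stopifnot(p_threshold > 0, p_threshold < 1, linked_cutoff_cM > 0)
  structure(list(p_threshold = p_threshold,
                 linked_cutoff_cM = linked_cutoff_cM),
            class = "epistasis_config")
}

#' Encode genotypes as per-homolog allele codes at bin positions
#'
#' Reconstructs, for every progeny individual and every bin representative
#' locus, a numeric code suitable for linkage-disequilibrium analysis:
#' for 1:1 loci the transmitted-homolog indicator (1 or 2) of the
#' informative parent, derived from the genotype code and the linkage
#' phase; for biparental `<hkxhk>` loci the genotype dosage (0, 1 or 2
#' copies of the `k` allele). Missing codes give `NA`.
#'
#' @param g A [genotype_matrix()].
#' @param bins Optional result of [collapse_bins()]; computed from `g`
#'   when omitted. Only bin representatives are encoded.
#' @return A list with `codes` (numeric progeny x bins matrix) and `loci`
#'   (the representatives' map data.frame).
#' @export
phase_encode <- function(g, bins = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(bins)) bins <- collapse_bins(g)
  gb <- bins$matrix
  loci <- gb$loci
  enc <- matrix(NA_real_, nrow = length(gb$progeny_ids),
                ncol = nrow(loci),
                dimnames = list(gb$progeny_ids, loci$marker_id))
  for (parent in c("maternal", "paternal")) {
    h <- homolog_indicators(gb, parent)
    if (nrow(h$loci))
      enc[, h$loci$marker_id] <- h$indicator
  }
  bi <- which(loci$seg_class == "biparental")
  for (j in bi) {
    v <- gb$codes[, j]
    enc[, j] <- c(hh = 0, hk = 1, kk = 2)[v]
  }
  list(codes = enc, loci = loci)
}

#' Linkage-disequilibrium r-squared between two loci
#'
#' `r^2` is the squared Pearson correlation between the two code vectors
#' over progeny observed at both loci; under independence `n * r^2` is
#' asymptotically chi-square with 1 degree of freedom, which supplies the
#' p-value. For binary codes `n * r^2` equals the Pearson chi-square of
#' the 2x2 contingency table exactly.
#'
#' @param a,b Numeric code vectors of equal length (`NA` = missing).
#' @param n_perm Optional number of permutations; when > 0 the p-value is
#'   instead the permutation tail probability of `r^2` (shuffling `b`),
#'   the slow exact oracle for the asymptotic test.
#' @return A list with `r_squared`, `n` (complete pairs), `chi2`,
#'   `p_value`; `NULL` when either vector has fewer than 2 distinct
#'   observed values (zero variance — the pair is untestable).
#' @export
pairwise_r2 <- function(a, b, n_perm = 0) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2 || stats::var(a) == 0 || stats::var(b) == 0) return(NULL)
  r2 <- stats::cor(a, b)^2
  chi2 <- n * r2
  if (n_perm > 0) {
    perm <- replicate(n_perm, stats::cor(a, sample(b))^2)
    p <- (sum(perm >= r2) + 1) / (n_perm + 1)
  } else {
    p <- chisq_upper_tail(chi2, 1L)
  }
  list(r_squared = r2, n = n, chi2 = chi2, p_value = p)
}

#' Scan all unlinked bin pairs for allelic interactions
#'
#' Encodes bin representatives with [phase_encode()], computes `r^2`
#' between every pair of loci satisfying the unlinked definition
#' (different chromosomes, or at least `linked_cutoff_cM` apart on the
#' same chromosome), and retains pairs with `p < p_threshold`. Pairs
#' where either locus has zero variance are skipped.
#'
#' @param g A [genotype_matrix()].
#' @param config An [epistasis_config()].
#' @param bins Optional precomputed [collapse_bins()] result.
#' @return A list with `hits` (data.frame: `locus_a`, `locus_b`,
#'   `chromosome_a`, `chromosome_b`, `r_squared`, `n`, `p_value`),
#'   `n_pairs_tested`, and `chromosome_pairs` (data.frame of hit counts
#'   per unordered chromosome pair).
#' @export
epistasis_scan <- function(g, config = epistasis_config(), bins = NULL) {
  enc <- phase_encode(g, bins)
  codes <- enc$codes
  loci <- enc$loci
  m <- ncol(codes)

  obs <- !is.na(codes)
  n_pair <- crossprod(obs)                    # complete pairs per locus pair
  suppressWarnings(r <- stats::cor(codes, use = "pairwise.complete.obs"))
  r2 <- r^2

  ia <- rep(seq_len(m), times = m)
  ib <- rep(seq_len(m), each = m)
  upper <- ia < ib
  same_chr <- loci$chromosome[ia] == loci$chromosome[ib]
  dist_cM <- abs(loci$genetic_pos[ia] - loci$genetic_pos[ib])
  unlinked <- upper & (!same_chr | dist_cM >= config$linked_cutoff_cM)
  testable <- unlinked & !is.na(as.vector(r2)) & as.vector(n_pair) >= 2

  idx <- which(testable)
  r2v <- as.vector(r2)[idx]
  nv <- as.vector(n_pair)[idx]
  pv <- chisq_upper_tail(nv * r2v, 1L)

  hit <- pv < config$p_threshold
  hits <- data.frame(locus_a = loci$marker_id[ia[idx][hit]],
                     locus_b = loci$marker_id[ib[idx][hit]],
                     chromosome_a = loci$chromosome[ia[idx][hit]],
                     chromosome_b = loci$chromosome[ib[idx][hit]],
                     r_squared = r2v[hit], n = nv[hit],
                     p_value = pv[hit], stringsAsFactors = FALSE)
  hits <- hits[order(hits$p_value), , drop = FALSE]
  rownames(hits) <- NULL

  if (nrow(hits)) {
    pair_key <- paste(pmin(hits$chromosome_a, hits$chromosome_b),
                      pmax(hits$chromosome_a, hits$chromosome_b),
                      sep = ":")
    tab <- as.data.frame(table(pair_key), stringsAsFactors = FALSE)
    chrom_pairs <- data.frame(
      chromosome_a = sub(":.*", "", tab$pair_key),
      chromosome_b = sub(".*:", "", tab$pair_key),
      n_hits = tab$Freq, stringsAsFactors = FALSE)
  } else {
    chrom_pairs <- data.frame(chromosome_a = character(0),
                              chromosome_b = character(0),
                              n_hits = integer(0), stringsAsFactors = FALSE)
  }
  list(hits = hits, n_pairs_tested = length(idx),
       chromosome_pairs = chrom_pairs)
}
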