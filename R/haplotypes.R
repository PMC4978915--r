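## Transmitted-homolog indicators for one parent's 1:1 loci.
## Phase convention: phase 0 puts the second-listed allele (m or p) on
## homolog 1, so a progeny carrying the heterozygous code (lm / np)
## received homolog 1 when the phase is 0 and homolog 2 when it is 1.
homolog_indicators <- function(g, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  sel <- g$loci$seg_class == parent
  loci <- g$loci[sel, , drop = FALSE]
  codes <- g$codes[, sel, drop = FALSE]
  phase <- if (parent == "maternal") loci$phase_maternal
  else loci$phase_paternal
  het <- if (parent == "maternal") "lm" else "np"
  ind <- matrix(NA_integer_, nrow(codes), ncol(codes),
                dimnames = dimnames(codes))
  if (ncol(codes)) {
    is_het <- codes == het
    is_obs <- codes != MISSING_CODE
    ph <- matrix(phase, nrow(codes), ncol(codes), byrow = TRUE)
    ind[is_obs] <- ifelse(is_het[is_obs] == (ph[is_obs] == 0L), 1L, 2L)
  }
  list(loci = loci, indicator = ind)
}

#' Haplotype-transmission frequencies along chromosomes
#'
#' For every 1:1 locus of the chosen parent, assigns each informative
#' progeny to the parental homolog it received (via the locus's linkage
#' phase) and reports the frequency of homolog 1 together with a 1:1
#' chi-square test on the homolog counts. Biparental loci are excluded:
#' their heterozygotes are ambiguous about parental origin.
#'
#' These per-locus frequencies are the input for the classical
#' two-haplotype transmission plots along each chromosome.
#'
#' @param g A [genotype_matrix()].
#' @param parent `"maternal"` or `"paternal"`.
#' @return A data.frame with one row per locus: map columns,
#'   `n_informative`, `n_homolog1`, `freq_homolog1`, `chi2`, `p_value`.
#' @export
transmission_profile <- function(g, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  h <- homolog_indicators(g, parent)
  if (!nrow(h$loci)) {
    warning("no ", parent, " 1:1 loci in this population")
    return(data.frame())
  }
  n1 <- colSums(h$indicator == 1L, na.rm = TRUE)
  n_inf <- colSums(!is.na(h$indicator))
  if (any(n_inf == 0)) stop("locus with zero informative progeny")
  e <- n_inf / 2
  chi2 <- (n1 - e)^2 / e + ((n_inf - n1) - e)^2 / e
  out <- data.frame(marker_id = h$loci$marker_id,
                    chromosome = h$loci$chromosome,
                    genetic_pos = h$loci$genetic_pos,
                    physical_pos = h$loci$physical_pos,
                    parent = parent,
                    n_informative = n_inf,
                    n_homolog1 = n1,
                    freq_homolog1 = n1 / n_inf,
                    chi2 = chi2,
                    p_value = chisq_upper_tail(chi2, 1L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Four-way biparental haplotype-combination profile
#'
#' Pairs each maternal 1:1 locus with the nearest paternal 1:1 locus on
#' the same chromosome within `window_cM`, counts the four maternal x
#' paternal homolog combinations (`M1P1`, `M1P2`, `M2P1`, `M2P2`) among
#' progeny informative at both loci, and tests the counts against
#' 1:1:1:1 with a chi-square on 3 degrees of freedom.
#'
#' @param g A [genotype_matrix()].
#' @param window_cM Maximum pairing distance in cM (default 1).
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.001).
#' @return A data.frame with one row per paired maternal locus: the pair,
#'   the four combination counts, `n`, `chi2`, `p_value`, `significant`.
#'   Maternal loci without a paternal partner inside the window are
#'   skipped.
#' @export
combination_profile <- function(g, window_cM = 1, alpha = 0.001) {
  hm <- homolog_indicators(g, "maternal")
  hp <- homolog_indicators(g, "paternal")
  if (!nrow(hm$loci) || !nrow(hp$loci))
    stop("combination_profile needs both maternal and paternal 1:1 loci")
  rows <- list()
  for (i in seq_len(nrow(hm$loci))) {
    same <- which(hp$loci$chromosome == hm$loci$chromosome[i])
    if (!length(same)) next
    d <- abs(hp$loci$genetic_pos[same] - hm$loci$genetic_pos[i])
    j <- same[which.min(d)]
    if (min(d) > window_cM) next
    im <- hm$indicator[, i]
    ip <- hp$indicator[, j]
    ok <- !is.na(im) & !is.na(ip)
    combo <- factor(COMBO_LABELS[(im[ok] - 1L) * 2L + ip[ok]],
                    levels = COMBO_LABELS)
    cnt <- as.integer(table(combo))
    n <- sum(cnt)
    if (n == 0) next
    e <- n / 4
    chi2 <- sum((cnt - e)^2 / e)
    p <- chisq_upper_tail(chi2, 3L)
    rows[[length(rows) + 1L]] <-
      data.frame(maternal_marker = hm$loci$marker_id[i],
                 paternal_marker = hp$loci$marker_id[j],
                 chromosome = hm$loci$chromosome[i],
                 maternal_cM = hm$loci$genetic_pos[i],
                 paternal_cM = hp$loci$genetic_pos[j],
                 n = n, n_M1P1 = cnt[1], n_M1P2 = cnt[2],
                 n_M2P1 = cnt[3], n_M2P2 = cnt[4],
                 chi2 = chi2, p_value = p,
                 significant = p < alpha,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count crossover events per progeny from phased 1:1 loci
#'
#' Counts transitions in the transmitted-homolog indicator sequence along
#' each chromosome, per progeny and parent. Missing codes are skipped
#' (the transition is judged between the flanking observed loci). With
#' `min_run > 1`, runs of fewer than `min_run` consecutive loci are
#' ignored before counting, a guard against isolated genotyping errors;
#' the default performs no smoothing.
#'
#' @param x A [genotype_matrix()], or the `truth` element of
#'   [simulate_population()] (whose indicator sequences are then counted
#'   directly, giving the true detected-crossover counts).
#' @param parent `"maternal"` or `"paternal"`.
#' @param min_run Minimum run length kept before counting (default 1).
#' @return A data.frame with `progeny_id`, `chromosome`, `parent`,
#'   `n_crossovers`.
#' @export
count_crossovers <- function(x, parent = c("maternal", "paternal"),
                             min_run = 1) {
  parent <- match.arg(parent)
  if (inherits(x, "genotype_matrix")) {
    h <- homolog_indicators(x, parent)
    if (!nrow(h$loci))
      stop("no ", parent, " 1:1 loci to count crossovers from")
    chr_of <- h$loci$chromosome
    ind <- h$indicator
    progeny <- rownames(ind)
  } else if (is.list(x) && !is.null(x[[parent]])) {
    mats <- lapply(x[[parent]], `[[`, "indicator")
    chr_of <- rep(names(x[[parent]]),
                  vapply(mats, ncol, 0L))
    ind <- do.call(cbind, mats)
    progeny <- rownames(ind)
  } else stop("x must be a genotype_matrix or a simulator truth record")

  rows <- list()
  for (chr in unique(chr_of)) {
    sub <- ind[, chr_of == chr, drop = FALSE]
    nxo <- apply(sub, 1, function(v) {
      v <- v[!is.na(v)]
      if (min_run > 1 && length(v)) v <- drop_short_runs(v, min_run)
      if (length(v) < 2) 0L else sum(diff(v) != 0)
    })
    rows[[chr]] <- data.frame(progeny_id = progeny, chromosome = chr,
                              parent = parent, n_crossovers = nxo,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

drop_short_runs <- function(v, min_run) {
  r <- rle(v)
  v[rep(r$lengths >= min_run, r$lengths)]
}

#' Totals and per-progeny mean of counted crossovers
#'
#' @param counts Output of [count_crossovers()] (rows from both parents
#'   may be concatenated).
#' @return A list with `total`, `n_progeny` and `mean_per_progeny`
#'   (= total / number of distinct progeny).
#' @export
summarize_crossovers <- function(counts) {
  total <- sum(counts$n_crossovers)
  n <- length(unique(counts$progeny_id))
  list(total = total, n_progeny = n,
       mean_per_progeny = mean_events_per_progeny(total, n))
}
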