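#' Compare two marker maps for shared markers and order concordance
#'
#' Counts markers mapped in both of two maps, flags markers assigned to
#' different chromosomes, and measures order concordance: the fraction of
#' within-chromosome pairs of shared markers whose relative genetic order
#' agrees between the maps (pairs tied in both maps count as concordant).
#'
#' @param a,b Marker maps: either [genotype_matrix()] objects or data.frames
#'   with columns `marker_id`, `chromosome`, `genetic_pos`.
#' @return A list of class `map_comparison`: `n_shared`,
#'   `shared_per_chromosome` (data.frame, chromosome label taken from `a`),
#'   `discordant_chromosome` (count of shared markers on different
#'   chromosomes), `order_concordance` (fraction in \[0, 1\], `NA` when no
#'   comparable pair exists) and `n_pairs` (pairs compared).
#' @export
compare_maps <- function(a, b) {
  la <- if (inherits(a, "genotype_matrix")) a$loci else as.data.frame(a)
  lb <- if (inherits(b, "genotype_matrix")) b$loci else as.data.frame(b)
  shared <- intersect(la$marker_id, lb$marker_id)
  ia <- match(shared, la$marker_id)
  ib <- match(shared, lb$marker_id)

  if (!length(shared)) {
    out <- list(n_shared = 0L,
                shared_per_chromosome =
                  data.frame(chromosome = character(0), n = integer(0)),
                discordant_chromosome = 0L,
                order_concordance = NA_real_, n_pairs = 0L)
    class(out) <- "map_comparison"
    return(out)
  }

  same_chr <- la$chromosome[ia] == lb$chromosome[ib]
  per_chr <- as.data.frame(table(chromosome = la$chromosome[ia]),
                           stringsAsFactors = FALSE)
  names(per_chr) <- c("chromosome", "n")

  conc <- 0L
  total <- 0L
  for (chr in unique(la$chromosome[ia][same_chr])) {
    k <- which(same_chr & la$chromosome[ia] == chr)
    if (length(k) < 2) next
    pa <- la$genetic_pos[ia[k]]
    pb <- lb$genetic_pos[ib[k]]
    prs <- utils::combn(length(k), 2)
    sa <- sign(pa[prs[1, ]] - pa[prs[2, ]])
    sb <- sign(pb[prs[1, ]] - pb[prs[2, ]])
    conc <- conc + sum(sa == sb)
    total <- total + ncol(prs)
  }

  out <- list(n_shared = length(shared),
              shared_per_chromosome = per_chr,
              discordant_chromosome = sum(!same_chr),
              order_concordance = if (total > 0) conc / total else NA_real_,
              n_pairs = total)
  class(out) <- "map_comparison"
  out
}

#' @export
print.map_comparison <- function(x, ...) {
  cat("map_comparison:", x$n_shared, "shared markers,",
      x$discordant_chromosome, "on discordant chromosomes\n")
  if (!is.na(x$order_concordance))
    cat(sprintf("  order concordance: %.1f%% of %d pairs\n",
                100 * x$order_concordance, x$n_pairs))
  invisible(x)
}
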