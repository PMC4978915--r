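#' @keywords internal
"_PACKAGE"

## missing-data sentinel used in all genotype files
MISSING_CODE <- "--"

## seg_class labels used internally and the JoinMap-style codes used on disk
SEG_CLASSES <- c("maternal", "paternal", "biparental")
SEG_CLASS_FILE_CODES <- c(maternal = "<lmxll>", paternal = "<nnxnp>",
                          biparental = "<hkxhk>")

## legal genotype codes per segregation class
legal_codes <- function(seg_class) {
  switch(seg_class,
         maternal   = c("ll", "lm"),
         paternal   = c("nn", "np"),
         biparental = c("hh", "hk", "kk"),
         stop("unknown seg_class: ", seg_class))
}

seg_class_from_file <- function(x) {
  idx <- match(x, SEG_CLASS_FILE_CODES)
  if (anyNA(idx)) {
    idx2 <- match(x, names(SEG_CLASS_FILE_CODES))
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  if (anyNA(idx))
    stop("unknown segregation class code(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  names(SEG_CLASS_FILE_CODES)[idx]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent decrease between two counts
#'
#' Report-arithmetic helper: the percentage by which `after` falls short of
#' `before`, e.g. the loss in unique bin positions when distorted markers are
#' excluded from a map.
#'
#' @param before,after Non-negative counts, `before > 0`.
#' @return `100 * (before - after) / before`.
#' @export
#' @examples
#' percent_decrease(414, 396)
percent_decrease <- function(before, after) {
  stopifnot(is.numeric(before), is.numeric(after), all(before > 0))
  100 * (before - after) / before
}

#' Mean number of events per progeny individual
#'
#' Report-arithmetic helper: divides a population total (e.g. recombination
#' events counted across all progeny) by the number of progeny.
#'
#' @param total Total event count.
#' @param n_progeny Number of progeny individuals (> 0).
#' @return `total / n_progeny`.
#' @export
#' @examples
#' mean_events_per_progeny(756, 96)
mean_events_per_progeny <- function(total, n_progeny) {
  stopifnot(is.numeric(total), is.numeric(n_progeny), all(n_progeny > 0))
  total / n_progeny
}

## upper-tail chi-square p-value, vectorised
chisq_upper_tail <- function(chi2, df) {
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

## stable map ordering: chromosome, then cM, then Mb, then marker_id
map_order <- function(loci) {
  mb <- loci$physical_pos
  mb[is.na(mb)] <- Inf
  order(loci$chromosome, loci$genetic_pos, mb, loci$marker_id,
        method = "radix")
}
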