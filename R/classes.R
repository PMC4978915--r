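#' Construct a genotype matrix for a CP-type full-sib family
#'
#' The central container of the package: an ordered marker map plus a
#' progeny-by-marker table of JoinMap-style genotype codes. Markers are
#' always kept sorted by (chromosome, genetic position, physical position,
#' marker id).
#'
#' @param loci A data.frame with one row per marker and columns
#'   `marker_id` (unique character), `chromosome` (character),
#'   `genetic_pos` (cM, non-negative), `physical_pos` (Mb, `NA` when the
#'   marker is unanchored), `seg_class` (`"maternal"`, `"paternal"` or
#'   `"biparental"`), `phase_maternal` and `phase_paternal` (0, 1 or `NA`).
#'   A phase must be present exactly when the corresponding parent is
#'   heterozygous at the locus: maternal phase for maternal and biparental
#'   markers, paternal phase for paternal and biparental markers.
#' @param codes Character matrix, progeny in rows, markers in columns
#'   (column names = `marker_id`). Legal codes are `ll`/`lm` for maternal
#'   markers, `nn`/`np` for paternal markers, `hh`/`hk`/`kk` for biparental
#'   markers, plus the missing sentinel `"--"`.
#' @param progeny_ids Character vector of progeny identifiers; defaults to
#'   the row names of `codes` or `ind001`... when absent.
#' @return An object of class `genotype_matrix` with elements `loci`,
#'   `codes` and `progeny_ids`.
#' @seealso [read_genotypes()], [simulate_population()]
#' @export
genotype_matrix <- function(loci, codes, progeny_ids = NULL) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("marker_id", "chromosome", "genetic_pos", "physical_pos",
                "seg_class", "phase_maternal", "phase_paternal")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols))
    stop("loci is missing column(s): ", paste(missing_cols, collapse = ", "))
  loci$marker_id <- as.character(loci$marker_id)
  loci$chromosome <- as.character(loci$chromosome)
  if (anyDuplicated(loci$marker_id))
    stop("duplicate marker_id: ",
         paste(unique(loci$marker_id[duplicated(loci$marker_id)]),
               collapse = ", "))
  if (any(loci$genetic_pos < 0)) stop("genetic_pos must be non-negative")
  if (!all(loci$seg_class %in% SEG_CLASSES))
    stop("seg_class must be one of: ", paste(SEG_CLASSES, collapse = ", "))

  mat_het <- loci$seg_class %in% c("maternal", "biparental")
  pat_het <- loci$seg_class %in% c("paternal", "biparental")
  if (any(is.na(loci$phase_maternal[mat_het])))
    stop("phase_maternal required for maternal/biparental markers")
  if (any(!is.na(loci$phase_maternal[!mat_het])))
    stop("phase_maternal must be absent when the mother is homozygous")
  if (any(is.na(loci$phase_paternal[pat_het])))
    stop("phase_paternal required for paternal/biparental markers")
  if (any(!is.na(loci$phase_paternal[!pat_het])))
    stop("phase_paternal must be absent when the father is homozygous")
  ph <- c(loci$phase_maternal, loci$phase_paternal)
  if (!all(ph %in% c(0L, 1L, NA)))
    stop("phases must be 0, 1 or NA")

  codes <- as.matrix(codes)
  if (ncol(codes) != nrow(loci))
    stop("codes has ", ncol(codes), " columns but loci has ", nrow(loci),
         " markers")
  if (is.null(colnames(codes))) colnames(codes) <- loci$marker_id
  if (!identical(colnames(codes), loci$marker_id)) {
    if (!setequal(colnames(codes), loci$marker_id))
      stop("codes column names do not match loci marker_ids")
    codes <- codes[, loci$marker_id, drop = FALSE]
  }
  if (is.null(progeny_ids))
    progeny_ids <- rownames(codes) %||%
      sprintf("ind%03d", seq_len(nrow(codes)))
  progeny_ids <- as.character(progeny_ids)
  if (length(progeny_ids) != nrow(codes))
    stop("progeny_ids length does not match codes rows")
  rownames(codes) <- progeny_ids

  for (j in seq_len(nrow(loci))) {
    ok <- codes[, j] %in% c(legal_codes(loci$seg_class[j]), MISSING_CODE)
    if (!all(ok))
      stop("illegal code '", codes[which(!ok)[1], j], "' for ",
           loci$seg_class[j], " marker '", loci$marker_id[j],
           "' (progeny ", progeny_ids[which(!ok)[1]], ")")
  }

  ord <- map_order(loci)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  codes <- codes[, ord, drop = FALSE]

  structure(list(loci = loci, codes = codes, progeny_ids = progeny_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cls <- table(factor(x$loci$seg_class, levels = SEG_CLASSES))
  cat("genotype_matrix:", length(x$progeny_ids), "progeny x",
      nrow(x$loci), "markers on",
      length(unique(x$loci$chromosome)), "chromosome(s)\n")
  cat(sprintf("  maternal <lmxll>: %d, paternal <nnxnp>: %d, biparental <hkxhk>: %d\n",
              cls[["maternal"]], cls[["paternal"]], cls[["biparental"]]))
  miss <- sum(x$codes == MISSING_CODE)
  if (miss > 0) cat("  missing codes:", miss, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

## number of markers / progeny helpers (internal)
n_markers <- function(g) nrow(g$loci)
n_progeny <- function(g) length(g$progeny_ids)

## subset markers by logical/integer index, keeping order
subset_markers <- function(g, idx) {
  genotype_matrix(g$loci[idx, , drop = FALSE],
                  g$codes[, idx, drop = FALSE],
                  g$progeny_ids)
}
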