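## Plain-TSV dialect close to the JoinMap CP ecosystem:
##   genotype file: marker_id, seg_class, phase, <one column per progeny>
##   map file:      marker_id, chromosome, genetic_pos, physical_pos, phase
## phase is a two-character string <maternal><paternal> with "-" for absent,
## e.g. "0-" (maternal marker), "-1" (paternal), "01" (biparental).

phase_to_string <- function(pm, pp) {
  paste0(ifelse(is.na(pm), "-", as.character(pm)),
         ifelse(is.na(pp), "-", as.character(pp)))
}

phase_from_string <- function(s) {
  if (any(nchar(s) != 2L))
    stop("phase strings must have exactly two characters, e.g. '0-'")
  one <- function(ch) {
    out <- suppressWarnings(as.integer(ch))
    bad <- !(ch %in% c("0", "1", "-"))
    if (any(bad)) stop("illegal phase character: ", ch[bad][1])
    out
  }
  list(maternal = one(substr(s, 1, 1)), paternal = one(substr(s, 2, 2)))
}

#' Read a genotype table and marker map into a genotype matrix
#'
#' Reads the two tab-separated files describing an F1 full-sib family:
#' a genotype file (one row per marker: `marker_id`, `seg_class`, `phase`,
#' then one genotype code column per progeny) and a map file (one row per
#' marker: `marker_id`, `chromosome`, `genetic_pos` in cM, `physical_pos`
#' in Mb or `NA` when unanchored, `phase`). Both files must describe the
#' same set of markers.
#'
#' Markers containing missing codes (`"--"`) are dropped by default, the
#' policy used when the source data were cleaned before mapping; set
#' `drop_missing = FALSE` to retain them.
#'
#' @param genotype_path,map_path Paths to the two TSV files.
#' @param drop_missing Drop markers with any missing genotype code
#'   (default `TRUE`). Dropped markers are reported via `message()`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(genotype_path, map_path, drop_missing = TRUE) {
  for (p in c(genotype_path, map_path))
    if (!file.exists(p)) stop("file not found: ", p)
  geno <- utils::read.delim(genotype_path, check.names = FALSE,
                            colClasses = "character")
  map <- utils::read.delim(map_path, check.names = FALSE,
                           colClasses = "character")
  need_g <- c("marker_id", "seg_class", "phase")
  if (!all(need_g %in% names(geno)))
    stop("genotype file must have columns: ",
         paste(need_g, collapse = ", "))
  need_m <- c("marker_id", "chromosome", "genetic_pos", "physical_pos",
              "phase")
  if (!all(need_m %in% names(map)))
    stop("map file must have columns: ", paste(need_m, collapse = ", "))

  if (anyDuplicated(geno$marker_id))
    stop("duplicate marker_id in genotype file: ",
         geno$marker_id[duplicated(geno$marker_id)][1])
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker_id in map file: ",
         map$marker_id[duplicated(map$marker_id)][1])
  only_g <- setdiff(geno$marker_id, map$marker_id)
  only_m <- setdiff(map$marker_id, geno$marker_id)
  if (length(only_g) || length(only_m))
    stop("markers present in only one file: ",
         paste(utils::head(c(only_g, only_m), 5), collapse = ", "))

  map <- map[match(geno$marker_id, map$marker_id), ]
  ph_g <- phase_from_string(geno$phase)
  ph_m <- phase_from_string(as.character(map$phase))
  if (!identical(ph_g$maternal, ph_m$maternal) ||
      !identical(ph_g$paternal, ph_m$paternal))
    stop("phase strings disagree between genotype and map files")

  prog_cols <- setdiff(names(geno), need_g)
  if (!length(prog_cols)) stop("genotype file has no progeny columns")
  codes <- t(as.matrix(geno[, prog_cols, drop = FALSE]))
  colnames(codes) <- geno$marker_id
  rownames(codes) <- prog_cols

  seg <- seg_class_from_file(geno$seg_class)
  ## name the offending cell before genotype_matrix() would: row = marker
  for (j in seq_along(seg)) {
    ok <- codes[, j] %in% c(legal_codes(seg[j]), MISSING_CODE)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("illegal code '", codes[i, j], "' for ",
           SEG_CLASS_FILE_CODES[[seg[j]]], " marker '", geno$marker_id[j],
           "' in progeny column '", prog_cols[i], "'")
    }
  }

  loci <- data.frame(marker_id = geno$marker_id,
                     chromosome = as.character(map$chromosome),
                     genetic_pos = as.numeric(map$genetic_pos),
                     physical_pos = as.numeric(map$physical_pos),
                     seg_class = seg,
                     phase_maternal = ph_g$maternal,
                     phase_paternal = ph_g$paternal,
                     stringsAsFactors = FALSE)
  g <- genotype_matrix(loci, codes, prog_cols)

  if (drop_missing) {
    has_missing <- colSums(g$codes == MISSING_CODE) > 0
    if (any(has_missing)) {
      message("dropping ", sum(has_missing),
              " marker(s) with missing codes: ",
              paste(utils::head(g$loci$marker_id[has_missing], 5),
                    collapse = ", "),
              if (sum(has_missing) > 5) ", ..." else "")
      g <- subset_markers(g, !has_missing)
    }
  }
  g
}

#' Write a genotype matrix to genotype and map TSV files
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(g, ...))`
#' reproduces `g` exactly (markers are stored in map order).
#'
#' @param g A [genotype_matrix()].
#' @param genotype_path,map_path Output paths.
#' @return `g`, invisibly.
#' @export
write_genotypes <- function(g, genotype_path, map_path) {
  stopifnot(inherits(g, "genotype_matrix"))
  phase <- phase_to_string(g$loci$phase_maternal, g$loci$phase_paternal)
  gt <- data.frame(marker_id = g$loci$marker_id,
                   seg_class = unname(SEG_CLASS_FILE_CODES[g$loci$seg_class]),
                   phase = phase,
                   stringsAsFactors = FALSE, check.names = FALSE)
  gt <- cbind(gt, as.data.frame(t(g$codes), check.names = FALSE))
  utils::write.table(gt, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mp <- data.frame(marker_id = g$loci$marker_id,
                   chromosome = g$loci$chromosome,
                   genetic_pos = g$loci$genetic_pos,
                   physical_pos = g$loci$physical_pos,
                   phase = phase,
                   stringsAsFactors = FALSE)
  utils::write.table(mp, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(g)
}
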