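#' Configuration for segregation-distortion-region calling
#'
#' An SDR is a cluster of more than five (i.e. at least `min_markers = 6`)
#' closely linked markers, all significantly distorted at `alpha`, where
#' consecutive significant members are no more than `max_gap_cM` apart.
#' The alternative reading of "clustered at a minimal distance of 5 cM" —
#' a minimum total genetic span — is available via `min_span_cM` and off
#' by default.
#'
#' @param alpha Significance threshold for member loci (default 0.001).
#' @param min_markers Minimum cluster size (default 6, >= 2).
#' @param max_gap_cM Maximum gap between consecutive significant members
#'   (default 5 cM).
#' @param min_span_cM Optional minimum genetic span of a cluster; `NULL`
#'   (default) disables the span rule.
#' @return An `sdr_config` list.
#' @export
sdr_config <- function(alpha = 0.001, min_markers = 6, max_gap_cM = 5,
                       min_span_cM = NULL) {
  stopifnot(alpha > 0, alpha < 1, min_markers >= 2, max_gap_cM > 0)
  structure(list(alpha = alpha, min_markers = as.integer(min_markers),
                 max_gap_cM = max_gap_cM, min_span_cM = min_span_cM),
            class = "sdr_config")
}

#' Call segregation distortion regions from per-locus test results
#'
#' Within each chromosome and parent stream (maternal, paternal and
#' biparental loci are called separately), consecutive significant loci
#' (`p < alpha`) are chained while the gap between them is at most
#' `max_gap_cM`; chains with at least `min_markers` members become SDRs.
#' Non-significant loci interleaved within a chain do not break it and are
#' not counted as members. The peak of an SDR is its member with the
#' largest `-log10(p)` (first such member on ties).
#'
#' @param results A data.frame from [test_distortion()], sorted by
#'   (chromosome, genetic position) — the order [test_distortion()]
#'   emits. Unsorted input is an error.
#' @param config An [sdr_config()].
#' @return A data.frame with one row per SDR: `chromosome`, `parent`
#'   (segregation stream), `start_cM`/`end_cM`, `start_Mb`/`end_Mb` (`NA`
#'   when any member is unanchored), `n_members`, `peak_marker`,
#'   `peak_cM`, `peak_Mb`, `peak_neg_log10_p`, `peak_ratio` and a
#'   list-column `members` of marker ids. Zero rows when nothing is called.
#' @export
call_sdrs <- function(results, config = sdr_config()) {
  req <- c("marker_id", "chromosome", "genetic_pos", "physical_pos",
           "seg_class", "p_value", "neg_log10_p", "distortion_ratio")
  if (!all(req %in% names(results)))
    stop("results must come from test_distortion()")
  for (chr in unique(results$chromosome))
    if (is.unsorted(results$genetic_pos[results$chromosome == chr]))
      stop("results are not sorted by genetic position within chromosome ",
           chr)

  empty <- data.frame(chromosome = character(0), parent = character(0),
                      start_cM = numeric(0), end_cM = numeric(0),
                      start_Mb = numeric(0), end_Mb = numeric(0),
                      n_members = integer(0), peak_marker = character(0),
                      peak_cM = numeric(0), peak_Mb = numeric(0),
                      peak_neg_log10_p = numeric(0),
                      peak_ratio = numeric(0), stringsAsFactors = FALSE)
  empty$members <- list()

  out <- list()
  for (chr in unique(results$chromosome)) {
    for (stream in intersect(SEG_CLASSES, results$seg_class)) {
      sig <- results[results$chromosome == chr &
                       results$seg_class == stream &
                       results$p_value < config$alpha, , drop = FALSE]
      if (nrow(sig) < config$min_markers) next
      gap <- diff(sig$genetic_pos)
      chain_id <- cumsum(c(1, gap > config$max_gap_cM))
      for (id in unique(chain_id)) {
        mem <- sig[chain_id == id, , drop = FALSE]
        if (nrow(mem) < config$min_markers) next
        span <- max(mem$genetic_pos) - min(mem$genetic_pos)
        if (!is.null(config$min_span_cM) && span < config$min_span_cM)
          next
        peak <- which.max(mem$neg_log10_p)
        anchored <- !anyNA(mem$physical_pos)
        row <- data.frame(chromosome = chr, parent = stream,
                          start_cM = min(mem$genetic_pos),
                          end_cM = max(mem$genetic_pos),
                          start_Mb = if (anchored) min(mem$physical_pos)
                                     else NA_real_,
                          end_Mb = if (anchored) max(mem$physical_pos)
                                   else NA_real_,
                          n_members = nrow(mem),
                          peak_marker = mem$marker_id[peak],
                          peak_cM = mem$genetic_pos[peak],
                          peak_Mb = mem$physical_pos[peak],
                          peak_neg_log10_p = mem$neg_log10_p[peak],
                          peak_ratio = mem$distortion_ratio[peak],
                          stringsAsFactors = FALSE)
        row$members <- list(mem$marker_id)
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flat report table for called SDRs
#'
#' One row per SDR with its genetic and physical extent formatted in the
#' conventional `start-end` style, the number of member loci, and the
#' position and distortion ratio of the peak locus.
#'
#' @param sdrs Output of [call_sdrs()].
#' @return A data.frame (zero rows for empty input) without list-columns,
#'   suitable for writing as TSV.
#' @export
sdr_report <- function(sdrs) {
  if (nrow(sdrs) == 0)
    return(data.frame(chromosome = character(0), parent = character(0),
                      range_cM = character(0), range_Mb = character(0),
                      n_members = integer(0), peak_marker = character(0),
                      peak_cM = numeric(0), peak_ratio = character(0),
                      stringsAsFactors = FALSE))
  fmt <- function(a, b) ifelse(is.na(a), NA_character_,
                               sprintf("%.1f-%.1f", a, b))
  data.frame(chromosome = sdrs$chromosome, parent = sdrs$parent,
             range_cM = fmt(sdrs$start_cM, sdrs$end_cM),
             range_Mb = fmt(sdrs$start_Mb, sdrs$end_Mb),
             n_members = sdrs$n_members,
             peak_marker = sdrs$peak_marker, peak_cM = sdrs$peak_cM,
             peak_ratio = ifelse(is.finite(sdrs$peak_ratio),
                                 sprintf("1:%.1f", sdrs$peak_ratio),
                                 "1:Inf"),
             stringsAsFactors = FALSE)
}
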