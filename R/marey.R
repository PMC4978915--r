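## Longest non-decreasing subsequence, leftmost among maximum-cardinality
## solutions (ties broken to keep earlier positions). O(n^2), fine at
## per-chromosome marker counts.
lnds_keep <- function(v) {
  n <- length(v)
  if (n == 0) return(integer(0))
  len_from <- integer(n)   # longest non-decreasing run starting at i
  for (i in n:1) {
    best <- 0L
    for (j in seq_len(n - i)) {
      jj <- i + j
      if (v[jj] >= v[i] && len_from[jj] > best) best <- len_from[jj]
    }
    len_from[i] <- best + 1L
  }
  total <- max(len_from)
  keep <- integer(total)
  last_val <- -Inf
  need <- total
  i <- 1L
  while (need > 0L) {
    while (!(v[i] >= last_val && len_from[i] == need)) i <- i + 1L
    keep[total - need + 1L] <- i
    last_val <- v[i]
    need <- need - 1L
    i <- i + 1L
  }
  keep
}

#' Build a Marey map for one chromosome, excluding discordant loci
#'
#' A Marey map plots genetic position (cM) against physical position (Mb);
#' its slope is the local recombination rate. Loci without a physical
#' anchor are excluded (reason `"unanchored"`), and loci breaking the
#' joint increasing order of the two coordinate systems are excluded as
#' outliers (reason `"non-monotone"`): the retained set is a
#' maximum-cardinality subset whose cM sequence is non-decreasing when
#' sorted by Mb, ties broken toward earlier Mb.
#'
#' @param loci Data.frame of one chromosome's markers with columns
#'   `marker_id`, `chromosome`, `genetic_pos`, `physical_pos`.
#' @return A `marey_map`: `chromosome`, `points` (data.frame of retained
#'   `marker_id`, `physical_pos`, `genetic_pos`, sorted by Mb) and
#'   `excluded` (data.frame of `marker_id`, `reason`).
#' @export
filter_marey_outliers <- function(loci) {
  loci <- as.data.frame(loci)
  chr <- unique(loci$chromosome)
  if (length(chr) != 1)
    stop("filter_marey_outliers expects loci of a single chromosome")
  unanchored <- is.na(loci$physical_pos)
  excl <- data.frame(marker_id = loci$marker_id[unanchored],
                     reason = rep("unanchored", sum(unanchored)),
                     stringsAsFactors = FALSE)
  anchored <- loci[!unanchored, , drop = FALSE]
  if (nrow(anchored) < 2)
    stop("chromosome ", chr, " has fewer than 2 physically anchored loci")
  ord <- order(anchored$physical_pos, anchored$genetic_pos,
               anchored$marker_id)
  anchored <- anchored[ord, , drop = FALSE]
  keep <- lnds_keep(anchored$genetic_pos)
  out_idx <- setdiff(seq_len(nrow(anchored)), keep)
  excl <- rbind(excl,
                data.frame(marker_id = anchored$marker_id[out_idx],
                           reason = rep("non-monotone", length(out_idx)),
                           stringsAsFactors = FALSE))
  pts <- anchored[keep, c("marker_id", "physical_pos", "genetic_pos")]
  rownames(pts) <- NULL
  structure(list(chromosome = chr, points = pts, excluded = excl),
            class = "marey_map")
}

#' Fit a smooth monotone interpolant to a Marey map
#'
#' Monotonicity-constrained cubic spline interpolation (Hyman filtering,
#' via `stats::splinefun(method = "hyman")`): smooth, non-decreasing,
#' passing through every point, with a closed-form derivative. A natural
#' cubic spline is not monotone in general, which is why the filtered
#' scheme is used for recombination-rate estimation. (The Fritsch-Carlson
#' `monoH.FC` variant was rejected: R's implementation can produce small
#' non-monotone wiggles.) Points sharing a physical position are collapsed
#' to their mean genetic position with a warning.
#'
#' @param m A `marey_map` from [filter_marey_outliers()].
#' @return A `marey_interpolant` with elements `chromosome`, `fun`
#'   (vectorised cM at Mb), `deriv` (vectorised cM/Mb at Mb), `range_Mb`
#'   and the fitted `points`.
#' @export
fit_monotone_interpolant <- function(m) {
  stopifnot(inherits(m, "marey_map"))
  pts <- m$points
  if (nrow(pts) < 2) stop("need at least 2 points to interpolate")
  if (anyDuplicated(pts$physical_pos)) {
    warning("duplicate physical positions collapsed to mean genetic position")
    agg <- stats::aggregate(genetic_pos ~ physical_pos, data = pts,
                            FUN = mean)
    pts <- data.frame(marker_id = NA_character_,
                      physical_pos = agg$physical_pos,
                      genetic_pos = agg$genetic_pos)
  }
  f <- stats::splinefun(pts$physical_pos, pts$genetic_pos,
                        method = "hyman")
  structure(list(chromosome = m$chromosome,
                 fun = function(x) f(x),
                 deriv = function(x) f(x, deriv = 1),
                 range_Mb = range(pts$physical_pos),
                 points = pts),
            class = "marey_interpolant")
}

#' Local recombination rates along a chromosome
#'
#' Evaluates the derivative of the fitted Marey interpolant on a grid of
#' physical positions. The monotone fit makes the derivative non-negative;
#' tiny negative numerical values are clamped to 0 as a guard.
#'
#' @param interp A `marey_interpolant` from [fit_monotone_interpolant()].
#' @param grid_Mb Physical evaluation positions; defaults to a regular
#'   grid over the fitted range at `spacing` Mb (endpoints included).
#' @param spacing Default grid spacing in Mb (0.5).
#' @return A `rate_profile`: `chromosome`, `grid_Mb`, `fitted_cM`,
#'   `rate` (cM/Mb at each grid point) and `chromosome_avg`
#'   (genetic span / physical span).
#' @export
local_rates <- function(interp, grid_Mb = NULL, spacing = 0.5) {
  stopifnot(inherits(interp, "marey_interpolant"))
  if (is.null(grid_Mb)) {
    r <- interp$range_Mb
    grid_Mb <- unique(c(seq(r[1], r[2], by = spacing), r[2]))
  }
  rate <- pmax(0, interp$deriv(grid_Mb))
  span_cM <- diff(range(interp$points$genetic_pos))
  span_Mb <- diff(interp$range_Mb)
  structure(list(chromosome = interp$chromosome, grid_Mb = grid_Mb,
                 fitted_cM = interp$fun(grid_Mb), rate = rate,
                 chromosome_avg = span_cM / span_Mb),
            class = "rate_profile")
}

#' Average recombination rates per chromosome and genome-wide
#'
#' Chromosome average = genetic span of mapped loci divided by their
#' physical span; the genome-wide average divides the total map length by
#' the total physical length (sum of spans over chromosomes), following
#' the convention that physical length is last minus first anchored Mb
#' per chromosome.
#'
#' @param x Either a data.frame of mapped loci (columns `chromosome`,
#'   `genetic_pos`, `physical_pos`; unanchored loci are ignored for the
#'   physical span) or a pre-aggregated data.frame with columns
#'   `chromosome`, `cM_span`, `Mb_span` (e.g. printed map-length tables).
#' @return A data.frame with one row per chromosome plus a final
#'   `"genome"` row: `chromosome`, `cM_span`, `Mb_span`, `rate` (cM/Mb).
#' @export
#' @examples
#' average_rates(data.frame(chromosome = "all", cM_span = 813.2,
#'                          Mb_span = 715.8))
average_rates <- function(x) {
  x <- as.data.frame(x)
  if (all(c("cM_span", "Mb_span") %in% names(x))) {
    spans <- x[, c("chromosome", "cM_span", "Mb_span")]
  } else {
    stopifnot(all(c("chromosome", "genetic_pos", "physical_pos") %in%
                    names(x)))
    spans <- do.call(rbind, lapply(unique(x$chromosome), function(chr) {
      sub <- x[x$chromosome == chr, ]
      anch <- sub$physical_pos[!is.na(sub$physical_pos)]
      data.frame(chromosome = chr,
                 cM_span = diff(range(sub$genetic_pos)),
                 Mb_span = if (length(anch) >= 2) diff(range(anch))
                           else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  if (any(is.na(spans$Mb_span)) || any(spans$Mb_span == 0))
    stop("zero or undefined physical span for chromosome(s): ",
         paste(spans$chromosome[is.na(spans$Mb_span) |
                                  spans$Mb_span == 0], collapse = ", "))
  spans$rate <- spans$cM_span / spans$Mb_span
  genome <- data.frame(chromosome = "genome",
                       cM_span = sum(spans$cM_span),
                       Mb_span = sum(spans$Mb_span),
                       stringsAsFactors = FALSE)
  genome$rate <- genome$cM_span / genome$Mb_span
  out <- rbind(spans, genome)
  rownames(out) <- NULL
  out
}

#' Regression of distortion significance on local recombination rate
#'
#' Ordinary least squares of `-log10(p)` of the per-locus distortion test
#' on the local recombination rate interpolated at each locus's physical
#' position, for one chromosome.
#'
#' @param interp A `marey_interpolant` for the chromosome.
#' @param results Rows of [test_distortion()] output for the same
#'   chromosome (loci without a physical position are skipped).
#' @return A list with `chromosome`, `n`, `r_squared`, `p_value`,
#'   `slope_sign` (-1, 0 or 1) and `note`. With fewer than 3 usable loci
#'   no fit is attempted (`NA` fields); with a constant predictor
#'   `r_squared` is reported as 0 with an explanatory note.
#' @export
rate_vs_distortion <- function(interp, results) {
  stopifnot(inherits(interp, "marey_interpolant"))
  sub <- results[!is.na(results$physical_pos) &
                   results$chromosome == interp$chromosome, , drop = FALSE]
  base <- list(chromosome = interp$chromosome, n = nrow(sub),
               r_squared = NA_real_, p_value = NA_real_,
               slope_sign = NA_integer_, note = NA_character_)
  if (nrow(sub) < 3) {
    base$note <- "fewer than 3 loci; no fit"
    return(base)
  }
  rate <- pmax(0, interp$deriv(sub$physical_pos))
  y <- sub$neg_log10_p
  if (stats::var(rate) == 0) {
    base$r_squared <- 0
    base$slope_sign <- 0L
    base$note <- "constant predictor: rate has no variance"
    return(base)
  }
  fit <- stats::lm(y ~ rate)
  sm <- summary(fit)
  slope <- stats::coef(fit)[["rate"]]
  pv <- if (nrow(sm$coefficients) >= 2) sm$coefficients["rate", 4]
  else NA_real_
  list(chromosome = interp$chromosome, n = nrow(sub),
       r_squared = sm$r.squared, p_value = pv,
       slope_sign = as.integer(sign(slope)), note = NA_character_)
}
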