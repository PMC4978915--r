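#' Collapse markers with identical genotype columns into bins
#'
#' Markers carrying the same genotype pattern across the whole population
#' are redundant for mapping and are collapsed to unique "bin positions".
#' Binning is done within chromosomes: a bin is one genetic position. The
#' representative of each bin is its member with the smallest genetic
#' position, ties broken lexicographically by marker id.
#'
#' With `max_missing_mismatch = 0` (the default) two columns must be
#' identical, missing sentinels included. With a positive value, positions
#' where exactly one of the two columns is missing are tolerated up to the
#' given count, and positions observed in both must agree; markers are then
#' greedily attached (in map order) to the first bin whose representative
#' is compatible, because compatibility is not transitive.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing_mismatch Number of tolerated positions where one
#'   column is missing and the other is not (default 0 = exact matching).
#' @return A list with `matrix` (the collapsed [genotype_matrix()], one
#'   representative per bin) and `bins` (a data.frame with `bin_id`,
#'   `representative`, `n_members` and a list-column `members`).
#' @export
collapse_bins <- function(g, max_missing_mismatch = 0) {
  stopifnot(inherits(g, "genotype_matrix"), max_missing_mismatch >= 0)
  loci <- g$loci
  codes <- g$codes
  bin_of <- integer(nrow(loci))
  n_bins <- 0L
  rep_idx <- integer(0)

  for (chr in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == chr)   # already in map order
    if (max_missing_mismatch == 0) {
      key <- apply(codes[, idx, drop = FALSE], 2, paste, collapse = "\r")
      grp <- match(key, unique(key))
      for (b in unique(grp)) {
        n_bins <- n_bins + 1L
        members <- idx[grp == b]
        bin_of[members] <- n_bins
        rep_idx[n_bins] <- pick_representative(loci, members)
      }
    } else {
      reps <- integer(0)  # representative column index per open bin (local)
      for (i in idx) {
        placed <- FALSE
        for (b in seq_along(reps)) {
          if (columns_compatible(codes[, reps[b]], codes[, i],
                                 max_missing_mismatch)) {
            bin_of[i] <- n_bins - length(reps) + b
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          reps <- c(reps, i)
          n_bins <- n_bins + 1L
          bin_of[i] <- n_bins
        }
      }
      for (b in unique(bin_of[idx])) {
        members <- idx[bin_of[idx] == b]
        rep_idx[b] <- pick_representative(loci, members)
      }
    }
  }

  bins <- data.frame(bin_id = sprintf("bin%04d", seq_len(n_bins)),
                     representative = loci$marker_id[rep_idx],
                     n_members = as.integer(table(bin_of)),
                     stringsAsFactors = FALSE)
  bins$members <- split(loci$marker_id, bin_of)
  collapsed <- subset_markers(g, sort(rep_idx))
  list(matrix = collapsed, bins = bins)
}

## member with smallest genetic_pos, tie-broken by marker_id
pick_representative <- function(loci, members) {
  members[order(loci$genetic_pos[members], loci$marker_id[members])][1]
}

columns_compatible <- function(a, b, max_missing_mismatch) {
  ma <- a == MISSING_CODE
  mb <- b == MISSING_CODE
  if (any(a[!ma & !mb] != b[!ma & !mb])) return(FALSE)
  sum(xor(ma, mb)) <= max_missing_mismatch
}
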