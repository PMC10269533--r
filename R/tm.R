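# Transmembrane geometry: a hydropathy fallback predictor (used only when
# no TM-segment file is supplied), surface-area scoring of TM residues,
# and the raft-propensity flag at the 172 A^2/residue threshold.

# Kyte-Doolittle hydropathy; X (unknown) contributes 0.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

#' Transmembrane analysis parameters
#'
#' @param hydropathy_window Odd sliding-window width in residues for the
#'   fallback predictor (default 19, the classic membrane-helix window).
#' @param hydropathy_threshold Minimum mean Kyte-Doolittle hydropathy at a
#'   window center for it to seed a TM region (default 1.6).
#' @param min_region_length Minimum region length in residues retained
#'   after merging (default 15).
#' @param merge_gap Regions separated by at most this many residues are
#'   merged (default 3).
#' @param raft_threshold Raft-propensity threshold on surface area per
#'   residue, in Angstrom^2 (default 172); the comparison is inclusive.
#' @return A `ttr_tm_params` list.
#' @export
tm_params <- function(hydropathy_window = 19L, hydropathy_threshold = 1.6,
                      min_region_length = 15L, merge_gap = 3L,
                      raft_threshold = 172) {
  ttr_assert(is_count(hydropathy_window, 5L) && hydropathy_window %% 2L == 1L,
             "ttr_bad_param", "hydropathy_window must be an odd count >= 5")
  ttr_assert(is.numeric(hydropathy_threshold) && is.finite(hydropathy_threshold),
             "ttr_bad_param", "hydropathy_threshold must be finite")
  ttr_assert(is_count(min_region_length, 1L), "ttr_bad_param",
             "min_region_length must be a positive count")
  ttr_assert(is_count(merge_gap, 0L), "ttr_bad_param",
             "merge_gap must be a non-negative count")
  ttr_assert(is.numeric(raft_threshold) && raft_threshold > 0, "ttr_bad_param",
             "raft_threshold must be > 0")
  structure(list(hydropathy_window = as.integer(hydropathy_window),
                 hydropathy_threshold = hydropathy_threshold,
                 min_region_length = as.integer(min_region_length),
                 merge_gap = as.integer(merge_gap),
                 raft_threshold = raft_threshold),
            class = "ttr_tm_params")
}

seq_residues <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

#' Predict transmembrane regions by windowed hydropathy
#'
#' Fallback predictor used when no TMHMM-style segment file covers a
#' protein.  The mean Kyte-Doolittle hydropathy is computed at every
#' full-window center; maximal runs of centers at or above
#' `hydropathy_threshold` are expanded to the window extent, runs separated
#' by at most `merge_gap` residues are merged, and regions shorter than
#' `min_region_length` are dropped.  Sequences shorter than the window
#' yield no regions.
#'
#' @param sequence Amino-acid string (canonical letters + `X`).
#' @param params A [tm_params()] object.
#' @return Integer matrix with columns `start`, `end` (1-based inclusive),
#'   sorted and non-overlapping; zero rows if no region is found.
#' @export
#' @examples
#' predict_tm_regions(paste0(strrep("E", 8), strrep("L", 30), strrep("K", 8)))
predict_tm_regions <- function(sequence, params = tm_params()) {
  ttr_assert(is.character(sequence) && length(sequence) == 1L &&
               nzchar(sequence), "ttr_empty_sequence",
             "sequence must be a nonempty string")
  n <- nchar(sequence)
  w <- params$hydropathy_window
  h <- w %/% 2L
  none <- cbind(start = integer(), end = integer())
  if (n < w) return(none)
  hyd <- KYTE_DOOLITTLE[seq_residues(sequence)]
  ttr_assert(!anyNA(hyd), "ttr_illegal_residue",
             "sequence contains letters outside the residue alphabet")
  cs <- c(0, cumsum(hyd))
  centers <- (h + 1L):(n - h)                      # full-window centers
  win_mean <- (cs[centers + h + 1L] - cs[centers - h]) / w
  # tolerance so windows exactly at the threshold are included regardless
  # of floating-point summation order
  hot <- win_mean >= params$hydropathy_threshold - 1e-9
  if (!any(hot)) return(none)
  r <- rle(hot)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- which(r$values)
  # expand center runs to window extent
  reg <- cbind(start = centers[starts[runs]] - h, end = centers[stops[runs]] + h)
  # merge regions separated by <= merge_gap residues
  if (nrow(reg) > 1L) {
    merged <- reg[1L, , drop = FALSE]
    for (i in 2L:nrow(reg)) {
      gap <- reg[i, "start"] - merged[nrow(merged), "end"] - 1L
      if (gap <= params$merge_gap) {
        merged[nrow(merged), "end"] <- reg[i, "end"]
      } else {
        merged <- rbind(merged, reg[i, , drop = FALSE])
      }
    }
    reg <- merged
  }
  reg <- reg[reg[, "end"] - reg[, "start"] + 1L >= params$min_region_length, ,
             drop = FALSE]
  dimnames(reg) <- list(NULL, c("start", "end"))
  reg
}

validate_regions <- function(sequence, regions) {
  ttr_assert(is.matrix(regions) && ncol(regions) == 2L, "ttr_bad_interval",
             "regions must be a two-column (start, end) matrix")
  if (nrow(regions) == 0L) return(invisible(TRUE))
  ttr_assert(all(regions[, 1L] >= 1L) && all(regions[, 2L] >= regions[, 1L]) &&
               all(regions[, 2L] <= nchar(sequence)), "ttr_bad_interval",
             "TM region outside sequence bounds")
  if (nrow(regions) > 1L) {
    o <- order(regions[, 1L])
    ttr_assert(all(regions[o, 1L][-1L] > regions[o, 2L][-nrow(regions)]),
               "ttr_overlapping_tm", "TM regions overlap")
  }
  invisible(TRUE)
}

#' Surface area per residue over transmembrane regions
#'
#' Pools the per-residue surface-area constants over every residue inside
#' any TM region of the protein (residue-weighted across regions, not an
#' unweighted mean of per-region means) and divides by the total TM
#' residue count.  Unit: Angstrom^2 per residue.
#'
#' @param sequence Amino-acid string.
#' @param regions Two-column (`start`, `end`) matrix of TM regions; must be
#'   nonempty and within sequence bounds.
#' @param table A `ttr_area_table`.
#' @return Surface area per residue (A^2/residue), a single number.
#' @export
surface_area_per_aa <- function(sequence, regions,
                                table = read_area_table()) {
  validate_regions(sequence, regions)
  ttr_assert(nrow(regions) >= 1L, "ttr_no_tm_residues",
             "no TM residues: region list is empty")
  res <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    seq_residues(substr(sequence, regions[i, 1L], regions[i, 2L]))
  }))
  a <- unclass(table)[res]
  ttr_assert(!anyNA(a), "ttr_illegal_residue",
             "TM region contains letters outside the residue alphabet")
  sum(a) / length(a)
}

#' Raft propensity of a transmembrane surface-area score
#'
#' `TRUE` iff the surface area per residue is at or below the raft
#' threshold (inclusive; default 172 A^2/residue).  Low per-residue surface
#' area correlates with partitioning into liquid-ordered (lipid-raft)
#' membrane domains.
#'
#' @param sa_per_aa Surface area per residue (A^2/residue), finite and > 0.
#' @param params A [tm_params()] object supplying `raft_threshold`.
#' @return Logical flag.
#' @export
raft_propensity <- function(sa_per_aa, params = tm_params()) {
  ttr_assert(is.numeric(sa_per_aa) && all(is.finite(sa_per_aa)) &&
               all(sa_per_aa > 0), "ttr_bad_param",
             "sa_per_aa must be finite and > 0")
  sa_per_aa <= params$raft_threshold
}

#' Transmembrane profile of one protein
#'
#' Aggregates the TM geometry the census consumes: region count, mean
#' region length, pooled surface area per residue and the raft flag.  For
#' proteins without TM regions the geometry fields are `NA` (absent), not
#' zero.
#'
#' @param sequence Amino-acid string.
#' @param regions Two-column (`start`, `end`) matrix; zero rows allowed.
#' @param params A [tm_params()] object.
#' @param table A `ttr_area_table`.
#' @return A `ttr_tm_profile` list with elements `n_regions`, `regions`,
#'   `mean_length`, `sa_per_aa`, `raft_flag`.
#' @export
tm_profile <- function(sequence, regions, params = tm_params(),
                       table = read_area_table()) {
  validate_regions(sequence, regions)
  n <- nrow(regions)
  if (n == 0L) {
    return(structure(list(n_regions = 0L, regions = regions,
                          mean_length = NA_real_, sa_per_aa = NA_real_,
                          raft_flag = NA), class = "ttr_tm_profile"))
  }
  regions <- regions[order(regions[, 1L]), , drop = FALSE]
  lens <- regions[, 2L] - regions[, 1L] + 1L
  sa <- surface_area_per_aa(sequence, regions, table)
  structure(list(n_regions = n, regions = regions, mean_length = mean(lens),
                 sa_per_aa = sa, raft_flag = raft_propensity(sa, params)),
            class = "ttr_tm_profile")
}
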