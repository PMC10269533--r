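# Per-residue surface-area constants (Angstrom^2) used to score
# transmembrane regions.  The uncalibrated scale is the theoretical
# maximum accessible surface area per residue of Tien et al. (2013);
# the calibrated table is that scale rescaled by one multiplicative
# factor so that the packaged single-TM anchor protein scores exactly
# 172 A^2/residue (see calibrate_area_table).

#' Read a per-residue surface-area table
#'
#' The table is a two-column TSV (`residue`, `area`) with one row per
#' canonical amino-acid letter.  The unknown residue `X` is assigned the
#' mean of the 20 canonical constants.
#'
#' @param path Path to the TSV; defaults to the packaged calibrated table.
#' @return A named numeric vector of length 21 (20 canonical residues plus
#'   `X`), class `ttr_area_table`, with the calibration factor (if any)
#'   in attribute `calibration_factor`.
#' @export
read_area_table <- function(path = ttr_extdata("area_table_calibrated.tsv")) {
  ttr_assert(file.exists(path), "ttr_missing_file",
             "area table not found: %s", path)
  df <- read_tsv(path)
  ttr_assert(all(c("residue", "area") %in% names(df)), "ttr_malformed_line",
             "%s: header must contain residue, area", path)
  lines <- readLines(path, n = 5L)
  fac <- NA_real_
  m <- regmatches(lines, regexpr("calibration_factor: [0-9.eE+-]+", lines))
  if (length(m)) fac <- as.numeric(sub("calibration_factor: ", "", m[[1L]]))
  area_table(setNames(df$area, df$residue), calibration_factor = fac)
}

#' Construct a surface-area table
#'
#' @param areas Named numeric vector over the 20 canonical residues
#'   (an `X` entry is added as their mean if absent).
#' @param calibration_factor Optional multiplicative factor recorded as
#'   provenance when the table was produced by [calibrate_area_table()].
#' @return A `ttr_area_table` named numeric vector of length 21.
#' @export
area_table <- function(areas, calibration_factor = NA_real_) {
  areas <- unlist(areas)
  missing <- setdiff(AA_CANONICAL, names(areas))
  ttr_assert(length(missing) == 0L, "ttr_bad_area_table",
             "area table missing residue(s): %s", paste(missing, collapse = ","))
  ttr_assert(all(is.finite(areas)) && all(areas > 0), "ttr_bad_area_table",
             "all surface-area constants must be finite and > 0")
  out <- areas[AA_CANONICAL]
  out[["X"]] <- mean(areas[AA_CANONICAL])
  extra <- setdiff(names(areas), c(AA_CANONICAL, "X"))
  ttr_assert(length(extra) == 0L, "ttr_bad_area_table",
             "unexpected residue letter(s) in area table: %s",
             paste(extra, collapse = ","))
  if ("X" %in% names(areas)) out[["X"]] <- areas[["X"]]
  structure(out, class = "ttr_area_table",
            calibration_factor = calibration_factor)
}

# Tien et al. 2013 theoretical maximum ASA (A^2); the raw, uncalibrated scale.
TIEN_MAX_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174)

#' The uncalibrated default surface-area table
#'
#' Theoretical maximum accessible surface area per residue (Tien et al.
#' 2013), in Angstrom^2.  For raft-propensity scoring use the calibrated
#' table ([read_area_table()] default) instead.
#'
#' @return A `ttr_area_table`.
#' @export
default_area_table <- function() area_table(TIEN_MAX_ASA)

#' Calibrate a surface-area table against an anchor transmembrane region
#'
#' Rescales every constant of `table` by one multiplicative factor so that
#' [surface_area_per_aa()] on the given anchor sequence/interval returns
#' exactly `target` (172 A^2/residue by default, the raft-propensity
#' threshold).  The factor is recorded in the returned table's
#' `calibration_factor` attribute and in all pipeline provenance output.
#'
#' @param sequence Anchor amino-acid sequence (string).
#' @param tm_start,tm_end 1-based inclusive bounds of the anchor's TM
#'   region.
#' @param table Table to rescale; default [default_area_table()].
#' @param target Target score in A^2/residue; default 172.
#' @return A calibrated `ttr_area_table`.
#' @export
calibrate_area_table <- function(sequence, tm_start, tm_end,
                                 table = default_area_table(),
                                 target = 172) {
  ttr_assert(is_count(tm_start, 1L) && is_count(tm_end, 1L) &&
               tm_start <= tm_end && tm_end <= nchar(sequence),
             "ttr_bad_interval", "anchor TM interval out of sequence bounds")
  raw <- surface_area_per_aa(sequence,
                             regions = cbind(start = tm_start, end = tm_end),
                             table = table)
  fac <- target / raw
  area_table(unclass(table) * fac, calibration_factor = fac)
}

#' Write a surface-area table to TSV
#'
#' @param table A `ttr_area_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(table, path) {
  fac <- attr(table, "calibration_factor")
  prov <- NULL
  if (!is.null(fac) && is.finite(fac)) {
    prov <- list(calibration_factor = format(fac, digits = 17L))
  }
  write_tsv(data.frame(residue = names(unclass(table)),
                       area = as.numeric(table)), path, provenance = prov)
}
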