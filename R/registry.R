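# The domain registry partitions profile-HMM model names into the three
# sets the classifier consults: DNA-binding effector domains, the
# two-component core domains (hybrid detection), and signal-transduction
# marker domains.

TCS_CORE_DEFAULT <- c("Response_reg", "HATPase_c", "HisKA")

#' Load a domain registry
#'
#' Reads a YAML registry with keys `dna_binding`, `tcs_core` (optional;
#' defaults to the three two-component core domains `Response_reg`,
#' `HATPase_c`, `HisKA`) and `st_membership`.  A protein counts as a
#' signal-transduction (ST) protein iff it carries at least one
#' `st_membership` model or is classified as a TTR, so TTRs are always a
#' subset of ST proteins.
#'
#' The DNA-binding set shipped with the package (`registry.yaml`) is an
#' editable stand-in seeded with common helix-turn-helix-family and other
#' widespread transcription-factor models; it is data, not code, and is
#' expected to be replaced or extended for production annotation sets.
#'
#' @param path Path to a YAML registry file; default is the packaged
#'   registry.
#' @return An object of class `ttr_registry`: a list with character-vector
#'   elements `dna_binding`, `tcs_core`, `st_membership`.
#' @export
#' @examples
#' reg <- load_registry()
#' reg$tcs_core
load_registry <- function(path = ttr_extdata("registry.yaml")) {
  ttr_assert(file.exists(path), "ttr_missing_file",
             "registry file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  registry(dna_binding = cfg$dna_binding,
           tcs_core = cfg$tcs_core,
           st_membership = cfg$st_membership,
           source = path)
}

#' Construct a domain registry from vectors
#'
#' @param dna_binding Character vector of DNA-binding model names; must be
#'   nonempty.
#' @param tcs_core Two-component core model names; `NULL` selects the
#'   default `c("Response_reg", "HATPase_c", "HisKA")`.  Must be disjoint
#'   from `dna_binding`.
#' @param st_membership Model names whose presence marks a protein as a
#'   signal-transduction protein; must be nonempty.
#' @param source Optional provenance string (file path).
#' @return A `ttr_registry` object.
#' @export
registry <- function(dna_binding, tcs_core = NULL, st_membership,
                     source = NA_character_) {
  if (is.null(tcs_core)) tcs_core <- TCS_CORE_DEFAULT
  dna_binding <- unique(as.character(dna_binding))
  tcs_core <- unique(as.character(tcs_core))
  st_membership <- unique(as.character(st_membership))
  ttr_assert(length(dna_binding) > 0L, "ttr_bad_registry",
             "registry: dna_binding set must be nonempty")
  ttr_assert(length(st_membership) > 0L, "ttr_bad_registry",
             "registry: st_membership set must be nonempty")
  clash <- intersect(dna_binding, tcs_core)
  ttr_assert(length(clash) == 0L, "ttr_bad_registry",
             "registry: model(s) %s appear in both dna_binding and tcs_core",
             paste(clash, collapse = ", "))
  structure(list(dna_binding = dna_binding, tcs_core = tcs_core,
                 st_membership = st_membership, source = source),
            class = "ttr_registry")
}

#' @export
print.ttr_registry <- function(x, ...) {
  cat("Domain registry:",
      sprintf("%d DNA-binding, %d two-component core, %d ST-marker models\n",
              length(x$dna_binding), length(x$tcs_core),
              length(x$st_membership)))
  invisible(x)
}
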