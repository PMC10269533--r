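#' @keywords internal
"_PACKAGE"

#' @importFrom stats complete.cases cor.test rbinom rgeom rlnorm rnorm rpois
#'   runif sd setNames shapiro.test t.test
#' @importFrom utils head read.delim write.table
NULL

# stop() with a class so callers/tests can distinguish failure modes
ttr_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "ttrcensus_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

ttr_assert <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) ttr_stop(class, fmt, ...)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

# md5 of an in-memory object via its serialized text form (provenance only)
hash_of <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

file_hash <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

# TSV writers/readers used for all pipeline outputs; '#' comment lines carry
# provenance and are skipped on read.
write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (nm in names(provenance)) {
      cat(sprintf("# %s: %s\n", nm, provenance[[nm]]), file = con)
    }
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             ...)
}

#' Path to a file shipped with the package
#'
#' Convenience wrapper around [system.file()] for the plain-text resources
#' under `extdata/` (default domain registry, surface-area tables, the
#' synthetic calibration anchor).
#'
#' @param ... File path components below `extdata/`.
#' @return Absolute path to the file; errors if it does not exist.
#' @export
#' @examples
#' ttr_extdata("registry.yaml")
ttr_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "ttrcensus", mustWork = FALSE)
  ttr_assert(nzchar(p), "ttr_missing_file",
             "packaged file extdata/%s not found", file.path(...))
  p
}
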