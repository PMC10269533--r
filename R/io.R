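# Readers for the four input artifacts: proteome FASTA, domain-hit tables,
# TM-segment files, genome/taxonomy metadata.  All residue coordinates are
# 1-based inclusive throughout the package (HMMER/TMHMM convention).

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_CANONICAL, "X")

#' Read a proteome FASTA file
#'
#' Parses an amino-acid FASTA file into a protein table.  The protein
#' identifier is the first whitespace-delimited token of each header;
#' sequences are uppercased.  Only the 20 canonical residue letters plus
#' `X` (unknown) are accepted.
#'
#' @param path Path to an (uncompressed or gzipped) amino-acid FASTA file.
#' @return A data.frame with columns `protein_id`, `sequence` and `length`
#'   (residues), one row per FASTA record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 demo", "MKTLLIV", ">p2", "mdelrr"), fa)
#' read_proteome_fasta(fa)
read_proteome_fasta <- function(path) {
  ttr_assert(file.exists(path), "ttr_missing_file", "FASTA file not found: %s",
             path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  ttr_assert(all(nzchar(ids)), "ttr_bad_fasta", "FASTA record with empty header in %s",
             path)
  dup <- ids[duplicated(ids)]
  ttr_assert(length(dup) == 0L, "ttr_duplicate_id",
             "duplicate protein_id in %s: %s", path,
             paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(aa))
  len <- nchar(seqs)
  bad_empty <- ids[len == 0L]
  ttr_assert(length(bad_empty) == 0L, "ttr_empty_sequence",
             "empty sequence for protein %s", paste(bad_empty, collapse = ", "))
  # reject any residue outside the 20 canonical letters + X
  illegal <- gsub(paste0("[", paste(AA_ALLOWED, collapse = ""), "]"), "", seqs)
  bad <- which(nzchar(illegal))
  if (length(bad)) {
    ttr_stop("ttr_illegal_residue",
             "illegal residue letter(s) '%s' in protein %s",
             substr(illegal[bad[1L]], 1L, 1L), ids[bad[1L]])
  }
  data.frame(protein_id = ids, sequence = unname(seqs), length = unname(len),
             stringsAsFactors = FALSE)
}

#' Read a domain-hit table
#'
#' Reads per-protein profile-HMM domain hits either from HMMER3's
#' per-domain tabular output (`domtblout`, whitespace-delimited with `#`
#' comment lines, `hmmsearch` orientation: target = protein, query = model)
#' or from a simple 7-column TSV dialect with header
#' `protein_id, model_name, model_accession, env_from, env_to, bit_score,
#' i_evalue`.  Hits whose independent E-value exceeds `max_i_evalue` are
#' discarded; input order is preserved.
#'
#' @param path Path to the hit table.
#' @param dialect `"domtblout"` or `"tsv"`.
#' @param max_i_evalue Significance cutoff applied to the independent
#'   (per-domain) E-value; default `1e-5`.
#' @return A data.frame with columns `protein_id`, `model_name`,
#'   `model_accession`, `env_from`, `env_to` (1-based inclusive envelope
#'   coordinates), `bit_score`, `i_evalue`.
#' @export
read_domain_hits <- function(path, dialect = c("tsv", "domtblout"),
                             max_i_evalue = 1e-5) {
  dialect <- match.arg(dialect)
  ttr_assert(file.exists(path), "ttr_missing_file",
             "domain-hit file not found: %s", path)
  ttr_assert(is.numeric(max_i_evalue) && max_i_evalue >= 0, "ttr_bad_param",
             "max_i_evalue must be a non-negative number")
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (dialect == "tsv") {
    ttr_assert(length(rows) >= 1L, "ttr_malformed_line",
               "%s: no header line found", path)
    header <- strsplit(trimws(lines[rows[1L]]), "\t|\\s+")[[1L]]
    expect <- c("protein_id", "model_name", "model_accession", "env_from",
                "env_to", "bit_score", "i_evalue")
    ttr_assert(identical(header, expect), "ttr_malformed_line",
               "%s: TSV header must be: %s", path, paste(expect, collapse = ", "))
    rows <- rows[-1L]
  }
  fields <- strsplit(trimws(lines[rows]), "\t|\\s+")
  nf <- lengths(fields)
  min_cols <- if (dialect == "domtblout") 22L else 7L
  bad <- which(if (dialect == "domtblout") nf < min_cols else nf != min_cols)
  if (length(bad)) {
    ttr_stop("ttr_malformed_line",
             "line %d of %s: expected %s%d columns, got %d", rows[bad[1L]],
             path, if (dialect == "domtblout") ">= " else "", min_cols,
             nf[bad[1L]])
  }
  pick <- function(k) vapply(fields, `[`, character(1L), k)
  if (length(fields) == 0L) {
    df <- empty_hits()
  } else if (dialect == "domtblout") {
    # hmmsearch orientation: target = protein, query = model
    num <- suppressWarnings(
      cbind(i_evalue = as.numeric(pick(13L)), bit_score = as.numeric(pick(14L)),
            env_from = as.numeric(pick(20L)), env_to = as.numeric(pick(21L))))
    acc <- pick(5L)
    df <- data.frame(protein_id = pick(1L), model_name = pick(4L),
                     model_accession = ifelse(acc == "-", "", acc),
                     env_from = as.integer(num[, "env_from"]),
                     env_to = as.integer(num[, "env_to"]),
                     bit_score = num[, "bit_score"],
                     i_evalue = num[, "i_evalue"], stringsAsFactors = FALSE)
  } else {
    num <- suppressWarnings(
      cbind(env_from = as.numeric(pick(4L)), env_to = as.numeric(pick(5L)),
            bit_score = as.numeric(pick(6L)), i_evalue = as.numeric(pick(7L))))
    acc <- pick(3L)
    df <- data.frame(protein_id = pick(1L), model_name = pick(2L),
                     model_accession = ifelse(acc == "-", "", acc),
                     env_from = as.integer(num[, "env_from"]),
                     env_to = as.integer(num[, "env_to"]),
                     bit_score = num[, "bit_score"],
                     i_evalue = num[, "i_evalue"], stringsAsFactors = FALSE)
  }
  if (nrow(df)) {
    bad <- which(!stats::complete.cases(df[c("env_from", "env_to", "bit_score",
                                             "i_evalue")]))
    if (length(bad)) {
      ttr_stop("ttr_malformed_line",
               "line %d of %s: non-numeric score or coordinate", rows[bad[1L]],
               path)
    }
  }
  bad <- which(df$env_from > df$env_to | df$env_from < 1L)
  if (length(bad)) {
    ttr_stop("ttr_bad_interval",
             "line %d of %s: envelope start %d > end %d (or < 1)",
             rows[bad[1L]], path, df$env_from[bad[1L]], df$env_to[bad[1L]])
  }
  ttr_assert(all(is.finite(df$bit_score)), "ttr_malformed_line",
             "%s: non-finite bit score", path)
  ttr_assert(all(df$i_evalue >= 0), "ttr_malformed_line",
             "%s: negative i-E-value", path)
  df[df$i_evalue <= max_i_evalue, , drop = FALSE]
}

empty_hits <- function() {
  data.frame(protein_id = character(), model_name = character(),
             model_accession = character(), env_from = integer(),
             env_to = integer(), bit_score = numeric(), i_evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Write domain hits in the TSV dialect
#'
#' Inverse of [read_domain_hits()] for `dialect = "tsv"`; round-tripping a
#' parsed hit table through this writer yields an identical table.
#'
#' @param hits Hit data.frame as returned by [read_domain_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  df <- hits[, c("protein_id", "model_name", "model_accession", "env_from",
                 "env_to", "bit_score", "i_evalue")]
  df$model_accession[!nzchar(df$model_accession)] <- "-"  # HMMER convention
  write_tsv(df, path)
}

#' Read TMHMM-style transmembrane segment files
#'
#' Consumes TMHMM long-format lines (`protein_id  program  label  start
#' end`); only lines whose region label is `TMhelix` contribute segments,
#' `inside`/`outside` (and any other) labels are ignored.  Per protein,
#' segments are returned sorted by start and must not overlap.
#'
#' @param path Path to the segment file.
#' @return A named list mapping `protein_id` to a two-column integer matrix
#'   (`start`, `end`; 1-based inclusive).  Proteins that appear only with
#'   non-`TMhelix` labels map to a zero-row matrix.
#' @export
read_tm_segments <- function(path) {
  ttr_assert(file.exists(path), "ttr_missing_file",
             "TM-segment file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\t|\\s+")[[1L]]
    if (length(f) < 5L) {
      ttr_stop("ttr_malformed_line",
               "line %d of %s: expected 5 whitespace-delimited fields", i, path)
    }
    id <- f[1L]
    label <- f[3L]
    if (is.null(out[[id]])) out[[id]] <- cbind(start = integer(), end = integer())
    if (label != "TMhelix") next
    se <- suppressWarnings(as.integer(f[4:5]))
    if (anyNA(se)) {
      ttr_stop("ttr_malformed_line", "line %d of %s: non-integer coordinates",
               i, path)
    }
    if (se[1L] > se[2L] || se[1L] < 1L) {
      ttr_stop("ttr_bad_interval",
               "line %d of %s: TMhelix start %d > end %d (or < 1)", i, path,
               se[1L], se[2L])
    }
    out[[id]] <- rbind(out[[id]], se)
  }
  for (id in names(out)) {
    m <- out[[id]]
    if (nrow(m) > 1L) {
      m <- m[order(m[, 1L]), , drop = FALSE]
      if (any(m[-1L, 1L] <= m[-nrow(m), 2L])) {
        ttr_stop("ttr_overlapping_tm",
                 "overlapping TMhelix intervals for protein %s in %s", id, path)
      }
    }
    dimnames(m) <- list(NULL, c("start", "end"))
    out[[id]] <- m
  }
  out
}

#' Read genome metadata with GTDB-style taxonomy
#'
#' Reads a TSV with header `genome_id, taxonomy, cds_total`.  The taxonomy
#' string uses GTDB rank prefixes (`d__;p__;c__;o__;f__;g__;s__`); ranks
#' are parsed positionally by prefix and the superkingdom is derived from
#' the `d__` value (`Bacteria`/`Archaea`).
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with columns `genome_id`, `cds_total`,
#'   `superkingdom`, and the seven rank columns `domain` .. `species`
#'   (empty string for unfilled ranks).
#' @export
read_genome_meta <- function(path) {
  ttr_assert(file.exists(path), "ttr_missing_file",
             "genome metadata file not found: %s", path)
  df <- read_tsv(path)
  expect <- c("genome_id", "taxonomy", "cds_total")
  ttr_assert(all(expect %in% names(df)), "ttr_malformed_line",
             "%s: header must contain %s", path, paste(expect, collapse = ", "))
  ttr_assert(all(!duplicated(df$genome_id)), "ttr_duplicate_id",
             "%s: duplicate genome_id", path)
  bad <- which(!is.finite(df$cds_total) | df$cds_total <= 0 |
                 df$cds_total != round(df$cds_total))
  if (length(bad)) {
    ttr_stop("ttr_bad_param", "%s: non-positive cds_total for genome %s",
             path, df$genome_id[bad[1L]])
  }
  ranks <- t(vapply(df$taxonomy, parse_gtdb_taxonomy, character(7L)))
  dimnames(ranks) <- list(NULL, GTDB_RANKS)
  sk <- ifelse(ranks[, "domain"] == "Bacteria", "bacteria",
               ifelse(ranks[, "domain"] == "Archaea", "archaea", NA_character_))
  bad <- which(is.na(sk))
  if (length(bad)) {
    ttr_stop("ttr_bad_taxonomy",
             "genome %s: d__ rank must be Bacteria or Archaea (got '%s')",
             df$genome_id[bad[1L]], ranks[bad[1L], "domain"])
  }
  cbind(data.frame(genome_id = df$genome_id,
                   cds_total = as.integer(df$cds_total),
                   superkingdom = sk, stringsAsFactors = FALSE),
        as.data.frame(ranks, stringsAsFactors = FALSE))
}

GTDB_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")
GTDB_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

parse_gtdb_taxonomy <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  out <- setNames(rep("", 7L), GTDB_RANKS)
  for (p in parts) {
    if (!nzchar(p)) next
    hit <- which(startsWith(p, GTDB_PREFIXES))
    if (length(hit) != 1L) {
      ttr_stop("ttr_bad_taxonomy", "unrecognized taxonomy field '%s' in '%s'",
               p, s)
    }
    out[hit] <- substring(p, 4L)
  }
  ttr_assert(nzchar(out[["domain"]]), "ttr_bad_taxonomy",
             "taxonomy '%s' is missing the required d__ rank", s)
  out
}
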