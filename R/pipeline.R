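# The end-to-end pipeline: read -> TM features -> classify -> summarize
# -> statistics, producing a deterministic TSV/JSON output bundle with
# provenance (input hashes, calibration factor) embedded in every file.

#' Pipeline configuration
#'
#' Collects and validates the paths and analysis constants of one census
#' run.  All referenced input paths must exist at validation time.
#'
#' @param proteome Cohort proteome FASTA path.
#' @param hits Domain-hit table path.
#' @param genome_meta Genome metadata TSV path.
#' @param protein_map Two-column TSV (`protein_id`, `genome_id`) linking
#'   proteins to genomes.
#' @param tm_segments Optional TMHMM-style segment file; when supplied it
#'   is authoritative for the whole cohort (the hydropathy predictor is
#'   never consulted), when `NULL` TM regions are predicted from sequence.
#' @param registry_path Domain registry YAML (default: packaged registry).
#' @param area_table_path Surface-area table TSV (default: packaged
#'   calibrated table).
#' @param hits_dialect `"tsv"` or `"domtblout"`.
#' @param max_i_evalue Hit significance cutoff (default 1e-5).
#' @param max_overlap Maximum tolerated hit overlap in residues (15).
#' @param min_genomes Minimum genomes per taxon for the statistical table
#'   (default 10).
#' @param params A [tm_params()] object.
#' @param var_equal Pooled-variance t test (default `TRUE`).
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Seed recorded in provenance (the census itself is
#'   deterministic; the seed matters when the inputs were simulated).
#' @return A validated `ttr_pipeline_config` list.
#' @export
pipeline_config <- function(proteome, hits, genome_meta, protein_map,
                            tm_segments = NULL,
                            registry_path = ttr_extdata("registry.yaml"),
                            area_table_path = ttr_extdata("area_table_calibrated.tsv"),
                            hits_dialect = c("tsv", "domtblout"),
                            max_i_evalue = 1e-5, max_overlap = 15L,
                            min_genomes = 10L, params = tm_params(),
                            var_equal = TRUE, out_dir, seed = 1L) {
  hits_dialect <- match.arg(hits_dialect)
  need <- c(proteome = proteome, hits = hits, genome_meta = genome_meta,
            protein_map = protein_map, registry = registry_path,
            area_table = area_table_path)
  if (!is.null(tm_segments)) need <- c(need, tm_segments = tm_segments)
  missing <- need[!file.exists(need)]
  ttr_assert(length(missing) == 0L, "ttr_missing_file",
             "input file(s) not found: %s", paste(missing, collapse = ", "))
  ttr_assert(is_count(min_genomes, 1L), "ttr_bad_param",
             "min_genomes must be >= 1")
  structure(list(proteome = proteome, hits = hits, genome_meta = genome_meta,
                 protein_map = protein_map, tm_segments = tm_segments,
                 registry_path = registry_path,
                 area_table_path = area_table_path,
                 hits_dialect = hits_dialect, max_i_evalue = max_i_evalue,
                 max_overlap = as.integer(max_overlap),
                 min_genomes = as.integer(min_genomes), params = params,
                 var_equal = var_equal, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "ttr_pipeline_config")
}

# statistics block shared by run_pipeline() and ttr_report(); pure
# function of the per-protein records + metadata, so re-running the
# report on a bundle's own per-protein table reproduces its JSON exactly.
compute_statistics <- function(records, meta, min_genomes = 10L,
                               var_equal = TRUE) {
  gsum <- summarize_genomes(records, meta)
  taxa <- taxon_aggregate(gsum, min_genomes)
  ttrs <- records[records$is_ttr, , drop = FALSE]
  n_ttr <- nrow(ttrs)
  pass <- c(single_pass = sum(ttrs$pass_class == "single_pass"),
            two_pass = sum(ttrs$pass_class == "two_pass"),
            multi_pass = sum(ttrs$pass_class == "multi_pass"))
  correlations <- lapply(split(gsum, gsum$superkingdom), function(g) {
    if (nrow(g) < 3L) return(NULL)
    adjusted_correlation(g)
  })
  strata <- tryCatch(raft_stratified_sensory_test(records, var_equal),
                     ttr_empty_stratum = function(e) {
                       list(note = conditionMessage(e))
                     })
  list(
    n_genomes = nrow(gsum),
    n_proteins = nrow(records),
    n_ttr = n_ttr,
    n_hybrid = sum(ttrs$is_hybrid),
    hybrid_fraction = if (n_ttr) sum(ttrs$is_hybrid) / n_ttr else NA_real_,
    pass_counts = as.list(pass),
    pass_fractions = if (n_ttr) as.list(pass / n_ttr) else NULL,
    raft_fraction = if (n_ttr) mean(ttrs$raft_flag, na.rm = TRUE) else NA_real_,
    mean_ttr_per_genome = mean(gsum$n_ttr),
    mean_ttr_per_genome_by_superkingdom =
      lapply(split(gsum$n_ttr, gsum$superkingdom), mean),
    mean_ttr_per_ttr_genome = mean(gsum$n_ttr[gsum$n_ttr > 0L]),
    mean_ratio_ttr_cds = lapply(split(gsum$ratio_ttr_cds, gsum$superkingdom),
                                mean),
    mean_ratio_ttr_st = lapply(split(gsum, gsum$superkingdom), function(g) {
      mean(g$ratio_ttr_st, na.rm = TRUE)
    }),
    mean_ratio_st_cds = lapply(split(gsum$ratio_st_cds, gsum$superkingdom),
                               mean),
    mean_tm_per_ttr = if (n_ttr) mean(ttrs$n_tm) else NA_real_,
    mean_tm_length = if (n_ttr) mean(ttrs$mean_tm_length, na.rm = TRUE)
                     else NA_real_,
    mean_sa_per_aa = if (n_ttr) mean(ttrs$sa_per_aa, na.rm = TRUE)
                     else NA_real_,
    correlations = correlations,
    raft_sensory_test = strata,
    genome_summaries = gsum,
    taxa = taxa)
}

serialize_stats <- function(stats, provenance) {
  corr <- lapply(stats$correlations, function(cr) {
    if (is.null(cr)) return(NULL)
    list(n = cr$n, pairs = cr$pairs, shapiro = cr$shapiro)
  })
  strata <- stats$raft_sensory_test
  if (inherits(strata, "ttr_strata_test")) strata <- unclass(strata)
  out <- stats[c("n_genomes", "n_proteins", "n_ttr", "n_hybrid",
                 "hybrid_fraction", "pass_counts", "pass_fractions",
                 "raft_fraction", "mean_ttr_per_genome",
                 "mean_ttr_per_genome_by_superkingdom",
                 "mean_ttr_per_ttr_genome", "mean_ratio_ttr_cds",
                 "mean_ratio_ttr_st", "mean_ratio_st_cds", "mean_tm_per_ttr",
                 "mean_tm_length", "mean_sa_per_aa")]
  out$correlations <- corr
  out$raft_sensory_test <- strata
  out$provenance <- provenance
  out
}

#' Run the census pipeline
#'
#' Executes the stages read -> TM features -> classify -> summarize ->
#' statistics and writes the output bundle into `config$out_dir`:
#' `per_protein.tsv`, `per_genome.tsv`, `per_taxon_stats.tsv`,
#' `per_taxon_census.tsv`, `domain_tally_dna.tsv`,
#' `domain_tally_sensory.tsv`, `statistics.json` and `log.txt`.  Every
#' output embeds the input hashes, calibration factor and seed; rerunning
#' an identical configuration yields byte-identical output.  On stage
#' failure, partial outputs are removed before the error propagates.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with `records`, `stats`, `tallies` and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  ttr_assert(inherits(config, "ttr_pipeline_config"), "ttr_bad_param",
             "config must come from pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(config$out_dir,
                       c("per_protein.tsv", "per_genome.tsv",
                         "per_taxon_stats.tsv", "per_taxon_census.tsv",
                         "domain_tally_dna.tsv", "domain_tally_sensory.tsv",
                         "statistics.json", "log.txt"))
  names(outputs) <- c("per_protein", "per_genome", "taxon_stats",
                      "taxon_census", "tally_dna", "tally_sensory",
                      "stats_json", "log")
  logbuf <- character()
  note <- function(fmt, ...) {
    logbuf <<- c(logbuf, sprintf(fmt, ...))
  }
  run <- function() {
    registry <- load_registry(config$registry_path)
    table <- read_area_table(config$area_table_path)
    proteins <- read_proteome_fasta(config$proteome)
    note("read: %d proteins from %s", nrow(proteins), config$proteome)
    pmap <- read_tsv(config$protein_map)
    ttr_assert(all(c("protein_id", "genome_id") %in% names(pmap)),
               "ttr_malformed_line",
               "protein map must have protein_id, genome_id columns")
    proteins$genome_id <- pmap$genome_id[match(proteins$protein_id,
                                               pmap$protein_id)]
    ttr_assert(!anyNA(proteins$genome_id), "ttr_unknown_protein",
               "protein(s) missing from the protein map")
    hits <- read_domain_hits(config$hits, config$hits_dialect,
                             config$max_i_evalue)
    note("read: %d significant domain hits (i-E-value <= %g)", nrow(hits),
         config$max_i_evalue)
    meta <- read_genome_meta(config$genome_meta)
    note("read: %d genomes", nrow(meta))
    tm <- NULL
    if (!is.null(config$tm_segments)) {
      tm <- read_tm_segments(config$tm_segments)
      note("read: TM segments for %d proteins (supplied file authoritative)",
           length(tm))
    } else {
      note("TM segments: none supplied; hydropathy predictor in use")
    }
    records <- classify_cohort(proteins, hits, registry, tm_segments = tm,
                               params = config$params, table = table,
                               max_overlap = config$max_overlap)
    note("classify: %d TTRs (%d hybrid) among %d proteins",
         sum(records$is_ttr), sum(records$is_hybrid), nrow(records))
    stats <- compute_statistics(records, meta, config$min_genomes,
                                config$var_equal)
    note("summarize: %d genomes, %d taxa (%d meeting min_genomes = %d)",
         stats$n_genomes, nrow(stats$taxa$census), nrow(stats$taxa$stats),
         config$min_genomes)
    tallies <- domain_composition_tally(records, hits, registry)
    prov <- list(
      # hash covers the analysis settings, not the output location
      config_hash = hash_of(unclass(config)[setdiff(names(config), "out_dir")]),
      registry_hash = file_hash(config$registry_path),
      area_table_hash = file_hash(config$area_table_path),
      calibration_factor = attr(table, "calibration_factor"),
      seed = config$seed)
    prov_chr <- lapply(prov, function(v) {
      if (is.numeric(v)) format(v, digits = 17L) else as.character(v)
    })
    write_tsv(records, outputs[["per_protein"]], provenance = prov_chr)
    write_tsv(stats$genome_summaries, outputs[["per_genome"]],
              provenance = prov_chr)
    write_tsv(stats$taxa$stats, outputs[["taxon_stats"]], provenance = prov_chr)
    write_tsv(stats$taxa$census, outputs[["taxon_census"]],
              provenance = prov_chr)
    write_tsv(tallies$dna_binding, outputs[["tally_dna"]], provenance = prov_chr)
    write_tsv(tallies$sensory, outputs[["tally_sensory"]],
              provenance = prov_chr)
    jsonlite::write_json(serialize_stats(stats, prov), outputs[["stats_json"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    writeLines(logbuf, outputs[["log"]])
    list(records = records, stats = stats, tallies = tallies, paths = outputs)
  }
  res <- tryCatch(run(), error = function(e) {
    unlink(outputs)
    stop(e)
  })
  invisible(res)
}

#' Recompute statistics from a prior per-protein table
#'
#' The report-only entry point: consumes a `per_protein.tsv` written by
#' [run_pipeline()] plus the genome metadata, and recomputes the genome
#' summaries and the statistics report without re-running classification.
#'
#' @param per_protein_path Path to a per-protein TSV.
#' @param genome_meta_path Genome metadata TSV path.
#' @param min_genomes,var_equal As in [pipeline_config()].
#' @return The statistics list of [compute_statistics()].
#' @export
ttr_report <- function(per_protein_path, genome_meta_path, min_genomes = 10L,
                       var_equal = TRUE) {
  records <- read_tsv(per_protein_path)
  ttr_assert(nrow(records) > 0L && any(records$is_ttr), "ttr_no_ttrs",
             "no TTRs in input %s", per_protein_path)
  records$pass_class <- as.character(records$pass_class)
  meta <- read_genome_meta(genome_meta_path)
  compute_statistics(records, meta, min_genomes, var_equal)
}
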