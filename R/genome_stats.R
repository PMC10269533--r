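# Genome-, taxon- and cohort-level census statistics: counts, the three
# normalization ratios (TTR/CDS, TTR/ST, ST/CDS), taxon aggregation with
# the minimum-genome rule, rank correlations on count-partition-adjusted
# vectors, and the raft-stratified sensory-domain comparison.

#' Summarize one genome
#'
#' Tallies classification records of a single genome against its metadata:
#' signal-transduction, TTR, hybrid and DNA-binding counts, the three
#' normalization ratios, the TM pass-class histogram and the mean TM count
#' per TTR.  Zero-denominator ratios are `NA` (absent), never zero-filled.
#'
#' @param records Classification data.frame (rows of [classify_cohort()])
#'   for one genome.
#' @param meta One-row genome metadata (from [read_genome_meta()]).
#' @return A one-row `ttr_genome_summary` data.frame.
#' @export
genome_summary <- function(records, meta) {
  ttr_assert(nrow(meta) == 1L, "ttr_bad_param", "meta must be a single row")
  gids <- unique(records$genome_id)
  ttr_assert(length(gids) <= 1L, "ttr_genome_mismatch",
             "records span multiple genomes: %s", paste(gids, collapse = ", "))
  if (length(gids) == 1L) {
    ttr_assert(identical(gids, meta$genome_id), "ttr_genome_mismatch",
               "records belong to genome %s, metadata to %s", gids,
               meta$genome_id)
  }
  cds <- meta$cds_total
  ttr_assert(cds >= nrow(records), "ttr_bad_param",
             "genome %s: cds_total (%d) < number of proteins supplied (%d)",
             meta$genome_id, cds, nrow(records))
  n_st <- sum(records$is_st)
  n_ttr <- sum(records$is_ttr)
  n_hybrid <- sum(records$is_hybrid)
  ttr <- records[records$is_ttr, , drop = FALSE]
  out <- data.frame(
    genome_id = meta$genome_id,
    superkingdom = meta$superkingdom,
    phylum = meta$phylum, class = meta$class,
    cds_total = cds,
    n_st = n_st, n_ttr = n_ttr, n_hybrid = n_hybrid,
    n_dna_binding_total = sum(records$has_dna_binding),
    ratio_ttr_cds = n_ttr / cds,
    ratio_ttr_st = if (n_st > 0L) n_ttr / n_st else NA_real_,
    ratio_st_cds = n_st / cds,
    n_single_pass = sum(ttr$pass_class == "single_pass"),
    n_two_pass = sum(ttr$pass_class == "two_pass"),
    n_multi_pass = sum(ttr$pass_class == "multi_pass"),
    mean_tm_per_ttr = if (n_ttr > 0L) mean(ttr$n_tm) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("ttr_genome_summary", class(out))
  out
}

#' Summarize every genome of a cohort
#'
#' @param records Classification data.frame for the whole cohort.
#' @param meta Genome metadata data.frame (one row per genome; genomes
#'   without classified proteins get zero counts).
#' @return A `ttr_genome_summary` data.frame, one row per metadata genome.
#' @export
summarize_genomes <- function(records, meta) {
  pieces <- lapply(seq_len(nrow(meta)), function(i) {
    g <- meta$genome_id[i]
    genome_summary(records[!is.na(records$genome_id) &
                             records$genome_id == g, , drop = FALSE],
                   meta[i, , drop = FALSE])
  })
  do.call(rbind, pieces)
}

#' Aggregate genome summaries by taxon
#'
#' Genomes are grouped by the key `"phylum;class"` (a genome with an empty
#' phylum goes to the `"unclassified"` bucket, never silently dropped).
#' Taxa with fewer than `min_genomes` genomes are excluded from the
#' statistical table but retained in the census table.  Means are
#' unweighted across genomes; SDs are sample standard deviations; the
#' hybrid fraction is the pooled ratio of summed counts.
#'
#' @param summaries A `ttr_genome_summary` data.frame.
#' @param min_genomes Minimum genomes per taxon for the statistical table
#'   (default 10).
#' @return A list with elements `stats` (taxa meeting `min_genomes`) and
#'   `census` (all taxa); both data.frames keyed by `taxon`.
#' @export
taxon_aggregate <- function(summaries, min_genomes = 10L) {
  ttr_assert(is_count(min_genomes, 1L), "ttr_bad_param",
             "min_genomes must be a positive count")
  key <- ifelse(nzchar(summaries$phylum),
                paste(summaries$phylum, summaries$class, sep = ";"),
                "unclassified")
  groups <- split(summaries, key)
  rows <- lapply(names(groups), function(k) {
    g <- groups[[k]]
    m <- function(v) mean(v, na.rm = TRUE)
    s <- function(v) if (sum(!is.na(v)) >= 2L) sd(v, na.rm = TRUE) else NA_real_
    data.frame(
      taxon = k,
      superkingdom = g$superkingdom[1L],
      n_genomes = nrow(g),
      mean_n_ttr = m(g$n_ttr), sd_n_ttr = s(g$n_ttr),
      mean_ratio_ttr_cds = m(g$ratio_ttr_cds), sd_ratio_ttr_cds = s(g$ratio_ttr_cds),
      mean_ratio_ttr_st = m(g$ratio_ttr_st), sd_ratio_ttr_st = s(g$ratio_ttr_st),
      mean_ratio_st_cds = m(g$ratio_st_cds), sd_ratio_st_cds = s(g$ratio_st_cds),
      hybrid_fraction = if (sum(g$n_ttr) > 0L) sum(g$n_hybrid) / sum(g$n_ttr)
                        else NA_real_,
      mean_tm_per_ttr = m(g$mean_tm_per_ttr),
      stringsAsFactors = FALSE)
  })
  census <- do.call(rbind, rows)
  census <- census[order(-census$n_genomes, census$taxon), , drop = FALSE]
  rownames(census) <- NULL
  list(stats = census[census$n_genomes >= min_genomes, , drop = FALSE],
       census = census)
}

#' Rank correlations on count-partition-adjusted vectors
#'
#' Before correlating, the genome counts are adjusted so the three
#' quantities partition the proteome: `x = n_ttr`, `y = n_st - n_ttr`
#' (non-TTR signal-transduction proteins) and `z = cds_total - n_st`
#' (non-ST proteins).  This removes the contribution of TTRs correlating
#' with themselves inside the ST and CDS totals.  Spearman (average-rank
#' ties) and Kendall tau-b with p-values are reported for the pairs
#' `(x, y)` and `(x, z)`, along with Shapiro-Wilk normality checks per
#' vector (motivating the nonparametric tests).
#'
#' @param summaries A `ttr_genome_summary` data.frame with at least 3 rows.
#' @return A `ttr_correlation_report` list: `n`, `pairs` (data.frame with
#'   `pair`, `rho`, `rho_p`, `tau`, `tau_p`, `defined`), and `shapiro`
#'   (data.frame with `vector`, `W`, `p`).
#' @export
adjusted_correlation <- function(summaries) {
  n <- nrow(summaries)
  ttr_assert(n >= 3L, "ttr_bad_param",
             "adjusted_correlation needs >= 3 genomes, got %d", n)
  x <- summaries$n_ttr
  y <- summaries$n_st - summaries$n_ttr
  z <- summaries$cds_total - summaries$n_st
  ttr_assert(all(y >= 0L) && all(z >= 0L), "ttr_bad_param",
             "count partition violated: need n_ttr <= n_st <= cds_total")
  one_pair <- function(name, a, b) {
    if (sd(a) == 0 || sd(b) == 0) {
      return(data.frame(pair = name, rho = NA_real_, rho_p = NA_real_,
                        tau = NA_real_, tau_p = NA_real_, defined = FALSE,
                        stringsAsFactors = FALSE))
    }
    sp <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    kd <- suppressWarnings(cor.test(a, b, method = "kendall", exact = FALSE))
    data.frame(pair = name, rho = unname(sp$estimate), rho_p = sp$p.value,
               tau = unname(kd$estimate), tau_p = kd$p.value, defined = TRUE,
               stringsAsFactors = FALSE)
  }
  shapiro_row <- function(name, v) {
    if (sd(v) == 0 || length(v) < 3L) {
      return(data.frame(vector = name, W = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    if (length(v) > 5000L) v <- v[seq(1L, length(v), length.out = 5000L)]
    sw <- shapiro.test(v)
    data.frame(vector = name, W = unname(sw$statistic), p = sw$p.value,
               stringsAsFactors = FALSE)
  }
  structure(list(
    n = n,
    pairs = rbind(one_pair("ttr_vs_st_minus_ttr", x, y),
                  one_pair("ttr_vs_cds_minus_st", x, z)),
    shapiro = rbind(shapiro_row("n_ttr", x),
                    shapiro_row("st_minus_ttr", y),
                    shapiro_row("cds_minus_st", z))),
    class = "ttr_correlation_report")
}

#' @export
print.ttr_correlation_report <- function(x, ...) {
  cat(sprintf("Adjusted rank correlations over %d genomes\n", x$n))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Raft-stratified comparison of sensory-domain counts
#'
#' Splits TTRs by the raft flag (surface area per residue at or below
#' versus above the threshold) and compares the mean number of sensory
#' (non-DNA-binding) domains between the strata with a two-tailed
#' two-sample Student t test (pooled variance by default, per the classic
#' form; `var_equal = FALSE` switches to the Welch form for sensitivity
#' analysis).
#'
#' @param records Classification data.frame; only rows with `is_ttr` and a
#'   defined raft flag enter the test.
#' @param var_equal Use the pooled-variance form (default `TRUE`).
#' @return A `ttr_strata_test` list: per-stratum `n`, `mean`, `sd`, plus
#'   `t`, `df`, `p`.
#' @export
raft_stratified_sensory_test <- function(records, var_equal = TRUE) {
  ttr <- records[records$is_ttr & !is.na(records$raft_flag), , drop = FALSE]
  lo <- ttr$n_sensory_domains[ttr$raft_flag]
  hi <- ttr$n_sensory_domains[!ttr$raft_flag]
  ttr_assert(length(lo) >= 2L, "ttr_empty_stratum",
             "raft stratum (sa_per_aa <= threshold) has %d TTR(s); need >= 2",
             length(lo))
  ttr_assert(length(hi) >= 2L, "ttr_empty_stratum",
             "non-raft stratum (sa_per_aa > threshold) has %d TTR(s); need >= 2",
             length(hi))
  tt <- t.test(lo, hi, var.equal = var_equal)
  structure(list(
    raft = list(n = length(lo), mean = mean(lo), sd = sd(lo)),
    non_raft = list(n = length(hi), mean = mean(hi), sd = sd(hi)),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    var_equal = var_equal), class = "ttr_strata_test")
}

#' @export
print.ttr_strata_test <- function(x, ...) {
  cat(sprintf(
    "Sensory domains per TTR: raft %.3f (n=%d) vs non-raft %.3f (n=%d); t=%.3f, p=%.3g\n",
    x$raft$mean, x$raft$n, x$non_raft$mean, x$non_raft$n, x$t, x$p))
  invisible(x)
}

#' Domain composition of the TTR set
#'
#' For every DNA-binding and every non-DNA-binding (sensory) model, the
#' fraction of TTRs carrying at least one hit of that model (a model
#' carried twice by one TTR counts once).  Tables are sorted by descending
#' fraction with a cumulative-coverage column (fraction of TTRs carrying
#' at least one of the models so far).
#'
#' @param records Classification data.frame.
#' @param hits Cohort hit data.frame (resolved or raw; presence-based).
#' @param registry A `ttr_registry`.
#' @return A list of two data.frames, `dna_binding` and `sensory`, with
#'   columns `model`, `n_ttr`, `fraction`, `cumulative_coverage`.
#' @export
domain_composition_tally <- function(records, hits, registry) {
  ttr_ids <- records$protein_id[records$is_ttr]
  empty <- data.frame(model = character(), n_ttr = integer(),
                      fraction = numeric(), cumulative_coverage = numeric(),
                      stringsAsFactors = FALSE)
  if (length(ttr_ids) == 0L) return(list(dna_binding = empty, sensory = empty))
  h <- hits[hits$protein_id %in% ttr_ids, , drop = FALSE]
  h <- h[!duplicated(h[c("protein_id", "model_name")]), , drop = FALSE]
  one_table <- function(sub) {
    if (nrow(sub) == 0L) return(empty)
    cnt <- sort(table(sub$model_name), decreasing = TRUE)
    models <- names(cnt)
    # cumulative coverage: TTRs carrying >= 1 of the first k models
    covered <- character()
    cum <- numeric(length(models))
    for (k in seq_along(models)) {
      covered <- union(covered, sub$protein_id[sub$model_name == models[k]])
      cum[k] <- length(covered) / length(ttr_ids)
    }
    data.frame(model = models, n_ttr = as.integer(cnt),
               fraction = as.integer(cnt) / length(ttr_ids),
               cumulative_coverage = cum, stringsAsFactors = FALSE)
  }
  list(dna_binding = one_table(h[h$model_name %in% registry$dna_binding, ,
                                 drop = FALSE]),
       sensory = one_table(h[!(h$model_name %in% registry$dna_binding), ,
                             drop = FALSE]))
}
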