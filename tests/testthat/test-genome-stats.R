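toy_records <- function(gid = "g1") {
  # hand-built genome: 5 proteins classified; 3 ST, 2 TTR, 1 hybrid
  data.frame(
    protein_id = paste0(gid, "_p", 1:5),
    genome_id = gid,
    is_ttr = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    is_hybrid = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    is_st = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    has_dna_binding = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    pass_class = c("single_pass", "two_pass", "none", "none", "none"),
    n_tm = c(1L, 2L, 0L, 0L, 0L),
    n_sensory_domains = c(0L, 1L, 1L, 0L, 0L),
    mean_tm_length = c(21, 21, NA, NA, NA),
    sa_per_aa = c(160, 210, NA, NA, NA),
    raft_flag = c(TRUE, FALSE, NA, NA, NA),
    dna_binding_models = c("HTH_1", "LytTR", "", "HTH_1", ""),
    stringsAsFactors = FALSE)
}

toy_meta <- function(gid = "g1", cds = 10L,
                     tax = "d__Bacteria;p__Bacillota;c__Bacilli;o__;f__;g__;s__") {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\ttaxonomy\tcds_total",
               paste(gid, tax, cds, sep = "\t")), f)
  read_genome_meta(f)
}

test_that("genome summary reproduces the hand tally and its ratios", {
  s <- genome_summary(toy_records(), toy_meta())
  expect_equal(s$n_st, 3L)
  expect_equal(s$n_ttr, 2L)
  expect_equal(s$n_hybrid, 1L)
  expect_equal(s$n_dna_binding_total, 3L)
  expect_equal(s$ratio_ttr_cds, 0.2)
  expect_equal(s$ratio_ttr_st, 2 / 3)
  expect_equal(s$ratio_st_cds, 0.3)
  expect_equal(s$mean_tm_per_ttr, 1.5)
  # count conservation: the adjusted vectors partition the proteome
  expect_equal(s$n_ttr + (s$n_st - s$n_ttr) + (s$cds_total - s$n_st),
               s$cds_total)
})

test_that("zero denominators yield absent ratios, and saturation yields 1", {
  r <- toy_records()
  r$is_st <- FALSE; r$is_ttr <- FALSE; r$is_hybrid <- FALSE
  s <- genome_summary(r, toy_meta())
  expect_true(is.na(s$ratio_ttr_st))
  expect_equal(s$ratio_ttr_cds, 0)
  r2 <- toy_records()
  r2$is_ttr <- TRUE; r2$is_st <- TRUE
  s2 <- genome_summary(r2, toy_meta(cds = 5L))
  expect_equal(s2$ratio_ttr_cds, 1)
  expect_equal(s2$ratio_ttr_st, 1)
  expect_equal(s2$ratio_st_cds, 1)
  # mismatched genome ids are rejected
  expect_error(genome_summary(toy_records("gX"), toy_meta("g1")),
               class = "ttr_genome_mismatch")
})

test_that("taxon aggregation applies the minimum-genome rule without losing genomes", {
  mk <- function(gid, phylum, cls, n_ttr) {
    data.frame(genome_id = gid, superkingdom = "bacteria", phylum = phylum,
               class = cls, cds_total = 1000L, n_st = 50L, n_ttr = n_ttr,
               n_hybrid = 0L, n_dna_binding_total = 20L,
               ratio_ttr_cds = n_ttr / 1000, ratio_ttr_st = n_ttr / 50,
               ratio_st_cds = 0.05, n_single_pass = n_ttr, n_two_pass = 0L,
               n_multi_pass = 0L, mean_tm_per_ttr = 1,
               stringsAsFactors = FALSE)
  }
  big <- do.call(rbind, lapply(1:10, function(i) mk(paste0("a", i), "P1", "C1", i)))
  small <- do.call(rbind, lapply(1:9, function(i) mk(paste0("b", i), "P2", "C2", i)))
  lost <- mk("c1", "", "", 3L)
  agg <- taxon_aggregate(rbind(big, small, lost), min_genomes = 10L)
  expect_equal(agg$stats$taxon, "P1;C1")
  expect_setequal(agg$census$taxon, c("P1;C1", "P2;C2", "unclassified"))
  expect_equal(sum(agg$census$n_genomes), 20L)
  # two-point statistics
  two <- taxon_aggregate(rbind(mk("x1", "P3", "C3", 4L), mk("x2", "P3", "C3", 6L)),
                         min_genomes = 2L)
  expect_equal(two$stats$mean_n_ttr, 5)
  expect_equal(two$stats$sd_n_ttr, sqrt(2))
})

test_that("adjusted correlations are perfect on a monotone fixture and undefined on a constant one", {
  i <- 1:20
  mono <- data.frame(genome_id = paste0("g", i), superkingdom = "bacteria",
                     phylum = "P", class = "C", cds_total = 10L * i,
                     n_st = 3L * i, n_ttr = i, stringsAsFactors = FALSE)
  cr <- adjusted_correlation(mono)
  expect_equal(cr$pairs$rho, c(1, 1))
  expect_equal(cr$pairs$tau, c(1, 1))
  # scale invariance of rank statistics
  mono10 <- mono; mono10$cds_total <- mono10$cds_total * 10L
  expect_equal(adjusted_correlation(mono10)$pairs$rho, cr$pairs$rho)
  expect_equal(adjusted_correlation(mono10)$pairs$tau, cr$pairs$tau)
  flat <- mono; flat$n_ttr <- 5L; flat$n_st <- 10L; flat$cds_total <- 100L
  cf <- adjusted_correlation(flat)
  expect_false(any(cf$pairs$defined))
  expect_error(adjusted_correlation(mono[1:2, ]), class = "ttr_bad_param")
})

test_that("independent vectors stay inside the permutation null", {
  set.seed(2024)
  n <- 200L
  x <- rpois(n, 5)
  y <- sample(rpois(n, 40))  # independent of x by construction
  z <- rpois(n, 400)
  summaries <- data.frame(genome_id = paste0("g", 1:n),
                          superkingdom = "bacteria", phylum = "P", class = "C",
                          cds_total = x + y + z, n_st = x + y, n_ttr = x,
                          stringsAsFactors = FALSE)
  cr <- adjusted_correlation(summaries)
  obs_rho <- abs(cr$pairs$rho[cr$pairs$pair == "ttr_vs_st_minus_ttr"])
  obs_tau <- abs(cr$pairs$tau[cr$pairs$pair == "ttr_vs_st_minus_ttr"])
  # permutation oracle for the 95% null quantile
  null_rho <- null_tau <- numeric(400)
  for (b in seq_len(400)) {
    yp <- sample(y)
    null_rho[b] <- abs(cor(x, yp, method = "spearman"))
    null_tau[b] <- abs(cor(x, yp, method = "kendall"))
  }
  expect_lt(obs_rho, quantile(null_rho, 0.95))
  expect_lt(obs_tau, quantile(null_tau, 0.95))
})

test_that("raft-stratified sensory test behaves at both extremes", {
  mk <- function(sens, raft) {
    k <- length(sens)
    data.frame(protein_id = paste0("p", seq_len(k), raft[1]), genome_id = "g",
               is_ttr = TRUE, is_hybrid = FALSE, is_st = TRUE,
               has_dna_binding = TRUE, pass_class = "single_pass", n_tm = 1L,
               n_sensory_domains = sens, mean_tm_length = 21,
               sa_per_aa = ifelse(raft, 150, 200), raft_flag = raft,
               dna_binding_models = "HTH_1", stringsAsFactors = FALSE)
  }
  # identical strata: t = 0, p = 1
  same <- rbind(mk(c(0L, 1L, 2L), TRUE), mk(c(0L, 1L, 2L), FALSE))
  res <- raft_stratified_sensory_test(same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # clearly separated strata: p < 1e-4
  set.seed(31)
  lo <- pmax(round(rnorm(200, 0.5, 0.5)), 0L)
  hi <- pmax(round(rnorm(200, 2.0, 0.5)), 0L)
  sep <- rbind(mk(lo, rep(TRUE, 200)), mk(hi, rep(FALSE, 200)))
  res2 <- raft_stratified_sensory_test(sep)
  expect_lt(res2$p, 1e-4)
  expect_lt(res2$raft$mean, res2$non_raft$mean)
  # empty stratum is an error naming the stratum
  err <- expect_error(raft_stratified_sensory_test(mk(c(0L, 1L), TRUE)),
                      class = "ttr_empty_stratum")
  expect_match(conditionMessage(err), "non-raft")
})

test_that("domain tallies report per-TTR presence fractions with coverage", {
  reg <- test_registry()
  rec <- data.frame(protein_id = paste0("t", 1:4), genome_id = "g",
                    is_ttr = TRUE, stringsAsFactors = FALSE)
  hits <- data.frame(
    protein_id = c("t1", "t2", "t3", "t3", "t4", "t4"),
    model_name = c("HTH_1", "HTH_1", "HTH_1", "HTH_1", "LytTR", "Y_Y_Y"),
    model_accession = "", env_from = 1L, env_to = 30L, bit_score = 50,
    i_evalue = 1e-10, stringsAsFactors = FALSE)
  tal <- domain_composition_tally(rec, hits, reg)
  # t3 carries HTH_1 twice but counts once
  expect_equal(tal$dna_binding$fraction[tal$dna_binding$model == "HTH_1"], 0.75)
  expect_equal(tal$dna_binding$cumulative_coverage[nrow(tal$dna_binding)], 1)
  expect_equal(tal$sensory$model, "Y_Y_Y")
  empty <- domain_composition_tally(rec[rec$is_ttr == FALSE, ], hits, reg)
  expect_equal(nrow(empty$dna_binding), 0L)
})

test_that("cohort mean TTR/CDS ratio recovers the generating fraction", {
  # parameter-recovery property at reduced scale; the acceptance suite runs
  # the full-size version
  d <- file.path(tempdir(), "recover-small")
  p <- cohort_params(n_genomes = 80, seed = 19)
  gen <- generate_cohort(p, d)
  cfg <- pipeline_config(proteome = gen$paths$proteome, hits = gen$paths$hits,
                         genome_meta = gen$paths$meta,
                         protein_map = gen$paths$map,
                         tm_segments = gen$paths$tm,
                         out_dir = file.path(d, "out"))
  res <- run_pipeline(cfg)
  gsum <- res$stats$genome_summaries
  for (sk in c("bacteria", "archaea")) {
    g <- gsum[gsum$superkingdom == sk, ]
    est <- mean(g$ratio_ttr_cds)
    f <- p$ttr_fraction[[sk]]
    # exact binomial standard error of the mean of per-genome ratios
    se <- sqrt(sum(f * (1 - f) / g$cds_total)) / nrow(g)
    expect_lt(abs(est - f), 3 * se)
  }
})
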