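make_hits <- function(models, from = NULL, to = NULL, score = NULL) {
  k <- length(models)
  if (is.null(from)) from <- 1L + 40L * (seq_len(k) - 1L)
  if (is.null(to)) to <- from + 29L
  if (is.null(score)) score <- rep(50, k)
  data.frame(protein_id = rep("p", k), model_name = models,
             model_accession = rep("", k), env_from = as.integer(from),
             env_to = as.integer(to), bit_score = score,
             i_evalue = rep(1e-10, k), stringsAsFactors = FALSE)
}

profile_with <- function(n_tm) {
  reg <- if (n_tm) cbind(start = 1L + 25L * (seq_len(n_tm) - 1L),
                         end = 21L + 25L * (seq_len(n_tm) - 1L))
         else cbind(start = integer(), end = integer())
  tm_profile(strrep("A", 200), reg, tm_params(), default_area_table())
}

test_that("overlap resolution keeps the best-scoring compatible hits", {
  # identical intervals: higher score wins
  h <- make_hits(c("HTH_1", "GerE"), from = c(10L, 10L), to = c(60L, 60L),
                 score = c(50, 30))
  expect_equal(resolve_overlaps(h)$model_name, "HTH_1")
  # disjoint hits: both kept, in coordinate order
  h2 <- make_hits(c("GGDEF", "HTH_1"), from = c(100L, 1L), to = c(150L, 40L))
  expect_equal(resolve_overlaps(h2)$model_name, c("HTH_1", "GGDEF"))
  # overlap of 6 residues <= max_overlap 10: both kept
  h3 <- make_hits(c("A_dom", "B_dom"), from = c(1L, 55L), to = c(60L, 120L),
                  score = c(50, 40))
  expect_equal(nrow(resolve_overlaps(h3, max_overlap = 10L)), 2L)
  # same pair under max_overlap 5: only the stronger survives
  kept <- resolve_overlaps(h3, max_overlap = 5L)
  expect_equal(kept$model_name, "A_dom")
})

test_that("the two census rules classify the canonical architectures", {
  reg <- test_registry()
  prot <- list(protein_id = "p", genome_id = "g")
  # DNA-binding domain + 1 TM -> plain single-pass TTR
  r <- classify_protein(prot, make_hits("HTH_1"), profile_with(1L), reg)
  expect_true(r$is_ttr); expect_false(r$is_hybrid)
  expect_equal(r$pass_class, "single_pass")
  # + response regulator receiver domain -> hybrid
  r2 <- classify_protein(prot, make_hits(c("HTH_1", "Response_reg")),
                         profile_with(1L), reg)
  expect_true(r2$is_ttr); expect_true(r2$is_hybrid)
  # receiver domain alone: rule (i) fails however many TM regions
  r3 <- classify_protein(prot, make_hits("Response_reg"), profile_with(2L), reg)
  expect_false(r3$is_ttr); expect_false(r3$is_hybrid)
  expect_true(r3$is_st)  # still a signal-transduction protein
  # DNA-binding but soluble: rule (ii) fails
  r4 <- classify_protein(prot, make_hits("HTH_1"), profile_with(0L), reg)
  expect_false(r4$is_ttr)
  expect_equal(r4$pass_class, "none")
})

test_that("sensory domains are the non-DNA-binding hits", {
  reg <- test_registry()
  expect_equal(count_sensory_domains(make_hits("HTH_1"), reg), 0L)
  expect_equal(count_sensory_domains(make_hits(c("HTH_1", "Y_Y_Y", "HisKA")),
                                     reg), 2L)
  expect_equal(count_sensory_domains(make_hits(character()), reg), 0L)
  # tandem repeats count multiply by default, once with distinct = TRUE
  h <- make_hits(c("HTH_1", "Y_Y_Y", "Y_Y_Y"))
  expect_equal(count_sensory_domains(h, reg), 2L)
  expect_equal(count_sensory_domains(h, reg, distinct = TRUE), 1L)
})

test_that("classification matches the brute-force rules on random architectures", {
  reg <- test_registry()
  set.seed(42)
  prot <- list(protein_id = "p", genome_id = "g")
  for (i in 1:400) {
    arch <- random_architecture(reg)
    r <- classify_protein(prot, arch$hits, profile_with(arch$n_tm), reg)
    o <- oracle_classify(arch$models, arch$n_tm, reg)
    expect_identical(r$is_ttr, o$is_ttr)
    expect_identical(r$is_hybrid, o$is_hybrid)
    expect_identical(r$is_st, o$is_st)
    expect_identical(r$pass_class, o$pass_class)
    # record invariants
    expect_true(!r$is_hybrid || r$is_ttr)
    expect_true(!r$is_ttr || (r$has_dna_binding && r$n_tm >= 1L))
    expect_true(!r$is_ttr || r$is_st)
    expect_identical(r$pass_class == "none", r$n_tm == 0L)
    # permutation invariance of the hit list
    if (nrow(arch$hits) > 1L) {
      perm <- arch$hits[sample.int(nrow(arch$hits)), ]
      r2 <- classify_protein(prot, perm, profile_with(arch$n_tm), reg)
      expect_identical(r2, r)
    }
  }
})

test_that("enlarging the DNA-binding registry never decreases the TTR count", {
  base <- registry(dna_binding = "HTH_1",
                   st_membership = c("GGDEF", "Y_Y_Y"))
  wider <- registry(dna_binding = c("HTH_1", "LytTR", "GerE"),
                    st_membership = c("GGDEF", "Y_Y_Y"))
  set.seed(7)
  for (i in 1:30) {
    arch <- random_architecture(wider)
    prot <- list(protein_id = "p", genome_id = "g")
    r_base <- classify_protein(prot, arch$hits, profile_with(arch$n_tm), base)
    r_wide <- classify_protein(prot, arch$hits, profile_with(arch$n_tm), wider)
    expect_gte(r_wide$is_ttr, r_base$is_ttr)
  }
})

test_that("cohort classification satisfies the subset chain", {
  d <- file.path(tempdir(), "chain-fixture")
  gen <- generate_cohort(cohort_params(n_genomes = 6, seed = 13), d)
  reg <- load_registry()
  pr <- read_proteome_fasta(gen$paths$proteome)
  pmap <- read.delim(gen$paths$map, comment.char = "#")
  pr$genome_id <- pmap$genome_id[match(pr$protein_id, pmap$protein_id)]
  rec <- classify_cohort(pr, read_domain_hits(gen$paths$hits, "tsv"), reg,
                         read_tm_segments(gen$paths$tm))
  meta <- read_genome_meta(gen$paths$meta)
  for (g in meta$genome_id) {
    r <- rec[rec$genome_id == g, ]
    expect_lte(sum(r$is_hybrid), sum(r$is_ttr))
    expect_lte(sum(r$is_ttr), sum(r$is_st))
    expect_lte(sum(r$is_st), sum(r$is_st | r$has_dna_binding))
    expect_lte(nrow(r), meta$cds_total[meta$genome_id == g])
    # pass classes partition the TTR set
    ttrs <- r[r$is_ttr, ]
    expect_equal(sum(ttrs$pass_class == "single_pass") +
                   sum(ttrs$pass_class == "two_pass") +
                   sum(ttrs$pass_class == "multi_pass"), nrow(ttrs))
  }
})
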