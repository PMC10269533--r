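test_that("hydropathy predictor finds a single helix in a hydrophobic stretch", {
  p <- tm_params()
  # all-polar sequence: no window reaches the threshold
  expect_equal(nrow(predict_tm_regions(strrep("D", 100), p)), 0L)
  # sequence shorter than the window: no full window exists
  expect_equal(nrow(predict_tm_regions(strrep("L", 10), p)), 0L)
  # one Leu stretch between charged flanks: exactly one region covering it
  seqn <- paste0("EEEEE", strrep("L", 30), "KKKKK")
  reg <- predict_tm_regions(seqn, p)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg, oracle_tm_regions(seqn, p))
  # region covers the Leu core (window expansion may add flank residues)
  expect_lte(reg[1L, "start"], 6L + 9L)
  expect_gte(reg[1L, "end"], 35L - 9L)
})

test_that("predictor matches the brute-force window rule on random small sequences", {
  p <- tm_params()
  set.seed(101)
  alphabet <- c("L", "D", "G")
  for (i in 1:2000) {
    n <- sample(1:60, 1L)
    s <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
    expect_identical(predict_tm_regions(s, p), oracle_tm_regions(s, p))
  }
  # also with a narrow window / short min length so merging is exercised
  p2 <- tm_params(hydropathy_window = 5L, min_region_length = 5L,
                  merge_gap = 2L, hydropathy_threshold = 1.0)
  for (i in 1:2000) {
    n <- sample(1:60, 1L)
    s <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
    expect_identical(predict_tm_regions(s, p2), oracle_tm_regions(s, p2))
  }
})

test_that("surface area per residue pools region residues under the table", {
  tab <- default_area_table()
  # identity on a uniform region
  g20 <- strrep("G", 40)
  expect_equal(surface_area_per_aa(g20, cbind(start = 5L, end = 24L), tab),
               unclass(tab)[["G"]])
  # exact mean on equal halves, independent of region order
  s <- paste0(strrep("G", 10), strrep("D", 5), strrep("W", 10))
  reg <- cbind(start = c(1L, 16L), end = c(10L, 25L))
  expect_equal(surface_area_per_aa(s, reg, tab),
               (unclass(tab)[["G"]] + unclass(tab)[["W"]]) / 2)
  expect_equal(surface_area_per_aa(s, reg[2:1, ], tab),
               surface_area_per_aa(s, reg, tab))
  # residue-weighted pooling, not a mean of per-region means
  s2 <- paste0(strrep("G", 30), strrep("W", 10))
  reg2 <- cbind(start = c(1L, 31L), end = c(30L, 40L))
  expect_equal(surface_area_per_aa(s2, reg2, tab),
               (30 * unclass(tab)[["G"]] + 10 * unclass(tab)[["W"]]) / 40)
  expect_error(surface_area_per_aa(s2, cbind(start = integer(), end = integer()),
                                   tab),
               class = "ttr_no_tm_residues")
})

test_that("upgrading any TM residue strictly increases the score, within table bounds", {
  tab <- default_area_table()
  letters20 <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
  a <- unclass(tab)[letters20]
  set.seed(5)
  for (i in 1:50) {
    res <- sample(names(a), 25, replace = TRUE)
    s <- paste(res, collapse = "")
    reg <- cbind(start = 3L, end = 22L)
    sa <- surface_area_per_aa(s, reg, tab)
    expect_gte(sa, min(a))
    expect_lte(sa, max(a))
    # replace one in-region residue by one with a strictly larger constant
    pos <- sample(3:22, 1L)
    bigger <- names(a)[a > a[[substr(s, pos, pos)]]]
    if (length(bigger)) {
      s2 <- s
      substr(s2, pos, pos) <- sample(bigger, 1L)
      expect_gt(surface_area_per_aa(s2, reg, tab), sa)
    }
  }
})

test_that("raft propensity is inclusive at the threshold", {
  p <- tm_params()
  expect_true(raft_propensity(172, p))
  expect_false(raft_propensity(172.01, p))
  expect_true(raft_propensity(100, p))
  expect_error(raft_propensity(NaN, p), class = "ttr_bad_param")
})

test_that("TM profiles aggregate count, length and geometry; empty case is absent", {
  tab <- default_area_table()
  p <- tm_params()
  s <- strrep("L", 60)
  pr1 <- tm_profile(s, cbind(start = 7L, end = 29L), p, tab)
  expect_equal(pr1$n_regions, 1L)
  expect_equal(pr1$mean_length, 23)
  pr2 <- tm_profile(s, cbind(start = c(1L, 31L), end = c(20L, 50L)), p, tab)
  expect_equal(pr2$mean_length, 20)
  expect_equal(pr2$sa_per_aa, unclass(tab)[["L"]])  # uniform composition
  pr0 <- tm_profile(s, cbind(start = integer(), end = integer()), p, tab)
  expect_equal(pr0$n_regions, 0L)
  expect_true(is.na(pr0$sa_per_aa) && is.na(pr0$raft_flag) &&
                is.na(pr0$mean_length))
  expect_error(tm_profile(s, cbind(start = 50L, end = 70L), p, tab),
               class = "ttr_bad_interval")
})

test_that("supplied TM segments take precedence over the predictor", {
  # a sequence whose hydrophobic stretch the predictor would find, but the
  # supplied file says otherwise: profiles must follow the file verbatim
  reg <- test_registry()
  seqn <- paste0(strrep("D", 20), strrep("L", 30), strrep("K", 20))
  pr <- data.frame(protein_id = "p1", sequence = seqn, length = nchar(seqn),
                   genome_id = "g1", stringsAsFactors = FALSE)
  hits <- data.frame(protein_id = "p1", model_name = "HTH_1",
                     model_accession = "", env_from = 1L, env_to = 15L,
                     bit_score = 50, i_evalue = 1e-10, stringsAsFactors = FALSE)
  supplied <- list(p1 = cbind(start = 25L, end = 44L))
  rec <- classify_cohort(pr, hits, reg, tm_segments = supplied,
                         table = default_area_table())
  expect_equal(rec$n_tm, 1L)
  expect_equal(rec$mean_tm_length, 20)
  expect_equal(rec$sa_per_aa, unclass(default_area_table())[["L"]])
  # an empty map entry means: no TM, even though the predictor would fire
  rec2 <- classify_cohort(pr, hits, reg,
                          tm_segments = list(p1 = cbind(start = integer(),
                                                        end = integer())),
                          table = default_area_table())
  expect_equal(rec2$n_tm, 0L)
  expect_false(rec2$is_ttr)
})
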