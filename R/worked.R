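# A fixed 10-protein toy genome used throughout the documentation and
# tests.  Hand-tallied summary: cds_total 10; 3 ST proteins; 2 TTRs (one
# single-pass plain, one two-pass hybrid); 1 hybrid; 3 proteins with a
# DNA-binding domain; so ratio_ttr_cds = 0.2, ratio_ttr_st = 2/3,
# ratio_st_cds = 0.3.

WORKED_FLANK40 <- strrep("DEKRQNSTEG", 4L)

worked_proteins <- function() {
  c20 <- strrep("GDERKNSTQE", 2L)
  c50 <- strrep("GDERKNSTQE", 5L)
  loop18 <- strrep("DKESQT", 3L)
  tm_low <- strrep("AVI", 7L)    # low-surface-area TM helix (21 aa)
  tm_high <- strrep("LFM", 7L)   # high-surface-area TM helix (21 aa)
  tm_mid <- strrep("LVA", 7L)
  list(
    ttrA = paste0(WORKED_FLANK40, tm_low, c20),                  # 81 aa
    ttrB = paste0(WORKED_FLANK40, tm_high, loop18, tm_high, c50), # 150 aa
    stC = strrep("DEKRQNSTEG", 8L),
    tfD = strrep("GDERKNSTQE", 9L),
    memE = paste0(strrep("DKESQTNGRE", 2L), tm_mid, strrep("DKESQTNGRE", 2L)),
    pf1 = strrep("DKESQTNGRE", 6L),
    pf2 = strrep("QERSTDNKGE", 7L),
    pf3 = strrep("NDSTEKQRGE", 8L),
    pf4 = strrep("TESDKQNRGE", 9L),
    pf5 = strrep("EKDQSTNRGE", 10L))
}

#' Generate the worked 10-protein toy genome
#'
#' Writes a fixed, versioned fixture into `dir`: genome `g_demo` with
#' `cds_total` 10, containing 3 signal-transduction proteins and 2 TTRs
#' (`ttrA`, a single-pass TTR with a low-surface-area helix; `ttrB`, a
#' two-pass hybrid carrying a `Response_reg` core domain), one soluble
#' regulator, one membrane protein without domains, and five plain
#' proteins.  The same file formats as [generate_cohort()] are produced,
#' including the ground-truth table; output is deterministic.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the `ground_truth`
#'   data.frame.
#' @export
generate_worked_genome <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prot <- worked_proteins()
  gid <- "g_demo"
  ids <- paste0(gid, "_", names(prot))
  names(prot) <- ids

  hit <- function(pid, model, from, to, score, ie) {
    data.frame(protein_id = pid, model_name = model, model_accession = "",
               env_from = from, env_to = to, bit_score = score, i_evalue = ie,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(
    hit("g_demo_ttrA", "HTH_1", 4L, 36L, 75.2, 1e-20),
    hit("g_demo_ttrB", "LytTR", 4L, 36L, 88.1, 1e-24),
    hit("g_demo_ttrB", "Response_reg", 105L, 140L, 60.3, 1e-15),
    hit("g_demo_stC", "GGDEF", 8L, 52L, 45.0, 1e-12),
    hit("g_demo_tfD", "HTH_1", 5L, 40L, 52.7, 1e-14))

  tm_lines <- c(
    "g_demo_ttrA\tsynthTM\tTMhelix\t41\t61",
    "g_demo_ttrB\tsynthTM\tTMhelix\t41\t61",
    "g_demo_ttrB\tsynthTM\tTMhelix\t80\t100",
    "g_demo_memE\tsynthTM\tTMhelix\t21\t41",
    "g_demo_stC\tsynthTM\tinside\t1\t80")

  meta <- data.frame(
    genome_id = gid,
    taxonomy = "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__;f__;g__;s__",
    cds_total = 10L, stringsAsFactors = FALSE)

  truth <- data.frame(
    protein_id = ids,
    genome_id = gid,
    role = c("ttr", "ttr", "st", "tf", "bg", "bg", "bg", "bg", "bg", "bg"),
    is_ttr = c(TRUE, TRUE, rep(FALSE, 8L)),
    is_hybrid = c(FALSE, TRUE, rep(FALSE, 8L)),
    is_st = c(TRUE, TRUE, TRUE, rep(FALSE, 7L)),
    n_tm = c(1L, 2L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    sa_stratum = c("low", "high", "none", "none", "low", rep("none", 5L)),
    n_sensory = c(0L, 1L, 1L, 0L, 0L, rep(0L, 5L)),
    stringsAsFactors = FALSE)

  paths <- list(proteome = file.path(dir, "proteome.faa"),
                hits = file.path(dir, "domain_hits.tsv"),
                tm = file.path(dir, "tm_segments.txt"),
                meta = file.path(dir, "genome_meta.tsv"),
                map = file.path(dir, "protein_map.tsv"),
                truth = file.path(dir, "ground_truth.tsv"))
  aa <- Biostrings::AAStringSet(unlist(prot))
  Biostrings::writeXStringSet(aa, paths$proteome)
  write_domain_hits(hits, paths$hits)
  writeLines(tm_lines, paths$tm)
  write_tsv(meta, paths$meta)
  write_tsv(truth[, c("protein_id", "genome_id")], paths$map)
  write_tsv(truth, paths$truth)
  invisible(list(paths = paths, ground_truth = truth))
}
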