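# Synthetic cohorts: fully self-contained proteome FASTA, domain-hit TSV,
# TM-segment file and genome metadata with the statistical structure the
# census assumes, plus a ground-truth table so tests are oracle-based.
# Sequences outside TM segments are drawn from a soluble-residue pool;
# TM segments are hydrophobic mixtures whose composition is steered (and,
# if sampling noise lands it on the wrong side, nudged residue-by-residue)
# into the intended surface-area stratum under the calibrated area table,
# so the supplied-segment and hydropathy-predictor paths agree on these
# fixtures.

# residue pools: soluble flanks are polar/charged (window hydropathy well
# below the predictor threshold); TM pools are hydrophobic on the
# Kyte-Doolittle scale but differ in per-residue surface area.
SOLUBLE_POOL <- c(D = 0.10, E = 0.11, K = 0.10, R = 0.09, N = 0.08, Q = 0.08,
                  S = 0.12, T = 0.10, G = 0.09, P = 0.07, H = 0.04, Y = 0.02)
TM_LOW_POOL <- c("A", "V", "I", "C")   # small side chains -> low area
TM_HIGH_POOL <- c("L", "F", "M")       # bulky side chains -> high area

SENSORY_MODELS <- c("Y_Y_Y", "PAS", "GAF", "Cache_1", "dCache_1", "CHASE",
                    "sCache_2", "MASE1", "HAMP", "Peripla_BP_6")
ST_ONLY_MODELS <- c("MCPsignal", "GGDEF", "EAL", "HD", "PilZ", "HisKA",
                    "PAS", "GAF")

#' Parameters of a synthetic cohort
#'
#' Defaults reflect the census conditions the generator emulates:
#' log-normal per-genome CDS counts; a signal-transduction protein
#' fraction of 9% (bacteria) / 6% (archaea) of CDS; a TTR fraction of
#' 0.15% / 0.13% of CDS; 8.2% hybrid TTRs among bacterial TTRs (hybrids
#' are essentially absent in archaea, default 1.3%); a TM-count mix of
#' 56% single-pass, 17% two-pass and 27% with three or more TM regions
#' (the multi-pass tail is 3 plus a geometric draw, capped at 22); and
#' 43% of TTRs composed to score at or below the raft threshold.
#'
#' @param n_genomes Number of genomes (default 500).
#' @param seed Master seed; drives a per-genome seed sequence so cohorts
#'   are reproducible under parallel generation.
#' @param taxon_layout Data.frame with columns `phylum`, `class`,
#'   `superkingdom`, `weight`; genome counts follow the weights.
#' @param cds_meanlog,cds_sdlog Named (`bacteria`, `archaea`) log-normal
#'   parameters of the per-genome CDS count.
#' @param st_fraction,ttr_fraction,hybrid_fraction Named per-superkingdom
#'   fractions (of CDS, of CDS, and of TTRs respectively).
#' @param tm_count_probs Probabilities of the 1 / 2 / >=3 TM classes.
#' @param tm_geom_p Geometric parameter of the multi-pass tail.
#' @param tm_count_cap Maximum TM regions per TTR (default 22).
#' @param sa_low_fraction Fraction of TTRs composed into the low
#'   surface-area (raft) stratum.
#' @param sensory_mean Named (`raft`, `non_raft`) Poisson means of the
#'   sensory-domain count per TTR.
#' @param soluble_tf_fraction Fraction of CDS given a DNA-binding domain
#'   but no TM region (token rate; supports the DNA-binding-total count).
#' @param background_per_genome Plain proteins with no hits per genome.
#' @return A validated `ttr_cohort_params` list.
#' @export
cohort_params <- function(n_genomes = 500L,
                          seed = 1L,
                          taxon_layout = default_taxon_layout(),
                          cds_meanlog = c(bacteria = log(3000), archaea = log(2200)),
                          cds_sdlog = c(bacteria = 0.40, archaea = 0.35),
                          st_fraction = c(bacteria = 0.09, archaea = 0.06),
                          ttr_fraction = c(bacteria = 0.0015, archaea = 0.0013),
                          hybrid_fraction = c(bacteria = 0.082, archaea = 0.013),
                          tm_count_probs = c(single = 0.56, two = 0.17, multi = 0.27),
                          tm_geom_p = 0.5,
                          tm_count_cap = 22L,
                          sa_low_fraction = 0.43,
                          sensory_mean = c(raft = 0.5, non_raft = 1.2),
                          soluble_tf_fraction = 0.005,
                          background_per_genome = 2L) {
  ttr_assert(is_count(n_genomes, 1L), "ttr_bad_param",
             "n_genomes must be a positive count")
  ttr_assert(is_count(seed, 0L) && seed < 2^31, "ttr_bad_param",
             "seed must be a non-negative 32-bit integer")
  for (nm in c("st_fraction", "ttr_fraction", "hybrid_fraction")) {
    v <- get(nm)
    ttr_assert(all(c("bacteria", "archaea") %in% names(v)) &&
                 all(v >= 0 & v <= 1), "ttr_bad_param",
               "%s must be named per-superkingdom fractions in [0,1]", nm)
  }
  ttr_assert(all(ttr_fraction[names(st_fraction)] <= st_fraction),
             "ttr_infeasible_params",
             "infeasible: ttr_fraction exceeds st_fraction")
  ttr_assert(abs(sum(tm_count_probs) - 1) < 1e-8 && all(tm_count_probs >= 0),
             "ttr_bad_param", "tm_count_probs must sum to 1")
  ttr_assert(sa_low_fraction >= 0 && sa_low_fraction <= 1, "ttr_bad_param",
             "sa_low_fraction must be in [0,1]")
  ttr_assert(is_count(tm_count_cap, 3L), "ttr_bad_param",
             "tm_count_cap must be a count >= 3")
  ttr_assert(soluble_tf_fraction >= 0 && soluble_tf_fraction <= 1,
             "ttr_bad_param", "soluble_tf_fraction must be in [0,1]")
  ttr_assert(all(c("phylum", "class", "superkingdom", "weight") %in%
                   names(taxon_layout)), "ttr_bad_param",
             "taxon_layout needs phylum, class, superkingdom, weight columns")
  structure(list(n_genomes = as.integer(n_genomes), seed = as.integer(seed),
                 taxon_layout = taxon_layout, cds_meanlog = cds_meanlog,
                 cds_sdlog = cds_sdlog, st_fraction = st_fraction,
                 ttr_fraction = ttr_fraction, hybrid_fraction = hybrid_fraction,
                 tm_count_probs = tm_count_probs, tm_geom_p = tm_geom_p,
                 tm_count_cap = as.integer(tm_count_cap),
                 sa_low_fraction = sa_low_fraction, sensory_mean = sensory_mean,
                 soluble_tf_fraction = soluble_tf_fraction,
                 background_per_genome = as.integer(background_per_genome)),
            class = "ttr_cohort_params")
}

#' Default taxon layout for synthetic cohorts
#'
#' A mix of common bacterial phylum;class groups plus a small archaeal
#' contingent (~7% of genomes), with a few groups kept under 10 genomes at
#' the default cohort size so the minimum-genome rule is exercised.
#'
#' @return A data.frame with columns `phylum`, `class`, `superkingdom`,
#'   `weight`.
#' @export
default_taxon_layout <- function() {
  data.frame(
    phylum = c("Pseudomonadota", "Pseudomonadota", "Bacillota", "Bacillota",
               "Bacteroidota", "Actinomycetota", "Actinomycetota",
               "Spirochaetota", "Campylobacterota", "Verrucomicrobiota",
               "Methanobacteriota", "Halobacteriota", "Thermoproteota"),
    class = c("Gammaproteobacteria", "Alphaproteobacteria", "Bacilli",
              "Clostridia", "Bacteroidia", "Actinomycetes", "Coriobacteriia",
              "Leptospirae", "Campylobacteria", "Verrucomicrobiae",
              "Methanobacteria", "Methanomicrobia", "Thermoproteia"),
    superkingdom = c(rep("bacteria", 10L), rep("archaea", 3L)),
    weight = c(110, 60, 80, 50, 60, 60, 20, 12, 12, 4, 12, 12, 8),
    stringsAsFactors = FALSE)
}

sample_soluble <- function(n) {
  if (n == 0L) return("")
  paste(sample(names(SOLUBLE_POOL), n, replace = TRUE, prob = SOLUBLE_POOL),
        collapse = "")
}

# Compose m TM residues whose mean calibrated area lands in the requested
# stratum: mixture weight chosen to aim at a target mean, then single
# residues swapped toward the extreme pool member until the stratum is met.
compose_tm_residues <- function(m, raft, areas, threshold) {
  mean_low <- mean(areas[TM_LOW_POOL])
  mean_high <- mean(areas[TM_HIGH_POOL])
  target <- if (raft) runif(1L, threshold - 22, threshold - 4)
            else runif(1L, threshold + 4, threshold + 28)
  w <- (mean_high - target) / (mean_high - mean_low)
  w <- min(1, max(0, w))
  from_low <- runif(m) < w
  res <- character(m)
  res[from_low] <- sample(TM_LOW_POOL, sum(from_low), replace = TRUE)
  res[!from_low] <- sample(TM_HIGH_POOL, sum(!from_low), replace = TRUE)
  repeat {
    sa <- mean(areas[res])
    if (raft && sa <= threshold) break
    if (!raft && sa > threshold) break
    if (raft) {
      cand <- which(res != "A")
      res[sample(cand, 1L)] <- "A"
    } else {
      cand <- which(res != "F")
      res[sample(cand, 1L)] <- "F"
    }
  }
  res
}

draw_tm_count <- function(params) {
  cls <- sample.int(3L, 1L, prob = params$tm_count_probs)
  if (cls < 3L) return(cls)
  min(3L + rgeom(1L, params$tm_geom_p), params$tm_count_cap)
}

# Build one TTR: sequence, TM intervals, domain hits, truth row.
build_ttr <- function(pid, gid, params, registry, areas, threshold, sk) {
  raft <- runif(1L) < params$sa_low_fraction
  hybrid <- runif(1L) < params$hybrid_fraction[[sk]]
  n_tm <- draw_tm_count(params)
  tm_len <- pmin(pmax(round(rnorm(n_tm, 22, 2)), 19L), 28L)
  n_sens <- rpois(1L, params$sensory_mean[[if (raft) "raft" else "non_raft"]])
  if (hybrid && n_sens == 0L) n_sens <- 1L
  # layout: N-flank | TM (loop TM)* | C-flank with one 30-residue slot per
  # sensory domain
  nflank <- 40L
  loop <- 18L
  cflank <- 30L + 30L * n_sens
  tm_res <- compose_tm_residues(sum(tm_len), raft, areas, threshold)
  starts <- integer(n_tm); ends <- integer(n_tm)
  pieces <- character(0L)
  pos <- nflank
  off <- 0L
  pieces <- sample_soluble(nflank)
  for (k in seq_len(n_tm)) {
    if (k > 1L) {
      pieces <- c(pieces, sample_soluble(loop))
      pos <- pos + loop
    }
    starts[k] <- pos + 1L
    ends[k] <- pos + tm_len[k]
    pieces <- c(pieces, paste(tm_res[(off + 1L):(off + tm_len[k])],
                              collapse = ""))
    off <- off + tm_len[k]
    pos <- pos + tm_len[k]
  }
  pieces <- c(pieces, sample_soluble(cflank))
  seqn <- paste(pieces, collapse = "")
  c_start <- pos + 1L

  dna_model <- sample(registry$dna_binding, 1L)
  hit <- function(model, from, to) {
    data.frame(protein_id = pid, model_name = model,
               model_accession = "", env_from = from, env_to = to,
               bit_score = round(runif(1L, 30, 160), 1L),
               i_evalue = signif(10^runif(1L, -30, -8), 3L),
               stringsAsFactors = FALSE)
  }
  hits <- hit(dna_model, 4L, 36L)
  if (n_sens > 0L) {
    sens_pool <- setdiff(SENSORY_MODELS, registry$dna_binding)
    sens_models <- sample(sens_pool, n_sens, replace = TRUE)
    if (hybrid) sens_models[1L] <- sample(registry$tcs_core, 1L)
    for (k in seq_len(n_sens)) {
      s0 <- c_start + 30L * (k - 1L) + 2L
      hits <- rbind(hits, hit(sens_models[k], s0, s0 + 24L))
    }
  }
  list(sequence = seqn, tm = cbind(start = starts, end = ends), hits = hits,
       truth = data.frame(protein_id = pid, genome_id = gid, role = "ttr",
                          is_ttr = TRUE, is_hybrid = hybrid, is_st = TRUE,
                          n_tm = n_tm,
                          sa_stratum = if (raft) "low" else "high",
                          n_sensory = n_sens, stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort on disk
#'
#' Writes `proteome.faa`, `domain_hits.tsv` (TSV dialect),
#' `tm_segments.txt` (TMHMM-style long format), `genome_meta.tsv` and
#' `ground_truth.tsv` into `dir`.  Every generated TTR carries at least
#' one DNA-binding hit and one TM segment (hybrids additionally a
#' two-component core hit); non-TTR signal-transduction proteins carry
#' ST-marker hits only; soluble regulators carry a DNA-binding hit but no
#' TM segment.  Regeneration with identical parameters and seed is
#' byte-identical.
#'
#' @param params A [cohort_params()] object.
#' @param dir Output directory (created if needed).
#' @param registry A `ttr_registry` supplying the model pools.
#' @param table Calibrated `ttr_area_table` used to steer TM composition.
#' @param tm_params_obj [tm_params()] supplying the raft threshold.
#' @return Invisibly, a list with the five file `paths` and the
#'   `ground_truth` data.frame.
#' @export
generate_cohort <- function(params = cohort_params(), dir,
                            registry = load_registry(),
                            table = read_area_table(),
                            tm_params_obj = tm_params()) {
  ttr_assert(inherits(params, "ttr_cohort_params"), "ttr_bad_param",
             "params must come from cohort_params()")
  ttr_assert(all(params$ttr_fraction <= params$st_fraction),
             "ttr_infeasible_params",
             "infeasible: ttr_fraction exceeds st_fraction")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  areas <- unclass(table)
  threshold <- tm_params_obj$raft_threshold

  set.seed(params$seed)
  gseeds <- sample.int(2147483646L, params$n_genomes, replace = TRUE)
  layout <- params$taxon_layout
  n_per_taxon <- diff(round(cumsum(c(0, layout$weight)) /
                              sum(layout$weight) * params$n_genomes))
  taxon_of <- rep(seq_len(nrow(layout)), n_per_taxon)
  # round-off: pad/trim against the largest group
  while (length(taxon_of) < params$n_genomes) {
    taxon_of <- c(taxon_of, which.max(layout$weight))
  }
  taxon_of <- sort(taxon_of[seq_len(params$n_genomes)])

  fasta_ids <- vector("list", params$n_genomes)
  fasta_seqs <- vector("list", params$n_genomes)
  hit_tabs <- vector("list", params$n_genomes)
  tm_lines <- vector("list", params$n_genomes)
  truth_tabs <- vector("list", params$n_genomes)
  meta <- data.frame(genome_id = character(params$n_genomes),
                     taxonomy = character(params$n_genomes),
                     cds_total = integer(params$n_genomes),
                     stringsAsFactors = FALSE)

  for (g in seq_len(params$n_genomes)) {
    set.seed(gseeds[g])
    lay <- layout[taxon_of[g], ]
    sk <- lay$superkingdom
    gid <- sprintf("G%04d", g)
    cds <- max(500L, as.integer(round(rlnorm(1L, params$cds_meanlog[[sk]],
                                             params$cds_sdlog[[sk]]))))
    n_ttr <- rbinom(1L, cds, params$ttr_fraction[[sk]])
    n_st <- max(rbinom(1L, cds, params$st_fraction[[sk]]), n_ttr)
    n_st_only <- n_st - n_ttr
    n_tf <- rbinom(1L, cds, params$soluble_tf_fraction)
    n_bg <- params$background_per_genome
    n_prot <- n_ttr + n_st_only + n_tf + n_bg
    cds <- max(cds, n_prot)

    ids <- character(n_prot); seqs <- character(n_prot)
    hits_g <- list(); tml_g <- character(0L); truth_g <- list()
    p <- 0L
    for (t in seq_len(n_ttr)) {
      p <- p + 1L
      ids[p] <- sprintf("%s_ttr%03d", gid, t)
      b <- build_ttr(ids[p], gid, params, registry, areas, threshold, sk)
      seqs[p] <- b$sequence
      hits_g[[length(hits_g) + 1L]] <- b$hits
      tml_g <- c(tml_g, sprintf("%s\tsynthTM\tTMhelix\t%d\t%d", ids[p],
                                b$tm[, "start"], b$tm[, "end"]))
      truth_g[[length(truth_g) + 1L]] <- b$truth
    }
    other <- n_st_only + n_tf + n_bg
    if (other > 0L) {
      lens <- sample(60:120, other, replace = TRUE)
      big <- sample(names(SOLUBLE_POOL), sum(lens), replace = TRUE,
                    prob = SOLUBLE_POOL)
      stops <- cumsum(lens)
      bigseq <- paste(big, collapse = "")
      osets <- substring(bigseq, c(1L, stops[-other] + 1L), stops)
      roles <- c(rep("st", n_st_only), rep("tf", n_tf), rep("bg", n_bg))
      oids <- sprintf("%s_%s%04d", gid, roles, seq_len(other))
      ids[p + seq_len(other)] <- oids
      seqs[p + seq_len(other)] <- osets
      p <- p + other
      with_hit <- roles != "bg"
      if (any(with_hit)) {
        mdl <- character(other)
        mdl[roles == "st"] <- sample(ST_ONLY_MODELS, n_st_only, replace = TRUE)
        mdl[roles == "tf"] <- sample(registry$dna_binding, n_tf, replace = TRUE)
        hits_g[[length(hits_g) + 1L]] <- data.frame(
          protein_id = oids[with_hit], model_name = mdl[with_hit],
          model_accession = "",
          env_from = ifelse(roles[with_hit] == "st", 8L, 5L),
          env_to = pmin(ifelse(roles[with_hit] == "st", 52L, 40L),
                        lens[with_hit]),
          bit_score = round(runif(sum(with_hit), 25, 120), 1L),
          i_evalue = signif(10^runif(sum(with_hit), -25, -8), 3L),
          stringsAsFactors = FALSE)
      }
      truth_g[[length(truth_g) + 1L]] <- data.frame(
        protein_id = oids, genome_id = gid, role = roles,
        is_ttr = FALSE, is_hybrid = FALSE, is_st = roles == "st",
        n_tm = 0L, sa_stratum = "none",
        # a lone ST-marker hit is one non-DNA-binding (sensory) domain
        n_sensory = ifelse(roles == "st", 1L, 0L),
        stringsAsFactors = FALSE)
    }
    fasta_ids[[g]] <- ids
    fasta_seqs[[g]] <- seqs
    hit_tabs[[g]] <- if (length(hits_g)) do.call(rbind, hits_g) else empty_hits()
    tm_lines[[g]] <- tml_g
    truth_tabs[[g]] <- do.call(rbind, truth_g)
    meta$genome_id[g] <- gid
    meta$taxonomy[g] <- sprintf("d__%s;p__%s;c__%s;o__;f__;g__;s__",
                                if (sk == "bacteria") "Bacteria" else "Archaea",
                                lay$phylum, lay$class)
    meta$cds_total[g] <- cds
  }

  paths <- list(proteome = file.path(dir, "proteome.faa"),
                hits = file.path(dir, "domain_hits.tsv"),
                tm = file.path(dir, "tm_segments.txt"),
                meta = file.path(dir, "genome_meta.tsv"),
                map = file.path(dir, "protein_map.tsv"),
                truth = file.path(dir, "ground_truth.tsv"))
  aa <- Biostrings::AAStringSet(setNames(unlist(fasta_seqs), unlist(fasta_ids)))
  Biostrings::writeXStringSet(aa, paths$proteome)
  write_domain_hits(do.call(rbind, hit_tabs), paths$hits)
  writeLines(unlist(tm_lines), paths$tm)
  write_tsv(meta, paths$meta)
  truth <- do.call(rbind, truth_tabs)
  write_tsv(truth[, c("protein_id", "genome_id")], paths$map)
  write_tsv(truth, paths$truth)
  invisible(list(paths = paths, ground_truth = truth))
}
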