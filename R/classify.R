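# Classification rules.  A transmembrane transcription regulator (TTR) is
# a protein with (i) at least one DNA-binding domain and (ii) at least one
# transmembrane region; a hybrid TTR additionally carries one or more
# two-component core domains (Response_reg, HATPase_c, HisKA).

PASS_CLASSES <- c("none", "single_pass", "two_pass", "multi_pass")

pass_class_of <- function(n_regions) {
  # 0 TM -> none; 1 -> single_pass; 2 -> two_pass; >= 3 -> multi_pass
  cut_idx <- pmin(n_regions, 3L) + 1L
  PASS_CLASSES[cut_idx]
}

#' Resolve overlapping domain hits on one protein
#'
#' Greedy selection by descending bit score: a candidate hit is kept iff
#' its envelope overlaps every already-kept hit by at most `max_overlap`
#' residues.  This tolerates fuzzy envelope boundaries while preventing
#' nested hits from double-counting.  Output is sorted by `env_from`.
#'
#' @param hits Hit data.frame (columns as from [read_domain_hits()]), all
#'   rows belonging to a single protein.
#' @param max_overlap Maximum tolerated pairwise overlap in residues
#'   (default 15).
#' @return The retained subset of `hits`, sorted by `env_from`.
#' @export
resolve_overlaps <- function(hits, max_overlap = 15L) {
  ttr_assert(is_count(max_overlap, 0L), "ttr_bad_param",
             "max_overlap must be a non-negative count")
  if (nrow(hits) <= 1L) return(hits[order(hits$env_from), , drop = FALSE])
  ttr_assert(length(unique(hits$protein_id)) == 1L, "ttr_bad_param",
             "resolve_overlaps expects hits of a single protein")
  # stable order: score desc, then input order for ties
  o <- order(-hits$bit_score, seq_len(nrow(hits)))
  kept <- integer()
  for (i in o) {
    ov <- vapply(kept, function(j) {
      min(hits$env_to[i], hits$env_to[j]) -
        max(hits$env_from[i], hits$env_from[j]) + 1L
    }, integer(1L))
    if (all(ov <= max_overlap)) kept <- c(kept, i)
  }
  hits[kept[order(hits$env_from[kept], kept)], , drop = FALSE]
}

#' Count sensory (non-DNA-binding) domains
#'
#' The number of resolved hits whose model is not in the registry's
#' DNA-binding set.  Tandem repeats of one model count multiply by
#' default; set `distinct = TRUE` to count distinct models instead.
#'
#' @param hits Resolved hit data.frame for one protein.
#' @param registry A `ttr_registry`.
#' @param distinct Count distinct sensory models rather than hits.
#' @return Non-negative integer count.
#' @export
count_sensory_domains <- function(hits, registry, distinct = FALSE) {
  sens <- hits$model_name[!(hits$model_name %in% registry$dna_binding)]
  if (distinct) length(unique(sens)) else length(sens)
}

#' Classify one protein
#'
#' Applies the census rules to one protein's resolved domain hits and TM
#' profile: `has_dna_binding` iff at least one hit is in the registry's
#' DNA-binding set; `is_ttr` iff it has a DNA-binding domain and at least
#' one TM region; `is_hybrid` iff it is a TTR that also carries a
#' two-component core domain; `is_st` iff it carries an ST-marker model or
#' is a TTR (so TTRs are a subset of ST proteins).  The pass class is
#' `single_pass` (1 TM), `two_pass` (2) or `multi_pass` (>= 3); `none` for
#' proteins without TM regions.
#'
#' @param protein One-row protein record (needs `protein_id`; a
#'   `genome_id` column is carried through if present).
#' @param hits Resolved hit data.frame for this protein (possibly empty).
#' @param profile A `ttr_tm_profile` for this protein.
#' @param registry A `ttr_registry`.
#' @param distinct_sensory Passed to [count_sensory_domains()].
#' @return A one-row data.frame (class `ttr_record`) with columns
#'   `protein_id`, `genome_id`, `is_ttr`, `is_hybrid`, `is_st`,
#'   `has_dna_binding`, `pass_class`, `n_tm`, `n_sensory_domains`,
#'   `mean_tm_length`, `sa_per_aa`, `raft_flag`, `dna_binding_models`
#'   (semicolon-joined).
#' @export
classify_protein <- function(protein, hits, profile, registry,
                             distinct_sensory = FALSE) {
  models <- hits$model_name
  has_dna <- any(models %in% registry$dna_binding)
  n_tm <- profile$n_regions
  is_ttr <- has_dna && n_tm >= 1L
  is_hybrid <- is_ttr && any(models %in% registry$tcs_core)
  is_st <- any(models %in% registry$st_membership) || is_ttr
  rec <- data.frame(
    protein_id = protein$protein_id,
    genome_id = if (!is.null(protein$genome_id)) protein$genome_id else NA_character_,
    is_ttr = is_ttr, is_hybrid = is_hybrid, is_st = is_st,
    has_dna_binding = has_dna,
    pass_class = pass_class_of(n_tm),
    n_tm = n_tm,
    n_sensory_domains = count_sensory_domains(hits, registry, distinct_sensory),
    mean_tm_length = profile$mean_length,
    sa_per_aa = profile$sa_per_aa,
    raft_flag = profile$raft_flag,
    dna_binding_models = paste(sort(unique(models[models %in% registry$dna_binding])),
                               collapse = ";"),
    stringsAsFactors = FALSE)
  class(rec) <- c("ttr_record", class(rec))
  rec
}

#' Classify a cohort of proteins
#'
#' Vectorized driver over [classify_protein()]'s rules for whole proteome
#' tables.  TM regions come from `tm_segments` when supplied (a supplied
#' segment file is authoritative for the whole cohort: proteins absent
#' from it are treated as having no TM region and the predictor is never
#' consulted); otherwise [predict_tm_regions()] is run on every sequence.
#'
#' @param proteins Protein data.frame from [read_proteome_fasta()], plus a
#'   `genome_id` column.
#' @param hits Hit data.frame from [read_domain_hits()] (cohort-wide).
#' @param registry A `ttr_registry`.
#' @param tm_segments Named list from [read_tm_segments()], or `NULL` to
#'   use the hydropathy predictor.
#' @param params A [tm_params()] object.
#' @param table A `ttr_area_table`.
#' @param max_overlap Passed to [resolve_overlaps()].
#' @param distinct_sensory Passed to [count_sensory_domains()].
#' @return A data.frame with one `ttr_record` row per protein, in input
#'   order.
#' @export
classify_cohort <- function(proteins, hits, registry, tm_segments = NULL,
                            params = tm_params(), table = read_area_table(),
                            max_overlap = 15L, distinct_sensory = FALSE) {
  ttr_assert(!is.null(proteins$genome_id), "ttr_bad_param",
             "proteins table must carry a genome_id column")
  n <- nrow(proteins)
  unknown <- setdiff(unique(hits$protein_id), proteins$protein_id)
  ttr_assert(length(unknown) == 0L, "ttr_unknown_protein",
             "domain hits reference unknown protein(s): %s",
             paste(head(unknown, 3L), collapse = ", "))

  # --- per-protein overlap resolution (only multi-hit proteins need it)
  hits <- hits[order(match(hits$protein_id, proteins$protein_id)), ,
               drop = FALSE]
  multi <- names(which(table(hits$protein_id) > 1L))
  if (length(multi)) {
    is_multi <- hits$protein_id %in% multi
    solo <- hits[!is_multi, , drop = FALSE]
    resolved <- lapply(split(hits[is_multi, , drop = FALSE],
                             hits$protein_id[is_multi]),
                       resolve_overlaps, max_overlap = max_overlap)
    hits <- rbind(solo, do.call(rbind, resolved))
  }

  # --- per-protein model-set predicates, vectorized over the hit table
  pid <- factor(hits$protein_id, levels = proteins$protein_id)
  zero <- integer(n)
  if (nrow(hits)) {
    in_dna <- hits$model_name %in% registry$dna_binding
    agg <- function(v) {
      s <- rowsum(v, pid, reorder = TRUE)  # rows follow factor levels present
      out <- zero
      out[match(rownames(s), proteins$protein_id)] <- s[, 1L]
      out
    }
    counts_dna <- agg(as.integer(in_dna))
    counts_core <- agg(as.integer(hits$model_name %in% registry$tcs_core))
    counts_st <- agg(as.integer(hits$model_name %in% registry$st_membership))
    if (distinct_sensory) {
      sens_hits <- hits[!in_dna, , drop = FALSE]
      cnt <- tapply(sens_hits$model_name, sens_hits$protein_id,
                    function(m) length(unique(m)))
      counts_sens <- zero
      counts_sens[match(names(cnt), proteins$protein_id)] <- as.integer(cnt)
    } else {
      counts_sens <- agg(as.integer(!in_dna))
    }
    dna_models <- rep("", n)
    dm <- tapply(hits$model_name[in_dna], hits$protein_id[in_dna],
                 function(m) paste(sort(unique(m)), collapse = ";"))
    dna_models[match(names(dm), proteins$protein_id)] <- dm
  } else {
    counts_dna <- counts_core <- counts_st <- counts_sens <- zero
    dna_models <- rep("", n)
  }

  # --- TM profiles
  n_tm <- zero
  mean_len <- rep(NA_real_, n)
  sa <- rep(NA_real_, n)
  if (is.null(tm_segments)) {
    for (i in seq_len(n)) {
      reg <- predict_tm_regions(proteins$sequence[i], params)
      n_tm[i] <- nrow(reg)
      if (nrow(reg)) {
        mean_len[i] <- mean(reg[, 2L] - reg[, 1L] + 1L)
        sa[i] <- surface_area_per_aa(proteins$sequence[i], reg, table)
      }
    }
  } else {
    idx <- match(names(tm_segments), proteins$protein_id)
    ttr_assert(!anyNA(idx), "ttr_unknown_protein",
               "TM segments reference unknown protein(s): %s",
               paste(head(names(tm_segments)[is.na(idx)], 3L), collapse = ", "))
    for (k in seq_along(tm_segments)) {
      reg <- tm_segments[[k]]
      i <- idx[k]
      validate_regions(proteins$sequence[i], reg)
      n_tm[i] <- nrow(reg)
      if (nrow(reg)) {
        mean_len[i] <- mean(reg[, 2L] - reg[, 1L] + 1L)
        sa[i] <- surface_area_per_aa(proteins$sequence[i], reg, table)
      }
    }
  }
  raft <- ifelse(is.na(sa), NA, sa <= params$raft_threshold)

  has_dna <- counts_dna > 0L
  is_ttr <- has_dna & n_tm >= 1L
  out <- data.frame(
    protein_id = proteins$protein_id,
    genome_id = proteins$genome_id,
    is_ttr = is_ttr,
    is_hybrid = is_ttr & counts_core > 0L,
    is_st = counts_st > 0L | is_ttr,
    has_dna_binding = has_dna,
    pass_class = pass_class_of(n_tm),
    n_tm = n_tm,
    n_sensory_domains = counts_sens,
    mean_tm_length = mean_len,
    sa_per_aa = sa,
    raft_flag = raft,
    dna_binding_models = dna_models,
    stringsAsFactors = FALSE)
  out
}
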