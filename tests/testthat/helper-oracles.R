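# Independent brute-force re-implementations used as oracles.  These are
# deliberately written as plain loops, sharing no code with the package
# internals they check.

# windowed-hydropathy rule, loop form
oracle_tm_regions <- function(sequence, params = tm_params()) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
          G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
          P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)
  res <- strsplit(sequence, "")[[1L]]
  n <- length(res)
  w <- params$hydropathy_window
  h <- (w - 1L) / 2L
  none <- cbind(start = integer(), end = integer())
  if (n < w) return(none)
  hot <- logical(n)
  for (c in (h + 1L):(n - h)) {
    s <- 0
    for (j in (c - h):(c + h)) s <- s + kd[[res[j]]]
    hot[c] <- (s / w) >= params$hydropathy_threshold - 1e-9
  }
  # maximal runs of hot centers, expanded to window extent
  regions <- NULL
  i <- 1L
  while (i <= n) {
    if (hot[i]) {
      j <- i
      while (j < n && hot[j + 1L]) j <- j + 1L
      regions <- rbind(regions, c(i - h, j + h))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(regions)) return(none)
  # merge regions separated by <= merge_gap residues
  merged <- regions[1L, , drop = FALSE]
  if (nrow(regions) > 1L) {
    for (k in 2L:nrow(regions)) {
      if (regions[k, 1L] - merged[nrow(merged), 2L] - 1L <= params$merge_gap) {
        merged[nrow(merged), 2L] <- regions[k, 2L]
      } else {
        merged <- rbind(merged, regions[k, , drop = FALSE])
      }
    }
  }
  keep <- merged[, 2L] - merged[, 1L] + 1L >= params$min_region_length
  out <- merged[keep, , drop = FALSE]
  colnames(out) <- c("start", "end")
  storage.mode(out) <- "integer"
  out
}

# the two census rules, direct form
oracle_classify <- function(models, n_tm, registry) {
  has_dna <- FALSE
  hybrid_domain <- FALSE
  st_domain <- FALSE
  for (m in models) {
    if (m %in% registry$dna_binding) has_dna <- TRUE
    if (m %in% registry$tcs_core) hybrid_domain <- TRUE
    if (m %in% registry$st_membership) st_domain <- TRUE
  }
  is_ttr <- has_dna && n_tm >= 1L
  list(is_ttr = is_ttr,
       is_hybrid = is_ttr && hybrid_domain,
       is_st = st_domain || is_ttr,
       has_dna_binding = has_dna,
       pass_class = if (n_tm == 0L) "none" else if (n_tm == 1L) "single_pass"
                    else if (n_tm == 2L) "two_pass" else "multi_pass")
}

test_registry <- function() {
  registry(dna_binding = c("HTH_1", "LytTR", "GerE"),
           st_membership = c("GGDEF", "Y_Y_Y", "HisKA", "Response_reg",
                             "HATPase_c", "PAS"))
}

# a random small architecture: model list + TM regions + matching protein
random_architecture <- function(registry, max_hits = 4L) {
  pool <- c(registry$dna_binding, registry$tcs_core, registry$st_membership,
            "Unknown_dom")
  k <- sample(0:max_hits, 1L)
  models <- if (k) sample(pool, k, replace = TRUE) else character()
  n_tm <- sample(0:5, 1L)
  seqlen <- 60L + 40L * max(k, 1L)
  hits <- if (k) {
    data.frame(protein_id = "p", model_name = models, model_accession = "",
               env_from = 1L + 40L * (seq_len(k) - 1L),
               env_to = 30L + 40L * (seq_len(k) - 1L),
               bit_score = round(runif(k, 20, 100), 1L),
               i_evalue = 1e-10, stringsAsFactors = FALSE)
  } else {
    data.frame(protein_id = character(), model_name = character(),
               model_accession = character(), env_from = integer(),
               env_to = integer(), bit_score = numeric(), i_evalue = numeric(),
               stringsAsFactors = FALSE)
  }
  regions <- if (n_tm) {
    cbind(start = 1L + 25L * (seq_len(n_tm) - 1L),
          end = 21L + 25L * (seq_len(n_tm) - 1L))
  } else cbind(start = integer(), end = integer())
  seqn <- strrep("A", max(seqlen, 25L * n_tm + 10L))
  list(models = models, n_tm = n_tm, hits = hits, regions = regions,
       sequence = seqn)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
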