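# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

# A bare probe design: n probes on one chromosome, fixed length/spacing.
toy_design <- function(n, chrom = "chr01", start0 = 1000L, len = 50L,
                       spacing = 200L, promoter_id = "prom_00001",
                       prefix = "p") {
  starts <- start0 + (seq_len(n) - 1L) * spacing
  probe_design(data.frame(
    probe_id = sprintf("%s%03d", prefix, seq_len(n)),
    chrom = chrom, start = starts, end = starts + len,
    promoter_id = promoter_id))
}

# An intensity set with exactly prescribed log2 enrichment per probe/sample:
# input fixed at 1000, medip = 1000 * 2^r.
toy_intensities <- function(r, groups = c("HF-CON", "CON-CON"),
                            n_rep = ncol(r) / 2) {
  samples <- data.frame(
    sample_id = paste0(rep(groups, each = n_rep), "_", seq_len(n_rep)),
    group = rep(groups, each = n_rep),
    replicate = rep(seq_len(n_rep), 2L))
  input <- matrix(1000, nrow(r), ncol(r),
                  dimnames = list(rownames(r), samples$sample_id))
  medip <- input * 2^r
  dimnames(medip) <- dimnames(input)
  # single-replicate toys are legitimate where no CV is computed
  suppressWarnings(intensity_matrix(medip, input, samples))
}

# Independent maximal-run enumeration (peak-finding oracle).
enumerate_runs <- function(scores, design, cutoff = 2, min_probes = 2) {
  out <- list()
  i <- 1L
  n <- length(scores)
  while (i <= n) {
    if (scores[i] >= cutoff) {
      j <- i
      while (j < n && scores[j + 1L] >= cutoff &&
             design$chrom[j + 1L] == design$chrom[i]) j <- j + 1L
      if (j - i + 1L >= min_probes)
        out[[length(out) + 1L]] <- list(
          chrom = design$chrom[i],
          start = min(design$start[i:j]),
          end = max(design$end[i:j]),
          probes = design$probe_id[i:j])
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Fixed-point merge oracle: repeated pairwise merging until stable.
merge_fixed_point <- function(intervals, gap_bp = 500) {
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < length(intervals)) {
      a <- intervals[[i]]; b <- intervals[[i + 1L]]
      if (a$chrom == b$chrom && b$start - a$end <= gap_bp) {
        intervals[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                               end = max(a$end, b$end),
                               probes = unique(c(a$probes, b$probes)))
        intervals[[i + 1L]] <- NULL
        changed <- TRUE
      } else i <- i + 1L
    }
    if (!changed) return(intervals)
  }
}

# Per-window one-sided KS score oracle built on stats::ks.test.
window_score_oracle <- function(track, design, window_bp = 750) {
  m <- length(track)
  mids <- (design$start + design$end) / 2
  vapply(seq_len(m), function(i) {
    win <- which(design$chrom == design$chrom[i] &
                   abs(mids - mids[i]) <= window_bp / 2)
    n <- length(win)
    if (n < 2L) return(0)
    d <- suppressWarnings(
      stats::ks.test(track[win], track, alternative = "less")$statistic)
    max(0, 2 * d^2 * n * m / (n + m) / log(10))
  }, numeric(1))
}

# Row-by-row DEP filter predicate, coded independently of filter_deps.
dep_predicate <- function(peak_probes, r, m, groups = c("HF-CON", "CON-CON"),
                          median_min = 0.3, cv_max = 0.8, cv_frac = 0.5) {
  s <- m$samples
  c1 <- s$sample_id[s$group == groups[1]]
  c2 <- s$sample_id[s$group == groups[2]]
  ratio <- m$medip / m$input
  v1 <- as.vector(r[peak_probes, c1])
  v2 <- as.vector(r[peak_probes, c2])
  med <- function(v) { v <- sort(v); k <- length(v)
    if (k %% 2) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2 }
  mprime <- mean(v1) - mean(v2)
  cvs <- function(cols) vapply(peak_probes, function(p) {
    x <- ratio[p, cols]; sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x)
  }, numeric(1))
  max(med(v1), med(v2)) >= median_min && mprime != 0 &&
    mean(cvs(c1) <= cv_max) >= cv_frac && mean(cvs(c2) <= cv_max) >= cv_frac
}

# One full synthetic recovery run at the given scale; returns evaluation.
recovery_run <- function(seed, n_promoters = 500, n_dmrs = 20, effect = 1.5,
                         noise_sd = 0.3) {
  set.seed(seed)
  planted <- data.frame(
    promoter = sample(n_promoters, n_dmrs),
    direction = rep_len(c("hyper", "hypo"), n_dmrs),
    effect = effect)
  cfg <- sim_config(n_promoters = n_promoters, planted_dmrs = planted,
                    noise_sd = noise_sd, seed = seed)
  ps <- gen_promoter_set(cfg, emit_sequences = FALSE)
  des <- gen_array_design(ps$promoters, cfg)
  ex <- gen_medip_experiment(des, cfg)
  r <- log_ratio(ex$intensities)
  deps <- filter_deps(call_candidate_regions(r, des), r, ex$intensities)
  evaluate_recovery(deps, ex$truth)
}
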