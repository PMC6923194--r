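#' Simulation configuration for a synthetic MeDIP promoter-array experiment
#'
#' Bundles every parameter of the synthetic two-group design. Defaults give a
#' desk-scale array — 500 promoters tiled by ~4,000 probes — with the window
#' geometry of a promoter tiling array (probes spanning ~-1,300 to +500 bp of
#' each TSS) and a two-group, three-replicate layout. The full published
#' scale (22,327 promoters / ~180,000 probes) is reached by raising
#' `n_promoters`.
#'
#' @param n_promoters Number of promoters (default 500).
#' @param probe_length Probe length in bp (default 50).
#' @param probe_spacing Start-to-start probe spacing in bp (default 220,
#'   giving 8 probes per 1,800-bp promoter window).
#' @param promoter_window `c(upstream, downstream)` extent around the TSS in
#'   bp (default `c(1300, 500)`).
#' @param n_replicates Replicates per group (default 3).
#' @param planted_dmrs Data.frame of planted differentially methylated
#'   regions: columns `promoter` (index), `direction` (`"hyper"`/`"hypo"`),
#'   `effect` (log2 enrichment difference, positive). `NULL` for none.
#' @param noise_sd SD of the per-probe baseline log2 enrichment (default 0.3).
#' @param replicate_cv Target across-replicate CV of the linear MeDIP/Input
#'   ratio (default 0.3); the generator calibrates its multiplicative noise
#'   so the expected sample CV at `n_replicates` equals this value.
#' @param mu_base Mean baseline log2 enrichment (default 0.5, so unplanted
#'   promoters straddle the 0.3 median filter threshold realistically).
#' @param n_chromosomes Synthetic chromosomes the promoters are spread over
#'   (default 4, minimum 2).
#' @param promoter_gap Gap between consecutive promoter windows on a
#'   chromosome, bp (default 10000).
#' @param group_labels `c(treatment, control)` labels
#'   (default `c("HF-CON", "CON-CON")`).
#' @param seed Integer seed fixing all generator output bit-for-bit.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_promoters = 500L, probe_length = 50L,
                       probe_spacing = 220L,
                       promoter_window = c(upstream = 1300L, downstream = 500L),
                       n_replicates = 3L, planted_dmrs = NULL,
                       noise_sd = 0.3, replicate_cv = 0.3, mu_base = 0.5,
                       n_chromosomes = 4L, promoter_gap = 10000L,
                       group_labels = c("HF-CON", "CON-CON"), seed = 1L) {
  cfg <- list(n_promoters = as.integer(n_promoters),
              probe_length = as.integer(probe_length),
              probe_spacing = as.integer(probe_spacing),
              promoter_window = as.integer(promoter_window),
              n_replicates = as.integer(n_replicates),
              planted_dmrs = planted_dmrs,
              noise_sd = noise_sd, replicate_cv = replicate_cv,
              mu_base = mu_base, n_chromosomes = as.integer(n_chromosomes),
              promoter_gap = as.integer(promoter_gap),
              group_labels = group_labels, seed = as.integer(seed))
  stopifnot(cfg$n_promoters >= 1L, cfg$probe_length > 0L,
            cfg$probe_spacing >= 1L, length(cfg$promoter_window) == 2L,
            all(cfg$promoter_window >= 0L),
            sum(cfg$promoter_window) > cfg$probe_length,
            cfg$n_replicates >= 1L, cfg$noise_sd >= 0, cfg$replicate_cv >= 0,
            cfg$n_chromosomes >= 2L, length(cfg$group_labels) == 2L,
            is.finite(cfg$seed))
  if (!is.null(planted_dmrs)) {
    stopifnot(is.data.frame(planted_dmrs),
              all(c("promoter", "direction", "effect") %in% names(planted_dmrs)),
              all(planted_dmrs$direction %in% c("hyper", "hypo")),
              all(is.finite(planted_dmrs$effect)),
              all(planted_dmrs$effect > 0),
              all(planted_dmrs$promoter >= 1L),
              all(planted_dmrs$promoter <= cfg$n_promoters),
              !anyDuplicated(planted_dmrs$promoter))
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic promoter set with class-targeted sequences
#'
#' Lays promoters on `n_chromosomes` synthetic chromosomes with alternating
#' strand, windows spanning `upstream`..`downstream` bp around each TSS
#' (mirrored for minus-strand promoters), and emits one DNA sequence per
#' promoter constructed to a requested CpG class. Emitted sequences are
#' verified with [classify_promoter()] and resampled until the requested
#' class is met; an impossible request fails explicitly.
#'
#' @param cfg A [sim_config()].
#' @param classes Character vector of requested classes per promoter
#'   (`"HCP"`, `"ICP"`, `"LCP"`), recycled; default draws classes with
#'   probabilities 0.5/0.3/0.2 (a CpG-rich promoter-array-like mix).
#' @param emit_sequences Set `FALSE` to skip sequence generation (geometry
#'   only; much faster for array-level simulations).
#' @return A list with `promoters` (data.frame: `promoter_id`, `gene_id`,
#'   `chrom`, `tss`, `strand`, `start`, `end`, `target_class`) and
#'   `sequences` (a [Biostrings::DNAStringSet] named by promoter id, or
#'   `NULL`).
#' @export
gen_promoter_set <- function(cfg, classes = NULL, emit_sequences = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_promoters
    if (is.null(classes)) {
      classes <- sample(c("HCP", "ICP", "LCP"), n, replace = TRUE,
                        prob = c(0.5, 0.3, 0.2))
    } else {
      stopifnot(all(classes %in% c("HCP", "ICP", "LCP")))
      classes <- rep_len(classes, n)
    }
    width <- sum(cfg$promoter_window)
    chrom <- sprintf("chr%02d", ((seq_len(n) - 1L) %% cfg$n_chromosomes) + 1L)
    slot <- (seq_len(n) - 1L) %/% cfg$n_chromosomes
    start <- 1000L + slot * (width + cfg$promoter_gap)
    end <- start + width
    strand <- rep_len(c("+", "-"), n)
    tss <- ifelse(strand == "+", start + cfg$promoter_window[[1L]],
                  start + cfg$promoter_window[[2L]])
    promoters <- data.frame(
      promoter_id = sprintf("prom_%05d", seq_len(n)),
      gene_id = sprintf("gene_%05d", seq_len(n)),
      chrom = chrom, tss = tss, strand = strand,
      start = start, end = end, target_class = classes)
    sequences <- NULL
    if (emit_sequences) {
      seqs <- vapply(classes, function(cl) sample_class_sequence(width, cl),
                     character(1))
      sequences <- Biostrings::DNAStringSet(seqs)
      names(sequences) <- promoters$promoter_id
    }
    list(promoters = promoters, sequences = sequences)
  })
}

# Draw one sequence of the requested CpG class; verify with the classifier
# and resample on failure (bounded retries -> explicit failure).
sample_class_sequence <- function(width, class, max_tries = 50L) {
  stopifnot(width >= 500L)
  params <- switch(class,
    HCP = list(p_cg = 0.105, base = c(A = 0.18, C = 0.32, G = 0.32, T = 0.18)),
    ICP = list(p_cg = 0.034, base = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
    LCP = list(p_cg = 0.002, base = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)),
    stop("unknown CpG class request: ", class))
  for (try in seq_len(max_tries)) {
    seq <- sample_dinuc_sequence(width, params$p_cg, params$base)
    if (classify_promoter(seq) == class) return(seq)
  }
  stop("could not generate a sequence classified as ", class,
       " after ", max_tries, " attempts (unreachable class parameters?)")
}

# Sample width bases from base frequencies, break every accidental CG
# dinucleotide (so CpG density is controlled, not emergent), then plant CG
# dinucleotides at non-overlapping sites at density p_cg per base.
sample_dinuc_sequence <- function(width, p_cg, base) {
  x <- sample(names(base), width, replace = TRUE, prob = base)
  cg <- which(x[-width] == "C" & x[-1L] == "G")
  if (length(cg))  # replacing G by A/T cannot create a new CG
    x[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
  slots <- seq.int(1L, width - 1L, by = 2L)  # odd starts: pairs never overlap
  n_cg <- min(stats::rbinom(1L, width, p_cg), length(slots))
  if (n_cg > 0L) {
    pos <- sample(slots, n_cg)
    x[pos] <- "C"
    x[pos + 1L] <- "G"
  }
  paste(x, collapse = "")
}

#' Generate the probe design tiling a promoter set
#'
#' Probes tile each promoter window left to right at `probe_spacing`
#' (`floor((width - probe_length) / spacing) + 1` probes per window), all
#' contained in the window. If the spacing exceeds the window width a single
#' probe is emitted with a warning.
#'
#' @param promoters Promoter table from [gen_promoter_set()].
#' @param cfg A [sim_config()].
#' @return A [probe_design()].
#' @export
gen_array_design <- function(promoters, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  width <- promoters$end - promoters$start
  if (any(width <= 0)) stop("degenerate promoter windows")
  len <- cfg$probe_length
  sp <- cfg$probe_spacing
  if (any(width - len < 0))
    stop("probe_length exceeds a promoter window")
  if (any(sp > width))
    warning("probe_spacing exceeds some promoter windows; one probe each")
  n_probes <- pmax(1L, ((width - len) %/% sp) + 1L)
  prom_idx <- rep.int(seq_len(nrow(promoters)), n_probes)
  offset <- unlist(lapply(n_probes, function(k) seq_len(k) - 1L)) * sp
  start <- promoters$start[prom_idx] + offset
  design <- data.frame(
    probe_id = sprintf("probe_%06d", seq_along(start)),
    chrom = promoters$chrom[prom_idx],
    start = start, end = start + len,
    promoter_id = promoters$promoter_id[prom_idx])
  probe_design(design)
}

#' Generate a two-group MeDIP experiment with planted DMRs
#'
#' The signal model: each probe carries a baseline log2 enrichment drawn
#' `N(mu_base, noise_sd^2)`, shared by both groups. A planted region raises
#' all of its promoter's probes by `effect` log2 units in the group where the
#' region is methylated — the treatment group for `hyper` regions, the
#' control group for `hypo` regions — so each direction yields a callable
#' peak in the corresponding group track and a region M' of `+effect`
#' (hyper) or `-effect` (hypo). Per replicate, the linear MeDIP/Input ratio
#' is the group-level `2^enrichment` times lognormal noise with unit mean,
#' calibrated so the expected across-replicate sample CV equals
#' `replicate_cv`; the Input channel is lognormal around a fixed brightness,
#' so both channels are strictly positive by construction.
#'
#' @param design A [probe_design()] from [gen_array_design()].
#' @param cfg A [sim_config()]; `cfg$planted_dmrs` names the planted regions.
#' @return A list with `intensities` (an [intensity_matrix()]) and `truth`
#'   (data.frame of planted regions: `chrom`, `start`, `end`, `direction`,
#'   `effect`, `promoter_id`, covering each planted promoter's probes).
#' @export
gen_medip_experiment <- function(design, cfg) {
  stopifnot(inherits(design, "probe_design"), inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    n_probes <- nrow(design)
    groups <- cfg$group_labels
    n_rep <- cfg$n_replicates
    samples <- data.frame(
      sample_id = paste0(rep(groups, each = n_rep), "_", seq_len(n_rep)),
      group = rep(groups, each = n_rep),
      replicate = rep(seq_len(n_rep), 2L))

    baseline <- stats::rnorm(n_probes, cfg$mu_base, cfg$noise_sd)
    level <- matrix(baseline, n_probes, 2L,
                    dimnames = list(design$probe_id, groups))
    truth <- NULL
    if (!is.null(cfg$planted_dmrs)) {
      prom_ids <- sprintf("prom_%05d", cfg$planted_dmrs$promoter)
      truth_rows <- lapply(seq_along(prom_ids), function(i) {
        rows <- which(design$promoter_id == prom_ids[i])
        if (length(rows) < 2L)
          stop("planted region in ", prom_ids[i],
               " is covered by fewer than 2 probes")
        dir <- cfg$planted_dmrs$direction[i]
        eff <- cfg$planted_dmrs$effect[i]
        target <- if (dir == "hyper") groups[1L] else groups[2L]
        level[rows, target] <<- level[rows, target] + eff
        data.frame(chrom = design$chrom[rows[1L]],
                   start = min(design$start[rows]),
                   end = max(design$end[rows]),
                   direction = dir, effect = eff, promoter_id = prom_ids[i])
      })
      truth <- do.call(rbind, truth_rows)
    }

    sigma <- cv_noise_sigma(cfg$replicate_cv, n_rep)
    n_samp <- nrow(samples)
    eps <- if (sigma == 0) matrix(1, n_probes, n_samp) else
      matrix(stats::rlnorm(n_probes * n_samp, -sigma^2 / 2, sigma),
             n_probes, n_samp)
    ratio <- 2^level[, samples$group, drop = FALSE] * eps
    input <- matrix(stats::rlnorm(n_probes * n_samp, log(1000), 0.2),
                    n_probes, n_samp)
    medip <- input * ratio
    # positivity is structural (lognormals); guard against numeric underflow
    for (try in 1:10) {
      bad <- !is.finite(medip) | medip <= 0 | !is.finite(input) | input <= 0
      if (!any(bad)) break
      input[bad] <- stats::rlnorm(sum(bad), log(1000), 0.2)
      medip[bad] <- input[bad] * ratio[bad]
    }
    if (any(!is.finite(medip) | medip <= 0))
      stop("failed to generate strictly positive intensities")
    dimnames(medip) <- dimnames(input) <-
      list(design$probe_id, samples$sample_id)
    list(intensities = intensity_matrix(medip, input, samples),
         truth = truth)
  })
}

# Lognormal sigma whose expected n-replicate sample CV equals target_cv.
# Solved by uniroot over a fixed panel of normal deviates (common random
# numbers), so the calibration is smooth and deterministic.
cv_noise_sigma <- function(target_cv, n_reps, n_panel = 5000L) {
  if (target_cv == 0) return(0)
  if (n_reps < 2L)
    stop("replicate_cv > 0 requires at least 2 replicates")
  z <- withr::with_seed(761543L,
    matrix(stats::rnorm(n_panel * n_reps), n_panel, n_reps))
  expected_cv <- function(sigma) {
    x <- exp(sigma * z - sigma^2 / 2)
    mu <- rowMeans(x)
    s <- sqrt(rowSums((x - mu)^2) / (n_reps - 1))
    mean(s / mu)
  }
  stats::uniroot(function(s) expected_cv(s) - target_cv,
                 lower = 1e-6, upper = 4, tol = 1e-6)$root
}

#' Compare called DEPs against planted ground truth
#'
#' A planted region is recovered if at least one DEP overlaps it (same
#' chromosome, intervals intersecting); a DEP is a true positive if it
#' overlaps any planted region. Direction accuracy and M' error are computed
#' over matched pairs (signed truth effect: `+effect` for hyper, `-effect`
#' for hypo).
#'
#' @param deps A `dep_set` (needs `chrom`, `start`, `end`, `direction`,
#'   `mprime`).
#' @param truth Planted-region table from [gen_medip_experiment()].
#' @return A list: `recall`, `precision`, `direction_accuracy` (NA when no
#'   matches), `mprime_error` (vector over matched pairs: called M' minus
#'   signed truth effect), `n_called`, `n_truth`.
#' @export
evaluate_recovery <- function(deps, truth) {
  overlaps <- function(i, j)  # dep i, truth j
    deps$chrom[i] == truth$chrom[j] &
      deps$start[i] < truth$end[j] & truth$start[j] < deps$end[i]
  n_dep <- nrow(deps); n_truth <- nrow(truth)
  hit_dep <- logical(n_dep)
  hit_truth <- logical(n_truth)
  dir_ok <- logical(0)
  mp_err <- numeric(0)
  for (j in seq_len(n_truth)) {
    for (i in seq_len(n_dep)) {
      if (overlaps(i, j)) {
        hit_dep[i] <- TRUE
        hit_truth[j] <- TRUE
        dir_ok <- c(dir_ok, deps$direction[i] == truth$direction[j])
        signed <- if (truth$direction[j] == "hyper") truth$effect[j]
                  else -truth$effect[j]
        mp_err <- c(mp_err, deps$mprime[i] - signed)
      }
    }
  }
  list(recall = if (n_truth) mean(hit_truth) else NA_real_,
       precision = if (n_dep) mean(hit_dep) else NA_real_,
       direction_accuracy = if (length(dir_ok)) mean(dir_ok) else NA_real_,
       mprime_error = mp_err,
       n_called = n_dep, n_truth = n_truth)
}

#' Write planted ground truth as a BED-like table
#'
#' @param truth Truth table from [gen_medip_experiment()].
#' @param path Output path (BED3 + `direction`, `effect`, `promoter_id`).
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  utils::write.table(truth[c("chrom", "start", "end", "direction", "effect",
                             "promoter_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
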