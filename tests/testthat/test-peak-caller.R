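test_that("a flat track scores zero everywhere", {
  des <- toy_design(20)
  s <- window_score(rep(0.5, 20), des)
  expect_equal(unname(s), rep(0, 20))
})

test_that("window scores equal a per-window ks.test oracle", {
  des <- toy_design(10, spacing = 150)
  track <- c(0.1, 0.2, 0.15, 2.1, 2.2, 2.05, 2.3, 0.1, 0.25, 0.2)
  expect_equal(unname(window_score(track, des)),
               window_score_oracle(track, des), tolerance = 1e-12)

  # and on random tracks with mixed geometry
  set.seed(31)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    des <- toy_design(n, spacing = sample(c(100, 200, 400), 1))
    track <- rnorm(n)
    expect_equal(unname(window_score(track, des, window_bp = 750)),
                 window_score_oracle(track, des, window_bp = 750),
                 tolerance = 1e-12)
  }
})

test_that("an isolated probe on its own chromosome scores zero", {
  d1 <- as.data.frame(toy_design(6))
  d2 <- data.frame(probe_id = "lone", chrom = "chr09", start = 500L,
                   end = 550L, promoter_id = "prom_x")
  des <- probe_design(rbind(d1, d2))
  s <- window_score(c(rnorm(6), 10), des)
  expect_equal(unname(s[des$probe_id == "lone"]), 0)
})

test_that("peak detection finds exactly the qualifying runs", {
  des <- toy_design(4)
  pk <- find_peaks(c(0, 3, 3, 0), des)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$n_probes, 2)
  expect_equal(pk$probes[[1]], c("p002", "p003"))

  expect_equal(nrow(find_peaks(c(3, 0, 3), toy_design(3))), 0)

  # ties at the cutoff are included
  pk <- find_peaks(c(2, 2, 0), toy_design(3), cutoff = 2)
  expect_equal(pk$n_probes, 2)

  # runs do not cross chromosome boundaries
  des2 <- probe_design(rbind(as.data.frame(toy_design(2)),
                             as.data.frame(toy_design(2, chrom = "chr02",
                                                      start0 = 1000L,
                                                      prefix = "q"))))
  expect_equal(nrow(find_peaks(c(3, 3, 3, 3), des2)), 2)
})

test_that("peak detection matches exhaustive run enumeration on random scores", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    des <- toy_design(n, spacing = sample(c(80, 300, 700), 1))
    s <- round(runif(n, 0, 4), 2)
    pk <- find_peaks(s, des)
    oracle <- enumerate_runs(s, des)
    expect_equal(nrow(pk), length(oracle))
    if (length(oracle)) {
      expect_equal(pk$start, vapply(oracle, `[[`, numeric(1), "start"))
      expect_equal(pk$end, vapply(oracle, `[[`, numeric(1), "end"))
      expect_equal(pk$probes, lapply(oracle, `[[`, "probes"),
                   ignore_attr = TRUE)
    }
  }
})

test_that("peak merging follows the genomic-gap rule", {
  mk <- function(starts, ends, chrom = "chr01")
    structure(data.frame(chrom = chrom, start = starts, end = ends,
                         n_probes = 2L, score = 3,
                         group = "HF-CON",
                         probes = I(lapply(seq_along(starts), function(i)
                           paste0("x", i, "_", 1:2)))),
              class = c("peak_set", "data.frame"))
  expect_equal(nrow(merge_peaks(mk(c(1000, 2000), c(1600, 2500)))), 1)  # gap 400
  expect_equal(nrow(merge_peaks(mk(c(1000, 2100), c(1600, 2500)))), 1)  # gap 500
  expect_equal(nrow(merge_peaks(mk(c(1000, 2101), c(1600, 2500)))), 2)  # gap 501
  # different chromosomes never merge
  two_chrom <- mk(c(1000, 1100), c(1600, 1700))
  two_chrom$chrom <- c("chr01", "chr02")
  expect_equal(nrow(merge_peaks(two_chrom)), 2)
})

test_that("chains of near peaks collapse to one, independent of input order", {
  mk_chain <- function(perm) {
    starts <- c(1000, 1800, 2600, 3400)[perm]
    ends <- c(1500, 2300, 3100, 3900)[perm]
    structure(data.frame(chrom = "chr01", start = starts, end = ends,
                         n_probes = 2L, score = seq_along(perm),
                         group = "HF-CON",
                         probes = I(lapply(perm, function(i)
                           paste0("c", i, "_", 1:2)))),
              class = c("peak_set", "data.frame"))
  }
  ref <- merge_peaks(mk_chain(1:4), gap_bp = 500)
  expect_equal(nrow(ref), 1)
  expect_equal(ref$start, 1000)
  expect_equal(ref$end, 3900)
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    alt <- merge_peaks(mk_chain(perm), gap_bp = 500)
    expect_equal(alt$start, ref$start)
    expect_equal(alt$end, ref$end)
    expect_setequal(alt$probes[[1]], ref$probes[[1]])
  }
})

test_that("merging is idempotent and agrees with a fixed-point oracle", {
  set.seed(19)
  for (i in 1:50) {
    k <- sample(1:8, 1)
    starts <- sort(sample(seq(1000, 20000, 100), k))
    ends <- starts + sample(seq(100, 700, 100), k, replace = TRUE)
    pk <- structure(data.frame(chrom = sample(c("chr01", "chr02"), k,
                                              replace = TRUE),
                               start = starts, end = ends, n_probes = 2L,
                               score = runif(k, 2, 6), group = "g",
                               probes = I(lapply(seq_len(k), function(j)
                                 paste0("r", i, "_", j, "_", 1:2)))),
                    class = c("peak_set", "data.frame"))
    pk <- pk[order(pk$chrom, pk$start), ]
    m1 <- merge_peaks(pk)
    m2 <- merge_peaks(m1)
    expect_equal(as.data.frame(m1), as.data.frame(m2))
    oracle <- merge_fixed_point(
      lapply(seq_len(nrow(pk)), function(j)
        list(chrom = pk$chrom[j], start = pk$start[j], end = pk$end[j],
             probes = pk$probes[[j]])))
    expect_equal(nrow(m1), length(oracle))
    expect_equal(m1$start, vapply(oracle, `[[`, numeric(1), "start"))
    expect_equal(m1$end, vapply(oracle, `[[`, numeric(1), "end"))
  }
})

test_that("caller output is stable under probe relabeling and duplicated chromosomes", {
  cfg <- sim_config(n_promoters = 40, seed = 6,
                    planted_dmrs = data.frame(promoter = c(3, 17),
                                              direction = c("hyper", "hypo"),
                                              effect = 2))
  ps <- gen_promoter_set(cfg, emit_sequences = FALSE)
  des <- gen_array_design(ps$promoters, cfg)
  ex <- gen_medip_experiment(des, cfg)
  r <- log_ratio(ex$intensities)
  base_peaks <- call_candidate_regions(r, des)

  # relabeling probes changes nothing but the labels
  des2 <- des
  des2$probe_id <- paste0("relabel_", des$probe_id)
  r2 <- r
  rownames(r2) <- paste0("relabel_", rownames(r))
  pk2 <- call_candidate_regions(r2, des2)
  expect_equal(pk2[c("chrom", "start", "end", "score")],
               base_peaks[c("chrom", "start", "end", "score")])

  # appending a value-identical copy of the array on another chromosome
  # leaves the original chromosomes' peak calls unchanged (the global
  # reference distribution is the same multiset)
  des_dup <- as.data.frame(des)
  des_dup$chrom <- "chr99"
  des_dup$probe_id <- paste0("dup_", des_dup$probe_id)
  des3 <- probe_design(rbind(as.data.frame(des), des_dup))
  m <- ex$intensities
  medip3 <- rbind(m$medip, m$medip)
  input3 <- rbind(m$input, m$input)
  rownames(medip3) <- rownames(input3) <-
    c(rownames(m$medip), paste0("dup_", rownames(m$medip)))
  ord <- match(des3$probe_id, rownames(medip3))
  m3 <- intensity_matrix(medip3[ord, ], input3[ord, ], m$samples)
  pk3 <- call_candidate_regions(log_ratio(m3), des3)
  pk3_orig <- pk3[pk3$chrom != "chr99", , drop = FALSE]
  expect_equal(pk3_orig$start, base_peaks$start)
  expect_equal(pk3_orig$end, base_peaks$end)
  expect_equal(pk3_orig$chrom, base_peaks$chrom)
})
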