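test_that("generators are bit-for-bit deterministic under a fixed seed", {
  cfg <- sim_config(n_promoters = 8, seed = 42,
                    planted_dmrs = data.frame(promoter = 2, direction = "hyper",
                                              effect = 1.5))
  a <- gen_promoter_set(cfg)
  b <- gen_promoter_set(cfg)
  expect_identical(a$promoters, b$promoters)
  expect_identical(as.character(a$sequences), as.character(b$sequences))

  des <- gen_array_design(a$promoters, cfg)
  e1 <- gen_medip_experiment(des, cfg)
  e2 <- gen_medip_experiment(des, cfg)
  expect_identical(e1$intensities$medip, e2$intensities$medip)
  expect_identical(e1$truth, e2$truth)

  amp <- synthetic_amplicon()
  expect_identical(gen_bsp_clones(amp, 0.6, 2, 10, seed = 3)$clones,
                   gen_bsp_clones(amp, 0.6, 2, 10, seed = 3)$clones)
  expect_identical(gen_phenotypes(seed = 5), gen_phenotypes(seed = 5))

  # a different seed changes the draw
  cfg2 <- sim_config(n_promoters = 8, seed = 43)
  expect_false(identical(as.character(gen_promoter_set(cfg2)$sequences),
                         as.character(a$sequences)))
})

test_that("requested CpG classes round-trip through the classifier", {
  cfg <- sim_config(n_promoters = 3, seed = 7)
  ps <- gen_promoter_set(cfg, classes = c("HCP", "ICP", "LCP"))
  expect_identical(unname(classify_promoters(ps$sequences)),
                   c("HCP", "ICP", "LCP"))
})

test_that("100 requested HCP promoters all classify HCP", {
  cfg <- sim_config(n_promoters = 100, seed = 8)
  ps <- gen_promoter_set(cfg, classes = "HCP")
  expect_equal(sum(classify_promoters(ps$sequences) == "HCP"), 100)
})

test_that("promoter geometry follows the strand-aware TSS window", {
  cfg <- sim_config(n_promoters = 6, seed = 1)
  p <- gen_promoter_set(cfg, emit_sequences = FALSE)$promoters
  plus <- p[p$strand == "+", ]
  minus <- p[p$strand == "-", ]
  expect_equal(plus$tss - plus$start, rep(1300, nrow(plus)))
  expect_equal(plus$end - plus$tss, rep(500, nrow(plus)))
  expect_equal(minus$tss - minus$start, rep(500, nrow(minus)))
  expect_equal(minus$end - minus$tss, rep(1300, nrow(minus)))
  expect_gte(length(unique(p$chrom)), 2)
})

test_that("probe tiling counts match the closed-form geometry", {
  # 1,800-bp window, 50-bp probes, 100-bp spacing -> 18 probes
  cfg <- sim_config(n_promoters = 1, probe_spacing = 100, seed = 1)
  des <- gen_array_design(gen_promoter_set(cfg, emit_sequences = FALSE)$promoters,
                          cfg)
  expect_equal(nrow(des), 18)
  expect_true(all(des$start >= 1000 & des$end <= 1000 + 1800))

  # spacing equal to the window width -> exactly one probe
  cfg1 <- sim_config(n_promoters = 1, probe_spacing = 1800, seed = 1)
  expect_equal(nrow(gen_array_design(
    gen_promoter_set(cfg1, emit_sequences = FALSE)$promoters, cfg1)), 1)

  # spacing beyond the window warns and still yields one probe per promoter
  cfg2 <- sim_config(n_promoters = 2, probe_spacing = 5000, seed = 1)
  expect_warning(
    des2 <- gen_array_design(
      gen_promoter_set(cfg2, emit_sequences = FALSE)$promoters, cfg2),
    "one probe")
  expect_equal(nrow(des2), 2)
})

test_that("published array scale is reproduced by the geometry", {
  # 22,327 promoters at 8 probes per 1,800-bp window gives ~180,000 probes
  cfg <- sim_config(n_promoters = 22327, seed = 1)
  des <- gen_array_design(gen_promoter_set(cfg, emit_sequences = FALSE)$promoters,
                          cfg)
  expect_gt(nrow(des), 170000)
  expect_lt(nrow(des), 190000)
})

test_that("a noise-free experiment with no planted effect gives M' = 0 everywhere", {
  cfg <- sim_config(n_promoters = 10, noise_sd = 0, replicate_cv = 0, seed = 3)
  ps <- gen_promoter_set(cfg, emit_sequences = FALSE)
  des <- gen_array_design(ps$promoters, cfg)
  ex <- gen_medip_experiment(des, cfg)
  r <- log_ratio(ex$intensities)
  expect_equal(max(abs(r - 0.5)), 0, tolerance = 1e-12)
  des_peak <- structure(data.frame(chrom = des$chrom[1], start = des$start[1],
                                   end = des$end[8], n_probes = 8L, score = 3,
                                   group = "HF-CON",
                                   probes = I(list(des$probe_id[1:8]))),
                        class = c("peak_set", "data.frame"))
  expect_equal(region_mprime(des_peak, r), 0)
  # and the flat track yields no peaks at all
  expect_equal(nrow(call_candidate_regions(r, des)), 0)
})

test_that("recovered M' is unbiased for the planted effect (Monte Carlo)", {
  mprimes <- vapply(1:100, function(seed) {
    cfg <- sim_config(n_promoters = 30, noise_sd = 0.1, seed = seed,
                      planted_dmrs = data.frame(promoter = 11,
                                                direction = "hyper",
                                                effect = 2.0))
    ps <- gen_promoter_set(cfg, emit_sequences = FALSE)
    des <- gen_array_design(ps$promoters, cfg)
    ex <- gen_medip_experiment(des, cfg)
    r <- log_ratio(ex$intensities)
    deps <- filter_deps(call_candidate_regions(r, des), r, ex$intensities)
    ev <- evaluate_recovery(deps, ex$truth)
    if (length(ev$mprime_error)) 2.0 + ev$mprime_error[1] else NA_real_
  }, numeric(1))
  expect_gt(mean(!is.na(mprimes)), 0.98)
  expect_lt(abs(mean(mprimes, na.rm = TRUE) - 2.0), 0.15)
})

test_that("requested replicate CV is realised in expectation", {
  cfg <- sim_config(n_promoters = 1250, replicate_cv = 0.8, noise_sd = 0.3,
                    seed = 21)
  ps <- gen_promoter_set(cfg, emit_sequences = FALSE)
  des <- gen_array_design(ps$promoters, cfg)
  m <- gen_medip_experiment(des, cfg)$intensities
  expect_gte(nrow(des), 10000)
  cv <- probe_cv(m, "HF-CON")
  expect_gt(median(cv), 0.7)
  expect_lt(median(cv), 0.9)
})

test_that("planted regions must be covered by at least two probes", {
  cfg <- sim_config(n_promoters = 2, promoter_window = c(30, 30),
                    probe_length = 50, probe_spacing = 220, seed = 2,
                    planted_dmrs = data.frame(promoter = 1,
                                              direction = "hyper", effect = 1))
  ps <- gen_promoter_set(cfg, emit_sequences = FALSE)
  expect_warning(des <- gen_array_design(ps$promoters, cfg), "one probe")
  expect_error(gen_medip_experiment(des, cfg), "fewer than 2 probes")
})

test_that("clone generation follows the bisulfite chemistry exactly", {
  amp <- synthetic_amplicon(120, 8)
  # full methylation, perfect conversion: all clones identical, CpG Cs kept
  cs <- gen_bsp_clones(amp, 1.0, 2, 10, conversion_rate = 1.0, seed = 4)
  expect_equal(length(unique(cs$clones)), 1)
  clone <- strsplit(cs$clones[[1]], "")[[1]]
  ref <- strsplit(amp, "")[[1]]
  expect_true(all(clone[cs$cpg_positions] == "C"))
  non_cpg_c <- setdiff(which(ref == "C"), cs$cpg_positions)
  expect_true(all(clone[non_cpg_c] == "T"))
  expect_true(all(clone[ref != "C"] == ref[ref != "C"]))

  # zero methylation: region ratio is exactly 0
  cs0 <- gen_bsp_clones(amp, 0.0, 2, 10, seed = 4)
  expect_equal(methylation_ratio(call_clones(cs0), "region"), 0)

  expect_error(gen_bsp_clones(strrep("AT", 30), 0.5, 1, 10, seed = 1),
               "no CpG")
})

test_that("per-site clone ratios fall in the exact binomial 99% CI", {
  amp <- synthetic_amplicon(120, 3)
  cs <- gen_bsp_clones(amp, 0.6, 1, 1000, seed = 6)
  site <- methylation_ratio(call_clones(cs), "site")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.6) / 1000
  expect_true(all(site >= ci[1] & site <= ci[2]))
})

test_that("phenotype tables honour the factorial design", {
  ph <- gen_phenotypes(n_per_group = 4, seed = 2)
  expect_equal(nrow(ph), 16)
  expect_equal(as.vector(table(ph$group)), rep(4L, 4))
  expect_true(all(c("ogtt_0", "ogtt_30", "ogtt_60", "ogtt_120") %in% names(ph)))
  expect_true(all(ph$fasting_glucose > 0))

  ph0 <- gen_phenotypes(sd = list(body_weight = 0, fasting_glucose = 0,
                                  fasting_insulin = 0, ogtt = 0),
                        n_per_group = 3, seed = 2)
  expect_equal(as.numeric(tapply(ph0$body_weight, ph0$group, sd)), rep(0, 4))

  expect_error(gen_phenotypes(n_per_group = 1, seed = 1), ">= 2")
})
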