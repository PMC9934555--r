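test_that("wild-type background filtering is inclusive at the 3-SD boundary", {
  expect_true(filter_wt_background(4e-5, 1e-5, 1e-5))   # exactly mean + 3 sd
  expect_false(filter_wt_background(3.9e-5, 1e-5, 1e-5))
  expect_true(filter_wt_background(2e-5, 1e-5, 0))      # sd = 0, above mean
  expect_false(filter_wt_background(1e-5, 1e-5, 1e-5))  # at the mean
  expect_true(filter_wt_background(1e-5, 1e-5, 0))      # at the mean, sd = 0
})

test_that("frequency adjustment and enrichment ratios follow the definitions", {
  expect_equal(adjust_frequencies(1e-4, 1e-5), 9e-5)
  expect_equal(adjust_frequencies(1e-4, NA), 1e-4)   # no control -> unchanged
  expect_equal(adjust_frequencies(1e-4, 0), 1e-4)
  expect_equal(enrichment_ratio(1e-4, 2e-4), 2)
  expect_equal(enrichment_ratio(1e-4, 1e-4), 1)
  expect_true(is.na(enrichment_ratio(0, 1e-4)))
})

test_that("region anchors use medians and exclude terminal nonsense", {
  L <- 100L
  phi <- c(0.10, 0.12, 0.08, 0.50, 0.9, 1.0, 1.1)
  class <- c("nonsense", "nonsense", "nonsense", "nonsense",
             "synonymous", "synonymous", "synonymous")
  pos <- c(10L, 20L, 30L, L - 13L, 40L, 50L, 60L)  # L-13 is inside the excluded window
  a <- region_anchors(phi, class, pos, L)
  expect_equal(a$phi_stop, 0.10)   # median of the three retained nonsense
  expect_equal(a$phi_syn, 1.0)
  expect_equal(a$n_stop, 3)

  # position L-14 is the last included one
  pos2 <- pos
  pos2[4] <- L - 14L
  a2 <- region_anchors(phi, class, pos2, L)
  expect_equal(a2$n_stop, 4)
  expect_equal(a2$phi_stop, median(c(0.10, 0.12, 0.08, 0.50)))

  expect_error(region_anchors(phi[5:7], class[5:7], pos[5:7], L), "too few")
  expect_error(
    region_anchors(rep(1, 6), c(rep("nonsense", 3), rep("synonymous", 3)),
                   c(1L, 2L, 3L, 4L, 5L, 6L), L),
    "degenerate")
})

test_that("the functional score formula anchors at 0 and 1 and is monotone", {
  expect_equal(functional_score(0.1, 0.1, 1.0), 0)
  expect_equal(functional_score(1.0, 0.1, 1.0), 1)
  expect_equal(functional_score(0.5, 0.1, 1.0), log(5) / log(10),
               tolerance = 1e-15)
  phi <- seq(0.05, 2, by = 0.05)
  fs <- functional_score(phi, 0.1, 1.0)
  expect_true(all(diff(fs) > 0))
  expect_true(is.na(functional_score(-0.5, 0.1, 1.0)))
})

test_that("error regularization shrinks toward a frequency-dependent prior", {
  # identical replicate agreement everywhere: no shrinkage, se = sd/sqrt(n)
  n <- 200
  fs <- cbind(rep(0.5, n), rep(0.7, n))   # constant sd = sd(c(0.5, 0.7))
  freq <- 10^seq(-5, -3, length.out = n)
  reg <- regularize_errors(fs, freq)
  common_sd <- sd(c(0.5, 0.7))
  expect_equal(reg$se, rep(common_sd / sqrt(2), n), tolerance = 1e-10)

  # zero observed disagreement still yields a positive error
  fs2 <- fs
  fs2[1, ] <- c(0.5, 0.5)
  reg2 <- regularize_errors(fs2, freq)
  expect_gt(reg2$se[1], 0)
  expect_lt(reg2$se[1], reg$se[1])

  # single-replicate variants fall back to the prior
  fs3 <- fs
  fs3[2, 2] <- NA
  reg3 <- regularize_errors(fs3, freq)
  expect_equal(reg3$n_reps[2], 1)
  expect_gt(reg3$se[2], 0)
})

test_that("replicate noise decreases with pre-selection frequency on synthetic data", {
  cfg <- tiny_config(reads_per_tile = 20000L, sigma_log = 1)
  sim <- simulate_tileseq(cfg)
  map <- score_tileseq(sim$counts, sim$controls,
                       scoring_config(protein_length = cfg$protein_length))
  ok <- !is.na(map$sd_obs) & !is.na(map$nonselect_freq)
  dec <- quantile(map$nonselect_freq[ok], c(0.1, 0.9))
  low <- ok & map$nonselect_freq <= dec[1]
  high <- ok & map$nonselect_freq >= dec[2]
  expect_gt(mean(map$se[low]), mean(map$se[high]))
})

test_that("quality and well-measured filters are inclusive at their cutoffs", {
  expect_false(quality_filter(0.31, 1e-3))
  expect_true(quality_filter(0.30, 5e-5))
  expect_false(quality_filter(0.1, 4e-5))
  expect_true(well_measured_flag(21, 2e6))    # 10.5 cpm
  expect_false(well_measured_flag(19, 2e6))   # 9.5 cpm
  expect_true(well_measured_flag(20, 2e6))    # exactly 10 cpm
})

test_that("the scoring chain matches a spreadsheet-style oracle to 1e-12", {
  fx <- hand_count_table()
  oracle <- hand_table_oracle()
  map <- score_tileseq(fx$counts, fx$controls,
                       scoring_config(protein_length = fx$protein_length))
  m <- merge(map, oracle, by = "variant")
  expect_equal(nrow(m), 20)

  # retained/flagged bookkeeping agrees
  expect_identical(!grepl("wt_indistinguishable", m$flags), m$retained)
  expect_identical(grepl("select_floored", m$flags) & m$retained,
                   m$floored & m$retained)

  scored <- m$retained & !is.na(m$fs)
  expect_true(any(scored))
  expect_equal(m$phi.x[scored], m$phi.y[scored], tolerance = 1e-12)
  expect_equal(m$score[scored], m$fs[scored], tolerance = 1e-12)

  # frozen spot checks computed independently from the fixture arithmetic:
  # A1G: phi = (380/1e5 - 2e-5) / (400/1e5 - 3e-5)
  a1g <- m[m$variant == "A1G", ]
  expect_equal(a1g$phi.x, (380e-5 - 2e-5) / (400e-5 - 3e-5), tolerance = 1e-12)
})

test_that("synonymous and nonsense medians anchor at exactly 1 and 0 per region", {
  cfg <- tiny_config()
  sim <- simulate_tileseq(cfg)
  map <- score_tileseq(sim$counts, sim$controls,
                       scoring_config(protein_length = cfg$protein_length))
  L <- cfg$protein_length
  for (rg in unique(map$region)) {
    syn <- map$region == rg & map$class == "synonymous" & !is.na(map$score)
    stp <- map$region == rg & map$class == "nonsense" & !is.na(map$score) &
      map$position <= L - 14
    expect_equal(median(map$score[syn]), 1, tolerance = 1e-12)
    expect_equal(median(map$score[stp]), 0, tolerance = 1e-12)
  }
})

test_that("scoring recovers true fitness on a small synthetic dataset", {
  cfg <- tiny_config()
  sim <- simulate_tileseq(cfg)
  map <- score_tileseq(sim$counts, sim$controls,
                       scoring_config(protein_length = cfg$protein_length))
  m <- merge(map[map$pass, ], sim$truth[, c("variant", "w")], by = "variant")
  expect_gt(cor(m$score, m$w), 0.9)
})

test_that("a missing control condition is a configuration error", {
  fx <- hand_count_table()
  ctrl_ns_only <- fx$controls[fx$controls$condition == "nonselect", ]
  expect_error(score_tileseq(fx$counts, ctrl_ns_only,
                             scoring_config(protein_length = fx$protein_length)),
               "configuration error")
})

test_that("filter bookkeeping conserves variants at every stage", {
  cfg <- tiny_config()
  sim <- simulate_tileseq(cfg)
  map <- score_tileseq(sim$counts, sim$controls,
                       scoring_config(protein_length = cfg$protein_length))
  log <- attr(map, "log")
  expect_true(all(log$n_in == log$n_retained + log$n_flagged))
})
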