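test_that("ground-truth fitness classes follow the configured mixture", {
  # degenerate mixture: everything deleterious
  cfg <- tiny_config()
  cfg$frac_deleterious <- 1
  cfg$frac_hyper <- 0
  truth <- draw_true_fitness(cfg)
  mis <- truth$class == "missense"
  expect_true(all(truth$w[mis] < 0.2))

  # synonymous exactly 1; nonsense 0 except the tolerated terminal window
  cfg2 <- tiny_config()
  truth2 <- draw_true_fitness(cfg2)
  expect_true(all(truth2$w[truth2$class == "synonymous"] == 1))
  non <- truth2$class == "nonsense"
  early <- truth2$position <= cfg2$protein_length - cfg2$tolerated_terminal_nonsense
  expect_true(all(truth2$w[non & early] == 0))
  expect_true(all(truth2$w[non & !early] == 1))
})

test_that("hyper-complementing fraction matches its 2.5% target within binomial error", {
  # ~10,000 missense draws; w > 1 identifies exactly the hyper class
  cfg <- simulation_config(protein_length = 527L, rng_seed = 11L)
  truth <- draw_true_fitness(cfg)
  mis <- truth[truth$class == "missense", ]
  frac <- mean(mis$w > 1)
  p <- cfg$frac_hyper
  tol <- 3 * sqrt(p * (1 - p) / nrow(mis))
  expect_lt(abs(frac - p), tol)
})

test_that("library frequencies scale with the per-clone mutation load", {
  cfg <- tiny_config()
  truth <- draw_true_fitness(cfg)

  cfg0 <- cfg
  cfg0$mean_aa_changes_per_clone <- 0
  lib0 <- simulate_library_frequencies(cfg0, truth)
  expect_true(all(lib0$freq == 0))

  lib <- simulate_library_frequencies(cfg, truth)
  # expected aa changes per clone = sum of frequencies within a region
  for (rg in unique(lib$region)) {
    expect_equal(sum(lib$freq[lib$region == rg]),
                 cfg$mean_aa_changes_per_clone, tolerance = 1e-12)
  }
  # frequencies within a tile leave a wild-type remainder
  tile_sums <- tapply(lib$freq, lib$tile, sum)
  expect_true(all(tile_sums < 1))
  # median variant is well measured at scaled-down depth (>= 10 cpm)
  expect_gte(median(lib$freq) * 1e6, 10)
})

test_that("library frequency draws are deterministic given the seed", {
  cfg <- tiny_config()
  truth <- draw_true_fitness(cfg)
  lib1 <- simulate_library_frequencies(cfg, truth)
  lib2 <- simulate_library_frequencies(cfg, truth)
  expect_identical(lib1$freq, lib2$freq)
})

test_that("selection is an identity at zero generations and monotone in fitness", {
  pre <- c(0.01, 0.02, 0.02, 0.001)
  w <- c(0, 0.5, 1, 1.3)
  expect_equal(simulate_selection(pre, w, generations = 0), pre)

  post <- simulate_selection(pre, w, generations = 3)
  # equal pre, higher fitness -> higher post
  expect_gt(post[3], post[2])
  # null variant driven to zero in the long-generation limit
  post_long <- simulate_selection(pre, w, generations = 200)
  expect_lt(post_long[1], 1e-12)
  # wild-type-like variant keeps its share (g(1) = 1 anchoring): post/pre
  # shrinks only through the mean-fitness renormalization
  expect_true(all(diff(post[order(w)] / pre[order(w)]) > 0))
})

test_that("sequencing counts conserve depth and share the error floor with the control", {
  cfg <- tiny_config()
  truth <- draw_true_fitness(cfg)
  lib <- simulate_library_frequencies(cfg, truth)
  freqs <- data.frame(variant = lib$variant, tile = lib$tile, freq = lib$freq)

  cfg0 <- cfg
  cfg0$sequencing_error_rate <- 0
  seq0 <- simulate_sequencing(freqs, cfg0, "nonselect")
  expect_true(all(seq0$control$count == 0))
  tile_tot <- tapply(seq0$counts$count, seq0$counts$tile, sum)
  expect_true(all(tile_tot <= cfg$reads_per_tile))

  # with error, expected control frequency equals the error floor
  cfg_err <- cfg
  cfg_err$sequencing_error_rate <- 2e-4
  seq_err <- simulate_sequencing(freqs, cfg_err, "nonselect")
  ctrl_freq <- mean(seq_err$control$count / seq_err$control$depth)
  expect_equal(ctrl_freq, cfg_err$sequencing_error_rate, tolerance = 0.15)
})

test_that("a full simulation is byte-identical when repeated with the same seed", {
  cfg <- tiny_config()
  sim1 <- simulate_tileseq(cfg)
  sim2 <- simulate_tileseq(cfg)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$controls, sim2$controls)
  expect_identical(sim1$truth, sim2$truth)

  cfg_b <- tiny_config(rng_seed = 8L)
  sim3 <- simulate_tileseq(cfg_b)
  expect_false(identical(sim1$counts$count, sim3$counts$count))
})

test_that("the isoform pair shares ground truth across the 17-residue offset", {
  cfg <- tiny_config()
  pair <- simulate_isoform_pair(cfg)
  tu <- pair$ubiquitous$truth
  te <- pair$erythroid$truth
  expect_equal(nrow(te), sum(tu$position > ISOFORM_OFFSET))
  back <- merge(
    data.frame(variant = format_variant(te$position + ISOFORM_OFFSET,
                                        te$ref, te$alt), w_e = te$w),
    data.frame(variant = tu$variant, w_u = tu$w), by = "variant")
  # fitness identical where the class is shared; the terminal-nonsense
  # window sits at different absolute positions in the two isoforms
  cls <- merge(
    data.frame(variant = format_variant(te$position + ISOFORM_OFFSET,
                                        te$ref, te$alt), class = te$class),
    back, by = "variant")
  not_nonsense <- cls$class != "nonsense"
  expect_identical(cls$w_e[not_nonsense], cls$w_u[not_nonsense])
})

test_that("simulation configs reject invalid fractions", {
  expect_error(simulation_config(frac_deleterious = 0.8, frac_hyper = 0.3),
               "sum to at most 1")
  expect_error(simulation_config(frac_hyper = -0.1), "\\[0,1\\]|sum to at most 1")
})
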