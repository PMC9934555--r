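test_that("reference sets apply the labeling and proxy-benign rules", {
  clinvar <- data.frame(
    variant = c("R167Q", "R173W", "A31V", "G111R"),
    classification = c("pathogenic", "likely_pathogenic", "benign", "benign"),
    review_criteria = c(TRUE, TRUE, TRUE, TRUE),
    conflicting = c(FALSE, FALSE, FALSE, TRUE)
  )
  expert <- data.frame(variant = c("R225Q", "V215E"),
                       label = c("disease", "non_disease"))
  gnomad <- data.frame(
    variant = c("T59I", "K98R", "E250K"),
    maf = c(4e-4, 4e-4, 6e-4),
    n_homozygotes = c(1L, 0L, 2L),
    pathogenic_annotation = c(FALSE, FALSE, FALSE)
  )
  ref <- build_reference_sets(clinvar, expert, gnomad)
  expect_setequal(ref$variant[ref$label == "positive"],
                  c("R167Q", "R173W", "R225Q"))
  # conflicting ClinVar benign excluded; MAF/homozygote rules enforced
  expect_setequal(ref$variant[ref$label == "negative"],
                  c("A31V", "V215E", "T59I"))
  expect_equal(ref$provenance[ref$variant == "T59I"], "proxy_benign")

  # a variant labeled both ways across sources resolves positive, with warning
  expert2 <- rbind(expert, data.frame(variant = "A31V", label = "disease"))
  expect_warning(ref2 <- build_reference_sets(clinvar, expert2, gnomad),
                 "resolved as positive")
  expect_equal(ref2$label[ref2$variant == "A31V"], "positive")

  # both ways in the same source is an error
  clinvar_bad <- rbind(clinvar,
                       data.frame(variant = "A31V", classification = "pathogenic",
                                  review_criteria = TRUE, conflicting = FALSE))
  expect_error(build_reference_sets(clinvar_bad), "both pathogenic and benign")
})

test_that("precision-recall agrees with exhaustive enumeration on small sets", {
  # hand case: perfectly separated
  curve <- precision_recall(c(0.1, 0.2, 0.8, 0.9),
                            c(TRUE, TRUE, FALSE, FALSE))
  at_half <- curve[which.min(abs(curve$threshold - 0.8)), ]
  expect_equal(at_half$precision, 1)
  expect_equal(at_half$recall, 1)
  expect_equal(max(curve$recall), 1)

  # property: random sets of size <= 12 vs brute-force confusion matrices
  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    score <- round(runif(n), 2)            # ties likely
    label <- c(TRUE, FALSE, runif(n - 2) < 0.5)[seq_len(n)]
    if (sum(label) == 0 || sum(!label) == 0) next
    got <- precision_recall(score, label)
    want <- pr_bruteforce(score, label)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$fpr, want$fpr)
  }
})

test_that("balanced precision equals precision under balanced classes and is duplication-invariant", {
  expect_equal(balanced_precision(0.8, 0.2), 0.8)
  expect_equal(balanced_precision(0.5, 0), 1)
  expect_true(is.na(balanced_precision(0, 0)))

  set.seed(5)
  score_pos <- runif(30, 0, 0.6)
  score_neg <- runif(30, 0.4, 1)
  curve <- precision_recall(c(score_pos, score_neg),
                            rep(c(TRUE, FALSE), each = 30))
  # balanced classes: balanced precision equals empirical precision
  expect_equal(curve$balanced_precision, curve$precision, tolerance = 1e-12)
  # duplicating the negative set leaves balanced precision unchanged
  curve_dup <- precision_recall(c(score_pos, score_neg, score_neg),
                                rep(c(TRUE, FALSE), c(30, 60)))
  expect_equal(curve_dup$balanced_precision, curve$balanced_precision,
               tolerance = 1e-12)
})

test_that("recall-at-90%-balanced-precision and curve area behave on hand cases", {
  perfect <- precision_recall(c(0.1, 0.2, 0.8, 0.9),
                              c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r90bp(perfect), 1)
  expect_equal(aubprc(perfect), 1)

  # inverted separation never reaches 90% balanced precision
  inverted <- precision_recall(c(0.8, 0.9, 0.1, 0.2),
                               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r90bp(inverted), 0)

  # 4-point hand curve: manual trapezoid oracle
  curve <- data.frame(recall = c(0.25, 0.5, 0.75, 1),
                      balanced_precision = c(1, 0.9, 0.8, 0.6))
  hand_area <- 0.25 * 1 +                       # recall-0 anchor at bp = 1
    0.25 * (1 + 0.9) / 2 + 0.25 * (0.9 + 0.8) / 2 + 0.25 * (0.8 + 0.6) / 2
  expect_equal(aubprc(curve), hand_area)
  expect_equal(r90bp(curve), 0.5)
})

test_that("Gaussian density fits are maximum-likelihood with population variance", {
  pair <- fit_density_pair(c(0, 0, 1, 1), c(2, 4))
  expect_equal(pair$mu_pos, 0.5)
  expect_equal(pair$sd_pos, 0.5)
  expect_equal(pair$mu_neg, 3)
  expect_equal(pair$sd_neg, 1)
  expect_error(fit_density_pair(c(1, 1), c(0, 1)), "constant")
  expect_error(fit_density_pair(c(1), c(0, 1)), "at least 2")

  set.seed(12)
  x <- rnorm(5000, 0.2, 0.3)
  y <- rnorm(5000, 0.9, 0.1)
  big <- fit_density_pair(x, y)
  expect_equal(big$mu_pos, 0.2, tolerance = 0.02)
  expect_equal(big$sd_pos, 0.3, tolerance = 0.02)
})

test_that("the log likelihood ratio matches the closed Gaussian form", {
  sym <- fit_density_pair(c(-2, 0), c(0, 2))   # mu = -1, 1; common sd = 1
  expect_equal(llrp(0, sym), 0)

  pair <- list(mu_pos = 0, sd_pos = 0.25, mu_neg = 1, sd_neg = 0.25)
  class(pair) <- "density_pair"
  expect_equal(llrp(0, pair), 8 / log(10), tolerance = 1e-12)

  # strictly decreasing in the score when damaging scores are low
  f <- seq(-1, 2, by = 0.05)
  expect_true(all(diff(llrp(f, pair)) < 0))
})

test_that("posterior odds follow the odds form of Bayes' rule and round-trip", {
  expect_equal(posterior_odds(2, 0.5), 100)
  expect_equal(posterior_odds(0, 0.1), 1 / 9)
  p <- odds_to_probability(posterior_odds(0.7, 0.1))
  expect_equal(p / (1 - p) * (1 - 0.1) / 0.1, 10^0.7, tolerance = 1e-12)
})

test_that("threshold calibration reproduces the halving/mirror structure and constraints", {
  thr <- calibrate_acmg_thresholds(prior = 0.10)
  th <- thr$thresholds
  expect_equal(unname(th["PSt"]), unname(th["PVSt"]) / 2)
  expect_equal(unname(th["PM"]), unname(th["PVSt"]) / 4)
  expect_equal(unname(th["PSu"]), unname(th["PVSt"]) / 8)
  expect_equal(unname(th["BSu"]), -unname(th["PSu"]))
  expect_equal(unname(th["BSt"]), -unname(th["PSt"]))
  expect_true(th["PVSt"] > th["PSt"] && th["PSt"] > th["PM"] &&
              th["PM"] > th["PSu"] && th["PSu"] > 0 &&
              0 > th["BSu"] && th["BSu"] > th["BSt"])

  # independent re-check of every posterior constraint at the refined odds
  rules <- thr$rules
  po <- 0.10 / 0.90
  post <- sapply(rules$exponent, function(e) {
    o <- thr$odds_raw^(e / 8) * po
    o / (1 + o)
  })
  expect_true(all(post[rules$tier == "P"] > 0.99))
  expect_true(all(post[rules$tier == "LP"] > 0.90 - 1e-9))
  expect_true(all(post[rules$tier == "LB"] < 0.10))
  expect_true(all(post[rules$tier == "B"] < 0.01))

  # posterior probability is monotone increasing in the prior at fixed
  # evidence odds, so pathogenic rules become satisfiable at smaller odds
  priors <- seq(0.05, 0.95, by = 0.05)
  for (e in c(6, 8, 10)) {
    post_grid <- sapply(priors, function(p) {
      o <- 350^(e / 8) * p / (1 - p)
      o / (1 + o)
    })
    expect_true(all(diff(post_grid) > 0))
  }

  # an unsatisfiable rule set fails loudly, naming the binding rule
  rules_bad <- acmg_rule_set()
  rules_bad$tier[rules_bad$rule == "LB: 2 supporting-benign"] <- "B"
  expect_error(calibrate_acmg_thresholds(rules = rules_bad, grid = 2:50),
               "supporting-benign")
})

test_that("rule sets round-trip through YAML", {
  rules <- acmg_rule_set()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rule_set(rules, path)
  back <- read_rule_set(path)
  expect_equal(back$exponent, rules$exponent)
  expect_equal(back$tier, rules$tier)
})

test_that("evidence categories follow the calibrated cut-points", {
  thr <- calibrate_acmg_thresholds(prior = 0.10)
  expect_equal(assign_evidence(0.70, thr), "PM")
  expect_equal(assign_evidence(0, thr), "indeterminate")
  expect_equal(assign_evidence(-1.5, thr), "BSt")
  expect_equal(assign_evidence(c(3, 1.3, 0.5, -0.33), thr),
               c("PVSt", "PSt", "PSu", "BSu"))
})

test_that("map evaluation separates pathogenic from benign on synthetic data with masking", {
  cfg <- tiny_config()
  sim <- simulate_tileseq(cfg)
  map <- score_tileseq(sim$counts, sim$controls,
                       scoring_config(protein_length = cfg$protein_length))
  ref <- synthetic_reference_set(sim$truth, map, n_positive = 20L,
                                 n_negative = 10L, seed = 4L)
  ev <- evaluate_map(map, ref)
  expect_gt(ev$aubprc, 0.9)
  expect_gt(ev$r90bp, 0.8)
  ev_masked <- evaluate_map(map, ref, mask = matrix(c(1, 30), ncol = 2))
  expect_lte(ev_masked$n_pos + ev_masked$n_neg, ev$n_pos + ev$n_neg)
})
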