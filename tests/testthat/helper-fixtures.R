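# Shared fixtures: a small, fast simulation configuration and a hand-built
# 20-variant count table (one region, one tile, one replicate) used for
# oracle-equivalence checks of the scoring chain.

tiny_config <- function(...) {
  defaults <- list(protein_length = 60L, n_regions = 2L,
                   n_tiles_per_region = 2L, reads_per_tile = 50000L,
                   rng_seed = 7L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# A 20-variant count table over a 40-residue protein: 12 missense, 3
# synonymous, 5 nonsense (one terminal, position 30 > 40 - 14 = 26, so it
# is excluded from the nonsense anchor). Depth 1e5 throughout. The
# wild-type control has two replicates per condition.
hand_count_table <- function() {
  depth <- 100000L
  tab <- data.frame(
    variant = c("A1G", "A2G", "C3R", "C4R", "G5*", "D6N", "D7E", "E8=",
                "F9L", "G10*", "H11Y", "I12V", "K13=", "L14P", "M15*",
                "N16D", "P17=", "Q18R", "R19K", "S30*"),
    ns_count = c(400L, 350L, 500L, 450L, 300L, 600L, 380L, 420L,
                 5L, 280L, 330L, 410L, 390L, 360L, 310L,
                 440L, 470L, 520L, 480L, 260L),
    sel_count = c(380L, 20L, 510L, 35L, 6L, 590L, 370L, 400L,
                  4L, 5L, 1L, 400L, 370L, 30L, 7L,
                  430L, 450L, 505L, 15L, 250L),
    stringsAsFactors = FALSE
  )
  counts <- rbind(
    data.frame(variant = tab$variant, tile = "R1T1", condition = "nonselect",
               replicate = 1L, count = tab$ns_count, depth = depth),
    data.frame(variant = tab$variant, tile = "R1T1", condition = "select",
               replicate = 1L, count = tab$sel_count, depth = depth)
  )
  # control counts: 2 and 4 reads in nonselect (mean 3e-5, sd ~1.41e-5),
  # 1 and 3 in select (mean 2e-5, sd ~1.41e-5), identical for all variants
  controls <- rbind(
    data.frame(variant = tab$variant, tile = "R1T1", condition = "nonselect",
               replicate = 1L, count = 2L, depth = depth),
    data.frame(variant = tab$variant, tile = "R1T1", condition = "nonselect",
               replicate = 2L, count = 4L, depth = depth),
    data.frame(variant = tab$variant, tile = "R1T1", condition = "select",
               replicate = 1L, count = 1L, depth = depth),
    data.frame(variant = tab$variant, tile = "R1T1", condition = "select",
               replicate = 2L, count = 3L, depth = depth)
  )
  list(counts = counts, controls = controls, depth = depth,
       protein_length = 40L)
}

# Spreadsheet-style independent computation of the scoring chain on the
# hand table: plain arithmetic only, no package scoring functions.
hand_table_oracle <- function() {
  fx <- hand_count_table()
  depth <- fx$depth
  ns <- fx$counts[fx$counts$condition == "nonselect", ]
  sl <- fx$counts[fx$counts$condition == "select", ]
  ns_freq <- ns$count / depth
  sel_freq <- sl$count[match(ns$variant, sl$variant)] / depth

  wt_mean_ns <- mean(c(2, 4) / depth)
  wt_sd_ns <- sd(c(2, 4) / depth)
  wt_mean_sel <- mean(c(1, 3) / depth)
  wt_sd_sel <- sd(c(1, 3) / depth)

  retained <- ns_freq >= wt_mean_ns + 3 * wt_sd_ns
  adj_ns <- ns_freq - wt_mean_ns
  adj_sel <- sel_freq - wt_mean_sel
  floored <- sel_freq < wt_mean_sel + 3 * wt_sd_sel | adj_sel <= 0
  adj_sel[floored] <- 1 / depth
  phi <- ifelse(retained & adj_ns > 0, adj_sel / adj_ns, NA_real_)

  pv <- regmatches(ns$variant, regexec("^([A-Z])([0-9]+)(.)$", ns$variant))
  pos <- as.integer(vapply(pv, `[`, character(1), 3L))
  alt <- vapply(pv, `[`, character(1), 4L)
  is_syn <- alt == "="
  is_stop <- alt == "*"
  phi_stop <- median(phi[is_stop & pos <= fx$protein_length - 14 & !is.na(phi)])
  phi_syn <- median(phi[is_syn & !is.na(phi)])
  fs <- log(phi / phi_stop) / log(phi_syn / phi_stop)
  data.frame(variant = ns$variant, retained = retained, floored = floored,
             phi = phi, fs = fs, stringsAsFactors = FALSE)
}

# Exhaustive confusion-matrix enumeration oracle for precision-recall.
pr_bruteforce <- function(score, positive) {
  thresholds <- c(sort(unique(score)), Inf)
  rows <- lapply(thresholds, function(t) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(score)) {
      pred <- score[i] < t
      if (pred && positive[i]) tp <- tp + 1
      if (pred && !positive[i]) fp <- fp + 1
      if (!pred && positive[i]) fn <- fn + 1
      if (!pred && !positive[i]) tn <- tn + 1
    }
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn), fpr = fp / (fp + tn))
  })
  do.call(rbind, rows)
}
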