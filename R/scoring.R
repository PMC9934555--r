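# Count tables to functional impact scores.
#
# The scoring chain, per region and replicate:
#   frequency = count / depth
#   -> wild-type background filter (retain if freq >= wt_mean + 3 wt_sd)
#   -> wild-type subtraction (adjusted = raw - control mean; depleted select
#      frequencies floored to one pseudo-read at tile depth)
#   -> enrichment ratio  Phi = adjusted_select / adjusted_nonselect
#   -> functional score  FS = ln(Phi/PhiSTOP) / ln(PhiSYN/PhiSTOP)
# with PhiSTOP the median nonsense enrichment (excluding the last 14
# residues) and PhiSYN the median synonymous enrichment, per region.
# Replicate scores are averaged, standard errors are regularized against a
# frequency-dependent prior, the averaged map is re-anchored per region so
# the synonymous median is exactly 1 and the nonsense median exactly 0, and
# quality filters (se <= 0.3, nonselect frequency >= 0.005%) are applied.
# All threshold comparisons are inclusive on the retained side.

#' Scoring configuration
#'
#' Thresholds and constants of the scoring chain. Defaults are the
#' published values: a 3-standard-deviation wild-type background rule,
#' standard-error cutoff 0.3, nonselect frequency cutoff 0.005% (5e-5),
#' well-measured bound of 10 counts per million, and exclusion of nonsense
#' variants in the last 14 residues from the nonsense anchor.
#'
#' @param n_sd Wild-type background filter width (standard deviations).
#' @param max_se Maximum regularized standard error for a quality pass.
#' @param min_freq Minimum nonselect frequency for a quality pass.
#' @param min_cpm Well-measured bound, in counts per million nonselect reads.
#' @param terminal_exclusion Number of C-terminal residues excluded from the
#'   nonsense anchor median.
#' @param min_anchor Minimum number of nonsense and synonymous anchor
#'   variants required per region.
#' @param nu Pseudo-replicate weight of the error-regularization prior.
#' @param pseudo_count Pseudo-reads used to floor depleted select
#'   frequencies.
#' @param protein_length Protein length; inferred from the data when `NULL`.
#' @param isoform Isoform label attached to the output.
#' @return A list of class `"scoring_config"`.
#' @export
scoring_config <- function(n_sd = 3, max_se = 0.3, min_freq = 5e-5,
                           min_cpm = 10, terminal_exclusion = 14L,
                           min_anchor = 3L, nu = 2, pseudo_count = 1,
                           protein_length = NULL, isoform = "ubiquitous") {
  cfg <- list(n_sd = n_sd, max_se = max_se, min_freq = min_freq,
              min_cpm = min_cpm, terminal_exclusion = as.integer(terminal_exclusion),
              min_anchor = as.integer(min_anchor), nu = nu,
              pseudo_count = pseudo_count, protein_length = protein_length,
              isoform = isoform)
  class(cfg) <- "scoring_config"
  cfg
}

#' Wild-type background filter
#'
#' A variant frequency is distinguishable from the wild-type-control
#' background when it reaches `wt_mean + n_sd * wt_sd` (inclusive).
#'
#' @param freq Observed variant frequencies.
#' @param wt_mean,wt_sd Mean and standard deviation of the corresponding
#'   wild-type-control frequencies.
#' @param n_sd Filter width in standard deviations (default 3).
#' @return Logical vector: `TRUE` where the variant is retained.
#' @export
filter_wt_background <- function(freq, wt_mean, wt_sd, n_sd = 3) {
  freq >= wt_mean + n_sd * wt_sd
}

#' Wild-type-subtracted frequencies
#'
#' @param raw Raw variant frequencies (count / depth).
#' @param control Wild-type-control mean frequencies (0 or `NA` mean no
#'   subtraction).
#' @return Adjusted frequencies `raw - control`.
#' @export
adjust_frequencies <- function(raw, control) {
  control[is.na(control)] <- 0
  raw - control
}

#' Enrichment ratio
#'
#' @param adjusted_nonselect,adjusted_select Wild-type-subtracted variant
#'   frequencies in the two conditions.
#' @return `Phi = adjusted_select / adjusted_nonselect`; `NA` where the
#'   nonselect frequency is not positive.
#' @export
enrichment_ratio <- function(adjusted_nonselect, adjusted_select) {
  phi <- adjusted_select / adjusted_nonselect
  phi[adjusted_nonselect <= 0] <- NA_real_
  phi
}

#' Region anchors: median nonsense and synonymous enrichment
#'
#' `PhiSTOP` is the median enrichment ratio over nonsense variants at
#' positions up to `protein_length - terminal_exclusion` (C-terminal
#' truncations are unlikely to abolish function and are excluded);
#' `PhiSYN` is the median over synonymous variants.
#'
#' @param phi Enrichment ratios.
#' @param class Variant classes (`"missense"`, `"synonymous"`, `"nonsense"`),
#'   parallel to `phi`.
#' @param position Residue positions, parallel to `phi`.
#' @param protein_length Full protein length (for the terminal exclusion).
#' @param terminal_exclusion Number of C-terminal residues excluded from the
#'   nonsense anchor (default 14).
#' @param min_anchor Minimum usable anchor variants of each class.
#' @return A list of class `"region_anchors"` with elements `phi_stop`,
#'   `phi_syn`, `n_stop`, `n_syn`.
#' @export
region_anchors <- function(phi, class, position, protein_length,
                           terminal_exclusion = 14L, min_anchor = 3L) {
  ok <- !is.na(phi)
  stop_idx <- ok & class == "nonsense" &
    position <= protein_length - terminal_exclusion
  syn_idx <- ok & class == "synonymous"
  if (sum(stop_idx) < min_anchor || sum(syn_idx) < min_anchor) {
    stop("too few anchor variants in region: ", sum(stop_idx), " nonsense, ",
         sum(syn_idx), " synonymous (need >= ", min_anchor, " of each)")
  }
  anchors <- list(phi_stop = median(phi[stop_idx]),
                  phi_syn = median(phi[syn_idx]),
                  n_stop = sum(stop_idx), n_syn = sum(syn_idx))
  if (anchors$phi_syn == anchors$phi_stop) {
    stop("degenerate anchors: synonymous and nonsense median enrichment are equal")
  }
  class(anchors) <- "region_anchors"
  anchors
}

#' Functional impact score
#'
#' `FS = ln(Phi/PhiSTOP) / ln(PhiSYN/PhiSTOP)`: 0 when `Phi` equals the
#' nonsense median, 1 when it equals the synonymous median.
#'
#' @param phi Enrichment ratios.
#' @param anchors A `"region_anchors"` object, or the nonsense median
#'   `PhiSTOP` when `phi_syn` is given separately.
#' @param phi_syn Synonymous median `PhiSYN` (when `anchors` is a number).
#' @return Functional scores; `NA` where `phi` is not positive.
#' @export
functional_score <- function(phi, anchors, phi_syn = NULL) {
  if (inherits(anchors, "region_anchors")) {
    phi_stop <- anchors$phi_stop
    phi_syn <- anchors$phi_syn
  } else {
    phi_stop <- anchors
  }
  stopifnot(phi_stop > 0, phi_syn > 0, phi_syn != phi_stop)
  fs <- rep(NA_real_, length(phi))
  ok <- !is.na(phi) & phi > 0
  fs[ok] <- log(phi[ok] / phi_stop) / log(phi_syn / phi_stop)
  fs
}

# Monotone (non-increasing in frequency) trend of replicate standard
# deviation versus nonselect frequency, fitted as a running median in
# log-log space followed by isotonic regression.
fit_sd_trend <- function(freq, sd_obs) {
  use <- !is.na(freq) & !is.na(sd_obs) & freq > 0 & sd_obs > 0
  if (sum(use) < 10) {
    fallback <- if (any(use)) exp(mean(log(sd_obs[use]))) else 0.1
    return(function(f) rep(fallback, length(f)))
  }
  lf <- log10(freq[use])
  ls <- log10(sd_obs[use])
  ord <- order(lf)
  lf <- lf[ord]
  ls <- ls[ord]
  k <- min(51L, 2L * (sum(use) %/% 2L) - 1L)
  if (k < 1L) k <- 1L
  smooth <- runmed(ls, k)
  # non-increasing in frequency <=> non-decreasing in -log10(freq)
  iso <- isoreg(-lf, smooth)
  fitted_inc <- iso$yf[order(order(-lf))]
  ux <- !duplicated(lf)
  function(f) {
    lfq <- log10(pmax(f, min(freq[use], na.rm = TRUE) / 10))
    10^approx(lf[ux], fitted_inc[ux], xout = lfq, rule = 2)$y
  }
}

#' Regularized standard errors from replicate agreement
#'
#' Combines the observed between-replicate standard deviation of each
#' variant's score with a prior standard deviation predicted from the
#' monotone trend of replicate disagreement versus pre-selection frequency,
#' by empirical-Bayes shrinkage:
#' `var_post = (nu * sd_prior^2 + (n - 1) * sd_obs^2) / (nu + n - 1)`,
#' and reports the standard error of the replicate mean,
#' `sqrt(var_post / n)`. Variants measured in a single replicate fall back
#' to the prior alone.
#'
#' @param fs_reps Matrix of per-replicate functional scores (variants in
#'   rows, replicates in columns; `NA` for missing).
#' @param nonselect_freq Pre-selection frequencies, one per variant.
#' @param nu Pseudo-replicate weight of the prior (default 2).
#' @return A data frame with columns `n_reps`, `sd_obs`, `sd_prior` and `se`
#'   (all strictly positive where defined).
#' @export
regularize_errors <- function(fs_reps, nonselect_freq, nu = 2) {
  fs_reps <- as.matrix(fs_reps)
  n_reps <- rowSums(!is.na(fs_reps))
  sd_obs <- apply(fs_reps, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2) sd(x) else NA_real_
  })
  trend <- fit_sd_trend(nonselect_freq[n_reps >= 2], sd_obs[n_reps >= 2])
  sd_prior <- trend(nonselect_freq)
  var_post <- ifelse(
    n_reps >= 2,
    (nu * sd_prior^2 + (n_reps - 1) * sd_obs^2) / (nu + n_reps - 1),
    sd_prior^2
  )
  se <- sqrt(var_post / pmax(n_reps, 1))
  se[n_reps == 0] <- NA_real_
  data.frame(n_reps = n_reps, sd_obs = sd_obs, sd_prior = sd_prior, se = se)
}

#' Quality filter
#'
#' A scored variant passes when its regularized standard error is at most
#' `max_se` (default 0.3) and its nonselect frequency at least `min_freq`
#' (default 0.005% = 5e-5); both comparisons inclusive.
#'
#' @param se Regularized standard errors.
#' @param nonselect_freq Pre-selection frequencies.
#' @param max_se,min_freq Cutoffs.
#' @return Logical vector.
#' @export
quality_filter <- function(se, nonselect_freq, max_se = 0.3, min_freq = 5e-5) {
  !is.na(se) & se <= max_se & nonselect_freq >= min_freq
}

#' Well-measured flag
#'
#' A variant is well measured when its pre-selection representation reaches
#' `min_cpm` counts per million reads (inclusive).
#'
#' @param count Pre-selection read counts.
#' @param depth Sequencing depths.
#' @param min_cpm Bound in counts per million (default 10).
#' @return Logical vector.
#' @export
well_measured_flag <- function(count, depth, min_cpm = 10) {
  count / depth * 1e6 >= min_cpm
}

# condition-wise frequency table for one replicate within one region
.freq_by_condition <- function(tab, condition) {
  sub <- tab[tab$condition == condition, ]
  agg <- stats::aggregate(cbind(count, depth) ~ variant, data = sub, FUN = sum)
  agg$freq <- agg$count / agg$depth
  agg
}

#' Score a TileSeq experiment
#'
#' Runs the full scoring chain on a count table plus matched wild-type
#' controls and returns one row per variant with its enrichment ratio,
#' functional score, regularized standard error, filter flags and quality
#' status. Filter bookkeeping (records in / retained / flagged per stage)
#' is attached as attribute `"log"`.
#'
#' @param counts Count records in the [read_count_table()] schema. A
#'   `region` column is used if present; otherwise the region is derived
#'   from the tile label prefix (`"R1T3"` belongs to region `"R1"`).
#' @param controls Wild-type-control count records, same schema (replicates
#'   here index control sequencing libraries).
#' @param config A [scoring_config()].
#' @return Data frame of class `"scored_map"` with columns `variant`,
#'   `position`, `ref`, `alt`, `class`, `region`, `isoform`, `phi`, `score`,
#'   `se`, `sd_obs`, `n_reps`, `nonselect_freq`, `select_freq`,
#'   `nonselect_count`, `depth`, `well_measured`, `flags`, `pass`.
#' @export
score_tileseq <- function(counts, controls, config = scoring_config()) {
  validate_count_table(counts, "counts")
  validate_count_table(controls, "controls")
  if (!all(c("nonselect", "select") %in% unique(controls$condition))) {
    stop("wild-type control is missing a condition (configuration error)")
  }
  if (!"region" %in% names(counts)) {
    counts$region <- sub("T[0-9]+$", "", counts$tile)
  }
  pv <- parse_variant(counts$variant)
  counts$position <- pv$position
  counts$ref <- pv$ref
  counts$alt <- pv$alt
  counts$class <- variant_class(pv$alt)
  L <- if (is.null(config$protein_length)) max(counts$position)
       else config$protein_length

  # per-variant control mean/sd per condition across control replicates
  ctrl <- controls
  ctrl$freq <- ctrl$count / ctrl$depth
  ctrl_stats <- stats::aggregate(
    freq ~ variant + condition, data = ctrl,
    FUN = function(x) c(mean = mean(x), sd = if (length(x) >= 2) sd(x) else 0)
  )
  ctrl_stats <- data.frame(
    variant = ctrl_stats$variant, condition = ctrl_stats$condition,
    wt_mean = ctrl_stats$freq[, "mean"], wt_sd = ctrl_stats$freq[, "sd"],
    stringsAsFactors = FALSE
  )
  ctrl_of <- function(variants, condition, what) {
    sub <- ctrl_stats[ctrl_stats$condition == condition, ]
    idx <- match(variants, sub$variant)
    out <- sub[[what]][idx]
    out[is.na(out)] <- 0
    out
  }

  replicates <- sort(unique(counts$replicate))
  regions <- sort(unique(counts$region))
  per_rep <- list()
  log_rows <- list()

  for (rg in regions) {
    for (rp in replicates) {
      tab <- counts[counts$region == rg & counts$replicate == rp, ]
      if (nrow(tab) == 0) next
      ns <- .freq_by_condition(tab, "nonselect")
      sl <- .freq_by_condition(tab, "select")
      rec <- merge(ns[, c("variant", "count", "depth", "freq")],
                   sl[, c("variant", "freq")],
                   by = "variant", all.x = TRUE, suffixes = c("_ns", ""))
      names(rec)[names(rec) == "freq_ns"] <- "ns_freq"
      names(rec)[names(rec) == "freq"] <- "sel_freq"
      rec$sel_freq[is.na(rec$sel_freq)] <- 0
      meta <- tab[!duplicated(tab$variant),
                  c("variant", "position", "ref", "alt", "class")]
      rec <- merge(rec, meta, by = "variant")

      rec$flag_wt <- !filter_wt_background(
        rec$ns_freq, ctrl_of(rec$variant, "nonselect", "wt_mean"),
        ctrl_of(rec$variant, "nonselect", "wt_sd"), config$n_sd)
      sel_low <- !filter_wt_background(
        rec$sel_freq, ctrl_of(rec$variant, "select", "wt_mean"),
        ctrl_of(rec$variant, "select", "wt_sd"), config$n_sd)

      rec$adj_ns <- adjust_frequencies(
        rec$ns_freq, ctrl_of(rec$variant, "nonselect", "wt_mean"))
      rec$adj_sel <- adjust_frequencies(
        rec$sel_freq, ctrl_of(rec$variant, "select", "wt_mean"))
      floor_freq <- config$pseudo_count / rec$depth
      rec$flag_floor <- sel_low | rec$adj_sel <= 0
      rec$adj_sel[rec$flag_floor] <- floor_freq[rec$flag_floor]
      rec$flag_lowfreq <- !rec$flag_wt & rec$adj_ns <= 0

      usable <- !rec$flag_wt & !rec$flag_lowfreq
      rec$phi <- NA_real_
      rec$phi[usable] <- enrichment_ratio(rec$adj_ns[usable], rec$adj_sel[usable])
      anchors <- region_anchors(rec$phi, rec$class, rec$position, L,
                                config$terminal_exclusion, config$min_anchor)
      rec$fs <- NA_real_
      rec$fs[usable] <- functional_score(rec$phi[usable], anchors)
      rec$region <- rg
      rec$replicate <- rp

      log_rows[[paste(rg, rp)]] <- data.frame(
        stage = c("wt_background", "nonselect_positive"),
        region = rg, replicate = rp,
        n_in = c(nrow(rec), sum(!rec$flag_wt)),
        n_retained = c(sum(!rec$flag_wt), sum(usable)),
        n_flagged = c(sum(rec$flag_wt), sum(rec$flag_lowfreq)),
        stringsAsFactors = FALSE
      )
      per_rep[[paste(rg, rp)]] <- rec
    }
  }
  all_rep <- do.call(rbind, per_rep)

  # aggregate replicates per (variant, region)
  key <- paste(all_rep$variant, all_rep$region, sep = "|")
  uk <- !duplicated(key)
  base <- all_rep[uk, c("variant", "position", "ref", "alt", "class", "region")]
  base_key <- key[uk]
  n_rep_total <- length(replicates)
  fs_mat <- matrix(NA_real_, nrow(base), n_rep_total)
  phi_mat <- matrix(NA_real_, nrow(base), n_rep_total)
  ns_mat <- matrix(NA_real_, nrow(base), n_rep_total)
  sel_mat <- matrix(NA_real_, nrow(base), n_rep_total)
  cnt_mat <- matrix(NA_real_, nrow(base), n_rep_total)
  dep_mat <- matrix(NA_real_, nrow(base), n_rep_total)
  flag_wt_any <- flag_floor_any <- flag_low_any <- logical(nrow(base))
  for (j in seq_along(replicates)) {
    sub <- all_rep[all_rep$replicate == replicates[j], ]
    idx <- match(paste(sub$variant, sub$region, sep = "|"), base_key)
    fs_mat[idx, j] <- sub$fs
    phi_mat[idx, j] <- sub$phi
    ns_mat[idx, j] <- sub$ns_freq
    sel_mat[idx, j] <- sub$sel_freq
    cnt_mat[idx, j] <- sub$count
    dep_mat[idx, j] <- sub$depth
    flag_wt_any[idx] <- flag_wt_any[idx] | sub$flag_wt
    flag_floor_any[idx] <- flag_floor_any[idx] | sub$flag_floor
    flag_low_any[idx] <- flag_low_any[idx] | sub$flag_lowfreq
  }
  base$phi <- rowMeans(phi_mat, na.rm = TRUE)
  base$phi[is.nan(base$phi)] <- NA_real_
  base$score <- rowMeans(fs_mat, na.rm = TRUE)
  base$score[is.nan(base$score)] <- NA_real_
  base$nonselect_freq <- rowMeans(ns_mat, na.rm = TRUE)
  base$select_freq <- rowMeans(sel_mat, na.rm = TRUE)
  base$nonselect_count <- rowSums(cnt_mat, na.rm = TRUE)
  base$depth <- rowSums(dep_mat, na.rm = TRUE)

  reg <- regularize_errors(fs_mat, base$nonselect_freq, config$nu)
  base$se <- reg$se
  base$sd_obs <- reg$sd_obs
  base$n_reps <- reg$n_reps

  # re-anchor the replicate-averaged scores per region so the synonymous
  # median is exactly 1 and the (non-terminal) nonsense median exactly 0
  for (rg in regions) {
    in_rg <- base$region == rg & !is.na(base$score)
    syn <- in_rg & base$class == "synonymous"
    stp <- in_rg & base$class == "nonsense" &
      base$position <= L - config$terminal_exclusion
    if (sum(syn) < config$min_anchor || sum(stp) < config$min_anchor) {
      stop("too few anchor variants for re-anchoring region ", rg)
    }
    med_syn <- median(base$score[syn])
    med_stp <- median(base$score[stp])
    if (med_syn == med_stp) stop("degenerate re-anchoring in region ", rg)
    scale <- med_syn - med_stp
    sel_rg <- base$region == rg
    base$score[sel_rg] <- (base$score[sel_rg] - med_stp) / scale
    base$se[sel_rg] <- base$se[sel_rg] / abs(scale)
    base$sd_obs[sel_rg] <- base$sd_obs[sel_rg] / abs(scale)
  }

  base$well_measured <- well_measured_flag(base$nonselect_count, base$depth,
                                           config$min_cpm)
  flags <- character(nrow(base))
  add_flag <- function(flags, which, label) {
    ifelse(which, ifelse(flags == "", label, paste(flags, label, sep = ",")),
           flags)
  }
  flags <- add_flag(flags, flag_wt_any, "wt_indistinguishable")
  flags <- add_flag(flags, flag_low_any, "low_freq")
  flags <- add_flag(flags, flag_floor_any, "select_floored")
  flags <- add_flag(flags, !is.na(base$se) & base$se > config$max_se, "high_se")
  base$flags <- flags

  base$pass <- quality_filter(base$se, base$nonselect_freq,
                              config$max_se, config$min_freq) &
    !flag_wt_any & !flag_low_any
  base$isoform <- config$isoform

  qc_log <- data.frame(
    stage = c("quality_se", "quality_freq"),
    region = "all", replicate = NA_integer_,
    n_in = c(sum(!is.na(base$se)), sum(!is.na(base$nonselect_freq))),
    n_retained = c(sum(base$se <= config$max_se, na.rm = TRUE),
                   sum(base$nonselect_freq >= config$min_freq, na.rm = TRUE)),
    n_flagged = c(sum(base$se > config$max_se, na.rm = TRUE),
                  sum(base$nonselect_freq < config$min_freq, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  out <- base[order(base$position, base$alt),
              c("variant", "position", "ref", "alt", "class", "region",
                "isoform", "phi", "score", "se", "sd_obs", "n_reps",
                "nonselect_freq", "select_freq", "nonselect_count", "depth",
                "well_measured", "flags", "pass")]
  rownames(out) <- NULL
  attr(out, "log") <- rbind(do.call(rbind, log_rows), qc_log)
  class(out) <- c("scored_map", "data.frame")
  out
}
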