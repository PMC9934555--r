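# Clinical calibration: reference variant sets, balanced precision-recall
# evaluation, Gaussian log-likelihood ratios of pathogenicity (LLRp), and
# ACMG/AMP evidence-strength threshold calibration in the posterior-odds
# framework of Tavtigian-style modeling (evidence levels on an
# exponent-halving odds scale).

#' Build labeled reference variant sets
#'
#' Assembles a positive (pathogenic) and negative (benign) reference set
#' from three sources. Positives are pathogenic/likely-pathogenic ClinVar
#' variants and expert-center disease variants. Negatives are
#' benign/likely-benign ClinVar variants submitted with review criteria and
#' without conflicting interpretations, expert-center non-disease variants,
#' and "proxy-benign" population variants: minor allele frequency below
#' 0.0005, observed homozygous in at least one individual, and carrying no
#' pathogenicity annotation. A variant labeled both ways across sources
#' resolves to positive with a warning.
#'
#' @param clinvar Data frame with columns `variant`, `classification`
#'   (`"pathogenic"`, `"likely_pathogenic"`, `"benign"`, `"likely_benign"`,
#'   others ignored), `review_criteria` (logical) and `conflicting`
#'   (logical). Optional.
#' @param expert Data frame with columns `variant` and `label`
#'   (`"disease"` or `"non_disease"`). Optional.
#' @param gnomad Data frame with columns `variant`, `maf`, `n_homozygotes`
#'   and `pathogenic_annotation` (logical). Optional.
#' @param max_maf Proxy-benign allele-frequency bound (default 0.0005).
#' @return Data frame with columns `variant`, `label` (`"positive"` /
#'   `"negative"`) and `provenance`.
#' @export
build_reference_sets <- function(clinvar = NULL, expert = NULL, gnomad = NULL,
                                 max_maf = 5e-4) {
  rows <- list()
  if (!is.null(clinvar) && nrow(clinvar) > 0) {
    cls <- tolower(clinvar$classification)
    path <- cls %in% c("pathogenic", "likely_pathogenic")
    ben <- cls %in% c("benign", "likely_benign") &
      clinvar$review_criteria & !clinvar$conflicting
    both <- clinvar$variant[path] [clinvar$variant[path] %in% clinvar$variant[ben]]
    if (length(both) > 0) {
      stop("variant(s) labeled both pathogenic and benign in ClinVar input: ",
           paste(unique(both), collapse = ", "))
    }
    if (any(path)) {
      rows$cp <- data.frame(variant = clinvar$variant[path], label = "positive",
                            provenance = "clinvar_pathogenic",
                            stringsAsFactors = FALSE)
    }
    if (any(ben)) {
      rows$cb <- data.frame(variant = clinvar$variant[ben], label = "negative",
                            provenance = "clinvar_benign",
                            stringsAsFactors = FALSE)
    }
  }
  if (!is.null(expert) && nrow(expert) > 0) {
    lab <- tolower(expert$label)
    dup <- expert$variant[lab == "disease"][
      expert$variant[lab == "disease"] %in% expert$variant[lab == "non_disease"]]
    if (length(dup) > 0) {
      stop("variant(s) labeled both disease and non-disease by expert centers: ",
           paste(unique(dup), collapse = ", "))
    }
    rows$ep <- data.frame(variant = expert$variant[lab == "disease"],
                          label = "positive", provenance = "expert_center",
                          stringsAsFactors = FALSE)
    rows$en <- data.frame(variant = expert$variant[lab == "non_disease"],
                          label = "negative", provenance = "expert_center",
                          stringsAsFactors = FALSE)
  }
  if (!is.null(gnomad) && nrow(gnomad) > 0) {
    proxy <- gnomad$maf < max_maf & gnomad$n_homozygotes >= 1 &
      !gnomad$pathogenic_annotation
    rows$pb <- data.frame(variant = gnomad$variant[proxy], label = "negative",
                          provenance = "proxy_benign", stringsAsFactors = FALSE)
  }
  ref <- do.call(rbind, rows)
  if (is.null(ref) || nrow(ref) == 0) stop("no reference variants supplied")
  pos <- unique(ref$variant[ref$label == "positive"])
  overlap <- ref$label == "negative" & ref$variant %in% pos
  if (any(overlap)) {
    warning("variant(s) in both sets resolved as positive: ",
            paste(unique(ref$variant[overlap]), collapse = ", "))
    ref <- ref[!overlap, ]
  }
  ref <- ref[!duplicated(ref$variant), ]
  rownames(ref) <- NULL
  ref
}

#' Threshold-indexed precision-recall curve
#'
#' One point per distinct score threshold `t`, under the classification
#' rule "score below `t` predicts pathogenic" (for maps where damaging
#' scores are low; set `damaging_direction = "high"` to flip). A final
#' threshold above all scores is always included so recall reaches 1.
#'
#' @param score Numeric scores.
#' @param label Logical (`TRUE` = positive/pathogenic) or character
#'   (`"positive"` / `"negative"`).
#' @param damaging_direction `"low"` (default) or `"high"`.
#' @return Data frame with columns `threshold`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `fpr`, `balanced_precision`.
#' @export
precision_recall <- function(score, label, damaging_direction = c("low", "high")) {
  damaging_direction <- match.arg(damaging_direction)
  if (is.character(label) || is.factor(label)) {
    label <- as.character(label) == "positive"
  }
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]
  label <- label[ok]
  if (sum(label) < 1 || sum(!label) < 1) {
    stop("need at least one positive and one negative scored variant")
  }
  if (damaging_direction == "high") score <- -score
  thresholds <- c(sort(unique(score)), Inf)
  out <- lapply(thresholds, function(t) {
    pred <- score < t
    tp <- sum(pred & label)
    fp <- sum(pred & !label)
    fn <- sum(!pred & label)
    tn <- sum(!pred & !label)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn),
               fpr = fp / (fp + tn))
  })
  curve <- do.call(rbind, out)
  if (damaging_direction == "high") curve$threshold <- -curve$threshold
  curve$balanced_precision <- balanced_precision(curve$recall, curve$fpr)
  curve
}

#' Balanced precision
#'
#' Precision recomputed under equal prior probability of the positive and
#' negative classes: `recall / (recall + FPR)`. Invariant to duplicating
#' either class.
#'
#' @param recall,fpr Recall and false-positive rate in `[0, 1]`.
#' @return Balanced precision; `NA` where recall and FPR are both 0.
#' @export
balanced_precision <- function(recall, fpr) {
  bp <- recall / (recall + fpr)
  bp[recall + fpr == 0] <- NA_real_
  bp
}

#' Recall at a stringent balanced-precision threshold
#'
#' @param curve A curve from [precision_recall()].
#' @param level Balanced-precision level (default 0.90).
#' @return Maximum recall over thresholds whose balanced precision reaches
#'   `level`; 0 if none does.
#' @export
r90bp <- function(curve, level = 0.9) {
  ok <- !is.na(curve$balanced_precision) & curve$balanced_precision >= level
  if (!any(ok)) return(0)
  max(curve$recall[ok])
}

#' Area under the balanced precision vs recall curve
#'
#' Trapezoidal area over recall-sorted curve points, anchored at recall 0
#' with the first defined balanced-precision value.
#'
#' @param curve A curve from [precision_recall()].
#' @return Area in `[0, 1]`.
#' @export
aubprc <- function(curve) {
  pts <- curve[!is.na(curve$balanced_precision), c("recall", "balanced_precision")]
  if (nrow(pts) == 0) stop("empty curve")
  pts <- pts[order(pts$recall), ]
  if (pts$recall[1] > 0) {
    pts <- rbind(data.frame(recall = 0,
                            balanced_precision = pts$balanced_precision[1]),
                 pts)
  }
  sum(diff(pts$recall) *
      (head(pts$balanced_precision, -1) + pts$balanced_precision[-1]) / 2)
}

#' Fit Gaussian score densities to the two reference sets
#'
#' Maximum-likelihood normal fits (mean and population standard deviation)
#' to positive- and negative-set scores.
#'
#' @param positive_scores,negative_scores Numeric score vectors (>= 2 each).
#' @return A list of class `"density_pair"` with `mu_pos`, `sd_pos`,
#'   `mu_neg`, `sd_neg`, `n_pos`, `n_neg`.
#' @export
fit_density_pair <- function(positive_scores, negative_scores) {
  mle <- function(x, set) {
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("need at least 2 ", set, " scores")
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (sigma <= 0) stop(set, " scores are constant: zero-variance density")
    c(mu, sigma)
  }
  p <- mle(positive_scores, "positive")
  n <- mle(negative_scores, "negative")
  structure(list(mu_pos = p[1], sd_pos = p[2], mu_neg = n[1], sd_neg = n[2],
                 n_pos = sum(!is.na(positive_scores)),
                 n_neg = sum(!is.na(negative_scores))),
            class = "density_pair")
}

#' Log likelihood ratio of pathogenicity
#'
#' `LLRp(f) = log10 [ rho(S|+)(f) / rho(S|-)(f) ]` for the fitted Gaussian
#' densities. Base 10 is used so that evidence thresholds combine
#' additively with log10 odds.
#'
#' @param f Functional scores.
#' @param pair A [fit_density_pair()] result.
#' @return LLRp values (log10).
#' @export
llrp <- function(f, pair) {
  (dnorm(f, pair$mu_pos, pair$sd_pos, log = TRUE) -
   dnorm(f, pair$mu_neg, pair$sd_neg, log = TRUE)) / log(10)
}

#' Posterior odds of pathogenicity
#'
#' Odds form of Bayes' rule: `O = 10^LLRp * P+ / (1 - P+)`.
#'
#' @param llr LLRp values (log10 likelihood ratios).
#' @param prior Prior probability of pathogenicity `P+`.
#' @return Posterior odds.
#' @export
posterior_odds <- function(llr, prior) {
  stopifnot(prior > 0, prior < 1)
  10^llr * prior / (1 - prior)
}

#' Convert odds to probability
#'
#' @param odds Odds values.
#' @return `odds / (1 + odds)`.
#' @export
odds_to_probability <- function(odds) {
  odds / (1 + odds)
}

#' Default ACMG/AMP evidence-combining rule set
#'
#' Each row is one combining rule: counts of Very Strong (`pvst`), Strong
#' (`pst`), Moderate (`pm`) and Supporting (`psu`) pathogenic evidence and
#' Strong (`bst`) / Supporting (`bsu`) benign evidence, together with the
#' posterior-probability constraint tier the combination must satisfy
#' (`P` > 0.99, `LP` > 0.90, `LB` < 0.10, `B` < 0.01).
#'
#' On the exponent-halving odds scale a combination's total evidence is
#' `X^(e/8)` with `e = 8 pvst + 4 pst + 2 pm + psu - 4 bst - bsu`. The
#' two-Strong combination is listed under the likely-pathogenic tier: in
#' this framework it attains only likely-pathogenic posterior probability
#' at the calibrated odds, as noted in the framework's own calibration.
#' The rule set is plain data; edit or replace it (e.g. via
#' [write_rule_set()] / [read_rule_set()]) to encode local practice.
#'
#' @return Data frame of combining rules.
#' @export
acmg_rule_set <- function() {
  rules <- rbind(
    data.frame(rule = "P: 1 very-strong + 1 strong",        tier = "P",  pvst = 1, pst = 1, pm = 0, psu = 0, bst = 0, bsu = 0),
    data.frame(rule = "P: 1 very-strong + 2 moderate",      tier = "P",  pvst = 1, pst = 0, pm = 2, psu = 0, bst = 0, bsu = 0),
    data.frame(rule = "P: 1 very-strong + 1 moderate + 1 supporting", tier = "P", pvst = 1, pst = 0, pm = 1, psu = 1, bst = 0, bsu = 0),
    data.frame(rule = "P: 1 very-strong + 2 supporting",    tier = "P",  pvst = 1, pst = 0, pm = 0, psu = 2, bst = 0, bsu = 0),
    data.frame(rule = "P: 1 strong + 3 moderate",           tier = "P",  pvst = 0, pst = 1, pm = 3, psu = 0, bst = 0, bsu = 0),
    data.frame(rule = "P: 1 strong + 2 moderate + 2 supporting", tier = "P", pvst = 0, pst = 1, pm = 2, psu = 2, bst = 0, bsu = 0),
    data.frame(rule = "P: 1 strong + 1 moderate + 4 supporting", tier = "P", pvst = 0, pst = 1, pm = 1, psu = 4, bst = 0, bsu = 0),
    data.frame(rule = "LP: 2 strong",                       tier = "LP", pvst = 0, pst = 2, pm = 0, psu = 0, bst = 0, bsu = 0),
    data.frame(rule = "LP: 1 very-strong + 1 moderate",     tier = "LP", pvst = 1, pst = 0, pm = 1, psu = 0, bst = 0, bsu = 0),
    data.frame(rule = "LP: 1 strong + 1 moderate",          tier = "LP", pvst = 0, pst = 1, pm = 1, psu = 0, bst = 0, bsu = 0),
    data.frame(rule = "LP: 1 strong + 2 moderate",          tier = "LP", pvst = 0, pst = 1, pm = 2, psu = 0, bst = 0, bsu = 0),
    data.frame(rule = "LP: 1 strong + 2 supporting",        tier = "LP", pvst = 0, pst = 1, pm = 0, psu = 2, bst = 0, bsu = 0),
    data.frame(rule = "LP: 3 moderate",                     tier = "LP", pvst = 0, pst = 0, pm = 3, psu = 0, bst = 0, bsu = 0),
    data.frame(rule = "LP: 2 moderate + 2 supporting",      tier = "LP", pvst = 0, pst = 0, pm = 2, psu = 2, bst = 0, bsu = 0),
    data.frame(rule = "LP: 1 moderate + 4 supporting",      tier = "LP", pvst = 0, pst = 0, pm = 1, psu = 4, bst = 0, bsu = 0),
    data.frame(rule = "LB: 1 strong-benign + 1 supporting-benign", tier = "LB", pvst = 0, pst = 0, pm = 0, psu = 0, bst = 1, bsu = 1),
    data.frame(rule = "LB: 2 supporting-benign",            tier = "LB", pvst = 0, pst = 0, pm = 0, psu = 0, bst = 0, bsu = 2),
    data.frame(rule = "B: 2 strong-benign",                 tier = "B",  pvst = 0, pst = 0, pm = 0, psu = 0, bst = 2, bsu = 0)
  )
  rules$exponent <- 8 * rules$pvst + 4 * rules$pst + 2 * rules$pm +
    rules$psu - 4 * rules$bst - rules$bsu
  rules
}

#' Serialize / read a rule set as YAML
#'
#' @param rules A rule-set data frame (see [acmg_rule_set()]).
#' @param path YAML path.
#' @export
write_rule_set <- function(rules, path) {
  yaml::write_yaml(lapply(seq_len(nrow(rules)), function(i) as.list(rules[i, ])),
                   path)
  invisible(path)
}

#' @rdname write_rule_set
#' @export
read_rule_set <- function(path) {
  items <- yaml::read_yaml(path)
  do.call(rbind, lapply(items, function(x) as.data.frame(x)))
}

rule_posteriors <- function(X, rules, prior) {
  odds <- X^(rules$exponent / 8) * prior / (1 - prior)
  odds_to_probability(odds)
}

rules_satisfied <- function(X, rules, prior) {
  post <- rule_posteriors(X, rules, prior)
  bounds <- c(P = 0.99, LP = 0.90, LB = 0.10, B = 0.01)
  lower <- rules$tier %in% c("P", "LP")
  ok <- ifelse(lower, post > bounds[rules$tier], post < bounds[rules$tier])
  structure(all(ok), posteriors = post, ok = ok)
}

#' Calibrate ACMG/AMP evidence thresholds
#'
#' Searches for the Very-Strong pathogenic odds `X` such that, with
#' evidence odds `X^(1/2^k)` for level `k` (the exponent-halving rule;
#' Supporting = `X^(1/8)`) and benign evidence as reciprocals, every
#' combining rule's posterior probability satisfies its tier constraint
#' (>0.99 pathogenic, >0.90 likely pathogenic, <0.10 likely benign,
#' <0.01 benign). The most conservative (smallest) satisfying `X` is
#' located by integer grid search plus bisection refinement, then rounded
#' to two significant figures as in the source framework; thresholds are
#' reported as log10 odds at each evidence level, with benign thresholds
#' mirrored.
#'
#' @param prior Prior probability of pathogenicity (default 0.10).
#' @param rules Combining rules (default [acmg_rule_set()]).
#' @param grid Integer candidates for the initial search (default 2:1500).
#' @param tol Bisection tolerance on `X` (default 1e-9, relative).
#' @return A list of class `"evidence_thresholds"` with elements `prior`,
#'   `odds_raw` (refined minimal `X`), `odds` (rounded), `thresholds`
#'   (named log10 vector `PVSt`, `PSt`, `PM`, `PSu`, `BSu`, `BSt` at the
#'   rounded odds), `thresholds_raw` (same at `odds_raw`), `binding_rule`
#'   and `posteriors` (per rule, at the rounded odds).
#' @export
calibrate_acmg_thresholds <- function(prior = 0.10, rules = acmg_rule_set(),
                                      grid = 2:1500, tol = 1e-9) {
  stopifnot(prior > 0, prior < 1)
  sat <- vapply(grid, function(X) isTRUE(rules_satisfied(X, rules, prior)),
                logical(1))
  if (!any(sat)) {
    post_max <- rule_posteriors(max(grid), rules, prior)
    res <- rules_satisfied(max(grid), rules, prior)
    failed <- rules$rule[!attr(res, "ok")]
    stop("no odds value in the search range satisfies all constraints; ",
         "binding rule(s): ", paste(failed, collapse = "; "))
  }
  X_hi <- grid[which(sat)[1]]
  X_lo <- if (which(sat)[1] > 1) grid[which(sat)[1] - 1] else X_hi / 2
  while ((X_hi - X_lo) / X_hi > tol) {
    mid <- (X_hi + X_lo) / 2
    if (isTRUE(rules_satisfied(mid, rules, prior))) X_hi <- mid else X_lo <- mid
  }
  odds_raw <- X_hi
  odds_round <- signif(odds_raw, 2)
  make_thresholds <- function(X) {
    pvst <- log10(X)
    c(PVSt = pvst, PSt = pvst / 2, PM = pvst / 4, PSu = pvst / 8,
      BSu = -pvst / 8, BSt = -pvst / 2)
  }
  post <- rule_posteriors(odds_raw, rules, prior)
  bounds <- c(P = 0.99, LP = 0.90, LB = 0.10, B = 0.01)
  margin <- ifelse(rules$tier %in% c("P", "LP"),
                   post - bounds[rules$tier], bounds[rules$tier] - post)
  out <- list(
    prior = prior,
    odds_raw = odds_raw,
    odds = odds_round,
    thresholds = make_thresholds(odds_round),
    thresholds_raw = make_thresholds(odds_raw),
    binding_rule = rules$rule[which.min(margin)],
    posteriors = setNames(rule_posteriors(odds_round, rules, prior), rules$rule),
    rules = rules
  )
  class(out) <- "evidence_thresholds"
  out
}

#' @export
print.evidence_thresholds <- function(x, ...) {
  cat("ACMG/AMP evidence thresholds (log10 likelihood ratio)\n")
  cat(sprintf("  prior P+ = %.3g; very-strong odds = %g (raw %.4f)\n",
              x$prior, x$odds, x$odds_raw))
  for (nm in names(x$thresholds)) {
    cat(sprintf("  %-4s % .4f\n", nm, x$thresholds[nm]))
  }
  cat("  binding rule:", x$binding_rule, "\n")
  invisible(x)
}

#' Assign an ACMG/AMP evidence category to LLRp values
#'
#' Returns the strongest category whose threshold is met; values between
#' the supporting-benign and supporting-pathogenic thresholds are
#' `"indeterminate"`.
#'
#' @param llr LLRp values (log10).
#' @param thresholds An `"evidence_thresholds"` object or a named log10
#'   threshold vector (`PVSt`, `PSt`, `PM`, `PSu`, `BSu`, `BSt`).
#' @return Character vector over
#'   `{"PVSt","PSt","PM","PSu","indeterminate","BSu","BSt"}`.
#' @export
assign_evidence <- function(llr, thresholds) {
  th <- if (inherits(thresholds, "evidence_thresholds")) thresholds$thresholds
        else thresholds
  out <- rep("indeterminate", length(llr))
  out[llr >= th["PSu"]] <- "PSu"
  out[llr >= th["PM"]] <- "PM"
  out[llr >= th["PSt"]] <- "PSt"
  out[llr >= th["PVSt"]] <- "PVSt"
  out[llr <= th["BSu"]] <- "BSu"
  out[llr <= th["BSt"]] <- "BSt"
  out[is.na(llr)] <- NA_character_
  out
}

#' Evaluate a map against a reference set
#'
#' Joins quality-passing map scores to labeled reference variants, computes
#' the balanced precision-recall curve and summary metrics, optionally
#' masking an interval list of positions (e.g. a map region where the assay
#' is known to under-report pathogenicity).
#'
#' @param map A scored map (needs `variant`, `position`, `score`, and
#'   optionally `pass`).
#' @param reference A reference set from [build_reference_sets()] (or any
#'   data frame with `variant` and `label`).
#' @param mask Optional two-column matrix/data frame of position intervals
#'   (start, end, inclusive) to exclude.
#' @param bp_level Balanced-precision level for the recall summary.
#' @return List with `curve`, `aubprc`, `r90bp`, `n_pos`, `n_neg`, `mask`.
#' @export
evaluate_map <- function(map, reference, mask = NULL, bp_level = 0.9) {
  ok <- if ("pass" %in% names(map)) map$pass else rep(TRUE, nrow(map))
  scored <- map[ok & !is.na(map$score), ]
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    masked <- rep(FALSE, nrow(scored))
    for (i in seq_len(nrow(mask))) {
      masked <- masked | (scored$position >= mask[i, 1] &
                          scored$position <= mask[i, 2])
    }
    scored <- scored[!masked, ]
  }
  joined <- merge(scored[, c("variant", "score")],
                  reference[, c("variant", "label")], by = "variant")
  curve <- precision_recall(joined$score, joined$label)
  list(curve = curve,
       aubprc = aubprc(curve),
       r90bp = r90bp(curve, bp_level),
       n_pos = sum(joined$label == "positive"),
       n_neg = sum(joined$label == "negative"),
       mask = mask)
}
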