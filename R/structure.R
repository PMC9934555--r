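# Structure-aware descriptive analyses: residue classification from
# solvent accessibility, interface and stability rules, moving-window
# profiles, per-residue medians, group comparisons, and the
# amino-acid-preference transforms used for phylogenetic model export.

#' Classify residues by solvent accessibility
#'
#' Exposed above 40% accessible surface area, buried below 20%,
#' intermediate otherwise (the boundary values 20% and 40% map to
#' intermediate).
#'
#' @param asa_pct Percent solvent-accessible surface area.
#' @return Character vector: `"buried"`, `"intermediate"` or `"exposed"`.
#' @export
classify_residue <- function(asa_pct) {
  out <- rep("intermediate", length(asa_pct))
  out[asa_pct > 40] <- "exposed"
  out[asa_pct < 20] <- "buried"
  out[is.na(asa_pct)] <- NA_character_
  out
}

#' Classify interface residues
#'
#' A residue is interfacial when its accessible surface area changes by
#' strictly more than 1 A^2 between the complex and the single chain.
#'
#' @param delta_asa Change in accessible surface area (A^2).
#' @return Logical vector.
#' @export
classify_interface <- function(delta_asa) {
  delta_asa > 1
}

#' Classify substitutions by predicted stability change
#'
#' Stabilizing when `ddG >= -1` kcal/mol, destabilizing below.
#'
#' @param ddg Predicted folding free-energy change (kcal/mol).
#' @return Character vector: `"stabilizing"` or `"destabilizing"`.
#' @export
classify_ddg <- function(ddg) {
  out <- ifelse(ddg >= -1, "stabilizing", "destabilizing")
  out[is.na(ddg)] <- NA_character_
  out
}

#' Moving-window positional profile
#'
#' Mean of available values in a centered window of `window` positions,
#' truncated at the protein termini; positions with no value in the window
#' are absent from the output.
#'
#' @param position Residue positions.
#' @param value Values (e.g. median scores or ddG), parallel to `position`;
#'   `NA` values are skipped.
#' @param window Odd window width (default 5).
#' @return Data frame with columns `position`, `mean`, `n`.
#' @export
moving_window_profile <- function(position, value, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  ok <- !is.na(value)
  position <- position[ok]
  value <- value[ok]
  if (length(position) == 0) {
    return(data.frame(position = integer(0), mean = numeric(0), n = integer(0)))
  }
  half <- (window - 1) / 2
  centers <- seq(min(position), max(position))
  rows <- lapply(centers, function(cc) {
    idx <- position >= cc - half & position <= cc + half
    if (!any(idx)) return(NULL)
    data.frame(position = cc, mean = mean(value[idx]), n = sum(idx))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median score per residue
#'
#' Median functional score of substitutions at each position, for
#' structure coloring and positional summaries.
#'
#' @param map A scored map.
#' @param classes Variant classes to include (default missense only).
#' @param pass_only Use only quality-passing variants (default `TRUE`).
#' @return Data frame with columns `position`, `median_score`, `n`;
#'   positions without scores are absent.
#' @export
median_score_per_residue <- function(map, classes = "missense",
                                     pass_only = TRUE) {
  keep <- map$class %in% classes & !is.na(map$score)
  if (pass_only && "pass" %in% names(map)) keep <- keep & map$pass
  sub <- map[keep, ]
  if (nrow(sub) == 0) {
    return(data.frame(position = integer(0), median_score = numeric(0),
                      n = integer(0)))
  }
  agg <- stats::aggregate(score ~ position, data = sub,
                          FUN = function(x) c(med = median(x), n = length(x)))
  data.frame(position = agg$position, median_score = agg$score[, "med"],
             n = agg$score[, "n"])
}

#' Compare two score groups
#'
#' Median difference and two-sided Mann-Whitney U test.
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @return List with `delta_median` (`median(a) - median(b)`),
#'   `statistic` (the U statistic) and `p_value`.
#' @export
compare_groups <- function(scores_a, scores_b) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  wt <- suppressWarnings(wilcox.test(scores_a, scores_b))
  list(delta_median = median(scores_a) - median(scores_b),
       statistic = unname(wt$statistic),
       p_value = wt$p.value)
}

#' Wild-type-normalized scores
#'
#' Divides each variant's score by the wild-type score at its position
#' (the synonymous-equivalent score, defaulting to 1 where unmeasured), so
#' positions whose wild-type scores slightly above 1 are not penalized.
#'
#' @param map A scored map containing missense and synonymous rows.
#' @param pass_only Use only quality-passing rows (default `TRUE`).
#' @return Data frame with columns `position`, `ref`, `alt`, `s`
#'   (normalized score), restricted to missense variants.
#' @export
wt_normalize_scores <- function(map, pass_only = TRUE) {
  keep <- !is.na(map$score)
  if (pass_only && "pass" %in% names(map)) keep <- keep & map$pass
  sub <- map[keep, ]
  syn <- sub[sub$class == "synonymous", c("position", "score")]
  wt_of <- setNames(syn$score, syn$position)
  mis <- sub[sub$class == "missense", c("position", "ref", "alt", "score")]
  wt <- unname(wt_of[as.character(mis$position)])
  wt[is.na(wt)] <- 1
  data.frame(position = mis$position, ref = mis$ref, alt = mis$alt,
             s = mis$score / wt)
}

#' Site-wise amino-acid preference table
#'
#' Converts wild-type-normalized scores `s` into per-site amino-acid
#' preferences under one of three hypotheses about above-wild-type scores:
#' `"advantageous"` keeps `s` as is; `"neutral"` clips `s > 1` to 1;
#' `"damaging"` maps `s > 1` to `1/s` (above-wild-type behavior in the
#' assay is treated as deleterious in the native context). Preferences are
#' normalized to sum to 1 per site. Missing values are imputed with the
#' site median by default. The wild-type residue itself is given `s = 1`.
#'
#' @param s_table Data frame from [wt_normalize_scores()] (`position`,
#'   `ref`, `alt`, `s`).
#' @param model One of `"advantageous"`, `"neutral"`, `"damaging"`.
#' @param impute Impute missing amino acids with the site median (default
#'   `TRUE`); sites with no data at all get uniform preferences.
#' @return Matrix of preferences (sites x 20 amino acids), rows summing
#'   to 1, with row names the positions.
#' @export
transform_preferences <- function(s_table,
                                  model = c("advantageous", "neutral", "damaging"),
                                  impute = TRUE) {
  model <- match.arg(model)
  positions <- sort(unique(s_table$position))
  mat <- matrix(NA_real_, length(positions), length(AA_ALPHABET),
                dimnames = list(positions, AA_ALPHABET))
  idx <- cbind(match(s_table$position, positions),
               match(s_table$alt, AA_ALPHABET))
  ok <- !is.na(idx[, 2])
  mat[idx[ok, , drop = FALSE]] <- s_table$s[ok]
  # the wild-type residue is its own reference: s = 1
  wt_aa <- tapply(s_table$ref, s_table$position, function(x) x[1])
  wt_col <- match(wt_aa[as.character(positions)], AA_ALPHABET)
  mat[cbind(seq_along(positions), wt_col)] <- 1
  if (impute) {
    for (i in seq_len(nrow(mat))) {
      miss <- is.na(mat[i, ])
      if (all(miss)) {
        mat[i, ] <- 1
      } else if (any(miss)) {
        mat[i, miss] <- median(mat[i, !miss])
      }
    }
  } else {
    mat[is.na(mat)] <- 0
  }
  mat <- pmax(mat, 0)
  if (model == "neutral") {
    mat[mat > 1] <- 1
  } else if (model == "damaging") {
    over <- mat > 1
    mat[over] <- 1 / mat[over]
  }
  sweep(mat, 1, rowSums(mat), "/")
}

#' Annotate residues from an accessibility table
#'
#' Adds `residue_class` and `is_interface` columns to a residue annotation
#' table with `ASA_pct` and `dASA` columns.
#'
#' @param annotations Data frame with columns `position`, `ASA_pct`, `dASA`.
#' @return The table with classification columns appended.
#' @export
annotate_residues <- function(annotations) {
  annotations$residue_class <- classify_residue(annotations$ASA_pct)
  annotations$is_interface <- classify_interface(annotations$dASA)
  annotations
}
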