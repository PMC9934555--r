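# Cross-isoform map harmonization: affine rescaling of one map onto the
# other, inverse-variance weighted combination, delta scores, and map
# comparison reports.

#' Rescale one map onto another
#'
#' Fits the affine transform `a * score + b` (or scale-only `a * score`)
#' that minimizes the mean squared score difference to `map_b` over shared
#' quality-passing variants, and applies it to `map_a` (standard errors are
#' scaled by `|a|`). Differences in selection stringency between isoforms
#' introduce scale changes that this transform absorbs.
#'
#' @param map_a,map_b Scored maps (data frames with `variant`, `score`,
#'   `se` and optionally `pass` columns), in a shared coordinate frame.
#' @param method `"affine"` (scale and offset, the default) or `"scale"`.
#' @return `map_a` with transformed `score`/`se`; the fitted coefficients
#'   are attached as attribute `"transform"` (named vector `a`, `b`).
#' @export
rescale_isoform <- function(map_a, map_b, method = c("affine", "scale")) {
  method <- match.arg(method)
  pa <- if ("pass" %in% names(map_a)) map_a$pass else rep(TRUE, nrow(map_a))
  pb <- if ("pass" %in% names(map_b)) map_b$pass else rep(TRUE, nrow(map_b))
  a_ok <- map_a[pa & !is.na(map_a$score), c("variant", "score")]
  b_ok <- map_b[pb & !is.na(map_b$score), c("variant", "score")]
  shared <- merge(a_ok, b_ok, by = "variant", suffixes = c("_a", "_b"))
  if (nrow(shared) < 2) {
    stop("need at least 2 shared quality-passing variants to rescale")
  }
  x <- shared$score_a
  y <- shared$score_b
  if (stats::var(x) == 0 || (method == "scale" && sum(x^2) == 0)) {
    warning("degenerate shared score set; applying identity transform")
    coefs <- c(a = 1, b = 0)
  } else if (method == "affine") {
    a <- stats::cov(x, y) / stats::var(x)
    coefs <- c(a = a, b = mean(y) - a * mean(x))
  } else {
    coefs <- c(a = sum(x * y) / sum(x^2), b = 0)
  }
  map_a$score <- coefs["a"] * map_a$score + coefs["b"]
  if ("se" %in% names(map_a)) map_a$se <- abs(coefs["a"]) * map_a$se
  attr(map_a, "transform") <- coefs
  map_a
}

#' Inverse-variance weighted score combination
#'
#' `FS = (FS1/se1^2 + FS2/se2^2) / (1/se1^2 + 1/se2^2)` with combined
#' variance `1 / (1/se1^2 + 1/se2^2)`. Where one score is missing the other
#' passes through unchanged. Symmetric in its two arguments.
#'
#' @param fs1,se1,fs2,se2 Scores and standard errors (vectors recycle).
#' @return A data frame with columns `score` and `se`.
#' @export
combine_scores <- function(fs1, se1, fs2, se2) {
  n <- max(length(fs1), length(fs2))
  fs1 <- rep_len(fs1, n); se1 <- rep_len(se1, n)
  fs2 <- rep_len(fs2, n); se2 <- rep_len(se2, n)
  w1 <- 1 / se1^2
  w2 <- 1 / se2^2
  score <- (fs1 * w1 + fs2 * w2) / (w1 + w2)
  se <- sqrt(1 / (w1 + w2))
  only1 <- !is.na(fs1) & is.na(fs2)
  only2 <- is.na(fs1) & !is.na(fs2)
  score[only1] <- fs1[only1]; se[only1] <- se1[only1]
  score[only2] <- fs2[only2]; se[only2] <- se2[only2]
  data.frame(score = score, se = se)
}

#' Assemble the combined cross-isoform map
#'
#' Joins an erythroid and a ubiquitous map (both already in ubiquitous
#' coordinates), rescales the erythroid scores onto the ubiquitous scale,
#' combines quality-passing scores by inverse-variance weighting, passes
#' single-isoform entries through unchanged, and reports per-variant delta
#' scores (erythroid minus ubiquitous, after rescaling).
#'
#' @param map_ery,map_ubi Scored maps in ubiquitous coordinates.
#' @param rescale Apply [rescale_isoform()] to the erythroid map first.
#' @param method Rescaling method (see [rescale_isoform()]).
#' @return Data frame with columns `variant`, `position`, `ref`, `alt`,
#'   `class`, `score_ery`, `se_ery`, `score_ubi`, `se_ubi`, `score`, `se`,
#'   `delta`, `pass`.
#' @export
assemble_map <- function(map_ery, map_ubi, rescale = TRUE,
                         method = c("affine", "scale")) {
  method <- match.arg(method)
  if (rescale) map_ery <- rescale_isoform(map_ery, map_ubi, method)
  keep <- c("variant", "position", "ref", "alt", "class", "score", "se", "pass")
  e <- map_ery[, intersect(keep, names(map_ery))]
  u <- map_ubi[, intersect(keep, names(map_ubi))]
  m <- merge(e, u, by = "variant", all = TRUE, suffixes = c("_ery", "_ubi"))
  for (col in c("position", "ref", "alt", "class")) {
    a <- m[[paste0(col, "_ery")]]
    b <- m[[paste0(col, "_ubi")]]
    m[[col]] <- ifelse(is.na(a), b, a)
  }
  m$pass_ery[is.na(m$pass_ery)] <- FALSE
  m$pass_ubi[is.na(m$pass_ubi)] <- FALSE
  s_e <- ifelse(m$pass_ery, m$score_ery, NA_real_)
  s_u <- ifelse(m$pass_ubi, m$score_ubi, NA_real_)
  comb <- combine_scores(s_e, m$se_ery, s_u, m$se_ubi)
  m$score <- comb$score
  m$se <- comb$se
  m$delta <- m$score_ery - m$score_ubi
  m$pass <- m$pass_ery | m$pass_ubi
  out <- m[order(m$position, m$alt),
           c("variant", "position", "ref", "alt", "class",
             "score_ery", "se_ery", "score_ubi", "se_ubi",
             "score", "se", "delta", "pass")]
  rownames(out) <- NULL
  if (!is.null(attr(map_ery, "transform"))) {
    attr(out, "transform") <- attr(map_ery, "transform")
  }
  out
}

#' Compare two maps
#'
#' Pearson correlation over shared quality-passing variants plus a
#' per-position summary of score differences. Descriptive only: no
#' segment-level difference calls are made.
#'
#' @param map_a,map_b Scored maps in a shared coordinate frame.
#' @return List with `r`, `n`, `p_value` and a `position_deltas` data frame
#'   (`position`, `mean_delta`, `n`).
#' @export
compare_maps <- function(map_a, map_b) {
  pa <- if ("pass" %in% names(map_a)) map_a$pass else rep(TRUE, nrow(map_a))
  pb <- if ("pass" %in% names(map_b)) map_b$pass else rep(TRUE, nrow(map_b))
  a_ok <- map_a[pa & !is.na(map_a$score), c("variant", "position", "score")]
  b_ok <- map_b[pb & !is.na(map_b$score), c("variant", "score")]
  shared <- merge(a_ok, b_ok, by = "variant", suffixes = c("_a", "_b"))
  if (nrow(shared) < 3) stop("need at least 3 shared variants to compare maps")
  ct <- cor.test(shared$score_a, shared$score_b)
  shared$delta <- shared$score_a - shared$score_b
  pd <- stats::aggregate(delta ~ position, data = shared,
                         FUN = function(x) c(mean = mean(x), n = length(x)))
  position_deltas <- data.frame(position = pd$position,
                                mean_delta = pd$delta[, "mean"],
                                n = pd$delta[, "n"])
  list(r = unname(ct$estimate), n = nrow(shared), p_value = ct$p.value,
       position_deltas = position_deltas)
}
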