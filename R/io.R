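# Tabular input/output: TileSeq count tables, score maps, ground truth and
# run configuration. Count tables are TSV with one row per
# (variant, tile, condition, replicate); score maps follow MaveDB score-set
# conventions (variant, score, se, ...) and may be written as TSV or CSV.

COUNT_COLUMNS <- c("variant", "tile", "condition", "replicate", "count", "depth")
SCORE_COLUMNS <- c("variant", "score", "se", "isoform", "region", "filter_flags")

#' Read a TileSeq count table
#'
#' Expects a TSV with columns `variant`, `tile`, `condition` (`nonselect` or
#' `select`), `replicate`, `count` and `depth`. Duplicate
#' (variant, tile, condition, replicate) keys and counts exceeding depth are
#' rejected.
#'
#' @param path Path to a tab-separated count table.
#' @return A data frame of count records.
#' @export
read_count_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_count_table(tab, where = path)
  tab
}

validate_count_table <- function(tab, where = "count table") {
  missing_cols <- setdiff(COUNT_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop(where, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    return(invisible(tab))
  }
  if (!all(tab$condition %in% c("nonselect", "select"))) {
    stop(where, ": condition must be 'nonselect' or 'select'")
  }
  if (any(tab$count < 0) || any(tab$depth <= 0)) {
    stop(where, ": counts must be non-negative and depths positive")
  }
  if (any(tab$count > tab$depth)) {
    stop(where, ": count exceeds depth")
  }
  key <- paste(tab$variant, tab$tile, tab$condition, tab$replicate, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    stop(where, ": duplicate (variant, tile, condition, replicate) key(s): ",
         paste(unique(key[dup]), collapse = "; "))
  }
  invisible(tab)
}

#' Write a TileSeq count table
#'
#' @param tab Data frame of count records (see [read_count_table()]).
#' @param path Output TSV path.
#' @export
write_count_table <- function(tab, path) {
  validate_count_table(tab)
  write.table(tab[, COUNT_COLUMNS], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Full-precision serialization of doubles so that write/read round-trips are
# value-identical.
format_double <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a score map
#'
#' Serializes a scored variant map with MaveDB-style columns `variant`,
#' `score`, `se`, `isoform`, `region`, `filter_flags`. Numeric values are
#' written with enough digits that reading the file back reproduces them
#' exactly. The delimiter follows the file extension: `.csv` gives a comma,
#' anything else a tab.
#'
#' @param map Data frame with at least `variant` and `score` columns. A
#'   `flags` column, if present, is used for `filter_flags`.
#' @param path Output path.
#' @export
write_score_map <- function(map, path) {
  out <- data.frame(
    variant = map$variant,
    score = format_double(map$score),
    se = if ("se" %in% names(map)) format_double(map$se) else NA_character_,
    isoform = if ("isoform" %in% names(map)) map$isoform else NA_character_,
    region = if ("region" %in% names(map)) map$region else NA_character_,
    filter_flags = if ("filter_flags" %in% names(map)) map$filter_flags
                   else if ("flags" %in% names(map)) map$flags
                   else "",
    stringsAsFactors = FALSE
  )
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a score map written by [write_score_map()]
#'
#' @param path Path to a score map file (TSV or CSV by extension).
#' @return Data frame with columns `variant`, `score`, `se`, `isoform`,
#'   `region`, `filter_flags`. An empty file yields an empty map.
#' @export
read_score_map <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = c(variant = "character"))
  missing_cols <- setdiff(c("variant", "score"), names(tab))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  tab$score <- as.numeric(tab$score)
  if ("se" %in% names(tab)) tab$se <- as.numeric(tab$se)
  tab
}

#' Write and read simulation ground truth
#'
#' Ground truth tables carry one row per variant with its class and true
#' fitness `w` (1 = wild-type-like, 0 = null, >1 = hyper-complementing).
#'
#' @param truth Data frame with columns `variant`, `class`, `w`.
#' @param path TSV path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth[, c("variant", "class", "w")]
  out$w <- format_double(out$w)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$w <- as.numeric(tab$w)
  tab
}

#' Write and read run configuration as YAML
#'
#' @param config A configuration list (e.g. from [simulation_config()]).
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
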