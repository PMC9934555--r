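# Protein variant notation and isoform coordinate handling.
#
# Variants are represented in HGVS-p short form ("p.R167Q") or bare form
# ("R167Q"). Synonymous changes use "=" as the alternate symbol ("p.A31=")
# and stops use "*" ("Ter" is accepted on input). The canonical internal
# coordinate frame is the ubiquitous isoform; the erythroid isoform starts
# 17 residues downstream.

#' Single-letter amino acid alphabet
#'
#' The twenty standard amino acids in alphabetical single-letter order.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Offset between the two isoform coordinate systems
#'
#' The erythroid isoform uses a later translational start that removes the
#' first 17 residues of the ubiquitous isoform, so ubiquitous position =
#' erythroid position + 17.
#' @export
ISOFORM_OFFSET <- 17L

#' Parse protein variant strings
#'
#' Accepts HGVS-p short form (`"p.R167Q"`, `"p.C261*"`, `"p.C261Ter"`,
#' `"p.A31="`) or the bare form without the `"p."` prefix. Stops are
#' normalized to `"*"` and synonymous changes to `"="`.
#'
#' @param text Character vector of variant strings.
#' @return A data frame with columns `variant` (canonical bare form),
#'   `position` (integer), `ref` (single-letter amino acid) and `alt`
#'   (amino acid, `"*"` for stop, or `"="` for synonymous).
#' @examples
#' parse_variant(c("p.R167Q", "C261*", "p.A31="))
#' @export
parse_variant <- function(text) {
  text <- as.character(text)
  bare <- sub("^p\\.", "", text)
  m <- regmatches(bare, regexec("^([A-Za-z])([0-9]+)(=|\\*|Ter|[A-Za-z])$", bare))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed variant string(s): ", paste(sQuote(text[bad]), collapse = ", "))
  }
  ref <- toupper(vapply(m, `[`, character(1), 2L))
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  alt <- vapply(m, `[`, character(1), 4L)
  alt[alt == "Ter"] <- "*"
  alt[alt %in% AA_ALPHABET == FALSE & !alt %in% c("*", "=")] <-
    toupper(alt[alt %in% AA_ALPHABET == FALSE & !alt %in% c("*", "=")])

  bad_ref <- !ref %in% AA_ALPHABET
  if (any(bad_ref)) {
    stop("unknown reference amino acid in: ",
         paste(sQuote(text[bad_ref]), collapse = ", "))
  }
  bad_alt <- !(alt %in% c(AA_ALPHABET, "*", "="))
  if (any(bad_alt)) {
    stop("unknown alternate amino acid in: ",
         paste(sQuote(text[bad_alt]), collapse = ", "))
  }
  bad_pos <- pos < 1L
  if (any(bad_pos)) {
    stop("position must be >= 1 in: ", paste(sQuote(text[bad_pos]), collapse = ", "))
  }
  self <- ref == alt
  if (any(self)) {
    stop("reference and alternate amino acid are identical (not a variant): ",
         paste(sQuote(text[self]), collapse = ", "),
         "; use '=' for synonymous changes")
  }
  data.frame(
    variant = paste0(ref, pos, alt),
    position = pos,
    ref = ref,
    alt = alt,
    stringsAsFactors = FALSE
  )
}

#' Format protein variants
#'
#' Inverse of [parse_variant()]: builds variant strings from parsed fields.
#'
#' @param position Integer residue positions (1-based).
#' @param ref Reference amino acids (single-letter).
#' @param alt Alternate amino acids (`"*"` stop, `"="` synonymous).
#' @param hgvs If `TRUE`, prefix with `"p."`.
#' @return Character vector of variant strings.
#' @export
format_variant <- function(position, ref, alt, hgvs = FALSE) {
  out <- paste0(ref, as.integer(position), alt)
  if (hgvs) out <- paste0("p.", out)
  out
}

#' Classify variants as missense, synonymous or nonsense
#'
#' @param alt Alternate amino acid symbols as produced by [parse_variant()].
#' @return Character vector with values `"missense"`, `"synonymous"` or
#'   `"nonsense"`.
#' @export
variant_class <- function(alt) {
  ifelse(alt == "=", "synonymous", ifelse(alt == "*", "nonsense", "missense"))
}

#' Map variants between isoform coordinate systems
#'
#' The ubiquitous isoform has 17 extra N-terminal residues, so ubiquitous
#' position = erythroid position + 17. Ubiquitous positions 1-17 have no
#' erythroid image and raise an error.
#'
#' @param variant Character vector of variant strings, or a data frame as
#'   returned by [parse_variant()].
#' @param from,to Source and destination coordinate systems, one of
#'   `"erythroid"` or `"ubiquitous"`.
#' @return A parsed variant data frame (see [parse_variant()]) in the
#'   destination coordinates.
#' @examples
#' map_isoform_coordinates("M1V", from = "erythroid", to = "ubiquitous")
#' @export
map_isoform_coordinates <- function(variant, from, to) {
  from <- match.arg(from, c("erythroid", "ubiquitous"))
  to <- match.arg(to, c("erythroid", "ubiquitous"))
  pv <- if (is.data.frame(variant)) variant else parse_variant(variant)
  if (from == to) {
    return(pv)
  }
  if (from == "erythroid") {
    pv$position <- pv$position + ISOFORM_OFFSET
  } else {
    out_of_range <- pv$position <= ISOFORM_OFFSET
    if (any(out_of_range)) {
      stop("ubiquitous position(s) ",
           paste(pv$position[out_of_range], collapse = ", "),
           " have no erythroid image (positions 1-", ISOFORM_OFFSET, ")")
    }
    pv$position <- pv$position - ISOFORM_OFFSET
  }
  pv$variant <- format_variant(pv$position, pv$ref, pv$alt)
  pv
}
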