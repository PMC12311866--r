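# HLA nomenclature: the six classical loci analysed, two-field resolution.

.HLA_LOCI <- c("A", "B", "C", "DPB1", "DQB1", "DRB1")
.CLASS_I_LOCI <- c("A", "B", "C")

# Abbreviations used in scatter-plot labels for the 14 Continental Western
# European countries; keys are matched case-insensitively.
.COUNTRY_ALIASES <- c(
  au = "austria", be = "belgium", de = "denmark", fi = "finland",
  fr = "france", ge = "germany", gr = "greece", it = "italy",
  ne = "netherlands", no = "norway", po = "portugal", sp = "spain",
  swe = "sweden", swi = "switzerland"
)

#' The six classical HLA loci handled by this package
#'
#' Class I loci are A, B and C; class II loci are DPB1, DQB1 and DRB1.
#' Alleles at any other locus (e.g. DQA1, DPA1) are rejected by
#' [parse_hla_allele()] rather than silently classified.
#'
#' @return Character vector of locus names.
#' @export
hla_loci <- function() .HLA_LOCI

#' HLA class of a locus
#'
#' @param locus Character vector of locus names (e.g. `"A"`, `"DQB1"`).
#' @return Character vector, `"I"` or `"II"`.
#' @export
#' @examples
#' hla_class_of(c("A", "DRB1"))
hla_class_of <- function(locus) {
  bad <- setdiff(unique(locus), .HLA_LOCI)
  if (length(bad) > 0L) {
    stop("unknown HLA locus: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ifelse(locus %in% .CLASS_I_LOCI, "I", "II")
}

#' Format a two-field HLA allele name
#'
#' @param locus Locus name.
#' @param field1 Allele group (non-negative integer).
#' @param field2 Protein number (non-negative integer).
#' @return Canonical `"LOCUS*ff:ss"` strings with zero-padded two-digit fields.
#' @export
#' @examples
#' format_hla_allele("A", 1, 1)  # "A*01:01"
format_hla_allele <- function(locus, field1, field2) {
  sprintf("%s*%02d:%02d", locus, as.integer(field1), as.integer(field2))
}

#' Parse two-field HLA allele names
#'
#' Accepts the canonical colon-delimited form (`"A*01:01"`) and the older
#' four-digit run without a colon (`"DRB1*0401"`), which is split 2+2.
#' Higher-resolution names (`"A*01:01:01"`) are truncated to two fields with
#' a warning. Only the six classical loci of [hla_loci()] are accepted.
#'
#' @param x Character vector of allele names.
#' @return A data.frame with one row per input: `allele` (canonical name),
#'   `locus`, `field1`, `field2`, `hla_class`.
#' @export
#' @examples
#' parse_hla_allele(c("A*01:01", "DQB1*03:02", "DRB1*0401"))
parse_hla_allele <- function(x) {
  if (length(x) == 0L) stop("no allele names supplied", call. = FALSE)
  x <- trimws(as.character(x))
  if (any(is.na(x) | x == "")) {
    stop("empty allele name at position ",
         which(is.na(x) | x == "")[1L], call. = FALSE)
  }
  parts <- strsplit(x, "*", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed allele name (expected LOCUS*fields): ",
         x[bad][1L], call. = FALSE)
  }
  locus <- toupper(vapply(parts, `[`, "", 1L))
  badloc <- !locus %in% .HLA_LOCI
  if (any(badloc)) {
    stop("unknown HLA locus in allele name: ", x[badloc][1L], call. = FALSE)
  }
  fields <- vapply(parts, `[`, "", 2L)

  parse_fields <- function(f, orig) {
    if (grepl("^[0-9]{2,3}:[0-9]{2,3}(:.*)?$", f)) {
      toks <- strsplit(f, ":", fixed = TRUE)[[1L]]
      if (length(toks) > 2L) {
        warning("truncating '", orig, "' to two-field resolution",
                call. = FALSE)
      }
      as.integer(toks[1:2])
    } else if (grepl("^[0-9]{4}$", f)) {
      # legacy four-digit style, split 2+2
      c(as.integer(substr(f, 1L, 2L)), as.integer(substr(f, 3L, 4L)))
    } else {
      stop("malformed allele fields in: ", orig, call. = FALSE)
    }
  }
  ff <- mapply(parse_fields, fields, x, SIMPLIFY = FALSE)
  field1 <- vapply(ff, `[`, 0L, 1L)
  field2 <- vapply(ff, `[`, 0L, 2L)
  data.frame(
    allele = format_hla_allele(locus, field1, field2),
    locus = locus,
    field1 = field1,
    field2 = field2,
    hla_class = hla_class_of(locus),
    stringsAsFactors = FALSE
  )
}

#' Percent disease prevalence from case counts
#'
#' @param cases Non-negative integer number of cases.
#' @param population Positive integer population size.
#' @return `100 * cases / population`, a percentage.
#' @export
#' @examples
#' prevalence_pct(5000, 1e6)  # 0.5
prevalence_pct <- function(cases, population) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (any(cases < 0)) stop("case count must be non-negative", call. = FALSE)
  if (any(cases > population)) {
    stop("case count exceeds population", call. = FALSE)
  }
  100 * cases / population
}

#' Normalize country identifiers
#'
#' Country names are treated as opaque case-insensitive keys so that joins
#' between frequency and prevalence tables do not fail on formatting; common
#' plot-label abbreviations (Au, Be, ..., Swi) are expanded.
#'
#' @param x Character vector of country names or abbreviations.
#' @return Lower-case, trimmed country keys.
#' @export
#' @examples
#' normalize_country(c("Austria", " FINLAND ", "Swi"))
normalize_country <- function(x) {
  key <- tolower(trimws(as.character(x)))
  hit <- match(key, names(.COUNTRY_ALIASES))
  key[!is.na(hit)] <- .COUNTRY_ALIASES[hit[!is.na(hit)]]
  key
}

# Canonical ordering used for profile layout: locus order A, B, C, DPB1,
# DQB1, DRB1, then numeric allele fields.
allele_order <- function(locus, field1, field2) {
  order(match(locus, .HLA_LOCI), field1, field2)
}
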