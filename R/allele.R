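#' @keywords internal
"_PACKAGE"

## Recognised HLA loci. DRB3/4/5 and DPA1 are carried through parsing and
## genotypes but excluded from the six-locus mismatch scheme.
HLA_LOCI <- c("A", "B", "C", "DRB1", "DRB3", "DRB4", "DRB5",
              "DQA1", "DQB1", "DPA1", "DPB1")
CLASS_I_LOCI <- c("A", "B", "C")
CLASS_II_LOCI <- setdiff(HLA_LOCI, CLASS_I_LOCI)

## Loci whose gene products pair as alpha/beta heterodimers on SAB beads.
HETERODIMER_BETA <- c(DQB1 = "DQA1", DPB1 = "DPA1")

#' Parse an HLA allele string
#'
#' Accepts the conventional `LOCUS*F1` (one-field, allele group) or
#' `LOCUS*F1:F2` (two-field, protein) form, e.g. `"A*11"` or `"A*11:01"`.
#' Third/fourth fields, expression suffixes and G/P groups are out of scope.
#'
#' @param text A single allele string.
#' @return An object of class `hla_allele` with elements `locus`, `field1`,
#'   `field2` (`NULL` for one-field alleles) and `raw` (the input string).
#' @examples
#' parse_allele("A*11:01")
#' parse_allele("DRB1*11")
#' @export
parse_allele <- function(text) {
  if (length(text) != 1L || !is.character(text) || is.na(text)) {
    stop("parse_allele() expects a single allele string", call. = FALSE)
  }
  raw <- trimws(text)
  m <- regexec("^([A-Za-z0-9]+)\\*([0-9]+)(:([0-9]+))?$", raw)
  parts <- regmatches(raw, m)[[1]]
  if (length(parts) == 0L) {
    stop("malformed HLA allele string: '", raw, "'", call. = FALSE)
  }
  locus <- toupper(parts[2L])
  if (!locus %in% HLA_LOCI) {
    stop("unknown HLA locus '", locus, "' in allele '", raw, "'", call. = FALSE)
  }
  field1 <- as.integer(parts[3L])
  field2 <- if (nzchar(parts[5L])) as.integer(parts[5L]) else NULL
  if (field1 <= 0L || (!is.null(field2) && field2 <= 0L)) {
    stop("allele fields must be positive integers in '", raw, "'", call. = FALSE)
  }
  structure(list(locus = locus, field1 = field1, field2 = field2, raw = raw),
            class = "hla_allele")
}

#' @export
format.hla_allele <- function(x, ...) {
  s <- sprintf("%s*%02d", x$locus, x$field1)
  if (!is.null(x$field2)) s <- sprintf("%s:%02d", s, x$field2)
  s
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.hla_allele <- function(x, ...) format(x)

as_hla_allele <- function(x) {
  if (inherits(x, "hla_allele")) x else parse_allele(x)
}

#' Canonicalise allele strings
#'
#' Parses and re-serialises each allele so fields are zero-padded to two
#' digits (`"A*1:1"` becomes `"A*01:01"`); parsing a canonical string is the
#' identity.
#'
#' @param x Character vector of allele strings.
#' @return Character vector of canonical allele strings.
#' @export
canonical_allele <- function(x) {
  vapply(x, function(t) {
    hit <- .allele_cache[[t]]
    if (!is.null(hit)) return(hit)
    v <- format(parse_allele(t))
    assign(t, v, envir = .allele_cache)
    v
  }, character(1), USE.NAMES = FALSE)
}

## Memoised canonicalisation: allele vocabularies are tiny relative to the
## number of genotypes touched in simulation, so a string cache pays off.
.allele_cache <- new.env(parent = emptyenv())

## Fast accessors for canonical allele strings (no validation).
str_locus <- function(x) sub("\\*.*$", "", x)
str_is_two_field <- function(x) grepl(":", x, fixed = TRUE)
str_field1 <- function(x) as.integer(sub("^[A-Z0-9]+\\*([0-9]+).*$", "\\1", x))

#' Reduce an allele to one-field (allele group) resolution
#'
#' @param a An `hla_allele` or allele string.
#' @return Same type as the input, reduced to its first field; idempotent.
#' @examples
#' reduce_to_one_field("A*11:02")  # "A*11"
#' @export
reduce_to_one_field <- function(a) {
  if (is.character(a)) {
    return(vapply(a, function(s) {
      key <- paste0("1f|", s)
      hit <- .allele_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- parse_allele(s)
      p$field2 <- NULL
      v <- format(p)
      assign(key, v, envir = .allele_cache)
      v
    }, character(1), USE.NAMES = FALSE))
  }
  a <- as_hla_allele(a)
  a$field2 <- NULL
  a$raw <- format(a)
  a
}

#' Is an allele typed at two-field resolution?
#'
#' @param a An `hla_allele` or allele string.
#' @return Logical flag.
#' @export
is_two_field <- function(a) {
  if (is.character(a)) return(str_is_two_field(canonical_allele(a)))
  !is.null(as_hla_allele(a)$field2)
}

#' Antigen-level (first-field) match
#'
#' True when two alleles share locus and allele group, the equivalence behind
#' low-resolution serologic-style matching. Splits/broads are not modelled.
#'
#' @param a,b `hla_allele` objects or allele strings.
#' @return Logical flag.
#' @examples
#' antigen_match("A*11:01", "A*11")   # TRUE
#' antigen_match("A*11:01", "B*11")   # FALSE
#' @export
antigen_match <- function(a, b) {
  a <- as_hla_allele(a); b <- as_hla_allele(b)
  a$locus == b$locus && a$field1 == b$field1
}

#' Allele-level (two-field) match
#'
#' Exact protein-level equality. Both alleles must be two-field.
#'
#' @param a,b `hla_allele` objects or allele strings.
#' @return Logical flag.
#' @examples
#' allele_match("A*11:01", "A*11:02") # FALSE
#' @export
allele_match <- function(a, b) {
  a <- as_hla_allele(a); b <- as_hla_allele(b)
  if (is.null(a$field2) || is.null(b$field2)) {
    stop("allele_match() requires two-field alleles; got '",
         format(a), "' and '", format(b), "'", call. = FALSE)
  }
  a$locus == b$locus && a$field1 == b$field1 && a$field2 == b$field2
}

## Vector-friendly internal variants over canonical strings.
any_antigen_match <- function(members, donor) {
  if (length(members) == 0L || length(donor) == 0L) return(FALSE)
  ml <- str_locus(members); dl <- str_locus(donor)
  mf <- str_field1(members); df <- str_field1(donor)
  any(outer(ml, dl, "==") & outer(mf, df, "=="))
}

any_allele_match <- function(members, donor) {
  if (length(members) == 0L || length(donor) == 0L) return(FALSE)
  any(members %in% donor)
}

hla_class_of <- function(locus) {
  ifelse(locus %in% CLASS_I_LOCI, "I", "II")
}
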