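#' Construct a per-subject HLA genotype
#'
#' A genotype holds up to two distinct alleles per locus together with a
#' provenance flag. Homozygosity is represented by a single allele entry.
#' A locus flagged `"unavailable"` carries no alleles.
#'
#' @param subject Subject identifier (coerced to character).
#' @param loci Named list; each element is `list(alleles = <character>,
#'   provenance = "typed"|"imputed"|"unavailable")`. Names are loci.
#' @return An object of class `hla_genotype`.
#' @examples
#' hla_genotype("D1", list(
#'   A = list(alleles = c("A*11:01", "A*02:01"), provenance = "typed"),
#'   DPB1 = list(alleles = character(), provenance = "unavailable")))
#' @export
hla_genotype <- function(subject, loci = list()) {
  subject <- as.character(subject)
  if (length(loci) && (is.null(names(loci)) || any(!nzchar(names(loci))))) {
    stop("loci must be a named list", call. = FALSE)
  }
  out <- list()
  for (locus in names(loci)) {
    if (!locus %in% HLA_LOCI) {
      stop("unknown HLA locus '", locus, "'", call. = FALSE)
    }
    slot <- loci[[locus]]
    prov <- match.arg(slot$provenance, c("typed", "imputed", "unavailable"))
    alleles <- slot$alleles
    if (prov == "unavailable") {
      if (length(alleles)) {
        stop("locus ", locus, " flagged unavailable but carries alleles",
             call. = FALSE)
      }
      out[[locus]] <- list(alleles = character(), provenance = prov)
      next
    }
    if (!length(alleles)) {
      stop("locus ", locus, " (", prov, ") carries no alleles", call. = FALSE)
    }
    alleles <- unique(canonical_allele(alleles))
    if (any(str_locus(alleles) != locus)) {
      stop("allele(s) ", paste(alleles[str_locus(alleles) != locus],
                               collapse = ", "),
           " do not belong to locus ", locus, call. = FALSE)
    }
    if (length(alleles) > 2L) {
      stop("locus ", locus, " carries more than two distinct alleles",
           call. = FALSE)
    }
    out[[locus]] <- list(alleles = alleles, provenance = prov)
  }
  structure(list(subject = subject, loci = out), class = "hla_genotype")
}

#' @export
print.hla_genotype <- function(x, ...) {
  cat("<hla_genotype> subject ", x$subject, "\n", sep = "")
  for (locus in names(x$loci)) {
    slot <- x$loci[[locus]]
    al <- if (length(slot$alleles)) paste(slot$alleles, collapse = ", ") else "-"
    cat(sprintf("  %-5s %-22s [%s]\n", locus, al, slot$provenance))
  }
  invisible(x)
}

#' Alleles carried at a locus
#'
#' @param g An `hla_genotype`.
#' @param locus Locus name.
#' @return Character vector of canonical allele strings; empty when the locus
#'   is absent or unavailable.
#' @export
gt_alleles <- function(g, locus) {
  slot <- g$loci[[locus]]
  if (is.null(slot)) character() else slot$alleles
}

#' Provenance flag of a locus
#'
#' @param g An `hla_genotype`.
#' @param locus Locus name.
#' @return `"typed"`, `"imputed"`, or `"unavailable"` (also for absent loci).
#' @export
gt_provenance <- function(g, locus) {
  slot <- g$loci[[locus]]
  if (is.null(slot)) "unavailable" else slot$provenance
}

gt_set_locus <- function(g, locus, alleles, provenance) {
  alleles <- unique(canonical_allele(alleles))
  g$loci[[locus]] <- list(alleles = alleles, provenance = provenance)
  g
}

#' Build genotypes from a long typing table
#'
#' @param df Data frame with columns `subject_id`, `locus`, `allele1`,
#'   `allele2`, `provenance`. Blank `allele2` encodes homozygosity or a
#'   single known allele; blank both with provenance `"unavailable"` encodes
#'   an untyped locus.
#' @return Named list of `hla_genotype` objects, keyed by subject id.
#' @export
genotypes_from_table <- function(df) {
  need <- c("subject_id", "locus", "allele1", "allele2", "provenance")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("typing table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (id in unique(as.character(df$subject_id))) {
    rows <- df[as.character(df$subject_id) == id, , drop = FALSE]
    loci <- list()
    for (k in seq_len(nrow(rows))) {
      locus <- as.character(rows$locus[k])
      a <- c(rows$allele1[k], rows$allele2[k])
      a <- a[!is.na(a) & nzchar(trimws(a))]
      loci[[locus]] <- list(alleles = as.character(a),
                            provenance = as.character(rows$provenance[k]))
    }
    out[[id]] <- hla_genotype(id, loci)
  }
  out
}

#' Read a typing table (TSV)
#'
#' Columns: `subject_id`, `locus`, `allele1`, `allele2`, `provenance`.
#'
#' @param path Path to a tab-separated file.
#' @return Named list of `hla_genotype` objects.
#' @export
read_typing <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  genotypes_from_table(df)
}

#' Write genotypes to a typing table (TSV)
#'
#' @param genotypes List of `hla_genotype` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_typing <- function(genotypes, path) {
  rows <- list()
  for (g in genotypes) {
    for (locus in names(g$loci)) {
      slot <- g$loci[[locus]]
      a <- slot$alleles
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = g$subject, locus = locus,
        allele1 = if (length(a) >= 1L) a[1L] else "",
        allele2 = if (length(a) >= 2L) a[2L] else "",
        provenance = slot$provenance, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
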