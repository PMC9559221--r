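## Haplotype-frequency expansion of untyped loci from low-resolution typing,
## emulating the clinical practice of estimating donor HLA-C/DQ from
## population frequency tables.

#' Construct a haplotype frequency table
#'
#' @param df Data frame with one column per locus (canonical or bare allele
#'   strings, e.g. `"A*01:01"`), a `freq` column with positive frequencies
#'   summing to at most 1 (tolerance 1e-6), and an optional `population`
#'   label column.
#' @return Object of class `haplotype_table`: the validated data frame with
#'   attribute `loci`.
#' @export
haplotype_table <- function(df) {
  if (!"freq" %in% names(df)) stop("haplotype table needs a freq column",
                                   call. = FALSE)
  loci <- intersect(names(df), HLA_LOCI)
  if (!length(loci)) stop("haplotype table has no locus columns", call. = FALSE)
  freq <- as.numeric(df$freq)
  if (any(!is.finite(freq)) || any(freq <= 0)) {
    stop("haplotype frequencies must be positive", call. = FALSE)
  }
  if (sum(freq) > 1 + 1e-6) {
    stop("haplotype frequencies sum to more than 1", call. = FALSE)
  }
  for (locus in loci) {
    vals <- as.character(df[[locus]])
    vals <- ifelse(grepl("*", vals, fixed = TRUE), vals, paste0(locus, "*", vals))
    vals <- canonical_allele(vals)
    if (any(str_locus(vals) != locus)) {
      stop("column ", locus, " contains alleles of another locus", call. = FALSE)
    }
    df[[locus]] <- vals
  }
  df$freq <- freq
  structure(df, class = c("haplotype_table", "data.frame"), loci = loci)
}

#' Read a haplotype frequency table (CSV)
#'
#' @param path CSV with locus columns, `freq` and optional `population`.
#' @return A `haplotype_table`.
#' @export
read_haplotype_table <- function(path) {
  haplotype_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

ht_loci <- function(table) attr(table, "loci")

hap_string <- function(table, i, loci = ht_loci(table)) {
  paste(vapply(loci, function(l) table[[l]][i], character(1)), collapse = "~")
}

## Does observed allele `obs` match table allele `tab` at the observed
## resolution? One-field observations match any table allele of the group.
obs_matches <- function(obs, tab) {
  if (str_is_two_field(obs)) return(obs == tab)
  str_locus(obs) == str_locus(tab) && str_field1(obs) == str_field1(tab)
}

pair_explains_locus <- function(a1, a2, observed) {
  if (length(observed) == 1L) {
    obs_matches(observed, a1) && obs_matches(observed, a2)
  } else {
    (obs_matches(observed[1L], a1) && obs_matches(observed[2L], a2)) ||
      (obs_matches(observed[2L], a1) && obs_matches(observed[1L], a2))
  }
}

#' Enumerate haplotype pairs compatible with an observed genotype
#'
#' Standard two-haplotype genotype decomposition: all unordered row pairs of
#' the table whose allele union reproduces the observed genotype at every
#' observed locus, matched at the observed resolution (a one-field observed
#' allele matches any two-field table allele of the same group). The pair
#' weight is `f(h1) * f(h2)`, doubled for heterozygous pairs.
#'
#' @param observed An `hla_genotype`; loci flagged unavailable are ignored.
#' @param table A `haplotype_table`.
#' @return Data frame with columns `h1`, `h2` (row indices), `weight`, `prob`
#'   (weights normalised to sum 1); zero rows when nothing is compatible.
#' @export
enumerate_compatible_pairs <- function(observed, table) {
  loci <- ht_loci(table)
  obs_loci <- names(observed$loci)
  obs_loci <- obs_loci[vapply(obs_loci, function(l)
    gt_provenance(observed, l) != "unavailable" &&
      length(gt_alleles(observed, l)) > 0, logical(1))]
  extra <- setdiff(obs_loci, loci)
  if (length(extra)) {
    stop("observed loci not covered by the haplotype table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  n <- nrow(table)
  h1 <- integer(); h2 <- integer(); w <- numeric()
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- TRUE
      for (locus in obs_loci) {
        if (!pair_explains_locus(table[[locus]][i], table[[locus]][j],
                                 gt_alleles(observed, locus))) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        h1 <- c(h1, i); h2 <- c(h2, j)
        w <- c(w, table$freq[i] * table$freq[j] * (if (i == j) 1 else 2))
      }
    }
  }
  data.frame(h1 = h1, h2 = h2, weight = w,
             prob = if (length(w)) w / sum(w) else numeric(),
             stringsAsFactors = FALSE)
}

#' Impute untyped loci from a haplotype frequency table
#'
#' Fills the target loci from the maximum-weight compatible haplotype pair (a
#' point estimate mirroring clinical "estimated typing"); equal-weight ties
#' are broken lexicographically on the serialised pair for determinism. The
#' reported probability is the best pair's share of total compatible weight,
#' so callers can flag low-confidence (< 0.5) imputations.
#'
#' @param observed An `hla_genotype` whose target loci are unavailable.
#' @param table A `haplotype_table` covering observed and target loci.
#' @param target_loci Character vector of loci to fill.
#' @return Object of class `hla_imputation`: list with `genotype` (expanded,
#'   target loci flagged `"imputed"`), `probability`, and `pairs` (the ranked
#'   alternatives with normalised probabilities and serialised haplotypes).
#' @export
impute_loci <- function(observed, table, target_loci) {
  loci <- ht_loci(table)
  bad <- setdiff(target_loci, loci)
  if (length(bad)) {
    stop("target loci not in haplotype table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (locus in target_loci) {
    if (length(gt_alleles(observed, locus))) {
      stop("target locus ", locus, " already carries alleles in '",
           observed$subject, "'", call. = FALSE)
    }
  }
  pairs <- enumerate_compatible_pairs(observed, table)
  if (!nrow(pairs)) {
    stop("observed genotype '", observed$subject,
         "' is inconsistent with the haplotype panel", call. = FALSE)
  }
  pairs$serialized <- vapply(seq_len(nrow(pairs)), function(k) {
    paste(sort(c(hap_string(table, pairs$h1[k]), hap_string(table, pairs$h2[k]))),
          collapse = " | ")
  }, character(1))
  ord <- order(-pairs$weight, pairs$serialized)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  best <- pairs[1L, ]
  g <- observed
  for (locus in target_loci) {
    alleles <- unique(c(table[[locus]][best$h1], table[[locus]][best$h2]))
    g <- gt_set_locus(g, locus, alleles, "imputed")
  }
  structure(list(genotype = g, probability = best$prob, pairs = pairs),
            class = "hla_imputation")
}

#' @export
print.hla_imputation <- function(x, ...) {
  cat("<hla_imputation> best pair p =", signif(x$probability, 4),
      "over", nrow(x$pairs), "compatible pair(s)\n")
  print(x$genotype)
  invisible(x)
}
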