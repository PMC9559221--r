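## HLAMatchmaker-style eplet set algebra: registry lookup, donor-minus-
## recipient mismatch, antibody-verified subsets, and non-shared-eplet
## explanations for antibodies presumed donor-specific at low resolution but
## refuted at high resolution.

#' Construct an eplet registry
#'
#' @param df Data frame with columns `allele` (two-field strings), `eplet`
#'   (name), `abv` (0/1 antibody-verified flag, global per eplet).
#' @return Object of class `eplet_registry`: list with `sets` (named list,
#'   allele -> eplet names) and `abv` (named logical by eplet).
#' @export
eplet_registry <- function(df) {
  need <- c("allele", "eplet", "abv")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("eplet registry lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  alleles <- canonical_allele(as.character(df$allele))
  if (any(!str_is_two_field(alleles))) {
    stop("eplet registry alleles must be two-field; offending: ",
         paste(unique(df$allele[!str_is_two_field(alleles)]), collapse = ", "),
         call. = FALSE)
  }
  eplet <- as.character(df$eplet)
  abv <- as.logical(as.integer(df$abv))
  flag <- tapply(abv, eplet, function(v) {
    u <- unique(v)
    if (length(u) > 1L) NA else u
  })
  if (anyNA(flag)) {
    stop("conflicting antibody-verified flags for eplet(s): ",
         paste(names(flag)[is.na(flag)], collapse = ", "), call. = FALSE)
  }
  sets <- lapply(split(eplet, alleles), unique)
  structure(list(sets = sets, abv = unlist(flag)), class = "eplet_registry")
}

#' Read an eplet registry (CSV with columns allele, eplet, abv)
#'
#' @param path CSV path.
#' @return An `eplet_registry`.
#' @export
read_eplet_registry <- function(path) {
  eplet_registry(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Eplets carried by one allele
#'
#' @param allele Two-field allele string (or `hla_allele`).
#' @param registry An `eplet_registry`.
#' @return Character vector of eplet names.
#' @export
eplet_set <- function(allele, registry) {
  key <- if (inherits(allele, "hla_allele")) format(allele)
  else canonical_allele(allele)
  s <- registry$sets[[key]]
  if (is.null(s)) {
    stop("allele not in registry: ", key, call. = FALSE)
  }
  s
}

eplet_union <- function(alleles, registry) {
  if (!length(alleles)) return(character())
  missing_alleles <- setdiff(canonical_allele(alleles), names(registry$sets))
  if (length(missing_alleles)) {
    stop("allele(s) not in registry: ", paste(missing_alleles, collapse = ", "),
         call. = FALSE)
  }
  unique(unlist(lapply(alleles, eplet_set, registry = registry),
                use.names = FALSE))
}

#' Donor-minus-recipient eplet mismatch
#'
#' The union of eplets over the donor alleles minus the union over the
#' recipient alleles (genotype-level recipient union, HLAMatchmaker
#' convention), with the antibody-verified subset counted separately.
#'
#' @param donor_alleles,recipient_alleles Character vectors of two-field,
#'   registered alleles.
#' @param registry An `eplet_registry`.
#' @param scope Label for the result (e.g. `"class II"`).
#' @return Object of class `epmm_result`: list with `scope`, `eplets`,
#'   `count`, `abv_eplets`, `abv_count`.
#' @export
mismatched_eplets <- function(donor_alleles, recipient_alleles, registry,
                              scope = "") {
  mm <- setdiff(eplet_union(donor_alleles, registry),
                eplet_union(recipient_alleles, registry))
  abv <- mm[registry$abv[mm]]
  structure(list(scope = scope, eplets = mm, count = length(mm),
                 abv_eplets = abv, abv_count = length(abv)),
            class = "epmm_result")
}

#' @export
print.epmm_result <- function(x, ...) {
  cat("<epmm_result> ", x$scope, ": ", x$count, " eplet MM (",
      x$abv_count, " antibody-verified)\n", sep = "")
  invisible(x)
}

#' Eplets explaining an LR-presumed / HR-refuted discordance
#'
#' Eplets carried by the antibody-reactive (presumed) molecule but absent
#' from both the actual donor molecule and the recipient: the epitopes the
#' antibody can see that the donor does not actually display.
#'
#' @param presumed Allele(s) of the bead molecule the antibody reacts with
#'   (beta plus alpha for heterodimers).
#' @param actual_donor Allele(s) of the donor's actual molecule(s).
#' @param recipient_alleles Recipient alleles of the scope (may be empty).
#' @param registry An `eplet_registry`.
#' @return Data frame with columns `eplet` and logical `abv`; zero rows when
#'   the molecules share every registered eplet ("none").
#' @export
nonshared_eplets <- function(presumed, actual_donor,
                             recipient_alleles = character(), registry) {
  mm <- setdiff(eplet_union(presumed, registry),
                eplet_union(c(actual_donor, recipient_alleles), registry))
  data.frame(eplet = mm, abv = unname(registry$abv[mm]),
             stringsAsFactors = FALSE)
}

EPMM_SCOPES <- list(
  HR = list(class_i = c("A", "B", "C"),
            class_ii = c("DRB1", "DQB1", "DQA1", "DPB1"),
            dq = c("DQB1", "DQA1"),
            drb1 = "DRB1"),
  LR_imputed = list(class_i = c("A", "B"),
                    class_ii = c("DRB1", "DQB1"),
                    dq = "DQB1",
                    drb1 = "DRB1"))

#' Per-scope eplet mismatch profile for a donor/recipient pair
#'
#' Computes class I, class II, DQ-only and DRB1-only eplet mismatch. `"HR"`
#' mode uses the six-locus two-field scopes (class I A/B/C; class II
#' DRB1/DQ/DPB1); `"LR_imputed"` mirrors the clinical view (class I A/B;
#' class II DRB1/DQB1) and expects genotypes already expanded to two fields
#' via haplotype-frequency imputation. Loci without alleles in either
#' genotype are skipped, so partially typed pairs yield profiles over the
#' available scopes.
#'
#' @param recipient,donor `hla_genotype` objects with two-field alleles.
#' @param registry An `eplet_registry`.
#' @param mode `"HR"` or `"LR_imputed"`.
#' @param interlocus_dedupe Pool multi-locus scopes as one eplet union
#'   (`TRUE`, HLAMatchmaker convention) or sum per-locus counts (`FALSE`).
#' @return Named list of `epmm_result` objects (scopes as names).
#' @export
epmm_profile <- function(recipient, donor, registry,
                         mode = c("HR", "LR_imputed"),
                         interlocus_dedupe = TRUE) {
  mode <- match.arg(mode)
  scopes <- EPMM_SCOPES[[mode]]
  out <- list()
  for (scope_name in names(scopes)) {
    loci <- scopes[[scope_name]]
    loci <- loci[vapply(loci, function(l)
      length(gt_alleles(donor, l)) > 0 || length(gt_alleles(recipient, l)) > 0,
      logical(1))]
    d <- unlist(lapply(loci, gt_alleles, g = donor), use.names = FALSE)
    r <- unlist(lapply(loci, gt_alleles, g = recipient), use.names = FALSE)
    if (interlocus_dedupe || length(loci) <= 1L) {
      out[[scope_name]] <- mismatched_eplets(d, r, registry, scope = scope_name)
    } else {
      parts <- lapply(loci, function(l)
        mismatched_eplets(gt_alleles(donor, l), gt_alleles(recipient, l),
                          registry, scope = l))
      eplets <- unlist(lapply(parts, `[[`, "eplets"), use.names = FALSE)
      abv <- unlist(lapply(parts, `[[`, "abv_eplets"), use.names = FALSE)
      out[[scope_name]] <- structure(
        list(scope = scope_name, eplets = eplets, count = length(eplets),
             abv_eplets = abv, abv_count = length(abv)),
        class = "epmm_result")
    }
  }
  out
}
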