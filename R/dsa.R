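## Dual-resolution donor-specific antibody assignment: each antibody
## specificity receives one verdict per mode. LR mode sees the clinical view
## of the donor (first-field A/B/DRB1, two-field imputed C/DQB1, no DP or
## DQA1); HR mode sees complete two-field typing, matches DQ/DP heterodimers
## chain-by-chain, and accounts for donor alleles missing from the SAB panel.

DSA_VERDICTS <- c("DSA", "not_DSA", "unassessable_panel", "unclassifiable_typing")
LR_ANTIGEN_LOCI <- c("A", "B", "DRB1")
LR_IMPUTED_LOCI <- c("C", "DQB1")

new_dsa_call <- function(spec, mode, verdict, reason) {
  data.frame(patient_id = spec$sample_id,
             spec_id = as.character(spec$spec_id),
             target = format(spec),
             locus = spec$locus,
             hla_class = spec$class,
             mode = mode,
             verdict = verdict,
             reason = reason,
             stringsAsFactors = FALSE)
}

#' Assign a low-resolution (clinical-view) DSA verdict
#'
#' Under the LR view the donor is known at first-field A/B/DRB1 (so the
#' verdict is an antigen-level match), at two-field C/DQB1 when those loci
#' were imputed from haplotype frequencies (exact two-field comparison,
#' alpha chains ignored), and not at all at DP, DQA1 or DRB3/4/5 (verdict
#' `unclassifiable_typing`).
#'
#' @param spec An `hla_specificity`.
#' @param donor_lr Donor `hla_genotype` in the LR view.
#' @return One-row data frame (a DSA call): `patient_id`, `spec_id`,
#'   `target`, `locus`, `hla_class`, `mode`, `verdict`, `reason`.
#' @export
assign_lr <- function(spec, donor_lr) {
  locus <- spec$locus
  if (locus %in% LR_ANTIGEN_LOCI) {
    donor <- gt_alleles(donor_lr, locus)
    if (!length(donor)) {
      return(new_dsa_call(spec, "LR", "unclassifiable_typing",
                          paste0("locus ", locus, " not typed in LR donor view")))
    }
    if (any_antigen_match(spec$beta_alleles, donor)) {
      return(new_dsa_call(spec, "LR", "DSA",
                          "first-field antigen match to donor typing"))
    }
    return(new_dsa_call(spec, "LR", "not_DSA",
                        "no first-field antigen match to donor typing"))
  }
  if (locus %in% LR_IMPUTED_LOCI) {
    donor <- gt_alleles(donor_lr, locus)
    if (!length(donor)) {
      return(new_dsa_call(spec, "LR", "unclassifiable_typing",
                          paste0("locus ", locus,
                                 " not typed/imputed in LR donor view")))
    }
    if (any_allele_match(spec$beta_alleles, donor)) {
      return(new_dsa_call(spec, "LR", "DSA",
                          "two-field match to imputed donor allele"))
    }
    return(new_dsa_call(spec, "LR", "not_DSA",
                        "no two-field match to imputed donor allele"))
  }
  new_dsa_call(spec, "LR", "unclassifiable_typing",
               paste0("locus ", locus, " not assessed by LR typing"))
}

## Donor molecules at the specificity's locus, for panel-availability checks:
## class I / DRB loci give one molecule per allele; DQ gives beta/alpha chain
## pairs in listed order; DP gives beta-only molecules unless DPA1 is typed.
donor_molecules <- function(donor_hr, locus) {
  if (!locus %in% names(HETERODIMER_BETA)) {
    beta <- gt_alleles(donor_hr, locus)
    return(data.frame(beta = beta, alpha = rep(NA_character_, length(beta)),
                      stringsAsFactors = FALSE))
  }
  alpha_locus <- HETERODIMER_BETA[[locus]]
  beta <- gt_alleles(donor_hr, locus)
  alpha <- gt_alleles(donor_hr, alpha_locus)
  if (!length(alpha)) {
    return(data.frame(beta = beta, alpha = rep(NA_character_, length(beta)),
                      stringsAsFactors = FALSE))
  }
  n <- max(length(beta), length(alpha))
  unique(data.frame(beta = beta[pmin(seq_len(n), length(beta))],
                    alpha = alpha[pmin(seq_len(n), length(alpha))],
                    stringsAsFactors = FALSE))
}

#' Assign a high-resolution DSA verdict
#'
#' Class I and DRB specificities are donor-specific when any member allele
#' equals a donor allele at two-field resolution. DQ/DP heterodimer
#' specificities match chain-wise against unphased donor typing: some
#' reactive beta allele must equal a donor beta, and, when both the bead
#' group and the donor carry alpha information, some reactive alpha must
#' equal a donor alpha (a beta match with an alpha mismatch is not
#' donor-specific). When no match exists but a donor molecule at the locus
#' is absent from the SAB panel, the verdict is `unassessable_panel` rather
#' than `not_DSA` - the assay could never have probed that molecule.
#'
#' @param spec An `hla_specificity`.
#' @param donor_hr Donor `hla_genotype` with two-field typing at the
#'   specificity's locus (and the alpha locus for DQ, when typed).
#' @param panel An `sab_panel`.
#' @return One-row data frame (a DSA call), as [assign_lr()].
#' @export
assign_hr <- function(spec, donor_hr, panel) {
  locus <- spec$locus
  donor_beta <- gt_alleles(donor_hr, locus)
  if (!length(donor_beta)) {
    stop("donor '", donor_hr$subject, "' has no HR typing at locus ", locus,
         call. = FALSE)
  }
  if (any(!str_is_two_field(donor_beta))) {
    stop("HR assignment requires two-field donor typing at ", locus,
         call. = FALSE)
  }
  matched <- FALSE
  alpha_blocked <- FALSE
  if (!locus %in% names(HETERODIMER_BETA)) {
    matched <- any_allele_match(spec$beta_alleles, donor_beta)
  } else {
    alpha_locus <- HETERODIMER_BETA[[locus]]
    donor_alpha <- gt_alleles(donor_hr, alpha_locus)
    beta_hit <- any_allele_match(spec$beta_alleles, donor_beta)
    if (beta_hit) {
      if (!length(spec$alpha_alleles) || !length(donor_alpha)) {
        matched <- TRUE
      } else if (any_allele_match(spec$alpha_alleles, donor_alpha)) {
        matched <- TRUE
      } else {
        alpha_blocked <- TRUE
      }
    }
  }
  if (matched) {
    return(new_dsa_call(spec, "HR", "DSA",
                        "two-field (chain-level) match to donor typing"))
  }
  mol <- donor_molecules(donor_hr, locus)
  off_panel <- !vapply(seq_len(nrow(mol)), function(i)
    panel_contains(panel, mol$beta[i], mol$alpha[i]), logical(1))
  if (any(off_panel)) {
    missing <- target_key(mol$beta[off_panel], mol$alpha[off_panel])
    return(new_dsa_call(spec, "HR", "unassessable_panel",
                        paste0("donor molecule(s) absent from SAB panel: ",
                               paste(missing, collapse = ", "))))
  }
  reason <- if (alpha_blocked) {
    "beta chain matches donor but alpha chain does not (alpha mismatch)"
  } else {
    "no two-field match to donor typing"
  }
  new_dsa_call(spec, "HR", "not_DSA", reason)
}

#' Assign both verdicts for every specificity of a cohort
#'
#' @param specs List of `hla_specificity` objects.
#' @param donors_lr,donors_hr Named lists of donor `hla_genotype` objects
#'   (LR clinical view and HR complete view), keyed by patient id.
#' @param panel An `sab_panel`.
#' @return Data frame of DSA calls, two rows (LR and HR) per specificity.
#' @export
assign_cohort <- function(specs, donors_lr, donors_hr, panel) {
  rows <- vector("list", 2L * length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    pid <- spec$sample_id
    if (is.null(donors_lr[[pid]]) || is.null(donors_hr[[pid]])) {
      stop("no donor typing for patient '", pid, "'", call. = FALSE)
    }
    rows[[2L * i - 1L]] <- assign_lr(spec, donors_lr[[pid]])
    rows[[2L * i]] <- assign_hr(spec, donors_hr[[pid]], panel)
  }
  if (!length(rows)) {
    return(data.frame(patient_id = character(), spec_id = character(),
                      target = character(), locus = character(),
                      hla_class = character(), mode = character(),
                      verdict = character(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify one patient from their DSA calls
#'
#' A patient is LR_dnDSA+ (resp. HR_dnDSA+) when at least one specificity
#' received a `DSA` verdict in that mode; `unassessable_panel` and
#' `unclassifiable_typing` count as non-DSA. Class I/II flags are set only
#' from HR-confirmed specificities.
#'
#' @param patient_id Patient identifier.
#' @param calls DSA call data frame (any superset of the patient's rows).
#' @return One-row data frame: `patient_id`, `lr_dnDSA`, `hr_dnDSA`,
#'   `hr_class_i`, `hr_class_ii`, `group` (one of `LRpos_HRpos`,
#'   `LRpos_HRneg`, `LRneg_HRpos`, `neg`).
#' @export
classify_patient <- function(patient_id, calls) {
  mine <- calls[calls$patient_id == patient_id, , drop = FALSE]
  lr <- any(mine$mode == "LR" & mine$verdict == "DSA")
  hr_rows <- mine$mode == "HR" & mine$verdict == "DSA"
  hr <- any(hr_rows)
  group <- if (lr && hr) "LRpos_HRpos" else if (lr) "LRpos_HRneg"
  else if (hr) "LRneg_HRpos" else "neg"
  data.frame(patient_id = as.character(patient_id),
             lr_dnDSA = lr, hr_dnDSA = hr,
             hr_class_i = any(hr_rows & mine$hla_class == "I"),
             hr_class_ii = any(hr_rows & mine$hla_class == "II"),
             group = group, stringsAsFactors = FALSE)
}

#' Classify every patient of a cohort
#'
#' @param calls DSA call data frame from [assign_cohort()].
#' @param patients Character vector of all patient ids (so antibody-free
#'   patients are classified `neg`); defaults to the ids present in `calls`.
#' @return Data frame, one row per patient, as [classify_patient()].
#' @export
classify_cohort <- function(calls, patients = unique(calls$patient_id)) {
  do.call(rbind, lapply(as.character(patients), classify_patient, calls = calls))
}

#' Summarise dual-resolution concordance for a cohort
#'
#' @param classifications Output of [classify_cohort()].
#' @param calls Output of [assign_cohort()].
#' @return Object of class `dsa_summary`: nested list with patient-level
#'   counts (per concordance group, HR class I-only / class II-only / both)
#'   and specificity-level counts (LR-identified, confirmed by both, LR-only,
#'   HR-only), with percentages against their stated denominators.
#' @export
summarize_cohort <- function(classifications, calls) {
  cl <- classifications
  n <- nrow(cl)
  lr_pos <- sum(cl$lr_dnDSA)
  hr_pos <- sum(cl$hr_dnDSA)
  lr_hr_pos <- sum(cl$group == "LRpos_HRpos")
  lr_only <- sum(cl$group == "LRpos_HRneg")
  hr_only <- sum(cl$group == "LRneg_HRpos")
  hrp <- cl[cl$hr_dnDSA, , drop = FALSE]
  class_i_only <- sum(hrp$hr_class_i & !hrp$hr_class_ii)
  class_ii_only <- sum(!hrp$hr_class_i & hrp$hr_class_ii)
  class_both <- sum(hrp$hr_class_i & hrp$hr_class_ii)

  wide <- merge(calls[calls$mode == "LR", c("patient_id", "spec_id", "verdict")],
                calls[calls$mode == "HR", c("patient_id", "spec_id", "verdict")],
                by = c("patient_id", "spec_id"), suffixes = c("_lr", "_hr"))
  lr_specs <- sum(wide$verdict_lr == "DSA")
  confirmed <- sum(wide$verdict_lr == "DSA" & wide$verdict_hr == "DSA")
  lr_unconfirmed <- sum(wide$verdict_lr == "DSA" & wide$verdict_hr != "DSA")
  hr_only_specs <- sum(wide$verdict_lr != "DSA" & wide$verdict_hr == "DSA")

  pct <- function(x, d) if (d > 0) round(100 * x / d, 1) else NA_real_
  structure(list(
    patients = list(
      n = n, lr_pos = lr_pos, hr_pos = hr_pos,
      lr_pos_hr_pos = lr_hr_pos, lr_pos_hr_neg = lr_only,
      lr_neg_hr_pos = hr_only, neg = sum(cl$group == "neg"),
      pct_lr_pos = pct(lr_pos, n),
      pct_hr_pos = pct(hr_pos, n),
      pct_confirmed_of_lr = pct(lr_hr_pos, lr_pos),
      hr_class_i_only = class_i_only,
      hr_class_ii_only = class_ii_only,
      hr_class_both = class_both),
    specificities = list(
      lr_identified = lr_specs,
      confirmed_both = confirmed,
      lr_unconfirmed = lr_unconfirmed,
      hr_only = hr_only_specs,
      pct_confirmed_of_lr = pct(confirmed, lr_specs))),
    class = "dsa_summary")
}

#' @export
print.dsa_summary <- function(x, ...) {
  p <- x$patients; s <- x$specificities
  cat("Dual-resolution dnDSA summary\n")
  cat(sprintf("  patients: %d; LR_dnDSA+ %d (%.1f%%), HR_dnDSA+ %d (%.1f%%)\n",
              p$n, p$lr_pos, p$pct_lr_pos, p$hr_pos, p$pct_hr_pos))
  cat(sprintf("  groups: LR+/HR+ %d, LR+/HR- %d, LR-/HR+ %d, neg %d\n",
              p$lr_pos_hr_pos, p$lr_pos_hr_neg, p$lr_neg_hr_pos, p$neg))
  cat(sprintf("  HR+ class: I-only %d, II-only %d, both %d\n",
              p$hr_class_i_only, p$hr_class_ii_only, p$hr_class_both))
  cat(sprintf("  specificities: LR-identified %d, confirmed %d, LR-only %d, HR-only %d\n",
              s$lr_identified, s$confirmed_both, s$lr_unconfirmed, s$hr_only))
  invisible(x)
}
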