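## Antigen/allele mismatch counting over the three-locus low-resolution view
## (A, B, DRB1 allele groups) and the six-locus high-resolution view
## (A, B, C, DRB1, DQ as one combined alpha/beta unit, DPB1 at two fields).

LR3_LOCI <- c("A", "B", "DRB1")
HR6_SINGLE_LOCI <- c("A", "B", "C", "DRB1", "DPB1")

require_locus <- function(g, locus, who) {
  if (gt_provenance(g, locus) == "unavailable" || !length(gt_alleles(g, locus))) {
    stop("required locus ", locus, " is unavailable in ", who, " genotype '",
         g$subject, "'", call. = FALSE)
  }
}

require_two_field <- function(alleles, locus, who) {
  if (any(!str_is_two_field(alleles))) {
    stop("HR6 counting requires two-field typing at ", locus, " for ", who,
         " (got ", paste(alleles[!str_is_two_field(alleles)], collapse = ", "),
         ")", call. = FALSE)
  }
}

#' Donor DQ heterodimer units
#'
#' Pairs donor DQB1 with DQA1 alleles by the order they are listed (typing
#' is unphased; the listed order is the configurable pairing convention),
#' recycling the shorter chain list for homozygous loci.
#'
#' @param g An `hla_genotype`.
#' @return Data frame with columns `beta`, `alpha` (canonical strings), one
#'   row per distinct donor DQ unit; zero rows when DQ is not fully typed.
#' @export
dq_units <- function(g) {
  beta <- gt_alleles(g, "DQB1")
  alpha <- gt_alleles(g, "DQA1")
  if (!length(beta) || !length(alpha)) {
    return(data.frame(beta = character(), alpha = character(),
                      stringsAsFactors = FALSE))
  }
  n <- max(length(beta), length(alpha))
  units <- data.frame(beta = beta[pmin(seq_len(n), length(beta))],
                      alpha = alpha[pmin(seq_len(n), length(alpha))],
                      stringsAsFactors = FALSE)
  unique(units)
}

#' Count donor/recipient HLA antigen mismatches
#'
#' Counts donor antigens absent from the recipient, per locus, in one of two
#' schemes: `"LR3"` compares allele-group (first-field) antigens at A, B and
#' DRB1 (global range 0-6); `"HR6"` compares two-field alleles at A, B, C,
#' DRB1 and DPB1 plus the combined DQ unit, where a donor DQ unit mismatches
#' when its beta or its alpha chain is absent from the recipient (global
#' range 0-12). Homozygous donor loci contribute each distinct antigen once.
#'
#' @param recipient,donor `hla_genotype` objects.
#' @param mode `"LR3"` or `"HR6"`.
#' @return List with `mode`, `per_locus` (named integer), `class_i`,
#'   `class_ii` and `global` counts.
#' @export
count_antigen_mm <- function(recipient, donor, mode = c("LR3", "HR6")) {
  mode <- match.arg(mode)
  per_locus <- integer()
  if (mode == "LR3") {
    for (locus in LR3_LOCI) {
      require_locus(recipient, locus, "recipient")
      require_locus(donor, locus, "donor")
      d <- unique(reduce_to_one_field(gt_alleles(donor, locus)))
      r <- unique(reduce_to_one_field(gt_alleles(recipient, locus)))
      per_locus[[locus]] <- length(setdiff(d, r))
    }
    class_i <- sum(per_locus[c("A", "B")])
    class_ii <- per_locus[["DRB1"]]
  } else {
    for (locus in HR6_SINGLE_LOCI) {
      require_locus(recipient, locus, "recipient")
      require_locus(donor, locus, "donor")
      d <- gt_alleles(donor, locus)
      r <- gt_alleles(recipient, locus)
      require_two_field(d, locus, "donor")
      require_two_field(r, locus, "recipient")
      per_locus[[locus]] <- length(setdiff(d, r))
    }
    for (locus in c("DQB1", "DQA1")) {
      require_locus(recipient, locus, "recipient")
      require_locus(donor, locus, "donor")
      require_two_field(gt_alleles(donor, locus), locus, "donor")
      require_two_field(gt_alleles(recipient, locus), locus, "recipient")
    }
    units <- dq_units(donor)
    r_beta <- gt_alleles(recipient, "DQB1")
    r_alpha <- gt_alleles(recipient, "DQA1")
    per_locus[["DQ"]] <- sum(!(units$beta %in% r_beta) |
                               !(units$alpha %in% r_alpha))
    class_i <- sum(per_locus[c("A", "B", "C")])
    class_ii <- sum(per_locus[c("DRB1", "DQ", "DPB1")])
  }
  list(mode = mode, per_locus = per_locus,
       class_i = unname(class_i), class_ii = unname(class_ii),
       global = unname(class_i + class_ii))
}
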