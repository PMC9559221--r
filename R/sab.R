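## Single-antigen bead (SAB) assay model: bead targets, panel representation,
## the MFI positivity rule and grouping of positive beads into antibody
## specificities.

#' Parse a bead target string
#'
#' Class I beads carry one allele (`"A*11:01"`); class II DQ/DP beads carry a
#' beta/alpha heterodimer (`"DQB1*03:02/DQA1*02:01"`). DP donors are often
#' reported beta-only, so a bare `"DPB1*04:01"` is also a valid target.
#'
#' @param text Target string.
#' @return List with `beta`, `alpha` (canonical strings; `alpha` `NA` when
#'   absent), `locus` (beta locus) and `class` (`"I"`/`"II"`).
#' @export
bead_target <- function(text) {
  parts <- strsplit(trimws(text), "/", fixed = TRUE)[[1]]
  beta <- canonical_allele(parts[1L])
  alpha <- NA_character_
  locus <- str_locus(beta)
  if (length(parts) > 1L) {
    alpha <- canonical_allele(parts[2L])
    expected <- if (locus %in% names(HETERODIMER_BETA))
      HETERODIMER_BETA[[locus]] else NULL
    if (is.null(expected) || str_locus(alpha) != expected) {
      stop("alpha chain ", alpha, " cannot pair with beta ", beta,
           call. = FALSE)
    }
  }
  if (locus %in% c("DQA1", "DPA1")) {
    stop("bead targets are keyed by the beta (or class I) chain; got '",
         text, "'", call. = FALSE)
  }
  list(beta = beta, alpha = alpha, locus = locus,
       class = hla_class_of(locus))
}

target_key <- function(beta, alpha = NA_character_) {
  ifelse(is.na(alpha) | !nzchar(alpha), beta, paste0(beta, "/", alpha))
}

#' Define a SAB panel
#'
#' The alleles/heterodimers represented on the assay. Two membership modes:
#' `"inclusion"` lists every bead on the panel; `"exclusion"` treats every
#' target as present unless listed absent (how panel gaps are reported in
#' practice, e.g. "not available on SAB").
#'
#' @param targets Character vector of target keys present (inclusion mode).
#' @param absent Character vector of target keys absent (exclusion mode).
#' @param mode `"inclusion"` or `"exclusion"`.
#' @return Object of class `sab_panel`.
#' @export
sab_panel <- function(targets = character(), absent = character(),
                      mode = c("inclusion", "exclusion")) {
  mode <- match.arg(mode)
  norm <- function(keys) {
    vapply(keys, function(k) {
      t <- bead_target(k)
      target_key(t$beta, t$alpha)
    }, character(1), USE.NAMES = FALSE)
  }
  structure(list(mode = mode, targets = unique(norm(targets)),
                 absent = unique(norm(absent))),
            class = "sab_panel")
}

#' Is a target represented on the panel?
#'
#' @param panel An `sab_panel`.
#' @param beta Beta (or class I) allele string.
#' @param alpha Optional alpha allele string.
#' @return Logical flag.
#' @export
panel_contains <- function(panel, beta, alpha = NA_character_) {
  key <- target_key(canonical_allele(beta),
                    if (is.na(alpha)) NA_character_ else canonical_allele(alpha))
  if (panel$mode == "inclusion") key %in% panel$targets else !key %in% panel$absent
}

#' Read a bead results table (CSV)
#'
#' Columns: `sample_id`, `class` (`I`/`II`), `target`, `mfi`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_beads <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "target", "mfi")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("bead table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$mfi <- as.numeric(df$mfi)
  if (any(!is.finite(df$mfi)) || any(df$mfi < 0)) {
    stop("bead MFI values must be non-negative numbers", call. = FALSE)
  }
  df
}

#' Call bead positivity
#'
#' A bead is positive when its normalised MFI exceeds `mfi_cutoff` AND the
#' ratio of its MFI to the lowest-MFI bead of the comparison group exceeds
#' `ratio_cutoff`. The comparison group is, by default, the same sample and
#' bead class (`lowest_scope = "class"`); `"sample"` uses the panel-wide
#' lowest bead of the sample. A zero lowest MFI makes every ratio infinite,
#' so only the absolute cutoff then discriminates.
#'
#' @param beads Data frame with `sample_id`, `class`, `target`, `mfi`.
#' @param mfi_cutoff Absolute MFI threshold (default 500).
#' @param ratio_cutoff Ratio-to-lowest-bead threshold (default 5).
#' @param lowest_scope `"class"` or `"sample"`.
#' @return The input with logical columns `positive` and numeric `ratio`.
#' @export
call_positive <- function(beads, mfi_cutoff = 500, ratio_cutoff = 5,
                          lowest_scope = c("class", "sample")) {
  lowest_scope <- match.arg(lowest_scope)
  if (!nrow(beads)) stop("empty bead table", call. = FALSE)
  key <- if (lowest_scope == "class") {
    paste(beads$sample_id, beads$class, sep = "\r")
  } else {
    as.character(beads$sample_id)
  }
  counts <- table(key)
  if (any(counts < 2L)) {
    stop("positivity calling needs at least two beads per ",
         if (lowest_scope == "class") "sample and class" else "sample",
         call. = FALSE)
  }
  lowest <- stats::ave(beads$mfi, key, FUN = min)
  ratio <- ifelse(lowest == 0, Inf, beads$mfi / lowest)
  beads$ratio <- ratio
  beads$positive <- beads$mfi > mfi_cutoff & ratio > ratio_cutoff
  beads
}

#' Construct an antibody specificity (bead group)
#'
#' One target molecule per specificity: a list of reactive two-field class I
#' (or class II beta) alleles sharing one locus, plus, for DQ/DP, the list of
#' reactive alpha-chain variants, and the MFI range of the member beads.
#'
#' @param sample_id Sample/patient identifier.
#' @param beta_alleles Character vector of reactive beta/class I alleles.
#' @param alpha_alleles Character vector of reactive alpha alleles (DQ/DP).
#' @param mfi_min,mfi_max MFI range over member beads.
#' @param spec_id Optional identifier.
#' @return Object of class `hla_specificity`.
#' @export
specificity <- function(sample_id, beta_alleles, alpha_alleles = character(),
                        mfi_min = NA_real_, mfi_max = NA_real_,
                        spec_id = NA_character_) {
  beta_alleles <- unique(canonical_allele(beta_alleles))
  if (!length(beta_alleles)) stop("specificity needs at least one allele",
                                  call. = FALSE)
  locus <- unique(str_locus(beta_alleles))
  if (length(locus) != 1L) {
    stop("specificity members span several loci: ",
         paste(locus, collapse = ", "), call. = FALSE)
  }
  if (length(alpha_alleles)) {
    alpha_alleles <- unique(canonical_allele(alpha_alleles))
    expected <- if (locus %in% names(HETERODIMER_BETA))
      HETERODIMER_BETA[[locus]] else NULL
    if (is.null(expected) || any(str_locus(alpha_alleles) != expected)) {
      stop("alpha alleles must be at the ", if (is.null(expected)) "-" else
        expected, " locus for a ", locus, " specificity", call. = FALSE)
    }
  }
  structure(list(sample_id = as.character(sample_id), spec_id = spec_id,
                 locus = locus, class = hla_class_of(locus),
                 beta_alleles = beta_alleles, alpha_alleles = alpha_alleles,
                 mfi_min = mfi_min, mfi_max = mfi_max),
            class = "hla_specificity")
}

#' @export
format.hla_specificity <- function(x, ...) {
  beta <- paste(x$beta_alleles, collapse = "; ")
  if (length(x$alpha_alleles)) {
    paste0(beta, " / ", paste(x$alpha_alleles, collapse = "; "))
  } else beta
}

#' @export
print.hla_specificity <- function(x, ...) {
  cat("<hla_specificity> sample ", x$sample_id, ": ", format(x),
      " (MFI ", x$mfi_min, "-", x$mfi_max, ")\n", sep = "")
  invisible(x)
}

#' Parse a printed specificity target
#'
#' Accepts the reporting shorthand used for bead-group rows, e.g.
#' `"B*35:01;35:08"` or `"DQB1*03:02/DQA1*02:01;03:01;03:02"`, where members
#' after the first inherit the locus prefix.
#'
#' @param text Target string.
#' @return List with `beta_alleles` and `alpha_alleles` character vectors.
#' @export
parse_spec_target <- function(text) {
  parts <- strsplit(trimws(text), "/", fixed = TRUE)[[1]]
  expand <- function(part) {
    members <- trimws(strsplit(part, ";", fixed = TRUE)[[1]])
    locus_prefix <- sub("\\*.*$", "", members[1L])
    members <- ifelse(grepl("*", members, fixed = TRUE), members,
                      paste0(locus_prefix, "*", members))
    canonical_allele(members)
  }
  list(beta_alleles = expand(parts[1L]),
       alpha_alleles = if (length(parts) > 1L) expand(parts[2L]) else character())
}

#' Group positive beads into specificities
#'
#' Partitions the positive beads of each sample: DQ/DP beads sharing a beta
#' allele merge into one specificity accumulating the reactive alpha
#' variants; all other beads stay one specificity per bead (explicit
#' cross-reactive grouping is supplied upstream in the input when wanted).
#'
#' @param beads Output of [call_positive()] (or any data frame with
#'   `sample_id`, `target`, `mfi` and logical `positive`).
#' @return List of `hla_specificity` objects; every positive bead belongs to
#'   exactly one.
#' @export
group_specificities <- function(beads) {
  pos <- beads[beads$positive, , drop = FALSE]
  out <- list()
  if (!nrow(pos)) return(out)
  parsed <- lapply(pos$target, bead_target)
  pos$beta <- vapply(parsed, `[[`, character(1), "beta")
  pos$alpha <- vapply(parsed, `[[`, character(1), "alpha")
  pos$locus <- vapply(parsed, `[[`, character(1), "locus")
  for (sid in unique(pos$sample_id)) {
    rows <- pos[pos$sample_id == sid, , drop = FALSE]
    dimer <- rows$locus %in% names(HETERODIMER_BETA)
    k <- 0L
    for (beta in unique(rows$beta[dimer])) {
      grp <- rows[dimer & rows$beta == beta, , drop = FALSE]
      k <- k + 1L
      out[[length(out) + 1L]] <- specificity(
        sid, beta, grp$alpha[!is.na(grp$alpha)],
        mfi_min = min(grp$mfi), mfi_max = max(grp$mfi),
        spec_id = paste0(sid, ".", k))
    }
    singles <- rows[!dimer, , drop = FALSE]
    for (i in seq_len(nrow(singles))) {
      k <- k + 1L
      out[[length(out) + 1L]] <- specificity(
        sid, singles$beta[i], character(),
        mfi_min = singles$mfi[i], mfi_max = singles$mfi[i],
        spec_id = paste0(sid, ".", k))
    }
  }
  out
}
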