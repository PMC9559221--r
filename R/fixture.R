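## Bundled machine-readable encoding of the published 39-patient worked
## cohort: per-patient antibody bead-group rows with printed MFI ranges, the
## printed low-resolution donor typing (including "estimated" entries and
## unavailable DP), the printed high-resolution donor typing, and the
## printed panel-availability annotations. Inputs only: verdicts and group
## labels are outputs of the engine, never encoded.

table3_path <- function(file) {
  path <- system.file("extdata", "table3", file, package = "hladsa")
  if (!nzchar(path)) stop("bundled fixture file not found: ", file,
                          call. = FALSE)
  path
}

#' Load the bundled worked-cohort fixture
#'
#' Thirty-nine patients with post-transplant anti-HLA antibodies, encoded as
#' engine inputs: one specificity (bead-group) row per detected antibody
#' with its printed MFI range, the donor's low-resolution clinical view
#' (first-field A/B/DRB1; two-field haplotype-frequency estimates at C/DQB1
#' flagged `imputed`; DP unavailable), the donor's high-resolution typing at
#' the targeted loci, and the SAB panel in exclusion mode (targets reported
#' unavailable on the assay). Positivity is taken as given for these rows:
#' the source table lists detected antibodies only.
#'
#' @return Object of class `dsa_fixture`: list with `specs` (list of
#'   `hla_specificity`), `donors_lr`, `donors_hr` (named genotype lists),
#'   `panel` (`sab_panel`), and `patients` (character ids).
#' @export
load_table3 <- function() {
  raw <- utils::read.csv(table3_path("specs.csv"), stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character",
                                        spec_id = "character"))
  specs <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    parsed <- tryCatch(parse_spec_target(raw$target[i]),
                       error = function(e) {
                         stop("fixture specs.csv row ", i, ": ",
                              conditionMessage(e), call. = FALSE)
                       })
    specs[[i]] <- specificity(raw$patient_id[i], parsed$beta_alleles,
                              parsed$alpha_alleles,
                              mfi_min = raw$mfi_min[i],
                              mfi_max = raw$mfi_max[i],
                              spec_id = raw$spec_id[i])
  }
  donors_lr <- read_typing(table3_path("donor_lr.tsv"))
  donors_hr <- read_typing(table3_path("donor_hr.tsv"))
  absent <- utils::read.csv(table3_path("panel_absent.csv"),
                            stringsAsFactors = FALSE)$target
  panel <- sab_panel(absent = absent, mode = "exclusion")
  patients <- as.character(sort(as.integer(unique(raw$patient_id))))
  if (length(patients) != 39L) {
    stop("fixture integrity: expected 39 patients, found ", length(patients),
         call. = FALSE)
  }
  for (i in seq_along(specs)) {
    pid <- specs[[i]]$sample_id
    if (is.null(donors_lr[[pid]])) {
      stop("fixture integrity: no LR donor typing for patient ", pid,
           call. = FALSE)
    }
    if (is.null(donors_hr[[pid]])) {
      stop("fixture integrity: no HR donor typing for patient ", pid,
           call. = FALSE)
    }
  }
  structure(list(specs = specs, donors_lr = donors_lr, donors_hr = donors_hr,
                 panel = panel, patients = patients),
            class = "dsa_fixture")
}

#' Load the synthetic eplet registry accompanying the fixture
#'
#' A small constructed registry consistent with the worked cohort's
#' non-shared-eplet annotations; it is not a real HLAMatchmaker registry
#' (those are versioned external data supplied by the user).
#'
#' @return An `eplet_registry`.
#' @export
load_table3_registry <- function() {
  read_eplet_registry(table3_path("eplets_synthetic.csv"))
}

#' Run the dual-resolution pipeline on the worked-cohort fixture
#'
#' Assigns both verdicts for every bead-group row, classifies the 39
#' patients and summarises concordance.
#'
#' @param fixture Optionally a pre-loaded [load_table3()] bundle.
#' @return List with `calls`, `classifications`, `summary`.
#' @export
run_table3_pipeline <- function(fixture = load_table3()) {
  calls <- assign_cohort(fixture$specs, fixture$donors_lr, fixture$donors_hr,
                         fixture$panel)
  cls <- classify_cohort(calls, patients = fixture$patients)
  list(calls = calls, classifications = cls,
       summary = summarize_cohort(cls, calls))
}
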