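---
title: "Dual-resolution donor-specific antibody assignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-resolution donor-specific antibody assignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hladsa)
```

## The problem

After kidney transplantation, circulating anti-HLA antibodies are screened
with single-antigen bead (SAB) assays, and an antibody is called a *de novo*
donor-specific antibody (dnDSA) when its target allele is carried by the
donor. The verdict therefore depends entirely on how well the donor's HLA
type is known. In routine practice the donor is typed at one-field
("low-resolution", LR) level at HLA-A, -B and -DRB1 only; when antibodies
against HLA-C or -DQ appear, the missing loci are *estimated* from
population haplotype frequencies. High-resolution (HR) typing instead gives
two-field alleles at six loci (A, B, C, DRB1, DQA1/DQB1, DPB1), resolves
DQ/DP alpha chains, and exposes donor alleles that the bead panel does not
carry.

`hladsa` implements both views side by side: it calls bead positivity,
assigns every antibody specificity a verdict under the LR view and under the
HR view, classifies patients into the four concordance groups
(LR+/HR+, LR+/HR−, LR−/HR+, negative), computes antigen- and eplet-level
donor/recipient mismatch under both views, and compares immune-mediated
outcomes (antibody-mediated rejection, death-censored graft loss) across
groups.

## Assignment rules

**LR mode.** For specificities at A, B or DRB1 the donor is known at
allele-group level, so the verdict is an antigen-level (first-field) match;
serologic splits and broads are not modelled because every verdict in the
bundled worked cohort is consistent with plain first-field equality. For C
and DQB1 the donor's alleles are two-field *imputed* values, and the
comparison is exact two-field equality — a deliberately strict rule: an
estimated DQB1\*04:02 does not support an anti-DQB1\*03:01 antibody. DQ
alpha chains, DP and DRB3/4/5 are invisible to the LR view; specificities
there are `unclassifiable_typing`.

**HR mode.** Class I and DRB specificities are donor-specific when any
reactive allele equals a donor allele at two fields. DQ and DP antigens are
alpha/beta heterodimers; because donor typing is unphased, matching is
chain-level: some reactive beta must equal a donor beta *and*, when both
sides carry alpha information, some reactive alpha must equal a donor alpha.
A beta match with an alpha mismatch is **not** donor-specific — this is the
single most common reason a presumed DQ DSA dissolves under complete typing.
When the donor's alpha locus is untyped (common for DP, where donors are
reported beta-only), the beta match alone decides; we chose this permissive
rule over raising an error because reported DP confirmations in practice are
beta-level.

**Panel awareness.** If no reactive allele matches the donor but one of the
donor's molecules at that locus is absent from the SAB panel, the verdict is
`unassessable_panel` rather than `not_DSA`: the assay never probed the
molecule that could have bound. For patient and group counts,
`unassessable_panel` and `unclassifiable_typing` aggregate with `not_DSA` —
a patient is HR_dnDSA+ only on positive evidence. The panel object supports
an inclusion mode (every bead listed; used for simulated assays) and an
exclusion mode (targets reported "not available" listed; how gaps surface in
practice, and how the bundled cohort encodes them).

**The specificity unit** is one bead-group row: one target molecule, with
alpha-chain variants folded into a single specificity and multi-allele
class I reactivities kept as one row. Published specificity tallies can
differ by ±1 from any fixed convention because the grouping of one
multi-allele class I row and one mixed DQ row is ambiguous; patient-level
counts are convention-independent.

## Positivity rule

A bead is positive when its normalised MFI exceeds 500 **and** the ratio to
the lowest bead exceeds 5. The denominator's scope is not standardised; we
default to the lowest-MFI bead of the same sample and class, with a
panel-wide option. A zero lowest bead makes every ratio infinite, so only
the absolute cutoff then discriminates; this is documented rather than
special-cased. The rule is monotone in each bead's own MFI, and raising the
lowest bead can only shrink the positive set among the other beads — both
properties are enforced by tests.

## Haplotype-frequency imputation

Untyped loci are expanded by enumerating all unordered haplotype pairs from
a user-supplied frequency table whose union reproduces the observed genotype
at the observed resolution (a one-field observation matches any two-field
table allele of its group). The imputed typing is the maximum-weight pair —
a point estimate, matching the single-allele "estimated typing" a clinician
records — with weights `f(h1)·f(h2)`, doubled for heterozygous pairs. Ties
break lexicographically on the serialised pair, for determinism; the best
pair's normalised probability is reported so callers can flag low-confidence
(< 0.5) expansions. No reference table is bundled: frequency tables are
versioned, licensed external data, and the worked cohort carries its printed
estimated typings as literal inputs instead.

## Mismatch counting

Antigen mismatch is donor-against-recipient: at LR, allele-group differences
at A/B/DRB1 (0–6); at HR, two-field differences at A, B, C, DRB1 and DPB1
plus DQ counted as one combined locus unit whose donor antigens are
beta/alpha chain pairs (0–12 globally). A donor DQ unit mismatches when its
beta *or* alpha is absent from the recipient; chain pairs follow the order
listed in the typing table, since typing is unphased. Homozygous loci
contribute each distinct antigen once. Whether published class II means
counted DQA1 and DQB1 separately cannot be settled without raw data; the
0–12 global scale motivates the single-unit choice, recorded here as an
assumption.

Eplet mismatch is HLAMatchmaker-style set algebra: the union of donor-allele
eplets minus the union over all recipient alleles of the scope
(genotype-level, never allele-pairwise), with antibody-verified eplets
counted separately. Multi-locus scopes pool eplets with interlocus
deduplication by name (a toggle reverts to per-locus sums). The registry is
an input table; the bundled registry is synthetic (the filename says so),
constructed only to satisfy the worked cohort's non-shared-eplet
annotations, because real registries are versioned external data. The
`nonshared_eplets()` view — eplets on the antibody-reactive molecule absent
from both the actual donor molecule and the recipient — is the package's
explanation of why an LR-presumed DSA is HR-negative; two worked-cohort
comparisons legitimately return "none", meaning the registry cannot
distinguish the molecules.

## Outcome comparisons

Kaplan–Meier curves, global and pairwise log-rank tests, and Cox /
logistic models are computed with the `survival` package and `stats::glm`;
this module's own content is the comparison plan. Ties use the Efron
approximation (the choice is stated and fixed; results at this cohort size
are insensitive to it). Significance is two-tailed at 0.05. Exposure
encodings that are collinear by construction (any-LR-DSA versus the
HR-confirmed subgroup) are fitted in independent models. Degenerate strata —
an exposure level with zero events, complete separation, non-convergence —
are returned as NA-flagged rows rather than errors, because "no graft losses
in this group" is a finding, not a failure.

## The synthetic cohort generator

The generator exists so every stage can be validated against known ground
truth. Its defaults are the emulated study conditions and are not revisited:
241 donor/recipient pairs; administrative censoring normal with mean 55 and
SD 15.6 months; a planted hazard multiplier of 4 on ABMR and graft-loss
hazards for patients carrying a true anti-donor antibody; immunization and
degradation rates calibrated once (by simulation, at development time) so
that the expected observed HR_dnDSA prevalence is ≈ 0.13, the LR_dnDSA+
proportion ≈ 0.15, and the expected false-call fraction among LR+ patients
≈ 0.20.

Subjects are two haplotypes drawn from a 20-haplotype pool of common
European A\~B\~C\~DRB1\~DQA1\~DQB1 combinations with plausible frequencies,
plus an independently drawn DPB1 pair (the DP region is only weakly linked
to the rest of the complex). HLA-identical donors are redrawn. The LR
clinical view reduces A/B/DRB1 to one field and *imputes* C/DQB1: with
probability ε per allele the imputed value is swapped for the most frequent
alternative at the locus — a realistic failure mode that keeps the LR view
internally consistent. The SAB panel contains every pool allele plus
bead-only same-group neighbours (real panels carry more alleles than any one
cohort), each target omitted with probability γ.

Immunization is per mismatched donor molecule: probability
`plogis(alpha + beta · EpMM)` with the eplet mismatch of that molecule's
scope, separate class I / class II intercepts, and a negative DP offset (DP
antigens are expressed at lower levels and immunize less often). An
immunized response is *faithful* (beads carry the donor molecule), or — with
probability δ — *divergent* (reactivity lands on a same-group neighbour or,
for DQ, on non-donor alpha pairings: the biological source of LR+/HR−
verdicts), or *off-panel* when the donor molecule's bead is absent. True
positive beads draw log-normal MFI with median ≈ 5000, background beads
median ≈ 100, so the positivity rule is exercised on both sides of each
threshold.

Three structural consequences, each covered by tests: the false-call
fraction among LR+ patients rises with γ and δ; the imputation error ε
converts confirmed DQ/C calls into LR−/HR+ *misses* (it removes patients
from numerator and denominator of the false-call fraction almost
proportionally, so its marginal effect on that fraction is nearly flat —
monotonicity is therefore asserted over jointly increasing (ε, γ)
settings); and with ε = γ = δ = 0 every LR+ patient is HR-confirmed.

True-DSA status for outcome hazards includes off-panel responses (the
antibody is biologically anti-donor even when the assay cannot show it), so
the observed-group hazard ratio is very slightly attenuated relative to the
planted multiplier — visible in recovery experiments as a median estimate a
few percent below the planted value, and a realistic feature of
misclassified exposure.

**What the generator does not emulate:** realistic linkage beyond the
supplied pool, center effects, time-varying antibody appearance, MFI
titration behaviour, preformed-DSA exclusion dynamics, and Banff histology.
Passing recovery tests shows the pipeline's logic and the statistical plan
are sound under the planted mechanism; it does not validate clinical
performance on real sera.

## Problem sizes and numerical choices

The bundled worked cohort (39 patients, 59 bead-group rows) runs in well
under a second and is byte-deterministic. Property tests use cohorts of
60–150 pairs with a handful of replicates; recovery experiments use 200
replicates at the full 241 pairs, which completes in a few minutes on one
core. Frequencies in haplotype tables must be positive and sum to at most
1 + 1e-6; normalised pair probabilities sum to 1 within 1e-9; imputation
tie-breaks are lexicographic; Cox/logistic coefficients with |log effect| >
15 or SE > 100 are reported as NA-flagged (monotone likelihood).

## A worked example

```{r example, eval = FALSE}
library(hladsa)

# the bundled worked cohort
pipe <- run_table3_pipeline()
pipe$summary

# a synthetic cohort with ground truth
cohort <- generate_cohort(sim_config(), seed = 7)
sim <- run_simulated_pipeline(cohort)
sim$summary

# outcome comparison on the simulated records
rec <- sim$records
rec$hr_pos <- as.integer(rec$hr_dnDSA)
cox_models(rec, "graft_loss", "hr_pos")
```

## Known limitations

Nomenclature stops at two fields: third/fourth fields, expression suffixes
and G/P groups are out of scope, as are serologic equivalence tables.
The imputation module is a generic maximum-probability expansion over
user-supplied tables, not a reimplementation of any specific clinical
service. Specificity-level tallies depend on a stated row-grouping
convention (±1). The bundled eplet registry is synthetic and must not be
used for clinical eplet analysis.
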