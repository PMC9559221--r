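test_that("registry lookup returns the registered set and errors otherwise", {
  reg <- load_table3_registry()
  expect_true("19K" %in% eplet_set("A*11:01", reg))
  expect_error(eplet_set("B*99:99", reg), "not in registry")
  expect_error(eplet_registry(data.frame(allele = "A*11", eplet = "x",
                                         abv = 0)), "two-field")
  expect_error(eplet_registry(data.frame(allele = c("A*11:01", "A*11:02"),
                                         eplet = c("q", "q"), abv = c(0, 1))),
               "conflicting")
})

test_that("forced set algebra: donor {e1,e2,e3} vs recipient {e2}", {
  reg <- eplet_registry(data.frame(
    allele = c("A*01:01", "A*01:01", "A*01:01", "A*02:01"),
    eplet = c("e1", "e2", "e3", "e2"),
    abv = c(1, 0, 0, 0)))
  res <- mismatched_eplets("A*01:01", "A*02:01", reg, scope = "test")
  expect_setequal(res$eplets, c("e1", "e3"))
  expect_equal(res$count, 2)
  expect_equal(res$abv_count, 1)
  expect_equal(res$abv_eplets, "e1")
  # identity gives the empty set
  same <- mismatched_eplets("A*01:01", "A*01:01", reg)
  expect_equal(same$count, 0)
  expect_lte(same$abv_count, same$count)
})

test_that("mismatch equals the brute-force set-difference oracle on 50
           random registries", {
  set.seed(11)
  vocab <- c("A*01:01", "A*02:01", "B*07:02", "B*08:01", "C*04:01", "C*07:01")
  for (i in 1:50) {
    rr <- random_registry(vocab)
    d <- sample(vocab, sample(1:3, 1))
    r <- sample(vocab, sample(1:3, 1))
    got <- mismatched_eplets(d, r, rr$registry)
    donor_ep <- unique(rr$rows$eplet[rr$rows$allele %in% d])
    recip_ep <- unique(rr$rows$eplet[rr$rows$allele %in% r])
    want <- setdiff(donor_ep, recip_ep)
    expect_setequal(got$eplets, want)
    expect_equal(got$count, length(want))
    want_abv <- want[want %in% rr$rows$eplet[rr$rows$abv == 1]]
    expect_equal(got$abv_count, length(want_abv))
  }
})

test_that("non-shared eplets reproduce the worked-cohort annotations", {
  reg <- load_table3_registry()
  ns <- function(presumed, actual) nonshared_eplets(presumed, actual,
                                                    registry = reg)
  r <- ns("A*11:01", "A*11:02")
  expect_equal(r$eplet, "19K"); expect_false(r$abv)
  r <- ns("DRB1*11:03", "DRB1*11:04")
  expect_equal(r$eplet, "71E"); expect_false(r$abv)
  r <- ns(c("DQB1*03:03", "DQA1*04:01"), c("DQB1*03:03", "DQA1*03:02"))
  expect_setequal(r$eplet, c("40GR", "69T", "76L"))
  expect_equal(sort(r$eplet[r$abv]), "40GR")
  r <- ns("A*02:05", c("A*02:01", "A*02:13"))
  expect_equal(r$eplet, "43R"); expect_false(r$abv)
  r <- ns(c("DQB1*02:01", "DQA1*02:01"), c("DQB1*02:01", "DQA1*05:01"))
  expect_equal(r$eplet, "47KHL"); expect_true(r$abv)
  r <- ns("B*15:12", "B*15:17")
  expect_equal(r$eplet, "156WA"); expect_false(r$abv)
  # the two "none" cases: every reactive eplet is shared
  expect_equal(nrow(ns("B*35:08", "B*35:01")), 0L)
  expect_equal(nrow(ns("A*29:01", "A*29:02")), 0L)
  # identical molecules trivially share everything
  expect_equal(nrow(ns("A*11:01", "A*11:01")), 0L)
})

test_that("recipient broadening monotonically shrinks mismatch, and class II
           union is bounded by the per-locus sum", {
  alleles <- sim_registry_alleles(sim_config())
  reg <- synthetic_eplet_registry(alleles)
  set.seed(5)
  pool <- default_haplotype_pool()
  for (i in 1:15) {
    h <- sample(nrow(pool), 4, replace = TRUE)
    donor <- c(pool$DRB1[h[1:2]], pool$DQB1[h[1:2]], pool$DQA1[h[1:2]])
    recip <- c(pool$DRB1[h[3]], pool$DQB1[h[3]], pool$DQA1[h[3]])
    base <- mismatched_eplets(donor, recip, reg)
    wider <- mismatched_eplets(donor, c(recip, pool$DRB1[h[4]],
                                        pool$DQB1[h[4]], pool$DQA1[h[4]]), reg)
    expect_lte(wider$count, base$count)
    expect_lte(wider$abv_count, base$abv_count)
    # union over loci can only deduplicate relative to per-locus sums
    per_locus_sum <-
      mismatched_eplets(pool$DRB1[h[1:2]], pool$DRB1[h[3]], reg)$count +
      mismatched_eplets(c(pool$DQB1[h[1:2]], pool$DQA1[h[1:2]]),
                        c(pool$DQB1[h[3]], pool$DQA1[h[3]]), reg)$count
    expect_lte(base$count, per_locus_sum)
  }
})

test_that("profiles: identical pairs are all-zero; exact imputation matches
           direct typing; DQ/DP scopes weaken the LR/HR correlation", {
  cfg <- sim_config()
  reg <- synthetic_eplet_registry(sim_registry_alleles(cfg))
  pool <- default_haplotype_pool()
  mk <- function(h, id) {
    loci <- lapply(c("A", "B", "C", "DRB1", "DQA1", "DQB1"), function(l)
      list(alleles = unique(pool[[l]][h]), provenance = "typed"))
    names(loci) <- c("A", "B", "C", "DRB1", "DQA1", "DQB1")
    loci$DPB1 <- list(alleles = "DPB1*04:01", provenance = "typed")
    hla_genotype(id, loci)
  }
  g <- mk(c(1, 2), "x")
  prof <- epmm_profile(g, g, reg, mode = "HR")
  expect_true(all(vapply(prof, `[[`, numeric(1), "count") == 0))

  # a correctly imputed expansion equals direct typing over the same scopes:
  # haplotypes 1 and 2 are uniquely identified by their A/B/DRB1 alleles, so
  # imputing DQB1 from the pool recovers the true donor genotype exactly
  d_true <- mk(c(1, 2), "d")
  observed <- hla_genotype("d", list(
    A = list(alleles = gt_alleles(d_true, "A"), provenance = "typed"),
    B = list(alleles = gt_alleles(d_true, "B"), provenance = "typed"),
    DRB1 = list(alleles = gt_alleles(d_true, "DRB1"), provenance = "typed"),
    DQB1 = list(alleles = character(), provenance = "unavailable")))
  imp <- impute_loci(observed, pool, "DQB1")
  expect_equal(imp$probability, 1)
  d_imp <- imp$genotype
  r2 <- mk(c(4, 8), "r")
  p_imp <- epmm_profile(r2, d_imp, reg, mode = "LR_imputed")
  p_true <- epmm_profile(r2, d_true, reg, mode = "LR_imputed")
  expect_equal(lapply(p_imp, `[[`, "count"), lapply(p_true, `[[`, "count"))

  # Spearman correlation between the clinical-view class II profile and the
  # complete profile drops when DQ alpha / DP enter the complete scope
  set.seed(9)
  lr_cii <- hr_sub <- hr_full <- numeric(60)
  dp <- default_dp_frequencies()
  for (i in 1:60) {
    hd <- sample(nrow(pool), 2, TRUE, prob = pool$freq)
    hr <- sample(nrow(pool), 2, TRUE, prob = pool$freq)
    d <- mk(hd, "d"); r <- mk(hr, "r")
    d$loci$DPB1$alleles <- unique(sample(dp$allele, 2, TRUE, prob = dp$freq))
    r$loci$DPB1$alleles <- unique(sample(dp$allele, 2, TRUE, prob = dp$freq))
    lr_cii[i] <- epmm_profile(r, d, reg, mode = "LR_imputed")$class_ii$count
    hr_full[i] <- epmm_profile(r, d, reg, mode = "HR")$class_ii$count
    hr_sub[i] <- mismatched_eplets(
      c(gt_alleles(d, "DRB1"), gt_alleles(d, "DQB1")),
      c(gt_alleles(r, "DRB1"), gt_alleles(r, "DQB1")), reg)$count
  }
  cor_sub <- stats::cor(lr_cii, hr_sub, method = "spearman")
  cor_full <- stats::cor(lr_cii, hr_full, method = "spearman")
  expect_lt(cor_full, cor_sub)
})

test_that("the interlocus dedup toggle only matters when loci share eplets", {
  reg_shared <- eplet_registry(data.frame(
    allele = c("DRB1*03:01", "DQB1*02:01", "DRB1*15:01", "DQB1*06:02"),
    eplet = c("shared1", "shared1", "priv1", "priv2"),
    abv = 0))
  d <- hla_genotype("d", list(
    DRB1 = list(alleles = "DRB1*03:01", provenance = "typed"),
    DQB1 = list(alleles = "DQB1*02:01", provenance = "typed")))
  r <- hla_genotype("r", list(
    DRB1 = list(alleles = "DRB1*15:01", provenance = "typed"),
    DQB1 = list(alleles = "DQB1*06:02", provenance = "typed")))
  pooled <- epmm_profile(r, d, reg_shared, mode = "LR_imputed",
                         interlocus_dedupe = TRUE)$class_ii$count
  summed <- epmm_profile(r, d, reg_shared, mode = "LR_imputed",
                         interlocus_dedupe = FALSE)$class_ii$count
  expect_equal(pooled, 1)  # shared1 counted once
  expect_equal(summed, 2)  # counted per locus
})
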