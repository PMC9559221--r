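test_that("every worked-cohort row receives the printed verdict", {
  fixture <- load_table3()
  calls <- run_table3_pipeline(fixture)$calls
  expected <- expected_table3_verdicts()
  expect_equal(nrow(calls), 2L * nrow(expected))
  for (k in seq_len(nrow(expected))) {
    sid <- expected$spec_id[k]
    lr <- calls$verdict[calls$spec_id == sid & calls$mode == "LR"]
    hr <- calls$verdict[calls$spec_id == sid & calls$mode == "HR"]
    expect_equal(lr, expected$lr[k], info = paste("LR row", sid))
    expect_equal(hr, expected$hr[k], info = paste("HR row", sid))
  }
})

test_that("single-specificity assignment reproduces the canonical cases", {
  # antigen-level LR call against one-field donor typing
  spec_a11 <- specificity("p", "A*11:01")
  donor_lr <- hla_genotype("p", list(A = list(alleles = "A*11",
                                              provenance = "typed")))
  expect_equal(assign_lr(spec_a11, donor_lr)$verdict, "DSA")

  # DP antibodies cannot be classified from the LR view
  spec_dp <- specificity("p", "DPB1*04:02", c("DPA1*01:03", "DPA1*03:01"))
  expect_equal(assign_lr(spec_dp, donor_lr)$verdict, "unclassifiable_typing")

  # imputed DQ uses exact two-field comparison
  spec_dq <- specificity("p", "DQB1*03:01",
                         c("DQA1*03:02", "DQA1*05:01", "DQA1*06:01"))
  donor_imp <- hla_genotype("p", list(
    DQB1 = list(alleles = c("DQB1*04:02", "DQB1*06:03"),
                provenance = "imputed")))
  expect_equal(assign_lr(spec_dq, donor_imp)$verdict, "not_DSA")

  panel <- sab_panel(mode = "exclusion")
  # alpha-chain mismatch blocks a beta-chain match at HR
  spec_dq33 <- specificity("p", "DQB1*03:03", "DQA1*04:01")
  donor_hr <- hla_genotype("p", list(
    DQB1 = list(alleles = "DQB1*03:03", provenance = "typed"),
    DQA1 = list(alleles = "DQA1*03:02", provenance = "typed")))
  call <- assign_hr(spec_dq33, donor_hr, panel)
  expect_equal(call$verdict, "not_DSA")
  expect_match(call$reason, "alpha")

  # off-panel donor allele makes a non-matching specificity unassessable
  spec_b35 <- specificity("p", c("B*35:01", "B*35:08"))
  donor_b <- hla_genotype("p", list(B = list(alleles = "B*35:02",
                                             provenance = "typed")))
  gap <- sab_panel(absent = "B*35:02", mode = "exclusion")
  expect_equal(assign_hr(spec_b35, donor_b, gap)$verdict, "unassessable_panel")
  expect_equal(assign_hr(spec_b35, donor_b, panel)$verdict, "not_DSA")

  # chain-level DQ match: any reactive alpha equal to any donor alpha
  spec_dq32 <- specificity("p", "DQB1*03:02",
                           c("DQA1*02:01", "DQA1*03:01", "DQA1*03:02"))
  donor_dq <- hla_genotype("p", list(
    DQB1 = list(alleles = "DQB1*03:02", provenance = "typed"),
    DQA1 = list(alleles = "DQA1*03:01", provenance = "typed")))
  expect_equal(assign_hr(spec_dq32, donor_dq, panel)$verdict, "DSA")

  # missing donor typing at the locus is an error, not a silent verdict
  expect_error(assign_hr(spec_b35, donor_hr, panel), "no HR typing")
})

test_that("patient classification flags and groups are consistent", {
  fixture <- load_table3()
  pipe <- run_table3_pipeline(fixture)
  cl <- pipe$classifications
  expect_equal(nrow(cl), 39L)
  expect_true(all(cl$group %in% c("LRpos_HRpos", "LRpos_HRneg",
                                  "LRneg_HRpos", "neg")))
  expect_equal(cl$group == "LRpos_HRpos", cl$lr_dnDSA & cl$hr_dnDSA)
  expect_equal(cl$group == "LRpos_HRneg", cl$lr_dnDSA & !cl$hr_dnDSA)
  expect_true(all(cl$hr_class_i | cl$hr_class_ii | !cl$hr_dnDSA))
  # zero-specificity patients classify as neg
  empty <- classify_cohort(pipe$calls[0, ], patients = c("x", "y"))
  expect_equal(empty$group, c("neg", "neg"))
  s <- summarize_cohort(empty, pipe$calls[0, ])
  expect_equal(s$patients$lr_pos, 0)
  expect_equal(s$specificities$lr_identified, 0)
})

test_that("with no degradation, LR-positive patients are always HR-confirmed", {
  cfg <- sim_config(n_pairs = 100, imputation_error = 0, panel_gap = 0,
                    divergence = 0)
  for (seed in c(21, 22)) {
    pipe <- run_simulated_pipeline(generate_cohort(cfg, seed = seed))
    expect_equal(pipe$summary$patients$lr_pos_hr_neg, 0, info = seed)
  }
})

test_that("the LR false-call fraction rises with imputation error and panel
           gaps, and LR misses rise with imputation error", {
  settings <- list(c(eps = 0, gap = 0), c(eps = 0.3, gap = 0.10),
                   c(eps = 0.7, gap = 0.30))
  frac <- numeric(3)
  for (s in seq_along(settings)) {
    lr_pos <- 0; lr_hr_neg <- 0
    for (rep in 1:6) {
      cfg <- sim_config(n_pairs = 150, imputation_error = settings[[s]]["eps"],
                        panel_gap = settings[[s]]["gap"])
      pipe <- run_simulated_pipeline(generate_cohort(cfg, seed = 400 + rep))
      lr_pos <- lr_pos + pipe$summary$patients$lr_pos
      lr_hr_neg <- lr_hr_neg + pipe$summary$patients$lr_pos_hr_neg
    }
    frac[s] <- lr_hr_neg / lr_pos
  }
  expect_lt(frac[1], frac[2])
  expect_lt(frac[2], frac[3])

  # imputation error alone converts confirmed calls into LR misses
  miss <- numeric(2)
  eps_settings <- c(0, 0.6)
  for (s in seq_along(eps_settings)) {
    lr_neg_hr_pos <- 0
    for (rep in 1:6) {
      cfg <- sim_config(n_pairs = 150, imputation_error = eps_settings[s])
      pipe <- run_simulated_pipeline(generate_cohort(cfg, seed = 500 + rep))
      lr_neg_hr_pos <- lr_neg_hr_pos + pipe$summary$patients$lr_neg_hr_pos
    }
    miss[s] <- lr_neg_hr_pos
  }
  expect_lt(miss[1], miss[2])
})
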