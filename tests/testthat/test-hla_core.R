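test_that("allele parsing, serialisation and reduction behave as specified", {
  a <- parse_allele("A*11:01")
  expect_equal(a$locus, "A")
  expect_equal(a$field1, 11L)
  expect_equal(a$field2, 1L)
  expect_equal(format(a), "A*11:01")
  expect_equal(format(parse_allele(format(a))), "A*11:01")  # round trip

  b <- parse_allele("DRB1*11")
  expect_equal(b$locus, "DRB1")
  expect_null(b$field2)
  expect_false(is_two_field(b))

  expect_equal(reduce_to_one_field("A*11:02"), "A*11")
  expect_equal(reduce_to_one_field("B*44:03"), "B*44")
  expect_equal(reduce_to_one_field("A*11"), "A*11")  # idempotent
  expect_equal(reduce_to_one_field(reduce_to_one_field("A*11:02")), "A*11")

  expect_error(parse_allele("A11:01"), "malformed")
  expect_error(parse_allele("ZZ*01:01"), "unknown HLA locus")
  expect_error(parse_allele("A*0x:01"), "malformed")
})

test_that("antigen and allele matching predicates are correct", {
  expect_true(antigen_match("A*11:01", "A*11"))
  expect_true(antigen_match("B*15:12", "B*15"))
  expect_false(antigen_match("A*11:01", "B*11"))

  expect_false(allele_match("A*11:01", "A*11:02"))
  expect_true(allele_match("C*05:01", "C*05:01"))
  expect_true(allele_match("A*11:01", "A*11:01"))
  expect_error(allele_match("A*11", "A*11:01"), "two-field")
})

test_that("genotypes enforce locus identity, homozygosity and availability", {
  g <- gt("R1", A = c("A*01:01", "A*01:01"))
  expect_equal(gt_alleles(g, "A"), "A*01:01")  # homozygote stored once
  expect_error(hla_genotype("x", list(A = list(alleles = "B*07:02",
                                               provenance = "typed"))),
               "do not belong")
  expect_error(hla_genotype("x", list(A = list(alleles = "A*01:01",
                                               provenance = "unavailable"))),
               "unavailable")
  empty <- hla_genotype("x", list(DPB1 = list(alleles = character(),
                                              provenance = "unavailable")))
  expect_equal(gt_alleles(empty, "DPB1"), character())
  expect_equal(gt_provenance(empty, "A"), "unavailable")
})

test_that("mismatch counts: identity is zero and the disjoint pair saturates", {
  r <- gt("R", A = c("A*01:01", "A*02:01"), B = c("B*07:02", "B*08:01"),
          C = c("C*07:01", "C*07:02"), DRB1 = c("DRB1*03:01", "DRB1*15:01"),
          DQA1 = c("DQA1*05:01", "DQA1*01:02"),
          DQB1 = c("DQB1*02:01", "DQB1*06:02"),
          DPB1 = c("DPB1*04:01", "DPB1*02:01"))
  same <- count_antigen_mm(r, r, "HR6")
  expect_equal(same$global, 0)
  expect_equal(count_antigen_mm(r, r, "LR3")$global, 0)

  d <- gt("D", A = c("A*03:01", "A*11:01"), B = c("B*35:01", "B*44:02"),
          C = c("C*04:01", "C*05:01"), DRB1 = c("DRB1*07:01", "DRB1*04:01"),
          DQA1 = c("DQA1*03:01", "DQA1*02:01"),
          DQB1 = c("DQB1*03:02", "DQB1*02:02"),
          DPB1 = c("DPB1*03:01", "DPB1*01:01"))
  full <- count_antigen_mm(r, d, "HR6")
  expect_equal(full$class_i, 6)
  expect_equal(full$class_ii, 6)
  expect_equal(full$global, 12)
  expect_equal(count_antigen_mm(r, d, "LR3")$global, 6)

  r_nolocus <- gt("R2", A = c("A*01:01"), B = c("B*07:02"),
                  DRB1 = c("DRB1*03:01"))
  expect_error(count_antigen_mm(r_nolocus, d, "HR6"), "locus C")
})

test_that("mismatch counts equal the brute-force set-difference oracle", {
  set.seed(42)
  for (i in 1:20) {
    r <- random_hr_genotype("R")
    d <- random_hr_genotype("D")
    for (mode in c("LR3", "HR6")) {
      got <- count_antigen_mm(r, d, mode)
      want <- oracle_antigen_mm(r, d, mode)
      expect_equal(got$class_i, want$class_i, info = paste(mode, i))
      expect_equal(got$class_ii, want$class_ii, info = paste(mode, i))
      expect_equal(got$global, want$global, info = paste(mode, i))
    }
  }
})

test_that("LR3 counts never exceed HR6 counts on refining pairs, and adding a
           recipient allele never increases any count", {
  set.seed(99)
  for (i in 1:20) {
    r <- random_hr_genotype("R")
    d <- random_hr_genotype("D")
    expect_lte(count_antigen_mm(r, d, "LR3")$global,
               count_antigen_mm(r, d, "HR6")$global)

    # widen the recipient at a locus where it is homozygous
    for (locus in c("A", "B", "DRB1")) {
      if (length(gt_alleles(r, locus)) == 1L) {
        extra <- setdiff(gt_alleles(d, locus), gt_alleles(r, locus))
        if (!length(extra)) next
        r2 <- r
        r2$loci[[locus]]$alleles <- c(gt_alleles(r, locus), extra[1])
        for (mode in c("LR3", "HR6")) {
          expect_lte(count_antigen_mm(r2, d, mode)$global,
                     count_antigen_mm(r, d, mode)$global)
        }
        break
      }
    }
  }
})

test_that("typing tables round-trip through write_typing/read_typing", {
  g1 <- gt("S1", A = c("A*01:01", "A*02:01"), DQB1 = "DQB1*03:01")
  g2 <- hla_genotype("S2", list(
    B = list(alleles = "B*07:02", provenance = "imputed"),
    DPB1 = list(alleles = character(), provenance = "unavailable")))
  path <- tempfile(fileext = ".tsv")
  write_typing(list(g1, g2), path)
  back <- read_typing(path)
  expect_equal(gt_alleles(back$S1, "A"), c("A*01:01", "A*02:01"))
  expect_equal(gt_provenance(back$S2, "B"), "imputed")
  expect_equal(gt_provenance(back$S2, "DPB1"), "unavailable")
})
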