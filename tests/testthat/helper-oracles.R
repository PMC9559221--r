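# Shared helpers: small genotype builders and independent brute-force
# oracles used to cross-check the package implementations.

gt <- function(subject, ..., prov = "typed") {
  args <- list(...)
  loci <- lapply(args, function(a) list(alleles = a, provenance = prov))
  hla_genotype(subject, loci)
}

# Independent oracle for antigen mismatch counting: explicit per-locus set
# difference, with its own DQ-unit pairing.
oracle_antigen_mm <- function(recipient, donor, mode) {
  one_field <- function(x) sub(":[0-9]+$", "", x)
  if (mode == "LR3") {
    per <- sapply(c("A", "B", "DRB1"), function(l) {
      d <- unique(one_field(gt_alleles(donor, l)))
      r <- unique(one_field(gt_alleles(recipient, l)))
      sum(!d %in% r)
    })
    return(list(class_i = sum(per[c("A", "B")]), class_ii = per[["DRB1"]],
                global = sum(per)))
  }
  per <- sapply(c("A", "B", "C", "DRB1", "DPB1"), function(l) {
    sum(!unique(gt_alleles(donor, l)) %in% gt_alleles(recipient, l))
  })
  db <- gt_alleles(donor, "DQB1"); da <- gt_alleles(donor, "DQA1")
  n <- max(length(db), length(da))
  units <- unique(cbind(db[pmin(seq_len(n), length(db))],
                        da[pmin(seq_len(n), length(da))]))
  dq <- sum(apply(units, 1, function(u) {
    !(u[1] %in% gt_alleles(recipient, "DQB1")) ||
      !(u[2] %in% gt_alleles(recipient, "DQA1"))
  }))
  list(class_i = sum(per[c("A", "B", "C")]),
       class_ii = sum(per[c("DRB1", "DPB1")]) + dq,
       global = sum(per) + dq)
}

# Random two-field genotype over a small allele vocabulary.
random_hr_genotype <- function(subject) {
  vocab <- list(
    A = c("A*01:01", "A*02:01", "A*03:01", "A*11:01"),
    B = c("B*07:02", "B*08:01", "B*35:01"),
    C = c("C*04:01", "C*07:01", "C*07:02"),
    DRB1 = c("DRB1*03:01", "DRB1*15:01", "DRB1*07:01"),
    DQA1 = c("DQA1*01:02", "DQA1*05:01", "DQA1*02:01"),
    DQB1 = c("DQB1*02:01", "DQB1*06:02", "DQB1*03:01"),
    DPB1 = c("DPB1*04:01", "DPB1*02:01"))
  loci <- lapply(vocab, function(v)
    list(alleles = unique(sample(v, 2, replace = TRUE)), provenance = "typed"))
  hla_genotype(subject, loci)
}

# Independent brute-force enumeration of compatible haplotype pairs.
oracle_enumerate_pairs <- function(table, observed_list) {
  n <- nrow(table)
  loci <- names(observed_list)
  matches <- function(obs, tab) {
    if (grepl(":", obs)) obs == tab
    else sub(":[0-9]+$", "", tab) == obs
  }
  out <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- all(vapply(loci, function(l) {
        obs <- observed_list[[l]]
        a1 <- table[[l]][i]; a2 <- table[[l]][j]
        if (length(obs) == 1) matches(obs, a1) && matches(obs, a2)
        else (matches(obs[1], a1) && matches(obs[2], a2)) ||
          (matches(obs[2], a1) && matches(obs[1], a2))
      }, logical(1)))
      if (ok) {
        out <- rbind(out, data.frame(
          h1 = i, h2 = j,
          weight = table$freq[i] * table$freq[j] * ifelse(i == j, 1, 2)))
      }
    }
  }
  out
}

# Small random eplet registry for set-algebra oracle checks.
random_registry <- function(alleles, n_eplets = 12) {
  eplets <- paste0("ep", seq_len(n_eplets))
  abv <- seq_len(n_eplets) %% 2
  rows <- do.call(rbind, lapply(alleles, function(a) {
    k <- sample(2:6, 1)
    idx <- sample(n_eplets, k)
    data.frame(allele = a, eplet = eplets[idx], abv = abv[idx])
  }))
  list(registry = eplet_registry(rows), rows = rows)
}
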