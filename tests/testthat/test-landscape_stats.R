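make_partition <- function(n_hr, n_ot) {
  data.frame(patient_id = c(sprintf("H%03d", seq_len(n_hr)),
                            sprintf("O%03d", seq_len(n_ot))),
             group = rep(c("HR", "OT"), c(n_hr, n_ot)),
             stringsAsFactors = FALSE)
}

variant_rows <- function(ids, gene, cls = "Missense_Mutation") {
  data.frame(patient_id = ids, gene = gene, protein_change = "A5V",
             variant_classification = cls, ea_score = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("gene frequencies are patient-level and conserve the partition", {
  part <- make_partition(10, 10)
  # one patient with two EGFR rows counts once
  va <- rbind(variant_rows(c("H001", "H001", "H002"), "EGFR"),
              variant_rows("O001", "EGFR"),
              variant_rows(c("H001", "O001", "O002"), "KRAS"))
  tab <- gene_frequency_compare(va, part, min_patients = 1)
  egfr <- tab[tab$gene == "EGFR", ]
  expect_equal(egfr$hr_mutated, 2L)
  expect_equal(egfr$ot_mutated, 1L)
  expect_equal(egfr$hr_total + egfr$ot_total, 20L)
  expect_true(all(tab$hr_freq >= 0 & tab$hr_freq <= 1))
  # a gene mutated in everyone is uninformative: p = 1
  va_all <- variant_rows(part$patient_id, "TTN")
  expect_equal(
    gene_frequency_compare(va_all, part, 1)$p_value[1], 1)
  # below the minimum count: reported but untested
  rare <- gene_frequency_compare(variant_rows("H001", "RARE1"), part, 3)
  expect_equal(rare$test[rare$gene == "RARE1"], "untested")
})

test_that("a constructed between-group difference is detected", {
  set.seed(97)
  part <- make_partition(100, 100)
  mut_hr <- part$patient_id[part$group == "HR"][rbinom(100, 1, 0.30) == 1]
  mut_ot <- part$patient_id[part$group == "OT"][rbinom(100, 1, 0.05) == 1]
  va <- variant_rows(c(mut_hr, mut_ot), "GENEA")
  tab <- gene_frequency_compare(va, part, 1)
  expect_lt(tab$p_value[tab$gene == "GENEA"], 0.05)
  expect_gt(tab$hr_freq[1], tab$ot_freq[1])
})

test_that("pathway aggregation uses OR semantics and dominates member genes", {
  part <- make_partition(6, 6)
  pm <- data.frame(pathway = c("PW", "PW"), gene = c("A", "B"),
                   stringsAsFactors = FALSE)
  va <- variant_rows("H001", "B")  # mutated only in B -> pathway-altered
  pw <- pathway_aggregate(va, part, pm)
  expect_equal(pw$hr_altered, 1L)
  # pathway frequency >= each member gene frequency, per group
  set.seed(13)
  va2 <- rbind(variant_rows(sample(part$patient_id, 5), "A"),
               variant_rows(sample(part$patient_id, 4), "B"))
  pw2 <- pathway_aggregate(va2, part, pm)
  g2 <- gene_frequency_compare(va2, part, 1)
  for (grp in c("hr_freq", "ot_freq")) {
    expect_true(all(pw2[[grp]] >= g2[[grp]] - 1e-12))
  }
  # pathway with no genes in the cohort: empty and untested
  pm3 <- data.frame(pathway = "EMPTY", gene = "ZZZ9")
  expect_equal(pathway_aggregate(va2, part, pm3)$test, "untested")
})

test_that("DDR enrichment in the HR group reaches significance at n = 200", {
  set.seed(29)
  part <- make_partition(100, 100)
  pm <- load_pathway_map()
  ddr_genes <- pm$gene[pm$pathway == "DDR"][1:4]
  rows <- lapply(ddr_genes, function(g) {
    hr_ids <- part$patient_id[part$group == "HR"][rbinom(100, 1, 0.12) == 1]
    ot_ids <- part$patient_id[part$group == "OT"][rbinom(100, 1, 0.03) == 1]
    variant_rows(c(hr_ids, ot_ids), g)
  })
  pw <- pathway_aggregate(do.call(rbind, rows), part, pm)
  ddr <- pw[pw$pathway == "DDR", ]
  expect_gt(ddr$hr_freq, ddr$ot_freq)
  expect_lt(ddr$p_value, 0.05)
})

test_that("TMB arithmetic and eligibility rule", {
  va <- variant_rows(rep("A", 10), "G1")
  tmb <- compute_tmb(va, "A", panel_mb = 1.0)
  expect_equal(tmb$tmb, 10.0)
  expect_equal(compute_tmb(va[0, ], "A", panel_mb = 1.0)$tmb, 0.0)
  # 9 eligible of 12 (3 silent) at 1.2 Mb -> 7.5 mut/Mb
  va2 <- rbind(variant_rows(rep("A", 9), "G1"),
               variant_rows(rep("A", 3), "G1", cls = "Silent"))
  expect_equal(compute_tmb(va2, "A", panel_mb = 1.2)$tmb, 7.5)
  expect_error(compute_tmb(va, "A", panel_mb = 0), "positive")
})

test_that("Mann-Whitney comparison matches exact enumeration", {
  part <- make_partition(3, 3)
  tmb <- data.frame(patient_id = part$patient_id,
                    tmb = c(1, 2, 3, 4, 5, 6))
  res <- tmb_compare(tmb, part)
  expect_equal(unname(res$u_statistic), 0)
  expect_equal(res$p_value, 0.1)   # 2/20 assignments as extreme
  expect_equal(res$method, "exact")

  set.seed(37)
  for (i in 1:8) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    vals <- sample(1000, nx + ny)  # distinct -> no ties
    p2 <- make_partition(nx, ny)
    tm <- data.frame(patient_id = p2$patient_id, tmb = vals)
    res2 <- tmb_compare(tm, p2)
    expect_equal(res2$p_value,
                 mw_enum_p(vals[seq_len(nx)], vals[nx + seq_len(ny)]),
                 tolerance = 1e-10)
  }
})

test_that("exact and normal-approximation paths agree for moderate n", {
  set.seed(43)
  for (i in 1:5) {
    x <- rnorm(15); y <- rnorm(15, 0.3)
    part <- make_partition(15, 15)
    tm <- data.frame(patient_id = part$patient_id, tmb = c(x, y))
    p_exact <- tmb_compare(tm, part)$p_value  # exact path at n = 15
    p_norm <- stats::wilcox.test(x, y, exact = FALSE,
                                 correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.011)
  }
})

test_that("identical groups give p = 1 and empty groups error", {
  part <- make_partition(3, 3)
  tm <- data.frame(patient_id = part$patient_id, tmb = c(1, 2, 3, 1, 2, 3))
  expect_equal(tmb_compare(tm, part)$p_value, 1)
  bad <- data.frame(patient_id = "Q1", tmb = 1)
  expect_error(tmb_compare(bad, part), "non-empty")
})
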