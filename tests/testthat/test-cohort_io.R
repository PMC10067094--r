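test_that("clinical table validation catches the contract violations", {
  cl <- make_clinical(c("A", "B"))
  path <- tempfile(fileext = ".tsv")
  write.table(cl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_clinical_table(path)), 2L)

  dup <- rbind(cl, cl[1, ])
  expect_error(read_clinical_table(dup), "duplicate patient_id")

  bad_os <- cl; bad_os$os_event[1] <- 1L  # event without a time
  expect_error(read_clinical_table(bad_os), "os_months/os_event")

  bad_met <- make_clinical("C", stage = "II")
  bad_met$multi_organ_met <- "yes"
  expect_error(read_clinical_table(bad_met), "multi_organ_met")

  odd <- cl; odd$sex[1] <- "M?"
  expect_warning(out <- read_clinical_table(odd), "unknown sex")
  expect_equal(out$sex[1], "unknown")
})

test_that("variant table io preserves rows and requires the id columns", {
  va <- data.frame(patient_id = "A", gene = "NOVELGENE1",
                   protein_change = "A5V", stringsAsFactors = FALSE)
  out <- read_variant_table(va)
  expect_equal(out$gene, "NOVELGENE1")  # unknown symbols accepted
  expect_true(all(c("variant_classification", "ea_score") %in% names(out)))
  expect_error(read_variant_table(data.frame(x = 1)), "missing column")
})

test_that("cohort filters apply in order and match a hand tally", {
  cl <- make_clinical(sprintf("P%02d", 1:20))
  cl$stage <- rep(c("II", "III", "IV", "unknown"), 5)
  cl$multi_organ_met <- ifelse(cl$stage == "IV", "no", "not_applicable")
  cl$ici_treated <- rep(c(TRUE, FALSE), 10)
  cl$os_months <- rep(c(10, NA), each = 10)
  cl$os_event <- rep(c(1L, NA), each = 10)

  res <- apply_cohort_filters(cl, TRUE, TRUE, TRUE)
  # hand tally: stage III/IV keeps 10; of those, ICI-naive; of those, OS
  s1 <- cl[cl$stage %in% c("III", "IV"), ]
  s2 <- s1[!s1$ici_treated, ]
  s3 <- s2[!is.na(s2$os_months), ]
  expect_equal(res$report$criterion,
               c("stage_iii_iv", "ici_naive", "os_available"))
  expect_equal(res$report$removed,
               c(nrow(cl) - nrow(s1), nrow(s1) - nrow(s2),
                 nrow(s2) - nrow(s3)))
  expect_equal(res$clinical$patient_id, s3$patient_id)

  # all filters off -> identity
  expect_equal(apply_cohort_filters(cl)$clinical, cl)
  expect_warning(
    apply_cohort_filters(make_clinical("X", stage = "I"), TRUE),
    "empty")
})

test_that("patient aggregation follows the precedence and OR semantics", {
  cl <- make_clinical(c("A", "B", "C", "D"))
  ann <- annotate_simple(
    c("E298X", "R282W", "X187_splice", "Y236C"),
    patient_id = c("A", "A", "B", "C"),
    ea_score = c(NA, 80, NA, 50))
  st <- aggregate_patient_tp53(cl, ann)
  a <- st[st$patient_id == "A", ]
  expect_equal(a$four_group, "EAp53 high-risk")  # high risk beats truncating
  expect_true(a$has_truncating && a$has_missense)
  expect_equal(st$four_group[st$patient_id == "B"], "truncating")
  expect_true(st$has_truncating[st$patient_id == "B"])  # splice-only
  expect_equal(st$four_group[st$patient_id == "C"], "EAp53 low-risk")
  expect_true(st$wild_type[st$patient_id == "D"])
  # four-group labels partition the cohort
  expect_true(all(st$four_group %in%
                    c("EAp53 high-risk", "EAp53 low-risk", "truncating",
                      "WT", "other")))
  expect_equal(sum(table(st$four_group)), nrow(cl))
})

test_that("aggregation is order-invariant and idempotent", {
  cl <- make_clinical(sprintf("P%02d", 1:12))
  set.seed(5)
  ann <- annotate_simple(
    sample(c("E298X", "R282W", "R249S", "R110L", "R213fs"), 30, TRUE),
    patient_id = sample(cl$patient_id, 30, TRUE),
    ea_score = round(runif(30, 0, 100), 1))
  st1 <- aggregate_patient_tp53(cl, ann)
  st2 <- aggregate_patient_tp53(cl, ann[sample(nrow(ann)), ])
  expect_equal(st1, st2)
  st3 <- aggregate_patient_tp53(cl, ann)
  expect_equal(st1, st3)
})

test_that("synonymous-only carriers stay wild-type", {
  cl <- make_clinical("A")
  ann <- annotate_simple("P72=", patient_id = "A")
  st <- aggregate_patient_tp53(cl, ann)
  expect_true(st$wild_type)
  expect_equal(st$four_group, "WT")
})

test_that("cohort summary reproduces printed percentages from printed counts", {
  fix <- make_printed_cohort()
  cl <- read_clinical_table(fix$clinical)
  va <- read_variant_table(fix$variants)
  res <- annotate_variant_file(va, refset)
  st <- aggregate_patient_tp53(cl, res$annotations)
  s <- summarize_cohort(cl, st, res$annotations)

  expect_equal(s$n, 210L)
  expect_equal(s$age[["median"]], 65)
  expect_equal(s$sex$pct[s$sex$category == "male"], 60.0)
  expect_equal(s$smoking$pct[s$smoking$category == "smoker"], 50.0)
  expect_equal(s$histology$pct[s$histology$category == "LUAD"], 77.1)
  expect_equal(s$stage$pct[s$stage$category == "IV"], 75.2)
  mo <- s$multi_organ_met_stage_iv
  expect_equal(mo$pct[mo$category == "yes"], 32.3)
  expect_equal(mo$pct[mo$category == "no"], 66.5)
  expect_equal(s$tp53$pct, 51.4)
  expect_equal(s$alterations$n_alterations, 125L)

  # percentage rows sum to 100 within rounding
  for (tab in list(s$sex, s$smoking, s$histology, s$stage, mo)) {
    expect_lt(abs(sum(tab$pct) - 100), 0.1 * nrow(tab) + 1e-9)
  }
})
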