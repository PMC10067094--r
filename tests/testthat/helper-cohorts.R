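# Programmatic fixtures shared across test files.

refset <- load_reference_set()

# A clinical cohort reproducing the printed characteristics table of the
# study population: 210 patients, 126 male, 105 smokers, 162/46/2
# LUAD/LUSC/ASC, stages 9/8/31/158/4, 51/105/2 multi-organ yes/no/unknown
# among stage IV, 108 TP53-mutant patients carrying 125 alterations.
make_printed_cohort <- function() {
  n <- 210L
  stage <- rep(c("I", "II", "III", "IV", "unknown"), c(9, 8, 31, 158, 4))
  mo <- rep("not_applicable", n)
  mo[stage == "IV"] <- rep(c("yes", "no", "unknown"), c(51, 105, 2))
  clinical <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_years = c(34L, 87L, rep(65L, n - 2L)),
    sex = rep(c("male", "female"), c(126, 84)),
    smoking = rep(c("smoker", "nonsmoker"), c(105, 105)),
    histology = rep(c("LUAD", "LUSC", "ASC"), c(162, 46, 2)),
    stage = stage, multi_organ_met = mo,
    egfr_status = rep(c("mutant", "wild_type"), c(95, 115)),
    os_months = NA_real_, os_event = NA_integer_, ici_treated = FALSE,
    stringsAsFactors = FALSE)
  # 125 TP53 alterations over 108 patients: patients 1..108 carry one,
  # patients 1..17 carry a second.
  carrier <- c(sprintf("P%03d", 1:108), sprintf("P%03d", 1:17))
  change <- c(rep("R282W", 86), rep("E298X", 39))
  variants <- data.frame(patient_id = carrier, gene = "TP53",
                         protein_change = change,
                         stringsAsFactors = FALSE)
  list(clinical = clinical, variants = variants)
}

annotate_simple <- function(changes, patient_id = NULL, ea_score = NULL,
                            classification = NULL) {
  p <- parse_hgvs_p(changes, classification)
  if (!is.null(patient_id)) p$patient_id <- patient_id
  annotate_variants(p, refset$model, refset$domains, refset$properties,
                    ea = refset$ea, ea_score = ea_score)
}

# Minimal valid clinical frame for io/aggregation tests.
make_clinical <- function(ids, stage = "IV", os_months = NA_real_,
                          os_event = NA_integer_, sex = "male",
                          smoking = "smoker", egfr = "wild_type",
                          age = 60L, ici = FALSE) {
  n <- length(ids)
  data.frame(patient_id = ids, age_years = rep_len(age, n),
             sex = rep_len(sex, n), smoking = rep_len(smoking, n),
             histology = "LUAD", stage = rep_len(stage, n),
             multi_organ_met = ifelse(rep_len(stage, n) == "IV", "no",
                                      "not_applicable"),
             egfr_status = rep_len(egfr, n),
             os_months = rep_len(os_months, n),
             os_event = rep_len(os_event, n),
             ici_treated = rep_len(ici, n), stringsAsFactors = FALSE)
}
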