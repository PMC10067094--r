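# Read and validate clinical and variant tables, apply the cohort filters
# (advanced stage, ICI-naive, OS available), and aggregate variant-level
# annotations to patient-level TP53 status.

CLINICAL_COLUMNS <- c("patient_id", "age_years", "sex", "smoking", "histology",
                      "stage", "multi_organ_met", "egfr_status", "os_months",
                      "os_event", "ici_treated")

norm_category <- function(x, allowed, var) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- "unknown"
  bad <- !x %in% c(allowed, "unknown")
  if (any(bad)) {
    warning("unknown ", var, " value(s) mapped to 'unknown': ",
            paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    x[bad] <- "unknown"
  }
  x
}

#' Read and validate a clinical table
#'
#' Tab-delimited, one row per patient, columns \code{patient_id},
#' \code{age_years}, \code{sex}, \code{smoking}, \code{histology},
#' \code{stage}, \code{multi_organ_met}, \code{egfr_status},
#' \code{os_months}, \code{os_event}, \code{ici_treated}.  Unknown category
#' values are mapped to \code{"unknown"} with a warning, never dropped.
#' Validation enforces unique patient ids, paired survival fields
#' (\code{os_event} present iff \code{os_months} present), and
#' \code{multi_organ_met != "not_applicable"} only for stage IV.
#'
#' @param path path to the clinical TSV, or a data.frame already in memory.
#' @return validated data.frame of clinical records.
#' @export
read_clinical_table <- function(path) {
  cl <- if (is.data.frame(path)) path
        else read_tsv_checked(path, "patient_id", "clinical table")
  miss <- setdiff(CLINICAL_COLUMNS, names(cl))
  if (length(miss)) {
    stop("parse error: clinical table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cl$patient_id <- as.character(cl$patient_id)
  if (anyDuplicated(cl$patient_id)) {
    stop("validation error: duplicate patient_id: ",
         cl$patient_id[duplicated(cl$patient_id)][1], call. = FALSE)
  }
  cl$sex <- norm_category(cl$sex, c("male", "female"), "sex")
  cl$smoking <- norm_category(cl$smoking, c("smoker", "nonsmoker"), "smoking")
  hist_raw <- toupper(trimws(as.character(cl$histology)))
  cl$histology <- ifelse(hist_raw %in% c("LUAD", "LUSC", "ASC"), hist_raw,
                         "other")
  stage_raw <- toupper(trimws(as.character(cl$stage)))
  stage_raw[is.na(cl$stage)] <- "unknown"
  cl$stage <- ifelse(stage_raw %in% c("I", "II", "III", "IV"), stage_raw,
                     "unknown")
  cl$multi_organ_met <- norm_category(cl$multi_organ_met,
                                      c("yes", "no", "not_applicable"),
                                      "multi_organ_met")
  cl$egfr_status <- norm_category(cl$egfr_status, c("mutant", "wild_type"),
                                  "egfr_status")
  cl$ici_treated <- as.logical(cl$ici_treated)
  cl$os_months <- as.numeric(cl$os_months)
  cl$os_event <- as.integer(cl$os_event)

  mismatch <- xor(is.na(cl$os_months), is.na(cl$os_event))
  if (any(mismatch)) {
    stop("validation error: os_months/os_event must be present together ",
         "(patient ", cl$patient_id[mismatch][1], ")", call. = FALSE)
  }
  if (any(!is.na(cl$os_months) & cl$os_months < 0)) {
    stop("validation error: negative os_months", call. = FALSE)
  }
  if (any(!is.na(cl$os_event) & !cl$os_event %in% c(0L, 1L))) {
    stop("validation error: os_event must be 0 or 1", call. = FALSE)
  }
  bad_met <- cl$stage != "IV" & cl$multi_organ_met != "not_applicable"
  if (any(bad_met)) {
    stop("validation error: multi_organ_met set for non-stage-IV patient ",
         cl$patient_id[bad_met][1], call. = FALSE)
  }
  cl
}

#' Read a variant table (MAF subset)
#'
#' Tab-delimited with mandatory columns \code{patient_id}, \code{gene},
#' \code{protein_change}; optional \code{variant_classification} and
#' \code{ea_score}.  Rows are preserved verbatim; no classification happens
#' here.
#'
#' @param path path to the variant TSV, or a data.frame.
#' @return data.frame of variant records.
#' @export
read_variant_table <- function(path) {
  va <- if (is.data.frame(path)) path
        else read_tsv_checked(path, character(), "variant table")
  if (is.data.frame(path) || nrow(va) > 0L || ncol(va) > 1L) {
    miss <- setdiff(c("patient_id", "gene", "protein_change"), names(va))
    if (length(miss)) {
      stop("parse error: variant table missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  if (!"variant_classification" %in% names(va)) {
    va$variant_classification <- NA_character_
  }
  if (!"ea_score" %in% names(va)) va$ea_score <- NA_real_
  va$patient_id <- as.character(va$patient_id)
  va$gene <- as.character(va$gene)
  va$protein_change <- as.character(va$protein_change)
  va$ea_score <- as.numeric(va$ea_score)
  va
}

#' Apply the cohort filters in the order stage, ICI, OS
#'
#' @param clinical validated clinical data.frame.
#' @param require_stage keep only stage III/IV patients.
#' @param require_ici_naive keep only patients never treated with immune
#'   checkpoint inhibitors.
#' @param require_os keep only patients with overall-survival data.
#' @return list with \code{clinical} (the filtered table) and \code{report}
#'   (data.frame: criterion, removed, remaining, in application order).
#' @export
apply_cohort_filters <- function(clinical, require_stage = FALSE,
                                 require_ici_naive = FALSE,
                                 require_os = FALSE) {
  steps <- list(
    stage_iii_iv = if (require_stage) function(d) d$stage %in% c("III", "IV"),
    ici_naive    = if (require_ici_naive) function(d) !isTRUE_vec(d$ici_treated),
    os_available = if (require_os) function(d) !is.na(d$os_months))
  report <- data.frame(criterion = character(), removed = integer(),
                       remaining = integer(), stringsAsFactors = FALSE)
  d <- clinical
  for (nm in names(steps)) {
    if (is.null(steps[[nm]])) next
    keep <- steps[[nm]](d)
    report <- rbind(report, data.frame(criterion = nm,
                                       removed = sum(!keep),
                                       remaining = sum(keep)))
    d <- d[keep, , drop = FALSE]
  }
  if (nrow(d) == 0L) warning("cohort is empty after filtering", call. = FALSE)
  list(clinical = d, report = report)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Aggregate variant annotations to patient-level TP53 status
#'
#' Synonymous variants never count toward mutant status.  Patients with
#' several TP53 variants are placed in the four-group scheme by precedence
#' (default: EAp53 high-risk > EAp53 low-risk > truncating > other); the
#' boolean fields are ORs over the patient's counted variants, so the
#' dichotomous schemes are order-independent.
#'
#' @param clinical validated clinical table (defines the patient universe).
#' @param annotations annotated TP53 variants (from [annotate_variants()])
#'   carrying a \code{patient_id} column.
#' @param precedence character vector ordering
#'   \code{c("high_risk", "low_risk", "truncating", "other")} for the
#'   four-group label of multi-mutation patients.
#' @return data.frame, one row per patient: \code{patient_id},
#'   \code{has_mutation}, \code{has_missense}, \code{has_truncating},
#'   \code{has_exon8}, \code{has_nondisruptive}, \code{best_eap53},
#'   \code{wild_type}, \code{four_group}.
#' @export
aggregate_patient_tp53 <- function(clinical, annotations,
                                   precedence = c("high_risk", "low_risk",
                                                  "truncating", "other")) {
  stopifnot(setequal(precedence,
                     c("high_risk", "low_risk", "truncating", "other")))
  ann <- annotations[!annotations$effect %in% "synonymous", , drop = FALSE]
  ids <- clinical$patient_id
  unknown <- setdiff(unique(ann$patient_id), ids)
  if (length(unknown)) {
    stop("validation error: variant patient id(s) absent from clinical ",
         "table: ", paste(utils::head(unknown, 3), collapse = ", "),
         call. = FALSE)
  }
  f <- factor(ann$patient_id, levels = ids)
  or_by_patient <- function(x) {
    v <- tapply(x, f, any)
    v[is.na(v)] <- FALSE
    as.logical(v)
  }
  has_mutation <- or_by_patient(rep(TRUE, nrow(ann)))
  cand <- cbind(
    high_risk  = or_by_patient(ann$eap53_class == "high_risk"),
    low_risk   = or_by_patient(ann$eap53_class == "low_risk"),
    truncating = or_by_patient(ann$is_truncating),
    other      = has_mutation)
  # first matching label in precedence order wins
  key <- rep(NA_character_, length(ids))
  for (p in rev(precedence)) key[cand[, p]] <- p
  four_labels <- c(high_risk = "EAp53 high-risk",
                   low_risk = "EAp53 low-risk",
                   truncating = "truncating", other = "other")
  data.frame(
    patient_id = ids,
    has_mutation = has_mutation,
    has_missense = or_by_patient(ann$effect == "missense"),
    has_truncating = cand[, "truncating"],
    has_exon8 = or_by_patient(!is.na(ann$exon) & ann$exon == 8L),
    has_nondisruptive = or_by_patient(!ann$is_disruptive),
    best_eap53 = ifelse(cand[, "high_risk"], "high",
                        ifelse(cand[, "low_risk"], "low", "none")),
    wild_type = !has_mutation,
    four_group = ifelse(has_mutation, unname(four_labels[key]), "WT"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort summary in the style of a clinical characteristics table
#'
#' Percentages are computed on the applicable denominator (multi-organ
#' metastasis is summarized among stage IV patients only) and rendered to
#' one decimal place with half-up rounding.
#'
#' @param clinical validated clinical table.
#' @param status optional patient-level TP53 status from
#'   [aggregate_patient_tp53()]; adds the TP53 mutation frequency.
#' @param annotations optional annotated TP53 variants; adds alteration
#'   counts and the truncating share of alterations.
#' @return list of summary components (class \code{cohort_summary}).
#' @export
summarize_cohort <- function(clinical, status = NULL, annotations = NULL) {
  n <- nrow(clinical)
  cat_table <- function(x, levels_order = NULL, denom = length(x)) {
    tab <- table(x)
    if (!is.null(levels_order)) {
      tab <- tab[intersect(levels_order, names(tab))]
    }
    data.frame(category = names(tab), count = as.integer(tab),
               pct = round_half_up(100 * as.integer(tab) / denom, 1),
               stringsAsFactors = FALSE)
  }
  out <- list(
    n = n,
    age = c(median = stats::median(clinical$age_years, na.rm = TRUE),
            min = min(clinical$age_years, na.rm = TRUE),
            max = max(clinical$age_years, na.rm = TRUE)),
    sex = cat_table(clinical$sex, c("male", "female", "unknown")),
    smoking = cat_table(clinical$smoking,
                        c("smoker", "nonsmoker", "unknown")),
    histology = cat_table(clinical$histology,
                          c("LUAD", "LUSC", "ASC", "other")),
    stage = cat_table(clinical$stage, c("I", "II", "III", "IV", "unknown")))
  iv <- clinical[clinical$stage == "IV", , drop = FALSE]
  if (nrow(iv)) {
    out$multi_organ_met_stage_iv <-
      cat_table(iv$multi_organ_met, c("yes", "no", "unknown"))
  }
  if (!is.null(status)) {
    k <- sum(status$has_mutation)
    out$tp53 <- data.frame(mutant_patients = k, total = n,
                           pct = round_half_up(100 * k / n, 1))
  }
  if (!is.null(annotations)) {
    a <- annotations[!annotations$effect %in% "synonymous", , drop = FALSE]
    out$alterations <- data.frame(
      n_alterations = nrow(a),
      truncating = sum(a$is_truncating),
      truncating_pct = round_half_up(100 * mean(a$is_truncating), 1))
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n, "patients; age median", x$age[["median"]],
      sprintf("(range %s-%s)\n", x$age[["min"]], x$age[["max"]]))
  for (nm in c("sex", "smoking", "histology", "stage",
               "multi_organ_met_stage_iv")) {
    if (is.null(x[[nm]])) next
    cat(nm, ":\n", sep = "")
    print(x[[nm]], row.names = FALSE)
  }
  if (!is.null(x$tp53)) {
    cat(sprintf("TP53-mutant: %d/%d (%.1f%%)\n", x$tp53$mutant_patients,
                x$tp53$total, x$tp53$pct))
  }
  if (!is.null(x$alterations)) {
    cat(sprintf("TP53 alterations: %d, truncating %d (%.1f%%)\n",
                x$alterations$n_alterations, x$alterations$truncating,
                x$alterations$truncating_pct))
  }
  invisible(x)
}
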