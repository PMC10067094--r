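# Build the comparison schemes from patient-level TP53 status and run the
# clinical-association and mutation-pattern contingency tests.

SCHEMES <- c("missense_vs_others", "nondisruptive_vs_others",
             "exon8_vs_others", "eap53_vs_others", "four_group")

#' Stratify a cohort under a named scheme
#'
#' For the dichotomous schemes a patient belongs to the exposure group if
#' \emph{any} of their TP53 variants qualifies; the complement (wild-type
#' included) is \code{"others"}, which is the baseline level.  The
#' four-group scheme uses the precedence label from
#' [aggregate_patient_tp53()].
#'
#' @param status patient-level TP53 status data.frame.
#' @param scheme one of \code{missense_vs_others},
#'   \code{nondisruptive_vs_others}, \code{exon8_vs_others},
#'   \code{eap53_vs_others}, \code{four_group}.
#' @return data.frame \code{patient_id}, \code{scheme}, \code{group}
#'   (factor, baseline first).
#' @export
stratify <- function(status, scheme) {
  if (!scheme %in% SCHEMES) {
    stop("unknown scheme '", scheme, "'; choose one of: ",
         paste(SCHEMES, collapse = ", "), call. = FALSE)
  }
  grp <- switch(scheme,
    missense_vs_others =
      ifelse(status$has_missense, "missense", "others"),
    nondisruptive_vs_others =
      ifelse(status$has_mutation & status$has_nondisruptive,
             "nondisruptive", "others"),
    exon8_vs_others =
      ifelse(status$has_exon8, "exon8", "others"),
    eap53_vs_others =
      ifelse(status$best_eap53 == "high", "EAp53 high-risk", "others"),
    four_group = status$four_group)
  levels_order <- if (scheme == "four_group") {
    c("WT", "truncating", "EAp53 low-risk", "EAp53 high-risk", "other")
  } else {
    c("others", setdiff(unique(grp), "others"))
  }
  grp <- factor(grp, levels = intersect(levels_order, unique(grp)))
  if (nlevels(grp) < 2L) {
    warning("scheme '", scheme, "' yields a single group", call. = FALSE)
  }
  data.frame(patient_id = status$patient_id, scheme = scheme, group = grp,
             stringsAsFactors = FALSE)
}

#' Two-sided association test on a 2x2 table
#'
#' Deterministic test selection: Fisher's exact test whenever any expected
#' cell count is below 5, otherwise the chi-square test with continuity
#' correction.  Tables with an empty row or column margin are reported as
#' not testable rather than raising an error.
#'
#' @param tab 2x2 integer matrix (or table).
#' @return list with \code{test} (\code{"fisher"}, \code{"chisq"} or
#'   \code{"not_testable"}), \code{p_value} and the counts.
#' @export
association_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L, ncol(tab) == 2L, all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(test = "not_testable", p_value = NA_real_, table = tab))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    list(test = "fisher", p_value = p, table = tab)
  } else {
    p <- stats::chisq.test(tab, correct = TRUE)$p.value
    list(test = "chisq", p_value = p, table = tab)
  }
}

assoc_row <- function(variable, tab) {
  res <- association_test(tab)
  data.frame(variable = variable, test = res$test, p_value = res$p_value,
             n11 = tab[1, 1], n12 = tab[1, 2], n21 = tab[2, 1],
             n22 = tab[2, 2],
             rows = paste(rownames(tab), collapse = "/"),
             cols = paste(colnames(tab), collapse = "/"),
             stringsAsFactors = FALSE)
}

#' Clinical associations of TP53 mutation status
#'
#' TP53-mutant versus wild-type, tested against sex, smoking status, age
#' dichotomized at 65 years, and single- versus multiple-organ metastasis
#' (stage IV patients only).  Each row records the underlying 2x2 counts,
#' the test chosen by the expected-count rule, and the two-sided p-value.
#'
#' @param clinical validated clinical table.
#' @param status patient-level TP53 status.
#' @return data.frame, one row per variable.
#' @export
clinical_association_tests <- function(clinical, status) {
  d <- merge(clinical, status, by = "patient_id")
  mut <- factor(ifelse(d$has_mutation, "TP53-mutant", "TP53-WT"),
                levels = c("TP53-mutant", "TP53-WT"))
  rows <- list()
  add <- function(variable, keep, x, lv) {
    tab <- table(factor(x[keep], levels = lv), mut[keep])
    rows[[length(rows) + 1L]] <<- assoc_row(variable, tab)
  }
  add("sex", d$sex != "unknown", d$sex, c("male", "female"))
  add("smoking", d$smoking != "unknown", d$smoking,
      c("smoker", "nonsmoker"))
  add("age_gt65", !is.na(d$age_years),
      ifelse(d$age_years > 65, ">65", "<=65"), c("<=65", ">65"))
  add("multi_organ_met_stage_iv",
      d$stage == "IV" & d$multi_organ_met %in% c("yes", "no"),
      d$multi_organ_met, c("yes", "no"))
  do.call(rbind, rows)
}

#' Mutation-pattern contrasts of truncating versus missense variants
#'
#' For every exon, and for DNA-binding domain versus non-DBD, builds the
#' 2x2 table (effect class x location) over TP53 alterations and applies
#' the association test.  Splice variants carry no protein position and are
#' excluded from the location contrasts (they remain in the alteration
#' total).  Also returns the hotspot frequency table (share of each
#' distinct protein change among all alterations).
#'
#' @param annotations annotated TP53 variants.
#' @return list with \code{exon_tests}, \code{domain_test},
#'   \code{hotspots}, \code{n_alterations}.
#' @export
mutation_pattern_tests <- function(annotations) {
  a <- annotations[!annotations$effect %in% "synonymous", , drop = FALSE]
  loc <- a[(a$effect == "missense" | a$is_truncating) & !is.na(a$exon), ,
           drop = FALSE]
  cls <- factor(ifelse(loc$is_truncating, "truncating", "missense"),
                levels = c("truncating", "missense"))
  exon_rows <- lapply(sort(unique(loc$exon)), function(e) {
    tab <- table(cls, factor(ifelse(loc$exon == e, "in_exon", "elsewhere"),
                             levels = c("in_exon", "elsewhere")))
    res <- association_test(tab)
    data.frame(exon = e,
               truncating_in = tab[1, 1], missense_in = tab[2, 1],
               truncating_out = tab[1, 2], missense_out = tab[2, 2],
               test = res$test, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  dom_tab <- table(cls, factor(ifelse(loc$in_dbd, "DBD", "non-DBD"),
                               levels = c("DBD", "non-DBD")))
  dom_res <- association_test(dom_tab)
  label <- format_hgvs_p(a)
  hot <- sort(table(label), decreasing = TRUE)
  hotspots <- data.frame(variant = names(hot), count = as.integer(hot),
                         frequency = as.integer(hot) / nrow(a),
                         stringsAsFactors = FALSE)
  list(exon_tests = do.call(rbind, exon_rows),
       domain_test = list(table = dom_tab, test = dom_res$test,
                          p_value = dom_res$p_value),
       hotspots = hotspots,
       n_alterations = nrow(a))
}
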