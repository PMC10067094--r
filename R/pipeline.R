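# Report assembly tying the pipeline together: annotate TP53 variants,
# aggregate patient status, run the stratification / survival / landscape
# analyses, and emit a reproducible report bundle with a provenance block.

#' Annotate the TP53 rows of a variant table
#'
#' Non-TP53 rows are passed over (they are counted by the landscape
#' module); TP53 rows that fail to parse are collected in a skip table with
#' their row numbers instead of being silently dropped.
#'
#' @param variants variant table path or data.frame
#'   (see [read_variant_table()]).
#' @param references reference set from [load_reference_set()] (bundled
#'   defaults when \code{NULL}).
#' @param use_ea_lookup fall back to the reference EA table for missense
#'   variants without an \code{ea_score} value.
#' @return list: \code{annotations} (annotated TP53 variants with
#'   \code{patient_id}), \code{skipped} (data.frame \code{row},
#'   \code{patient_id}, \code{protein_change}, \code{reason}).
#' @export
annotate_variant_file <- function(variants, references = NULL,
                                  use_ea_lookup = TRUE) {
  refs <- references %||% load_reference_set()
  va <- read_variant_table(variants)
  idx <- which(va$gene == "TP53")
  parsed <- vector("list", length(idx))
  skipped <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    parsed[[k]] <- tryCatch({
      p <- parse_hgvs_p(va$protein_change[i], va$variant_classification[i])
      p$patient_id <- va$patient_id[i]
      p$ea_score_input <- va$ea_score[i]
      p
    }, error = function(e) {
      skipped[[length(skipped) + 1L]] <<- data.frame(
        row = i, patient_id = va$patient_id[i],
        protein_change = va$protein_change[i],
        reason = conditionMessage(e), stringsAsFactors = FALSE)
      NULL
    })
  }
  parsed <- do.call(rbind, parsed)
  ann <- if (!is.null(parsed) && nrow(parsed)) {
    annotate_variants(parsed, refs$model, refs$domains, refs$properties,
                      ea = if (use_ea_lookup) refs$ea else NULL,
                      ea_score = parsed$ea_score_input)
  } else {
    p0 <- parse_hgvs_p("R282W")[0, ]
    cbind(p0, patient_id = character(), ea_score_input = numeric())
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(row = integer(), patient_id = character(),
               protein_change = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(annotations = ann, skipped = skipped)
}

#' Run the full TP53 classification and prognosis pipeline
#'
#' Executes, in order: variant annotation, patient-level TP53 aggregation,
#' the cohort summary and clinical-association / mutation-pattern tests on
#' the whole cohort, the advanced-stage / ICI-naive / OS filters, the
#' survival analysis on the filtered cohort, and the HR-versus-OT
#' landscape, pathway and TMB comparisons.  The report carries a
#' provenance block (package version, config echo, input checksums when
#' paths were given) and contains no timestamps, so reruns on identical
#' inputs are byte-identical.
#'
#' @param clinical clinical table path or data.frame.
#' @param variants variant table path or data.frame.
#' @param references reference set (bundled defaults when \code{NULL}).
#' @param schemes dichotomous survival schemes to run.
#' @param filters named logicals \code{stage}, \code{ici}, \code{os}
#'   applied before the survival analysis.
#' @param ties Cox tie handling.
#' @param bh add BH-adjusted p-values to the per-gene landscape screen.
#' @param panel_mb panel size for TMB (skipped when \code{NULL} and the
#'   variant table has no precomputed \code{tmb} column).
#' @param min_gene_patients minimum mutated-patient count for the per-gene
#'   tests.
#' @return list of class \code{tp53_report}.
#' @export
run_tp53_analysis <- function(clinical, variants, references = NULL,
                              schemes = c("missense_vs_others",
                                          "nondisruptive_vs_others",
                                          "exon8_vs_others",
                                          "eap53_vs_others"),
                              filters = list(stage = TRUE, ici = TRUE,
                                             os = TRUE),
                              ties = "efron", bh = TRUE, panel_mb = NULL,
                              min_gene_patients = 3L) {
  refs <- references %||% load_reference_set()
  checksum <- function(x) if (is.character(x) && length(x) == 1L &&
                              file.exists(x)) unname(tools::md5sum(x))
                          else NA_character_
  prov <- list(package = "tp53ea",
               version = as.character(utils::packageVersion("tp53ea")),
               transcript_label = refs$model$transcript_label,
               clinical_md5 = checksum(clinical),
               variants_md5 = checksum(variants),
               schemes = schemes, ties = ties,
               filters = filters, panel_mb = panel_mb)

  cl <- read_clinical_table(clinical)
  annres <- annotate_variant_file(variants, refs)
  if (nrow(annres$skipped)) {
    warning(nrow(annres$skipped), " TP53 variant row(s) skipped; see the ",
            "report's skipped table", call. = FALSE)
  }
  status <- aggregate_patient_tp53(cl, annres$annotations)

  summary <- summarize_cohort(cl, status, annres$annotations)
  strata <- do.call(rbind, lapply(c(schemes, "four_group"), function(sc) {
    suppressWarnings(stratify(status, sc))
  }))
  assoc <- clinical_association_tests(cl, status)
  patterns <- mutation_pattern_tests(annres$annotations)

  filt <- apply_cohort_filters(cl,
                               require_stage = isTRUE(filters$stage),
                               require_ici_naive = isTRUE(filters$ici),
                               require_os = isTRUE(filters$os))
  survival <- if (nrow(filt$clinical) >= 2L) {
    tryCatch(run_survival_analysis(filt$clinical, status, schemes,
                                   ties = ties),
             error = function(e) {
               warning("survival stage skipped: ", conditionMessage(e),
                       call. = FALSE)
               NULL
             })
  } else NULL

  va <- read_variant_table(variants)
  part <- hr_ot_partition(status)
  landscape <- NULL
  if (length(unique(part$group)) == 2L) {
    genes <- gene_frequency_compare(va, part, min_gene_patients, bh = bh)
    pathways <- pathway_aggregate(va, part)
    tmb <- NULL
    tmb_test <- NULL
    if (!is.null(panel_mb)) {
      tmb <- compute_tmb(va, cl$patient_id, panel_mb)
      tmb_test <- tmb_compare(tmb, part)
    }
    landscape <- list(genes = genes, pathways = pathways, tmb = tmb,
                      tmb_comparison = tmb_test)
  } else {
    warning("landscape comparison skipped: only one of HR/OT present",
            call. = FALSE)
  }

  structure(list(provenance = prov, summary = summary, status = status,
                 annotations = annres$annotations,
                 skipped = annres$skipped, strata = strata,
                 clinical_associations = assoc,
                 mutation_patterns = patterns,
                 filter_report = filt$report, survival = survival,
                 landscape = landscape),
            class = "tp53_report")
}

#' @export
print.tp53_report <- function(x, ...) {
  cat("== TP53 classification & prognosis report ==\n")
  cat("transcript:", x$provenance$transcript_label, "\n\n")
  print(x$summary)
  cat("\nFour-group sizes:\n")
  print(table(x$status$four_group))
  if (!is.null(x$survival)) { cat("\n"); print(x$survival) }
  if (!is.null(x$landscape) && !is.null(x$landscape$tmb_comparison)) {
    tc <- x$landscape$tmb_comparison
    cat(sprintf("\nTMB HR vs OT: median %.2f vs %.2f mut/Mb, p=%.4g (%s)\n",
                tc$median_hr, tc$median_ot, tc$p_value, tc$method))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One TSV per tabular component plus a JSON index with the provenance
#' block and scalar results.  No timestamps: identical inputs give
#' identical files.
#'
#' @param report a \code{tp53_report}.
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tp53_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    status = wt(report$status, "patient_status"),
    annotations = wt(report$annotations, "tp53_annotations"),
    strata = wt(report$strata, "stratification"),
    associations = wt(report$clinical_associations,
                      "clinical_associations"),
    filter = wt(report$filter_report, "filter_report"))
  if (!is.null(report$landscape)) {
    paths <- c(paths,
               genes = wt(report$landscape$genes, "gene_frequencies"),
               pathways = wt(report$landscape$pathways, "pathways"))
    if (!is.null(report$landscape$tmb)) {
      paths <- c(paths, tmb = wt(report$landscape$tmb, "tmb"))
    }
  }
  idx <- list(provenance = report$provenance,
              n = report$summary$n,
              tp53 = report$summary$tp53,
              alterations = report$summary$alterations)
  if (!is.null(report$survival)) {
    idx$survival <- lapply(report$survival$schemes, function(r) {
      mt <- r$cox_multivariate$terms
      row <- mt[mt$term == "exposure", ]
      list(n = r$n, events = r$events,
           logrank_p = r$logrank$p_value,
           precheck_p = if (!is.null(r$precheck)) r$precheck$p_value,
           hr_univariate = r$cox_univariate$terms$hr[1],
           hr_multivariate = row$hr,
           ci = c(row$ci_lower, row$ci_upper),
           p_multivariate = row$p_value)
    })
  }
  if (!is.null(report$landscape$tmb_comparison)) {
    idx$tmb_comparison <- report$landscape$tmb_comparison
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(idx, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, json = jp))
}
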