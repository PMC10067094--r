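# Genomic-landscape comparison between EAp53 high-risk (HR) patients and
# all others (OT): per-gene mutation frequencies, pathway-level alteration
# rates (RTK, cell cycle, DDR), and tumor mutation burden.

NONCODING_CLASSES <- c("Silent", "Synonymous", "3'UTR", "5'UTR", "Intron",
                       "RNA", "IGR", "5'Flank", "3'Flank")

#' HR/OT partition from patient-level TP53 status
#'
#' @param status patient-level status from [aggregate_patient_tp53()].
#' @return data.frame \code{patient_id}, \code{group} ("HR" for EAp53
#'   high-risk carriers, "OT" otherwise).
#' @export
hr_ot_partition <- function(status) {
  data.frame(patient_id = status$patient_id,
             group = ifelse(status$best_eap53 == "high", "HR", "OT"),
             stringsAsFactors = FALSE)
}

# Like association_test, but a table whose mutated/wild-type margin is
# empty (a gene altered in everyone or no one) is an exact p of 1, not a
# degenerate case: both groups have identical frequency by construction.
landscape_test <- function(tab) {
  if (all(rowSums(tab) > 0) && any(colSums(tab) == 0)) {
    return(list(test = "fisher", p_value = 1, table = tab))
  }
  association_test(tab)
}

mutated_matrix <- function(variants, partition) {
  v <- variants[!variants$variant_classification %in% NONCODING_CLASSES |
                  is.na(variants$variant_classification), , drop = FALSE]
  v <- v[v$patient_id %in% partition$patient_id, , drop = FALSE]
  unique(v[, c("patient_id", "gene")])
}

#' Per-gene mutation-frequency comparison between HR and OT patients
#'
#' Frequencies are patient-level (a patient with two mutations in a gene
#' counts once).  Genes mutated in fewer patients than
#' \code{min_patients} are reported but flagged untested.
#'
#' @param variants variant table (all genes).
#' @param partition HR/OT partition covering the cohort.
#' @param min_patients minimum mutated-patient count for testing.
#' @param bh add a Benjamini-Hochberg adjusted p-value column.
#' @return data.frame sorted by HR-group frequency.
#' @export
gene_frequency_compare <- function(variants, partition, min_patients = 3L,
                                   bh = FALSE) {
  stopifnot(all(c("patient_id", "group") %in% names(partition)),
            all(partition$group %in% c("HR", "OT")))
  mm <- mutated_matrix(variants, partition)
  n_hr <- sum(partition$group == "HR")
  n_ot <- sum(partition$group == "OT")
  mm$group <- partition$group[match(mm$patient_id, partition$patient_id)]
  rows <- lapply(unique(mm$gene), function(g) {
    sub <- mm[mm$gene == g, ]
    hr_m <- sum(sub$group == "HR")
    ot_m <- sum(sub$group == "OT")
    tested <- (hr_m + ot_m) >= min_patients
    if (tested) {
      tab <- matrix(c(hr_m, n_hr - hr_m, ot_m, n_ot - ot_m), nrow = 2,
                    byrow = TRUE,
                    dimnames = list(c("HR", "OT"), c("mut", "wt")))
      res <- landscape_test(tab)
    } else {
      res <- list(test = "untested", p_value = NA_real_)
    }
    data.frame(gene = g, hr_mutated = hr_m, hr_total = n_hr,
               ot_mutated = ot_m, ot_total = n_ot,
               hr_freq = hr_m / n_hr, ot_freq = ot_m / n_ot,
               test = res$test, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$hr_freq, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (bh) {
    out$p_adjusted <- NA_real_
    tested <- !is.na(out$p_value)
    out$p_adjusted[tested] <- stats::p.adjust(out$p_value[tested], "BH")
  }
  out
}

#' Load a gene-to-pathway map
#'
#' Two-column TSV (\code{pathway}, \code{gene}).  The bundled default
#' covers RTK, cell-cycle and DNA-damage-repair gene sets; the mapping is
#' data, not code, and fully editable.
#'
#' @param path path to the map; \code{NULL} loads the default.
#' @return data.frame \code{pathway}, \code{gene}.
#' @export
load_pathway_map <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("pathways.tsv")
  pm <- read_tsv_checked(path, c("pathway", "gene"), "pathway map")
  if (any(table(pm$pathway) == 0L) || nrow(pm) == 0L) {
    stop("validation error: empty pathway map", call. = FALSE)
  }
  pm
}

#' Pathway-level alteration comparison between HR and OT patients
#'
#' A patient counts as pathway-altered when at least one mapped gene
#' carries at least one mutation.  Pathways with no member gene present in
#' the cohort are reported empty and untested.
#'
#' @param variants variant table.
#' @param partition HR/OT partition.
#' @param pathway_map data.frame from [load_pathway_map()].
#' @return data.frame, one row per pathway.
#' @export
pathway_aggregate <- function(variants, partition, pathway_map = NULL) {
  if (is.null(pathway_map)) pathway_map <- load_pathway_map()
  mm <- mutated_matrix(variants, partition)
  n_hr <- sum(partition$group == "HR")
  n_ot <- sum(partition$group == "OT")
  rows <- lapply(unique(pathway_map$pathway), function(pw) {
    genes <- pathway_map$gene[pathway_map$pathway == pw]
    hit <- mm[mm$gene %in% genes, , drop = FALSE]
    if (nrow(hit) == 0L) {
      return(data.frame(pathway = pw, hr_altered = 0L, hr_total = n_hr,
                        ot_altered = 0L, ot_total = n_ot,
                        hr_freq = 0, ot_freq = 0, test = "untested",
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    pats <- unique(hit$patient_id)
    grp <- partition$group[match(pats, partition$patient_id)]
    hr_a <- sum(grp == "HR"); ot_a <- sum(grp == "OT")
    tab <- matrix(c(hr_a, n_hr - hr_a, ot_a, n_ot - ot_a), nrow = 2,
                  byrow = TRUE)
    res <- landscape_test(tab)
    data.frame(pathway = pw, hr_altered = hr_a, hr_total = n_hr,
               ot_altered = ot_a, ot_total = n_ot,
               hr_freq = hr_a / n_hr, ot_freq = ot_a / n_ot,
               test = res$test, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-patient tumor mutation burden
#'
#' Eligible mutations (by default nonsynonymous coding variants: rows whose
#' \code{variant_classification} is not silent/non-coding) divided by the
#' panel size in megabases.  Patients with no variant rows get TMB 0.
#'
#' @param variants variant table.
#' @param patient_ids patient universe (defaults to patients present in the
#'   variant table).
#' @param panel_mb panel size in megabases; must be positive.
#' @param exclude_classes variant classes excluded from the count.
#' @return data.frame \code{patient_id}, \code{eligible_mutations},
#'   \code{panel_mb}, \code{tmb}.
#' @export
compute_tmb <- function(variants, patient_ids = NULL, panel_mb,
                        exclude_classes = NONCODING_CLASSES) {
  if (!is.numeric(panel_mb) || length(panel_mb) != 1L || !is.finite(panel_mb)
      || panel_mb <= 0) {
    stop("validation error: panel size must be a positive number of Mb",
         call. = FALSE)
  }
  if (is.null(patient_ids)) patient_ids <- unique(variants$patient_id)
  elig <- variants[!variants$variant_classification %in% exclude_classes |
                     is.na(variants$variant_classification), , drop = FALSE]
  cnt <- table(factor(elig$patient_id, levels = patient_ids))
  data.frame(patient_id = patient_ids,
             eligible_mutations = as.integer(cnt),
             panel_mb = panel_mb,
             tmb = as.integer(cnt) / panel_mb,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney comparison of TMB between HR and OT patients
#'
#' Exact enumeration of the rank-sum distribution when both groups have at
#' most 20 observations and no ties; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param tmb data.frame from [compute_tmb()] (or any table with
#'   \code{patient_id} and \code{tmb}).
#' @param partition HR/OT partition.
#' @return list: \code{u_statistic} (for the HR group), \code{p_value},
#'   \code{median_hr}, \code{median_ot}, \code{method}, group sizes.
#' @export
tmb_compare <- function(tmb, partition) {
  grp <- partition$group[match(tmb$patient_id, partition$patient_id)]
  x <- tmb$tmb[grp %in% "HR"]
  y <- tmb$tmb[grp %in% "OT"]
  if (length(x) == 0L || length(y) == 0L) {
    stop("validation error: both HR and OT groups must be non-empty",
         call. = FALSE)
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !has_ties && max(length(x), length(y)) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(u_statistic = unname(wt$statistic), p_value = wt$p.value,
       median_hr = stats::median(x), median_ot = stats::median(y),
       n_hr = length(x), n_ot = length(y),
       method = if (exact) "exact" else "normal_approximation")
}
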