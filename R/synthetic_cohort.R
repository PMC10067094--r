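# Seeded generator for synthetic NSCLC cohorts with the statistical
# structure the analyses assume: ~51% TP53 prevalence, a hotspot-weighted
# mutation spectrum concentrated in exons 5/7/8, ~31% truncating variants
# enriched outside the DNA-binding domain, EAp53 scores from a two-mode
# mixture spanning the 75 threshold, clinical covariates, and Weibull
# survival with group-specific hazard ratios under administrative plus
# exponential right-censoring.

#' Default TP53 mutation spectrum
#'
#' Fixed hotspot templates each carry more than 2\% of the TP53 alteration
#' mass; random templates place missense mass inside the DNA-binding
#' domain and truncating mass preferentially outside it (exons 4 and 10).
#' Total truncating weight is 0.31.
#'
#' @return data.frame \code{template}, \code{kind}, \code{weight}.
#' @export
default_spectrum <- function() {
  data.frame(
    template = c("R282W", "R158L", "Y236C", "E298X", "R110L", "R273C",
                 "R280K", "Y220C", "missense_dbd", "missense_nondbd",
                 "nonsense_random", "frameshift_random", "splice_random"),
    kind = c(rep("fixed", 8), "missense_dbd", "missense_nondbd",
             "nonsense_random", "frameshift_random", "splice_random"),
    weight = c(0.060, 0.048, 0.044, 0.040, 0.036, 0.032, 0.028, 0.028,
               0.360, 0.054, 0.100, 0.120, 0.050),
    stringsAsFactors = FALSE)
}

#' Default background gene mutation probabilities
#'
#' Per-patient mutation probabilities for the landscape comparison, higher
#' in the EAp53 high-risk (HR) group for RTK, cell-cycle and DDR genes.
#'
#' @return data.frame \code{gene}, \code{p_hr}, \code{p_ot}.
#' @export
default_gene_probs <- function() {
  data.frame(
    gene = c("EGFR", "KRAS", "PTPRD", "STK11", "KEAP1", "MLL2", "CDKN2A",
             "PTPRT", "RB1", "STAG2", "B2M", "RBM10", "ATM", "CHEK2",
             "BRCA2", "MET", "ERBB2", "ALK", "ROS1", "RET", "CCND1",
             "CDK4"),
    p_hr = c(0.33, 0.22, 0.12, 0.12, 0.11, 0.10, 0.10, 0.10, 0.09, 0.06,
             0.05, 0.05, 0.08, 0.05, 0.06, 0.08, 0.07, 0.05, 0.03, 0.03,
             0.05, 0.04),
    p_ot = c(0.25, 0.29, 0.05, 0.16, 0.16, 0.06, 0.05, 0.03, 0.03, 0.01,
             0.01, 0.09, 0.04, 0.02, 0.03, 0.05, 0.04, 0.05, 0.03, 0.02,
             0.02, 0.02),
    stringsAsFactors = FALSE)
}

#' Build and validate a simulation configuration
#'
#' Defaults reproduce the design conditions of the cohort the package
#' analyzes: 210 patients, TP53 prevalence 0.514, 60\% male, 50\% smokers,
#' the stage distribution of an advanced-disease cohort (75\% stage IV),
#' overall-survival data available for ~41\% of patients, and a
#' proportional-hazards survival model whose generative hazard ratios place
#' the prognostic signal on the EAp53 high-risk exposure (HR 3.63) with
#' EGFR mutation protective (HR 0.30).
#'
#' @param n_patients cohort size.
#' @param tp53_prevalence probability a patient carries >= 1 TP53 mutation.
#' @param second_mutation_prob probability a mutant patient carries a
#'   second TP53 mutation.
#' @param spectrum mutation-spectrum data.frame (see [default_spectrum()]).
#' @param ea_mixture EAp53 score mixture for missense variants:
#'   \code{weight_high}, \code{low_mean}, \code{low_sd}, \code{high_mean},
#'   \code{high_sd}.
#' @param covariates list of covariate prevalences and ranges.
#' @param survival Weibull baseline and censoring: \code{shape},
#'   \code{scale} (months), \code{horizon} (administrative censoring,
#'   months), \code{censor_rate} (independent exponential, per month).
#' @param log_hr named numeric vector of log hazard ratios applied to the
#'   linear predictor; recognised names: \code{eap53_high},
#'   \code{missense}, \code{exon8}, \code{nondisruptive}, \code{male},
#'   \code{smoker}, \code{egfr_mutant}, \code{age_gt65}.
#' @param gene_probs background gene table (see [default_gene_probs()]).
#' @param panel_mb panel size in megabases used for TMB.
#' @param seed mandatory integer seed; the generator derives one substream
#'   per component (covariates, TP53 spectrum, EA scores, survival,
#'   landscape) so changing one component's parameters does not perturb the
#'   draws of the others.
#' @return validated list of class \code{sim_config}.
#' @export
simulation_config <- function(n_patients = 210L,
                              tp53_prevalence = 0.514,
                              second_mutation_prob = 0.157,
                              spectrum = default_spectrum(),
                              ea_mixture = list(weight_high = 0.5,
                                                low_mean = 50, low_sd = 10,
                                                high_mean = 85, high_sd = 6),
                              covariates = list(
                                male = 0.60, smoker = 0.50,
                                egfr_mutant = 0.45,
                                stage_probs = c(I = 0.043, II = 0.038,
                                                III = 0.148, IV = 0.752,
                                                unknown = 0.019),
                                multi_organ_yes = 0.323,
                                multi_organ_unknown = 0.013,
                                histology_probs = c(LUAD = 0.771,
                                                    LUSC = 0.219,
                                                    ASC = 0.010),
                                ici_prob = 0,
                                os_available = 0.41,
                                age_mean = 64, age_sd = 11,
                                age_min = 34, age_max = 90),
                              survival = list(shape = 1.2, scale = 30,
                                              horizon = 40,
                                              censor_rate = 0.01),
                              log_hr = c(eap53_high = log(3.63),
                                         male = log(2.06),
                                         smoker = log(0.65),
                                         egfr_mutant = log(0.30),
                                         age_gt65 = log(0.82)),
                              gene_probs = default_gene_probs(),
                              panel_mb = 1.2,
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop("validation error: seed is mandatory", call. = FALSE)
  }
  cfg <- list(n_patients = as.integer(n_patients),
              tp53_prevalence = tp53_prevalence,
              second_mutation_prob = second_mutation_prob,
              spectrum = spectrum, ea_mixture = ea_mixture,
              covariates = covariates, survival = survival,
              log_hr = log_hr, gene_probs = gene_probs,
              panel_mb = panel_mb, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$tp53_prevalence, cfg$second_mutation_prob,
             cfg$covariates$male, cfg$covariates$smoker,
             cfg$covariates$egfr_mutant, cfg$covariates$ici_prob,
             cfg$covariates$os_available, cfg$covariates$stage_probs,
             cfg$covariates$histology_probs, cfg$covariates$multi_organ_yes,
             cfg$covariates$multi_organ_unknown, cfg$ea_mixture$weight_high,
             cfg$gene_probs$p_hr, cfg$gene_probs$p_ot)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("validation error: probability outside [0, 1] in config",
         call. = FALSE)
  }
  if (cfg$n_patients < 1L) {
    stop("validation error: n_patients must be >= 1", call. = FALSE)
  }
  if (any(cfg$spectrum$weight <= 0)) {
    stop("validation error: spectrum weights must be positive",
         call. = FALSE)
  }
  sv <- cfg$survival
  if (sv$shape <= 0 || sv$scale <= 0 || sv$horizon <= 0 ||
      sv$censor_rate < 0) {
    stop("validation error: Weibull shape/scale and horizon must be ",
         "positive, censor_rate non-negative", call. = FALSE)
  }
  if (cfg$panel_mb <= 0) {
    stop("validation error: panel_mb must be positive", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("validation error: seed must be an integer",
                            call. = FALSE)
  invisible(cfg)
}

#' Draw right-censored Weibull proportional-hazards survival times
#'
#' Event times follow a Weibull baseline whose hazard is multiplied by
#' \code{exp(lp)}; the observed time is the minimum of the event time, an
#' administrative horizon, and an independent exponential censoring time.
#' Uses the caller's RNG state (seed outside for reproducibility).
#'
#' @param lp numeric vector of linear predictors (one per subject).
#' @param shape,scale Weibull baseline parameters (scale in months).
#' @param horizon administrative censoring horizon in months.
#' @param censor_rate rate of the independent exponential censoring time
#'   (0 disables it).
#' @return data.frame \code{time}, \code{event}.
#' @export
simulate_survival <- function(lp, shape, scale, horizon = Inf,
                              censor_rate = 0) {
  if (shape <= 0 || scale <= 0) {
    stop("validation error: Weibull shape and scale must be positive",
         call. = FALSE)
  }
  if (horizon <= 0) {
    stop("validation error: censoring horizon must be positive",
         call. = FALSE)
  }
  n <- length(lp)
  u <- stats::runif(n)
  t_event <- scale * (-log(u) / exp(lp))^(1 / shape)
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, horizon)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

realize_tp53_variant <- function(kind, template, seq_chars, model) {
  pick_pos <- function(pool) pool[sample.int(length(pool), 1L)]
  non_dbd <- c(1:101, 293:393)
  exon4_10 <- c(33:125, 332:367)
  switch(kind,
    fixed = template,
    missense_dbd = {
      pos <- pick_pos(102:292)
      ref <- seq_chars[pos]
      alt <- sample(setdiff(AA_CODES, ref), 1L)
      paste0(ref, pos, alt)
    },
    missense_nondbd = {
      pos <- pick_pos(non_dbd)
      ref <- seq_chars[pos]
      alt <- sample(setdiff(AA_CODES, ref), 1L)
      paste0(ref, pos, alt)
    },
    nonsense_random = {
      pos <- if (stats::runif(1) < 0.6) pick_pos(exon4_10)
             else pick_pos(seq_along(seq_chars))
      paste0(seq_chars[pos], pos, "X")
    },
    frameshift_random = {
      pos <- if (stats::runif(1) < 0.6) pick_pos(exon4_10)
             else pick_pos(seq_along(seq_chars))
      paste0(seq_chars[pos], pos, "fs")
    },
    splice_random = {
      pos <- pick_pos(model$exons$first_codon[-1])
      paste0("X", pos, "_splice")
    },
    stop("unknown spectrum kind '", kind, "'", call. = FALSE))
}

kind_to_classification <- function(change) {
  ifelse(grepl("_splice$", change), "Splice_Site",
  ifelse(grepl("fs$", change), "Frame_Shift_Del",
  ifelse(grepl("(X|\\*)$", change), "Nonsense_Mutation",
         "Missense_Mutation")))
}

#' Simulate a full synthetic cohort
#'
#' Deterministic given the config seed: rerunning with the same config
#' gives byte-identical tables.  The truth table records every patient's
#' generative group and linear predictor for parameter-recovery tests.
#'
#' @param config a \code{sim_config} from [simulation_config()].
#' @param references reference set from [load_reference_set()] (the
#'   bundled defaults when \code{NULL}).
#' @return list of class \code{tp53_simulation}: \code{clinical},
#'   \code{variants}, \code{truth}, \code{config}.
#' @export
simulate_cohort <- function(config, references = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  refs <- references %||% load_reference_set()
  seq_chars <- strsplit(refs$sequence, "")[[1]]
  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  subseeds <- with_seed(config$seed,
                        sample.int(.Machine$integer.max - 1L, 5L))

  ## 1. clinical covariates -------------------------------------------------
  cv <- config$covariates
  clinical <- with_seed(subseeds[1], {
    age <- as.integer(round(pmin(pmax(
      stats::rnorm(n, cv$age_mean, cv$age_sd), cv$age_min), cv$age_max)))
    stage <- sample(names(cv$stage_probs), n, replace = TRUE,
                    prob = cv$stage_probs)
    mo <- rep("not_applicable", n)
    iv <- stage == "IV"
    if (any(iv)) {
      mo[iv] <- sample(c("yes", "no", "unknown"), sum(iv), replace = TRUE,
                       prob = c(cv$multi_organ_yes,
                                1 - cv$multi_organ_yes -
                                  cv$multi_organ_unknown,
                                cv$multi_organ_unknown))
    }
    data.frame(
      patient_id = ids, age_years = age,
      sex = ifelse(stats::rbinom(n, 1, cv$male) == 1, "male", "female"),
      smoking = ifelse(stats::rbinom(n, 1, cv$smoker) == 1, "smoker",
                       "nonsmoker"),
      histology = sample(names(cv$histology_probs), n, replace = TRUE,
                         prob = cv$histology_probs),
      stage = stage, multi_organ_met = mo,
      egfr_status = ifelse(stats::rbinom(n, 1, cv$egfr_mutant) == 1,
                           "mutant", "wild_type"),
      os_months = NA_real_, os_event = NA_integer_,
      ici_treated = stats::rbinom(n, 1, cv$ici_prob) == 1,
      stringsAsFactors = FALSE)
  })

  ## 2. TP53 mutations from the spectrum ------------------------------------
  tp53 <- with_seed(subseeds[2], {
    mutant <- stats::rbinom(n, 1, config$tp53_prevalence) == 1
    n_var <- ifelse(mutant,
                    1L + stats::rbinom(n, 1, config$second_mutation_prob),
                    0L)
    pat <- rep(ids, n_var)
    if (length(pat) == 0L) {
      data.frame(patient_id = character(), gene = character(),
                 protein_change = character(),
                 variant_classification = character(),
                 stringsAsFactors = FALSE)
    } else {
      sp <- config$spectrum
      rows <- sample.int(nrow(sp), length(pat), replace = TRUE,
                         prob = sp$weight)
      change <- vapply(rows, function(i) {
        realize_tp53_variant(sp$kind[i], sp$template[i], seq_chars,
                             refs$model)
      }, character(1))
      data.frame(patient_id = pat, gene = "TP53", protein_change = change,
                 variant_classification = kind_to_classification(change),
                 stringsAsFactors = FALSE)
    }
  })

  ## 3. EAp53 scores for missense variants ----------------------------------
  mis <- tp53$variant_classification == "Missense_Mutation"
  tp53$ea_score <- NA_real_
  if (any(mis)) {
    mx <- config$ea_mixture
    tp53$ea_score[mis] <- with_seed(subseeds[3], {
      m <- sum(mis)
      hi <- stats::rbinom(m, 1, mx$weight_high) == 1
      sc <- ifelse(hi, stats::rnorm(m, mx$high_mean, mx$high_sd),
                   stats::rnorm(m, mx$low_mean, mx$low_sd))
      round(pmin(pmax(sc, 0), 100), 1)
    })
  }

  ## 4. annotate (no RNG) to obtain the generative exposure flags -----------
  status <- if (nrow(tp53)) {
    parsed <- parse_hgvs_p(tp53$protein_change, tp53$variant_classification)
    parsed$patient_id <- tp53$patient_id
    ann <- annotate_variants(parsed, refs$model, refs$domains,
                             refs$properties, ea_score = tp53$ea_score)
    aggregate_patient_tp53(clinical, ann)
  } else {
    aggregate_patient_tp53(clinical,
                           cbind(parse_hgvs_p("R282W")[0, ],
                                 patient_id = character()))
  }

  ## 5. survival ------------------------------------------------------------
  ind <- cbind(
    eap53_high = as.numeric(status$best_eap53 == "high"),
    missense = as.numeric(status$has_missense),
    exon8 = as.numeric(status$has_exon8),
    nondisruptive = as.numeric(status$has_mutation &
                                 status$has_nondisruptive),
    male = as.numeric(clinical$sex == "male"),
    smoker = as.numeric(clinical$smoking == "smoker"),
    egfr_mutant = as.numeric(clinical$egfr_status == "mutant"),
    age_gt65 = as.numeric(clinical$age_years > 65))
  use <- intersect(names(config$log_hr), colnames(ind))
  lp <- as.numeric(ind[, use, drop = FALSE] %*% config$log_hr[use])
  sv <- config$survival
  surv_draw <- with_seed(subseeds[4], {
    st <- simulate_survival(lp, sv$shape, sv$scale, sv$horizon,
                            sv$censor_rate)
    st$available <- stats::rbinom(n, 1, cv$os_available) == 1
    st
  })
  has_os <- surv_draw$available
  clinical$os_months[has_os] <- pmax(round(surv_draw$time[has_os], 1), 0.1)
  clinical$os_event[has_os] <- surv_draw$event[has_os]

  ## 6. background gene landscape -------------------------------------------
  background <- with_seed(subseeds[5], {
    gp <- config$gene_probs
    hr <- status$best_eap53 == "high"
    rows <- list()
    for (i in seq_len(nrow(gp))) {
      p <- ifelse(hr, gp$p_hr[i], gp$p_ot[i])
      hit <- stats::rbinom(n, 1, p) == 1
      if (!any(hit)) next
      m <- sum(hit)
      cls <- sample(c("Missense_Mutation", "Nonsense_Mutation",
                      "Frame_Shift_Del"), m, replace = TRUE,
                    prob = c(0.8, 0.1, 0.1))
      pos <- sample.int(500L, m, replace = TRUE)
      ref <- sample(AA_CODES, m, replace = TRUE)
      alt <- sample(AA_CODES, m, replace = TRUE)
      change <- ifelse(cls == "Missense_Mutation", paste0(ref, pos, alt),
                ifelse(cls == "Nonsense_Mutation", paste0(ref, pos, "*"),
                       paste0(ref, pos, "fs")))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = ids[hit], gene = gp$gene[i], protein_change = change,
        variant_classification = cls, ea_score = NA_real_,
        stringsAsFactors = FALSE)
    }
    # silent passengers exercising TMB eligibility filtering
    sil <- stats::rbinom(n, 1, 0.3) == 1
    if (any(sil)) {
      m <- sum(sil)
      ref <- sample(AA_CODES, m, replace = TRUE)
      pos <- sample.int(500L, m, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = ids[sil],
        gene = sample(gp$gene, m, replace = TRUE),
        protein_change = paste0(ref, pos, ref),
        variant_classification = "Silent", ea_score = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  variants <- rbind(tp53[, c("patient_id", "gene", "protein_change",
                             "variant_classification", "ea_score")],
                    background)
  variants <- variants[order(variants$patient_id, variants$gene,
                             variants$protein_change), , drop = FALSE]
  rownames(variants) <- NULL

  truth <- data.frame(patient_id = ids,
                      tp53_mutant = status$has_mutation,
                      four_group = status$four_group,
                      eap53_high = status$best_eap53 == "high",
                      linear_predictor = lp,
                      stringsAsFactors = FALSE)
  structure(list(clinical = clinical, variants = variants, truth = truth,
                 config = config),
            class = "tp53_simulation")
}

#' Write a simulated cohort to tab-delimited files
#'
#' Emits \code{clinical.tsv}, \code{variants.tsv} and \code{truth.tsv} in
#' exactly the dialects [read_clinical_table()] and [read_variant_table()]
#' consume.  Output is byte-stable for a fixed config.
#'
#' @param sim a \code{tp53_simulation}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "tp53_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"),
             variants = file.path(dir, "variants.tsv"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(sim$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$variants, paths["variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
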