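# Kaplan-Meier estimation, log-rank comparison and Cox proportional-hazards
# modelling over a stratified cohort.  The numerical engines are the
# survival package's survfit/survdiff/coxph; this module owns validation,
# the analysis design (pre-combination checks, combined two-group
# comparisons, the adjusted multivariate model) and the report schema.

#' Kaplan-Meier product-limit estimate
#'
#' Censoring tied with an event time is processed after the events at that
#' time (the standard product-limit convention).
#'
#' @param time positive survival times (months).
#' @param event event indicators (1 death, 0 censored).
#' @return data.frame of class \code{km_curve}: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv}.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("at least one observation required",
                              call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("validation error: survival times must be positive", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("validation error: event indicator must be 0/1", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  attr(out, "n") <- length(time)
  out
}

#' k-group log-rank test
#'
#' @param time positive survival times.
#' @param event event indicators (1/0).
#' @param group grouping factor with at least two non-empty levels.
#' @return list: \code{statistic}, \code{df}, \code{p_value}, \code{n}.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) {
    stop("validation error: log-rank needs >= 2 non-empty groups",
         call. = FALSE)
  }
  if (any(table(group) == 0L)) {
    stop("validation error: empty group in log-rank comparison",
         call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("validation error: survival times must be positive", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  k <- nlevels(group)
  list(statistic = unname(sd$chisq), df = k - 1L,
       p_value = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE),
       n = length(time))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling by default
#' (Breslow available); Wald confidence intervals and p-values on the
#' log-hazard scale.  Non-convergence or separation is flagged on the fit,
#' not raised; a covariate constant across subjects is a validation error.
#'
#' @param data data.frame holding the time, event and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @param time_col,event_col column names for time and event.
#' @return list of class \code{cox_fit}: \code{terms} (data.frame with
#'   \code{term}, \code{coef}, \code{hr}, \code{ci_lower}, \code{ci_upper},
#'   \code{p_value}), \code{n}, \code{events}, \code{ties},
#'   \code{converged}.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow"),
                    time_col = "os_months", event_col = "os_event") {
  ties <- match.arg(ties)
  stopifnot(all(c(time_col, event_col, covariates) %in% names(data)))
  d <- data[stats::complete.cases(data[, c(time_col, event_col, covariates),
                                       drop = FALSE]), , drop = FALSE]
  for (cv in covariates) {
    v <- d[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      stop("validation error: covariate '", cv,
           "' is constant across subjects", call. = FALSE)
    }
  }
  n_events <- sum(d[[event_col]])
  if (n_events < length(covariates)) {
    stop("validation error: fewer events (", n_events,
         ") than covariates (", length(covariates), ")", call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|singular|beta may be", conditionMessage(w),
                ignore.case = TRUE)) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- fit$coefficients
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(0.975)
  terms <- data.frame(
    term = names(co), coef = unname(co), hr = exp(unname(co)),
    ci_lower = exp(unname(co) - z * se), ci_upper = exp(unname(co) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(co) / se)),
    stringsAsFactors = FALSE)
  structure(list(terms = terms, n = fit$n, events = n_events, ties = ties,
                 iterations = fit$iter,
                 converged = !flagged && all(is.finite(se))),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties), n=%d, events=%d%s\n", x$ties, x$n,
              x$events, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(transform(x$terms, hr = round(hr, 3), ci_lower = round(ci_lower, 3),
                  ci_upper = round(ci_upper, 3),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  invisible(x)
}

# Build the survival analysis frame: merge clinical + status, keep rows with
# OS data and positive time, derive the numeric covariates.
build_survival_frame <- function(clinical, status) {
  d <- merge(clinical, status, by = "patient_id")
  d <- d[!is.na(d$os_months) & !is.na(d$os_event), , drop = FALSE]
  nonpos <- d$os_months <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " observation(s) with non-positive os_months ",
            "excluded from survival analysis", call. = FALSE)
    d <- d[!nonpos, , drop = FALSE]
  }
  d$age_gt65 <- as.integer(d$age_years > 65)
  d$male <- as.integer(d$sex == "male")
  d$smoker <- as.integer(d$smoking == "smoker")
  d$egfr_mutant <- ifelse(d$egfr_status == "unknown", NA_integer_,
                          as.integer(d$egfr_status == "mutant"))
  d
}

scheme_exposure <- function(d, scheme) {
  switch(scheme,
    missense_vs_others      = as.integer(d$has_missense),
    nondisruptive_vs_others = as.integer(d$has_mutation & d$has_nondisruptive),
    exon8_vs_others         = as.integer(d$has_exon8),
    eap53_vs_others         = as.integer(d$best_eap53 == "high"),
    stop("unknown scheme '", scheme, "'", call. = FALSE))
}

# Pre-combination check: the complement subgroups compared before they are
# merged into the "others" arm (e.g. truncating vs WT under the missense
# scheme).
precheck_groups <- function(d, scheme) {
  rest <- d[scheme_exposure(d, scheme) == 0L, , drop = FALSE]
  grp <- switch(scheme,
    missense_vs_others =
      ifelse(rest$wild_type, "WT",
             ifelse(rest$has_truncating, "truncating", NA)),
    nondisruptive_vs_others =
      ifelse(rest$wild_type, "WT",
             ifelse(rest$has_mutation, "disruptive", NA)),
    exon8_vs_others =
      ifelse(rest$wild_type, "WT",
             ifelse(rest$has_mutation, "non-exon8 mutant", NA)),
    eap53_vs_others = ifelse(rest$four_group %in%
                               c("WT", "truncating", "EAp53 low-risk"),
                             rest$four_group, NA))
  keep <- !is.na(grp)
  list(data = rest[keep, , drop = FALSE], group = factor(grp[keep]))
}

#' Run the full survival analysis design
#'
#' For each dichotomous scheme: the pre-combination log-rank check among
#' the complement subgroups (e.g. truncating versus wild-type before they
#' are merged into "others"), the combined two-group log-rank, Kaplan-Meier
#' curves per group, a univariate Cox fit of the scheme indicator, and a
#' multivariate Cox fit adjusting for age > 65, sex, smoking and EGFR
#' status.  Schemes reduced to one group after filtering are skipped with a
#' warning.
#'
#' @param clinical validated clinical table (already filtered as desired).
#' @param status patient-level TP53 status.
#' @param schemes dichotomous schemes to run.
#' @param covariates adjustment covariates for the multivariate model.
#' @param ties Cox tie-handling method.
#' @return list of class \code{tp53_survival_report}.
#' @export
run_survival_analysis <- function(clinical, status,
                                  schemes = c("missense_vs_others",
                                              "nondisruptive_vs_others",
                                              "exon8_vs_others",
                                              "eap53_vs_others"),
                                  covariates = c("age_gt65", "male",
                                                 "smoker", "egfr_mutant"),
                                  ties = "efron") {
  d <- build_survival_frame(clinical, status)
  res <- list()
  for (sc in schemes) {
    expo <- scheme_exposure(d, sc)
    if (length(unique(expo)) < 2L) {
      warning("scheme '", sc, "' has a single group after filtering; skipped",
              call. = FALSE)
      res[[sc]] <- NULL
      next
    }
    d$exposure <- expo
    pre <- precheck_groups(d, sc)
    pre_res <- if (nlevels(droplevels(pre$group)) >= 2L) {
      logrank_test(pre$data$os_months, pre$data$os_event, pre$group)
    } else NULL
    lr <- logrank_test(d$os_months, d$os_event, factor(expo))
    km <- lapply(split(d, expo), function(g) {
      km_estimate(g$os_months, g$os_event)
    })
    names(km) <- ifelse(names(km) == "1", sc, "others")
    uni <- cox_fit(d, "exposure", ties = ties)
    multi <- cox_fit(d, c("exposure", covariates), ties = ties)
    res[[sc]] <- list(scheme = sc, n = nrow(d), events = sum(d$os_event),
                      precheck = pre_res, logrank = lr, km = km,
                      cox_univariate = uni, cox_multivariate = multi)
  }
  # four-group overall comparison (k-group log-rank)
  fg <- droplevels(factor(d$four_group))
  four <- if (nlevels(fg) >= 2L) {
    logrank_test(d$os_months, d$os_event, fg)
  } else NULL
  structure(list(schemes = res, four_group_logrank = four,
                 n = nrow(d), events = sum(d$os_event)),
            class = "tp53_survival_report")
}

#' @export
print.tp53_survival_report <- function(x, ...) {
  cat(sprintf("Survival analysis: n=%d, events=%d\n", x$n, x$events))
  for (sc in names(x$schemes)) {
    r <- x$schemes[[sc]]
    mt <- r$cox_multivariate$terms
    row <- mt[mt$term == "exposure", ]
    cat(sprintf(
      "  %-24s log-rank p=%.4g | HR(uni)=%.2f | HR(multi)=%.2f (%.2f-%.2f), p=%.3g\n",
      sc, r$logrank$p_value, r$cox_univariate$terms$hr[1],
      row$hr, row$ci_lower, row$ci_upper, row$p_value))
  }
  if (!is.null(x$four_group_logrank)) {
    cat(sprintf("  four-group log-rank: chi2=%.2f (df=%d), p=%.4g\n",
                x$four_group_logrank$statistic, x$four_group_logrank$df,
                x$four_group_logrank$p_value))
  }
  invisible(x)
}
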