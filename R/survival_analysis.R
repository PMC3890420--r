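#' Survival analysis with a random-signature hazard-ratio null
#'
#' Overall survival is analyzed with Kaplan-Meier curves, the Peto & Peto
#' modification of the Gehan-Wilcoxon test, and Cox proportional hazards
#' models whose covariates are the inferred polarization posteriors plus
#' molecular pathology. Because gene signatures fitted to outcome data are
#' prone to optimism, the hazard ratio of the Th1 posterior is compared
#' against an ensemble of random signature families of identical subset
#' sizes drawn from the same gene panel.
#'
#' @name survival-analysis
NULL

surv_check <- function(time, event) {
  if (any(time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate with Greenwood variance and log-transformed 95%
#' confidence interval, plus a number-at-risk table at regular intervals.
#'
#' @param time event/censoring times in months (> 0)
#' @param event 1 = event, 0 = censored
#' @param horizon truncate reporting at this time (default `max(time)`)
#' @param at_risk_every spacing of the at-risk table in months (default 12)
#' @return a `km_estimate`: data.frame `curve` (time, n_risk, n_event,
#'   survival, lower, upper), data.frame `at_risk` (time, n_risk), and the
#'   underlying [survival::survfit()] fit
#' @export
km_estimate <- function(time, event, horizon = max(time),
                        at_risk_every = 12) {
  surv_check(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log", conf.int = 0.95)
  keep <- fit$time <= horizon
  curve <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                      n_event = fit$n.event[keep],
                      survival = fit$surv[keep],
                      lower = fit$lower[keep], upper = fit$upper[keep])
  grid <- seq(0, horizon, by = at_risk_every)
  n_risk <- vapply(grid, function(t0) sum(time >= t0), 0L)
  structure(list(curve = curve,
                 at_risk = data.frame(time = grid, n_risk = n_risk),
                 fit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate, ", sum(x$curve$n_event), " events\n", sep = "")
  print(utils::head(x$curve))
  invisible(x)
}

#' Peto-Peto modified Gehan-Wilcoxon test
#'
#' Weighted log-rank test with Peto-Peto weights (the left-continuous
#' pooled survival estimate), emphasizing early differences; chi-square
#' p-value on 1 df. Degenerate inputs with no events in either group return
#' statistic 0, p = 1.
#'
#' @param time event/censoring times
#' @param event 1 = event, 0 = censored
#' @param group two-level grouping vector
#' @return list with `statistic` (chi-square), `p_value`, `n`, `observed`,
#'   `expected`
#' @export
peto_peto_test <- function(time, event, group) {
  surv_check(time, event)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(table(group) == 0L)) stop("empty group", call. = FALSE)
  if (sum(event) == 0) {
    return(list(statistic = 0, p_value = 1, n = length(time),
                observed = c(0, 0), expected = c(0, 0)))
  }
  sd1 <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 1)
  list(statistic = sd1$chisq,
       p_value = stats::pchisq(sd1$chisq, df = 1, lower.tail = FALSE),
       n = length(time), observed = sd1$obs, expected = sd1$exp)
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling (the default of
#' the R survival ecosystem); Wald confidence intervals and p-values per
#' covariate.
#'
#' @param data data.frame containing `os_months`, `os_event`, and the
#'   covariate columns
#' @param covariates character vector of covariate column names
#' @param ties `"efron"` (default) or `"breslow"`
#' @return a `cox_result`: data.frame `coefficients` (term, hr, lower,
#'   upper, p), `loglik`, `n`, `n_events`, and the [survival::coxph()] fit
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  surv_check(data$os_months, data$os_event)
  if (sum(data$os_event) < 2) stop("fewer than 2 events", call. = FALSE)
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2L) {
      stop("constant covariate: ", cv, call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(os_months, os_event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties)
  if (any(!is.finite(sqrt(diag(fit$var)))) ||
      any(abs(stats::coef(fit)) > 20)) {
    stop("monotone likelihood / complete separation suspected", call. = FALSE)
  }
  sf <- summary(fit)
  coefs <- data.frame(term = rownames(sf$coefficients),
                      hr = sf$conf.int[, "exp(coef)"],
                      lower = sf$conf.int[, "lower .95"],
                      upper = sf$conf.int[, "upper .95"],
                      p = sf$coefficients[, "Pr(>|z|)"],
                      row.names = NULL)
  structure(list(coefficients = coefs, loglik = fit$loglik[2L],
                 n = sf$n, n_events = sf$nevent, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional hazards: n = ", x$n, ", events = ", x$n_events,
      "\n", sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Random-signature hazard-ratio null ensemble
#'
#' For each of B replicates, genes are drawn without replacement from the
#' full panel gene list into K pseudo-subsets with the same cardinalities
#' as the reference family's exclusive sets (so pseudo-subsets are
#' disjoint, mirroring the mutual-exclusivity assumption). The per-sample
#' posterior of pseudo-subset 1 enters a Cox model alongside molecular
#' pathology, and its hazard ratio is collected. The one-sided empirical
#' p-value `(1 + #\{random HR <= observed HR\}) / (B + 1)` asks how often a
#' signature of identical size is at least as protective by chance.
#'
#' @param zm `zscore_matrix` covering the panel genes
#' @param clinical data.frame with `sample`, `pathology`, `os_months`,
#'   `os_event`; rows are matched to `colnames(zm)` by `sample`
#' @param panel_genes character vector to draw random signatures from
#'   (typically the full panel union present in `zm`)
#' @param reference_family reduced `signature_family` supplying the subset
#'   cardinalities and the observed model (its first subset is the type-1
#'   analog unless `observed_subset` says otherwise)
#' @param cfg an [inference_config()]
#' @param B ensemble size (default 1000)
#' @param seed integer seed
#' @param observed_subset subset name/index for the observed covariate
#'   (default `"Th1"` if present, else the first subset)
#' @return a `random_model_ensemble`: `hr` (replicate HRs, failures
#'   dropped), `observed_hr`, `p_value`, `n_failed`, `B`, `seed`, and the
#'   observed `cox_result`
#' @export
random_model_hr_ensemble <- function(zm, clinical, panel_genes,
                                     reference_family,
                                     cfg = inference_config(), B = 1000L,
                                     seed = 1L, observed_subset = NULL) {
  panel_genes <- intersect(canonical_symbol(panel_genes), rownames(zm))
  if (is.null(reference_family$exclusive)) {
    reference_family <- reduce_to_exclusive(reference_family)
  }
  cards <- lengths(reference_family$exclusive)
  if (sum(cards) > length(panel_genes)) {
    stop("panel gene list smaller than total exclusive cardinality",
         call. = FALSE)
  }
  clinical <- clinical[match(colnames(zm), clinical$sample), ]
  if (anyNA(clinical$sample)) {
    stop("clinical table lacks some z-matrix samples", call. = FALSE)
  }
  if (is.null(observed_subset)) {
    observed_subset <- if ("Th1" %in% names(cards)) "Th1" else 1L
  }
  use_pathology <- length(unique(clinical$pathology)) > 1L

  fit_hr <- function(p1) {
    df <- data.frame(os_months = clinical$os_months,
                     os_event = clinical$os_event,
                     posterior = p1, pathology = clinical$pathology)
    covs <- c("posterior", if (use_pathology) "pathology")
    cox_fit(df, covs)
  }

  post_obs <- posterior_matrix(zm, reference_family, cfg)
  obs_fit <- fit_hr(post_obs[, observed_subset])
  observed_hr <- obs_fit$coefficients$hr[
    obs_fit$coefficients$term == "posterior"]

  set.seed(seed)
  hrs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    picked <- sample(panel_genes, sum(cards))
    splits <- split(picked, rep(seq_along(cards), cards))
    fam <- signature_family(
      paste0("random", b),
      lapply(seq_along(splits), function(k) {
        gene_signature(paste0("R", k), splits[[k]], "random")
      }))
    fam <- reduce_to_exclusive(fam)
    p1 <- posterior_matrix(zm, fam, cfg)[, 1L]
    hrs[b] <- tryCatch({
      f <- fit_hr(p1)
      f$coefficients$hr[f$coefficients$term == "posterior"]
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(hrs))
  if (n_failed > 0) {
    message(n_failed, " of ", B, " replicate Cox fits failed and were ",
            "excluded")
  }
  hrs <- hrs[!is.na(hrs)]
  p_value <- (1 + sum(hrs <= observed_hr)) / (length(hrs) + 1)
  structure(list(hr = hrs, observed_hr = observed_hr, p_value = p_value,
                 n_failed = n_failed, B = B, seed = seed,
                 observed_fit = obs_fit),
            class = "random_model_ensemble")
}

#' @export
print.random_model_ensemble <- function(x, ...) {
  cat("random-signature HR ensemble: B = ", x$B, " (", x$n_failed,
      " failed), observed HR = ", round(x$observed_hr, 3),
      ", empirical p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}
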