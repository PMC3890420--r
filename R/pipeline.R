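#' End-to-end cohort pipeline
#'
#' Orchestrates the analysis stages on an expression matrix + clinical
#' table (or on a freshly generated synthetic cohort): normalization,
#' z-scoring, Ward clustering, infiltration scoring, polarization
#' inference with its bootstrap null, PCA, survival analysis with the
#' random-signature hazard-ratio ensemble, and cohort contingency
#' statistics. All stochastic stages derive from the single `seed`; rerun
#' with the same inputs and seed reproduces every number.
#'
#' @param expression an [expression_matrix()]; raw matrices are log2
#'   median-centered first
#' @param clinical clinical data.frame (see [read_clinical_table()]);
#'   `NULL` disables the survival stages
#' @param panel gene panel list (default packaged panel)
#' @param use_revised_th2 score T-helper polarization with the revised Th2
#'   signature (PPARG and IL6 removed)?
#' @param n_groups Ward tree cut (default 2)
#' @param a likelihood amplitude passed to [inference_config()]
#' @param B bootstrap replicates for the polarization null and the HR
#'   ensemble
#' @param n_cohort synthetic cohort size per null replicate
#' @param seed integer seed
#' @param output_dir if non-`NULL`, write stage-prefixed TSV/JSON outputs
#'   there
#' @return a `pipeline_result` list: `assignment`, `infiltration`,
#'   `posteriors`, `cohort_posteriors`, `null`, `null_pvalues`, `pca`,
#'   `km`, `peto_peto`, `cox`, `hr_ensemble`, `stats`, `seed`
#' @export
run_pipeline <- function(expression, clinical = NULL, panel = load_panel(),
                         use_revised_th2 = FALSE, n_groups = 2L, a = 1,
                         B = 1000L, n_cohort = 200L, seed = 1L,
                         output_dir = NULL) {
  stopifnot(inherits(expression, "expression_matrix"))
  if (!is.null(clinical)) {
    clinical <- validate_clinical(clinical)
    if (!all(colnames(expression) %in% clinical$sample)) {
      stop("clinical table lacks some expression samples", call. = FALSE)
    }
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  cfg <- inference_config(a = a)

  if (attr(expression, "scale") == "raw") {
    expression <- log2_median_center(expression)
  }
  panel_genes <- unique(unlist(lapply(panel, family_genes),
                               use.names = FALSE))
  m <- expression[intersect(panel_genes, rownames(expression)), ,
                  drop = FALSE]
  m <- expression_matrix(m, scale = "log2_median_ratio")
  zm <- zscore(m)

  assignment <- ward_cluster(m, n_groups = n_groups)
  membership <- paste0("group", assignment$groups[colnames(m)])
  if (!is.null(clinical)) {
    normal <- clinical$sample[clinical$pathology == "normal"]
    membership[colnames(m) %in% normal] <- "normal"
  }
  membership <- stats::setNames(membership, colnames(m))

  infil <- lapply(infiltration_markers(), function(mk) {
    suppressWarnings(infiltration_score(m, mk))
  })

  thfam <- if (use_revised_th2) revised_th2_family(panel) else
    panel[["Thelper"]]
  thfam <- restrict_family(reduce_to_exclusive(thfam), rownames(zm))
  mphfam <- restrict_family(reduce_to_exclusive(panel[["macrophage"]]),
                            rownames(zm))

  posteriors <- list(Thelper = posterior_matrix(zm, thfam, cfg),
                     macrophage = posterior_matrix(zm, mphfam, cfg))
  cohort_post <- list(
    Thelper = cohort_mean_posterior(zm, thfam, cfg, membership),
    macrophage = cohort_mean_posterior(zm, mphfam, cfg, membership))

  nulls <- list(
    Thelper = bootstrap_null(zm, thfam, cfg, n_cohort = n_cohort, B = B,
                             seed = seed),
    macrophage = bootstrap_null(zm, mphfam, cfg, n_cohort = n_cohort,
                                B = B, seed = seed + 1L))
  null_p <- lapply(names(nulls), function(fam) {
    cp <- cohort_post[[fam]]
    sapply(colnames(cp), function(sub) {
      sapply(rownames(cp), function(grp) {
        empirical_pvalue(cp[grp, sub], nulls[[fam]], sub)
      })
    })
  })
  names(null_p) <- names(nulls)

  pca <- pca_fit(m)

  km <- peto <- cox <- ensemble <- NULL
  if (!is.null(clinical)) {
    cl <- clinical[match(colnames(zm), clinical$sample), ]
    tum <- cl$pathology != "normal" & cl$os_months > 0
    cl_t <- cl[tum, ]
    grp_t <- membership[cl_t$sample]
    km <- km_estimate(cl_t$os_months, cl_t$os_event)
    if (length(unique(grp_t)) == 2L) {
      peto <- peto_peto_test(cl_t$os_months, cl_t$os_event, grp_t)
    }
    df <- data.frame(os_months = cl_t$os_months, os_event = cl_t$os_event,
                     p_th1 = posteriors$Thelper[cl_t$sample, 1L],
                     pathology = cl_t$pathology)
    covs <- c("p_th1", if (length(unique(df$pathology)) > 1L) "pathology")
    cox <- tryCatch(cox_fit(df, covs), error = function(e) {
      message("Cox stage skipped: ", conditionMessage(e)); NULL
    })
    zt <- zm[, cl_t$sample, drop = FALSE]
    class(zt) <- class(zm)
    ensemble <- tryCatch(
      random_model_hr_ensemble(zt, cl_t, rownames(zm), thfam, cfg, B = B,
                               seed = seed + 2L),
      error = function(e) {
        message("HR ensemble skipped: ", conditionMessage(e)); NULL
      })
  }

  stats_out <- NULL
  if (!is.null(clinical)) {
    cl <- clinical[match(colnames(zm), clinical$sample), ]
    tum <- cl$pathology != "normal"
    grp <- membership[cl$sample][tum]
    tn <- cl$pathology[tum] == "TN"
    n_cohort_t <- sum(tum); k_cohort_t <- sum(tn)
    per_group <- lapply(sort(unique(grp)), function(g) {
      kk <- sum(tn[grp == g]); nn <- sum(grp == g)
      or <- tryCatch(odds_ratio_vs_cohort(kk, nn, k_cohort_t, n_cohort_t),
                     error = function(e) NULL)
      list(group = g, n = nn, tn = kk, odds_ratio = or)
    })
    stats_out <- list(tn_odds_ratios = per_group)
  }

  res <- structure(list(assignment = assignment, membership = membership,
                        infiltration = infil, posteriors = posteriors,
                        cohort_posteriors = cohort_post, null = nulls,
                        null_pvalues = null_p, pca = pca, km = km,
                        peto_peto = peto, cox = cox,
                        hr_ensemble = ensemble, stats = stats_out,
                        seed = seed),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_outputs(res, output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (seed ", x$seed, ")\n", sep = "")
  print(x$assignment)
  cat("cohort-mean T-helper posteriors:\n")
  print(round(x$cohort_posteriors$Thelper, 3))
  if (!is.null(x$cox)) print(x$cox)
  if (!is.null(x$hr_ensemble)) print(x$hr_ensemble)
  invisible(x)
}

write_pipeline_outputs <- function(res, dir) {
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(data.frame(sample = names(res$membership), group = res$membership),
     "cluster_assignment.tsv")
  wt(data.frame(sample = rownames(res$posteriors$Thelper),
                res$posteriors$Thelper, check.names = FALSE),
     "polarization_thelper.tsv")
  wt(data.frame(sample = rownames(res$posteriors$macrophage),
                res$posteriors$macrophage, check.names = FALSE),
     "polarization_macrophage.tsv")
  wt(data.frame(res$null$Thelper$replicates, check.names = FALSE),
     "null_thelper_replicates.tsv")
  wt(data.frame(gene = rownames(res$pca$loadings),
                res$pca$loadings[, seq_len(min(10L, ncol(res$pca$loadings))),
                                 drop = FALSE], check.names = FALSE),
     "pca_loadings.tsv")
  summary_json <- list(
    seed = res$seed,
    group_sizes = as.list(table(res$membership)),
    cohort_posteriors = lapply(res$cohort_posteriors, function(m)
      as.data.frame(m)),
    null_pvalues = lapply(res$null_pvalues, function(m) as.data.frame(m)),
    cox = if (!is.null(res$cox)) res$cox$coefficients,
    hr_ensemble = if (!is.null(res$hr_ensemble)) list(
      observed_hr = res$hr_ensemble$observed_hr,
      p_value = res$hr_ensemble$p_value,
      n_failed = res$hr_ensemble$n_failed))
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
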