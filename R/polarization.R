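#' Bayesian inference of immune cell polarization
#'
#' Polarization of the immune cells in a homogenized tissue sample is
#' treated as model selection among the K mutually exclusive subsets of a
#' signature family. Each subset model M_k predicts its own exclusive genes
#' at a target z-score of +a and every other subset's exclusive genes at -a;
#' the likelihood of the observed per-gene z-scores under M_k is a product
#' of Gaussian kernels around those targets,
#'
#'   L_k = exp( -1/2 * sum_{g in E_k} (z_g - a)^2
#'              -1/2 * sum_{j != k} sum_{g in E_j} (z_g + a)^2 ),
#'
#' and the posterior follows from Bayes' rule with (by default uniform)
#' priors. Posteriors depend on the data only through `2a * sum(z)` over
#' each exclusive set, so they are invariant to any common rescaling of the
#' likelihoods. Cohort-level significance is assessed against an empirical
#' null built by bootstrap resampling of the pooled z-values.
#'
#' @name polarization-inference
NULL

#' Inference configuration
#'
#' @param a target |z| for signature genes (amplitude of the expected
#'   expression shift, in z-score units); default 1
#' @param prior per-model prior probabilities; default uniform `1/K`
#'   (resolved once K is known)
#' @param use_exclusive score on the mutually exclusive gene sets (default
#'   `TRUE`); `FALSE` scores the full subset gene lists
#' @return an `inference_config` list
#' @export
inference_config <- function(a = 1, prior = NULL, use_exclusive = TRUE) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop("amplitude a must be a positive scalar", call. = FALSE)
  }
  if (!is.null(prior)) {
    if (any(prior <= 0)) stop("priors must be positive", call. = FALSE)
    if (abs(sum(prior) - 1) > 1e-8) stop("priors must sum to 1", call. = FALSE)
  }
  structure(list(a = a, prior = prior, use_exclusive = use_exclusive),
            class = "inference_config")
}

# Gene sets actually scored, as a named list over subsets.
scored_sets <- function(family, cfg) {
  if (cfg$use_exclusive) {
    if (is.null(family$exclusive)) family <- reduce_to_exclusive(family)
    family$exclusive
  } else {
    lapply(family$subsets, `[[`, "genes")
  }
}

resolve_prior <- function(cfg, K) {
  if (is.null(cfg$prior)) rep(1 / K, K)
  else if (length(cfg$prior) != K) {
    stop("prior length ", length(cfg$prior), " != K = ", K, call. = FALSE)
  } else cfg$prior
}

#' Likelihood of one subset model for one sample
#'
#' @param z named numeric vector of per-gene z-scores covering all scored
#'   genes of the family
#' @param family a `signature_family`
#' @param k subset index or name
#' @param cfg an [inference_config()]
#' @return positive scalar likelihood L_k
#' @export
subset_likelihood <- function(z, family, k, cfg = inference_config()) {
  exp(subset_loglik(z, family, cfg)[[k]])
}

# Log-likelihoods of all K models for one sample (full quadratic form).
subset_loglik <- function(z, family, cfg) {
  sets <- scored_sets(family, cfg)
  genes <- unlist(sets, use.names = FALSE)
  miss <- setdiff(genes, names(z))
  if (length(miss)) {
    stop("z-scores missing for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vapply(seq_along(sets), function(k) {
    own <- z[sets[[k]]]
    oth <- z[unlist(sets[-k], use.names = FALSE)]
    -0.5 * sum((own - cfg$a)^2) - 0.5 * sum((oth + cfg$a)^2)
  }, 0)
}

#' Posterior probability of polarization for one sample
#'
#' `p_k = L_k pi_k / sum_j L_j pi_j`, computed in log space so finite
#' z-scores never underflow to an undefined posterior.
#'
#' @inheritParams subset_likelihood
#' @return named simplex vector over the K subsets
#' @export
polarization_posterior <- function(z, family, cfg = inference_config()) {
  ll <- subset_loglik(z, family, cfg)
  pr <- resolve_prior(cfg, length(ll))
  lp <- ll + log(pr)
  w <- exp(lp - max(lp))
  stats::setNames(w / sum(w), names(scored_sets(family, cfg)))
}

#' Posterior probabilities for every sample of a z matrix
#'
#' Vectorized over samples: the log-likelihood differences reduce to
#' `2a * colSums(z over each exclusive set)` plus a per-sample constant
#' common to all models, which cancels in the posterior.
#'
#' @param zm a `zscore_matrix` (genes x samples) covering the scored genes
#' @param family a `signature_family`
#' @param cfg an [inference_config()]
#' @return samples x K matrix of posterior probabilities (rows on the
#'   simplex)
#' @export
posterior_matrix <- function(zm, family, cfg = inference_config()) {
  sets <- scored_sets(family, cfg)
  genes <- unlist(sets, use.names = FALSE)
  miss <- setdiff(genes, rownames(zm))
  if (length(miss)) {
    stop("z matrix lacks gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  K <- length(sets)
  pr <- resolve_prior(cfg, K)
  # S[k, i] = sum of z over E_k for sample i
  S <- do.call(rbind, lapply(sets, function(g) {
    colSums(zm[g, , drop = FALSE])
  }))
  lp <- 2 * cfg$a * S + log(pr)       # K x n, up to a per-sample constant
  lp <- sweep(lp, 2L, apply(lp, 2L, max))
  w <- exp(lp)
  post <- t(sweep(w, 2L, colSums(w), `/`))
  dimnames(post) <- list(colnames(zm), names(sets))
  post
}

#' Cohort-mean polarization posteriors
#'
#' Arithmetic mean of the per-sample posteriors within each cohort.
#'
#' @inheritParams posterior_matrix
#' @param membership factor/character vector over samples giving cohort
#'   labels (names or order matching `colnames(zm)`)
#' @return cohorts x K matrix of mean posteriors (rows on the simplex)
#' @export
cohort_mean_posterior <- function(zm, family, cfg = inference_config(),
                                  membership) {
  if (length(membership) != ncol(zm)) {
    stop("membership length != number of samples", call. = FALSE)
  }
  if (!is.null(names(membership))) {
    membership <- membership[colnames(zm)]
  }
  membership <- as.factor(membership)
  if (any(table(membership) == 0L)) stop("empty cohort", call. = FALSE)
  post <- posterior_matrix(zm, family, cfg)
  means <- apply(post, 2L, function(p) tapply(p, membership, mean))
  if (nlevels(membership) == 1L) {
    means <- matrix(means, nrow = 1L,
                    dimnames = list(levels(membership), colnames(post)))
  }
  means
}

#' Bootstrap null distribution of cohort-mean posteriors
#'
#' Pools *all* z-values of the matrix and, for each of B replicates, builds
#' a synthetic cohort of `n_cohort` samples by drawing one pooled value per
#' scored gene with replacement. The replicate statistic is the cohort-mean
#' posterior vector; under this null the gene values carry no polarization
#' information, so the distribution quantifies how far random expression
#' drifts from the prior.
#'
#' @inheritParams posterior_matrix
#' @param n_cohort synthetic cohort size per replicate (default 200)
#' @param B number of bootstrap replicates (default 1000)
#' @param seed integer seed; every draw is derived from it
#' @return a `polarization_null` list: `replicates` (B x K matrix), `kde`
#'   (per-subset [stats::density()] with Silverman bandwidth), `B`,
#'   `n_cohort`, `seed`
#' @export
bootstrap_null <- function(zm, family, cfg = inference_config(),
                           n_cohort = 200L, B = 1000L, seed = 1L) {
  stopifnot(B >= 1L, n_cohort >= 1L, length(zm) > 0L)
  sets <- scored_sets(family, cfg)
  genes <- unlist(sets, use.names = FALSE)
  pool <- as.numeric(zm)
  set.seed(seed)
  reps <- matrix(NA_real_, B, length(sets),
                 dimnames = list(NULL, names(sets)))
  for (b in seq_len(B)) {
    draw <- matrix(sample(pool, n_cohort * length(genes), replace = TRUE),
                   nrow = length(genes),
                   dimnames = list(genes, seq_len(n_cohort)))
    class(draw) <- c("zscore_matrix", "matrix", "array")
    reps[b, ] <- colMeans(posterior_matrix(draw, family, cfg))
  }
  kde <- if (B >= 2L) {
    apply(reps, 2L, function(v) {
      if (stats::sd(v) == 0) NULL else stats::density(v, bw = "nrd0")
    }, simplify = FALSE)
  } else NULL
  structure(list(replicates = reps, kde = kde, B = B, n_cohort = n_cohort,
                 seed = seed),
            class = "polarization_null")
}

#' @export
print.polarization_null <- function(x, ...) {
  cat("polarization bootstrap null: B = ", x$B, ", n_cohort = ", x$n_cohort,
      ", seed = ", x$seed, "\n", sep = "")
  print(round(colMeans(x$replicates), 4))
  invisible(x)
}

#' Empirical p-value against a bootstrap null
#'
#' One-sided add-one rule: `p = (1 + #\{null >= observed\}) / (B + 1)`; the
#' probability that the observed cohort-mean posterior, or a more extreme
#' value, arises from polarization-free expression.
#'
#' @param observed observed cohort-mean posterior for one subset
#' @param null a `polarization_null`
#' @param subset subset name or index to compare against
#' @return p-value in (0, 1]
#' @export
empirical_pvalue <- function(observed, null, subset = 1L) {
  v <- null$replicates[, subset]
  (1 + sum(v >= observed)) / (length(v) + 1)
}
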