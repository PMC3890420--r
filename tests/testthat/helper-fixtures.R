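# Shared fixtures: tiny families, z matrices, and the independent
# direct-evaluation oracle for the polarization posterior.

# K = 2 family with one gene per subset.
toy_family <- function() {
  reduce_to_exclusive(signature_family("toy", list(
    gene_signature("A", "G1", "toy"),
    gene_signature("B", "G2", "toy"))))
}

# Symmetric family: K subsets, `per` disjoint genes each.
sym_family <- function(K = 4L, per = 3L) {
  genes <- sprintf("X%02d", seq_len(K * per))
  subsets <- lapply(seq_len(K), function(k) {
    gene_signature(paste0("S", k), genes[(k - 1L) * per + seq_len(per)],
                   "sym")
  })
  reduce_to_exclusive(signature_family("sym", subsets))
}

# Random z matrix with the zscore_matrix class, genes x n.
rand_zm <- function(genes, n, sd = 1) {
  z <- matrix(rnorm(length(genes) * n, sd = sd), length(genes), n,
              dimnames = list(genes, sprintf("s%03d", seq_len(n))))
  structure(z, class = c("zscore_matrix", "matrix", "array"))
}

# Independent oracle: literal product of per-gene Gaussian kernels,
# exp(-(z - a)^2 / 2) for own-subset genes and exp(-(z + a)^2 / 2) for the
# other subsets' genes, normalized by Bayes' rule. No log-space tricks.
naive_posterior <- function(z, family, a = 1, prior = NULL) {
  sets <- family$exclusive
  K <- length(sets)
  if (is.null(prior)) prior <- rep(1 / K, K)
  lik <- vapply(seq_len(K), function(k) {
    own <- prod(exp(-(z[sets[[k]]] - a)^2 / 2))
    oth <- prod(exp(-(z[unlist(sets[-k])] + a)^2 / 2))
    own * oth
  }, 0)
  p <- lik * prior
  stats::setNames(p / sum(p), names(sets))
}

# Small log-ratio expression matrix fixture.
toy_expression <- function(values, genes, samples) {
  expression_matrix(matrix(values, length(genes), length(samples),
                           dimnames = list(genes, samples)),
                    scale = "log2_median_ratio")
}

# Synthetic survival data: two exponential arms with a given hazard ratio.
two_arm_surv <- function(n_per_arm, hr, base = 0.05, cens = 0.02) {
  grp <- rep(c("a", "b"), each = n_per_arm)
  haz <- ifelse(grp == "a", base, base * hr)
  t_ev <- rexp(2 * n_per_arm, haz)
  t_cn <- rexp(2 * n_per_arm, cens)
  data.frame(os_months = pmin(t_ev, t_cn),
             os_event = as.integer(t_ev <= t_cn), group = grp)
}
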