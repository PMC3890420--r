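test_that("hand-evaluated two-model case matches the stated likelihood", {
  fam <- toy_family()
  cfg <- inference_config(a = 1)
  z <- c(G1 = 1, G2 = 0)
  expect_equal(subset_likelihood(z, fam, 1, cfg), exp(-0.5), tolerance = 1e-12)
  expect_equal(subset_likelihood(z, fam, 2, cfg), exp(-2.5), tolerance = 1e-12)
  post <- polarization_posterior(z, fam, cfg)
  expect_equal(unname(post), c(1 / (1 + exp(-2)), exp(-2) / (1 + exp(-2))),
               tolerance = 1e-12)
  # z at the model's own target gives the maximal likelihood of 1
  expect_equal(subset_likelihood(c(G1 = 1, G2 = -1), fam, 1, cfg), 1)
})

test_that("symmetric data yields the uniform posterior", {
  fam <- sym_family(4L, 3L)
  z <- setNames(rep(0, 12), unlist(fam$exclusive))
  post <- polarization_posterior(z, fam)
  expect_equal(unname(post), rep(0.25, 4), tolerance = 1e-12)
  lik <- vapply(1:4, function(k) subset_likelihood(z, fam, k), 0)
  expect_equal(max(lik) - min(lik), 0, tolerance = 1e-15)
})

test_that("log-space posterior equals the naive oracle on random inputs", {
  set.seed(11)
  for (i in 1:100) {
    K <- sample(2:4, 1)
    per <- sample(1:4, 1)
    fam <- sym_family(K, per)
    genes <- unlist(fam$exclusive)
    z <- setNames(rnorm(length(genes), sd = 2), genes)
    a <- runif(1, 0.5, 2)
    cfg <- inference_config(a = a)
    post <- polarization_posterior(z, fam, cfg)
    expect_equal(unname(post), unname(naive_posterior(z, fam, a = a)),
                 tolerance = 1e-10)
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_true(all(post >= 0))
  }
})

test_that("posterior is equivariant under subset relabeling", {
  fam <- sym_family(3L, 2L)
  genes <- unlist(fam$exclusive)
  z <- setNames(rnorm(6), genes)
  post <- polarization_posterior(z, fam)
  # swap subsets 1 and 2 together with their gene values
  perm <- fam
  perm$subsets <- fam$subsets[c(2, 1, 3)]
  perm$exclusive <- fam$exclusive[c(2, 1, 3)]
  expect_equal(unname(polarization_posterior(z, perm, inference_config())),
               unname(post[c(2, 1, 3)]), tolerance = 1e-12)
})

test_that("own-gene z-score increases the subset posterior monotonically", {
  fam <- sym_family(4L, 3L)
  genes <- unlist(fam$exclusive)
  zs <- seq(-2, 2, by = 0.25)
  p1 <- vapply(zs, function(v) {
    z <- setNames(rep(0, 12), genes)
    z[fam$exclusive$S1[1]] <- v
    polarization_posterior(z, fam)[["S1"]]
  }, 0)
  expect_true(all(diff(p1) > 0))
})

test_that("vectorized posteriors match per-sample evaluation", {
  fam <- sym_family(4L, 2L)
  zm <- rand_zm(unlist(fam$exclusive), 25)
  cfg <- inference_config(a = 1.3)
  pm <- posterior_matrix(zm, fam, cfg)
  expect_equal(dim(pm), c(25L, 4L))
  expect_equal(unname(rowSums(pm)), rep(1, 25), tolerance = 1e-12)
  for (i in c(1, 13, 25)) {
    expect_equal(unname(pm[i, ]),
                 unname(polarization_posterior(zm[, i], fam, cfg)),
                 tolerance = 1e-12)
  }
  expect_error(posterior_matrix(zm[-1, , drop = FALSE], fam, cfg),
               "lacks gene")
})

test_that("cohort means average the per-sample posteriors", {
  fam <- toy_family()
  zm <- rand_zm(c("G1", "G2"), 4)
  pm <- posterior_matrix(zm, fam)
  cm <- cohort_mean_posterior(zm, fam,
                              membership = c("a", "a", "b", "b"))
  expect_equal(unname(cm["a", ]), unname((pm[1, ] + pm[2, ]) / 2),
               tolerance = 1e-12)
  single <- cohort_mean_posterior(zm[, 1, drop = FALSE], fam,
                                  membership = "solo")
  expect_equal(unname(single[1, ]), unname(pm[1, ]), tolerance = 1e-12)
  expect_error(cohort_mean_posterior(zm, fam,
                                     membership = factor(rep("a", 4),
                                                         levels = c("a", "b"))),
               "empty cohort")
})

test_that("planted Th1 bias is recovered as the cohort argmax", {
  # z-scores are cohort-relative, so the biased group needs an unbiased
  # contrast group in the same cohort
  cfg0 <- synthetic_cohort_config(
    n_normal = 50L, n_group1 = 0L, n_group2 = 50L,
    amplitudes = list(group2 = c(Th1 = 1.5)), seed = 1L)
  cc <- generate_cohort(cfg0)
  zm <- suppressWarnings(zscore(cc$expression))
  th <- reduce_to_exclusive(load_panel()$Thelper)
  cm <- cohort_mean_posterior(zm, th, membership = cc$clinical$group)
  expect_identical(colnames(cm)[which.max(cm["group2", ])], "Th1")
})

test_that("bootstrap null is seeded, simplex-valued, and calibrated", {
  fam <- sym_family(4L, 2L)
  zm <- rand_zm(unlist(fam$exclusive), 30)
  n1 <- bootstrap_null(zm, fam, n_cohort = 20, B = 1, seed = 5)
  expect_equal(dim(n1$replicates), c(1L, 4L))
  expect_equal(sum(n1$replicates), 1, tolerance = 1e-12)
  n2 <- bootstrap_null(zm, fam, n_cohort = 50, B = 40, seed = 9)
  n3 <- bootstrap_null(zm, fam, n_cohort = 50, B = 40, seed = 9)
  expect_identical(n2$replicates, n3$replicates)
  expect_equal(unname(rowSums(n2$replicates)), rep(1, 40),
               tolerance = 1e-12)
})

test_that("empirical p-values follow the add-one convention", {
  null <- list(replicates = matrix(seq(0.001, 1, length.out = 1000),
                                   ncol = 1, dimnames = list(NULL, "S1")))
  class(null) <- "polarization_null"
  expect_equal(empirical_pvalue(2, null, "S1"), 1 / 1001)
  p_med <- empirical_pvalue(median(null$replicates[, 1]), null, "S1")
  expect_equal(p_med, 0.5, tolerance = 0.01)
  expect_equal(empirical_pvalue(-1, null, "S1"), 1)
})
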