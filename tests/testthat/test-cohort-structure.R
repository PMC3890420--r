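make_expr <- function(x) {
  expression_matrix(x, scale = "log2_median_ratio")
}

test_that("Ward clustering separates well-separated samples", {
  x <- matrix(c(0, 1, 10, 11), 1, 4,
              dimnames = list("G1", c("s1", "s2", "s3", "s4")))
  asg <- ward_cluster(make_expr(x), n_groups = 2)
  expect_equal(unname(asg$groups[c("s1", "s2")]),
               rep(asg$groups[["s1"]], 2))
  expect_equal(unname(asg$groups[c("s3", "s4")]),
               rep(asg$groups[["s3"]], 2))
  expect_false(asg$groups[["s1"]] == asg$groups[["s3"]])
  # n_groups = n gives singletons; n_groups > n errors
  expect_equal(sort(unname(ward_cluster(make_expr(x), 4)$groups)), 1:4)
  expect_error(ward_cluster(make_expr(x), 5), "exceeds")
})

test_that("two-group cut matches the exhaustive minimum within-SS split", {
  set.seed(3)
  x <- matrix(rnorm(16), 2, 8)
  x[, 5:8] <- x[, 5:8] + 4        # two well-separated blobs
  dimnames(x) <- list(c("G1", "G2"), sprintf("s%d", 1:8))
  asg <- ward_cluster(make_expr(x), 2)
  wss <- function(idx) {
    sum(apply(x[, idx, drop = FALSE], 1, function(v) sum((v - mean(v))^2)))
  }
  best <- Inf; best_set <- NULL
  for (code in 1:(2^7 - 1)) {          # all 2-partitions, s1 fixed in side A
    side <- c(TRUE, as.logical(bitwAnd(code, 2^(0:6))))
    tot <- wss(which(side)) + wss(which(!side))
    if (tot < best) { best <- tot; best_set <- side }
  }
  got <- asg$groups == asg$groups[["s1"]]
  expect_true(identical(unname(got), best_set) ||
                identical(unname(got), !best_set))
})

test_that("clustering is order-invariant and largest group is group 1", {
  set.seed(8)
  x <- matrix(rnorm(30), 3, 10)
  x[, 1:7] <- x[, 1:7] + 5
  dimnames(x) <- list(paste0("G", 1:3), sprintf("s%02d", 1:10))
  a1 <- ward_cluster(make_expr(x), 2)
  perm <- sample(10)
  a2 <- ward_cluster(make_expr(x[, perm]), 2)
  expect_identical(a1$groups, a2$groups[names(a1$groups)])
  expect_equal(sum(a1$groups == 1L), 7L)   # largest cluster labeled 1
  expect_true(all(diff(a1$tree$height) >= -1e-12))
})

test_that("infiltration score averages marker genes per sample", {
  x <- rbind(KLRD1 = c(1, 0), KLRC2 = c(2, 0), KLRC3 = c(3, 6))
  colnames(x) <- c("s1", "s2")
  m <- make_expr(x)
  expect_equal(unname(infiltration_score(m, c("KLRD1", "KLRC2", "KLRC3"))),
               c(2, 2))
  expect_warning(sc <- infiltration_score(m, c("KLRD1", "KLRC2", "CD3E")),
                 "CD3E")
  expect_equal(unname(sc), c(1.5, 0))
  expect_error(infiltration_score(m, "CD14"), "no marker")
})

test_that("planted infiltration offset is recovered in group means", {
  cfg <- synthetic_cohort_config(n_normal = 100L, n_group1 = 0L,
                                 n_group2 = 100L, seed = 4L)
  cc <- generate_cohort(cfg)
  sc <- infiltration_score(cc$expression,
                           unlist(infiltration_markers()))
  diff_means <- mean(sc[cc$clinical$group == "group2"]) -
    mean(sc[cc$clinical$group == "normal"])
  # planted offset 1.0; se of the difference ~ sqrt(2/(11*100))
  expect_equal(diff_means, 1.0, tolerance = 3 * sqrt(2 / 1100))
})

test_that("PCA recovers closed-form structure and is orthonormal", {
  set.seed(21)
  # build samples whose *sample* covariance is exactly [[2,1],[1,2]],
  # giving eigenvalues 3 and 1 in closed form
  y <- scale(matrix(rnorm(4000), 2000, 2), TRUE, FALSE)
  y <- y %*% solve(chol(cov(y)))           # whitened: cov(y) = I
  x <- t(y %*% chol(matrix(c(2, 1, 1, 2), 2)))
  dimnames(x) <- list(c("GA", "GB"), sprintf("s%04d", 1:2000))
  pca <- pca_fit(make_expr(x))
  expect_equal(pca$variance_fraction[1], 3 / 4, tolerance = 1e-10)
  expect_equal(abs(unname(pca$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
  expect_true(all(pca$loadings[cbind(apply(abs(pca$loadings), 2, which.max),
                                     1:2)] > 0))
  expect_equal(crossprod(pca$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-10)
})

test_that("kept components reconstruct the centered matrix", {
  set.seed(5)
  x <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("G", 1:6), sprintf("s%02d", 1:10)))
  pca <- pca_fit(make_expr(x))
  recon <- pca$scores %*% t(pca$loadings) +
    rep(pca$center, each = 10)
  expect_equal(unname(recon), unname(t(x)), tolerance = 1e-8)
  expect_error(pca_fit(make_expr(matrix(1, 2, 3,
                                        dimnames = list(c("A", "B"),
                                                        c("x", "y", "z"))))),
               "degenerate")
})

test_that("bootstrap noise thresholds are seeded and well calibrated", {
  set.seed(31)
  x <- matrix(rnorm(1200), 6, 200,
              dimnames = list(paste0("G", 1:6), sprintf("s%03d", 1:200)))
  m <- make_expr(x)
  pca <- pca_fit(m)
  th1 <- pca_noise_thresholds(m, pca, B = 2000, seed = 2)
  th2 <- pca_noise_thresholds(m, pca, B = 2000, seed = 2)
  expect_identical(th1$projections, th2$projections)
  expect_equal(unname(th1$radii["3sd", ] / th1$sd), rep(3, 6))
  # Gaussian pool: ~99.7% of projections inside 3 sd per component
  inside <- abs(th1$projections[, 1] - th1$median[1]) < th1$radii["3sd", 1]
  expect_gt(mean(inside), 0.99)
  # zero-variance pool degenerates to a point
  const <- make_expr(matrix(0, 6, 4, dimnames = list(paste0("G", 1:6),
                                                     paste0("s", 1:4))))
  th0 <- pca_noise_thresholds(const, pca, B = 50, seed = 1)
  expect_equal(max(th0$radii), 0)
})

test_that("projection onto loadings reproduces training scores", {
  set.seed(12)
  x <- matrix(rnorm(80), 8, 10,
              dimnames = list(paste0("G", 1:8), sprintf("s%02d", 1:10)))
  m <- make_expr(x)
  pca <- pca_fit(m)
  proj <- project_onto_loadings(m, pca)
  expect_equal(unname(proj), unname(pca$scores), tolerance = 1e-10)
  dup <- x[, c(3, 3), drop = FALSE]
  colnames(dup) <- c("d1", "d2")
  pd <- project_onto_loadings(make_expr(dup), pca)
  expect_equal(unname(pd[1, ]), unname(pca$scores[3, ]), tolerance = 1e-10)
  expect_warning(project_onto_loadings(
    make_expr(x[1:5, , drop = FALSE]), pca), "contribute 0")
  expect_error(project_onto_loadings(
    make_expr(x[1:3, , drop = FALSE]), pca), "50%")
})
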