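#' Cohort structure: Ward clustering, infiltration scores, PCA
#'
#' Patient cohorts are identified by agglomerative clustering of samples on
#' the immune gene panel (Ward criterion on Euclidean distances), immune
#' infiltration is summarized as the mean log-ratio over NK / T cell /
#' macrophage marker genes, and the variance structure of the panel is
#' characterized by PCA with bootstrap noise thresholds and projection of
#' external studies onto the fitted loadings.
#'
#' @name cohort-structure
NULL

#' Ward hierarchical clustering of samples
#'
#' Samples are ordered lexicographically by id before clustering so the
#' assignment is invariant to input order; groups from the tree cut are
#' relabeled by decreasing size (largest = group 1, matching the convention
#' that the dominant cohort is group 1).
#'
#' @param m an [expression_matrix()] on the `log2_median_ratio` scale,
#'   typically restricted to panel genes
#' @param n_groups number of groups to cut the tree into
#' @param method `"ward.D2"` (Ward criterion on Euclidean distances,
#'   default) or `"ward.D"` (on squared distances)
#' @return a `cohort_assignment`: list with `groups` (named integer vector,
#'   1-based group per sample), `tree` (the [stats::hclust()] object),
#'   `sizes`
#' @export
ward_cluster <- function(m, n_groups = 2L, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (n_groups > ncol(m)) {
    stop("n_groups exceeds number of samples", call. = FALSE)
  }
  x <- unclass(m)[, order(colnames(m)), drop = FALSE]
  tree <- stats::hclust(stats::dist(t(x)), method = method)
  cut <- stats::cutree(tree, k = n_groups)
  # relabel by decreasing size; ties broken by original label order
  sizes <- table(cut)
  relabel <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                             names(sizes))
  groups <- stats::setNames(as.integer(relabel[as.character(cut)]),
                            names(cut))
  structure(list(groups = groups, tree = tree,
                 sizes = as.integer(table(groups))),
            class = "cohort_assignment")
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat("cohort_assignment: ", length(x$groups), " samples in ",
      length(x$sizes), " groups (sizes ",
      paste(x$sizes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Default infiltration marker sets
#'
#' NK cell, T cell, and macrophage recruitment markers whose mean
#' log2 median-centered expression summarizes immune infiltration.
#'
#' @return named list of gene symbol vectors
#' @export
infiltration_markers <- function() {
  list(NK = c("KLRD1", "KLRC2", "KLRC3"),
       Tcell = c("CD247", "CD3G", "CD3D", "CD3E"),
       macrophage = c("CD14", "CPM", "MRC1", "ITGAM"))
}

#' Immune infiltration score per sample
#'
#' Arithmetic mean of the log2 median-centered values over the marker genes
#' present in the matrix. Markers absent from the matrix are dropped with a
#' warning; an error is raised only when none remain.
#'
#' @param m an [expression_matrix()] on the `log2_median_ratio` scale
#' @param markers character vector of marker gene symbols (e.g. one element
#'   of [infiltration_markers()], or their union)
#' @return named numeric vector, one score per sample
#' @export
infiltration_score <- function(m, markers) {
  markers <- canonical_symbol(markers)
  present <- intersect(markers, rownames(m))
  if (length(present) == 0L) {
    stop("no marker gene present in matrix", call. = FALSE)
  }
  if (length(present) < length(markers)) {
    warning("marker(s) absent from matrix: ",
            paste(setdiff(markers, present), collapse = ", "), call. = FALSE)
  }
  colMeans(unclass(m)[present, , drop = FALSE])
}

#' Principal component analysis of a gene panel
#'
#' Eigendecomposition of the gene-gene covariance (default) or correlation
#' of per-gene mean-centered log ratios, with samples as observations.
#' Components are ordered by decreasing variance; each loading vector is
#' signed so its largest-magnitude entry is positive.
#'
#' @param m an [expression_matrix()] restricted to the genes of interest
#' @param use_correlation scale genes to unit variance first? (default
#'   `FALSE`: covariance PCA)
#' @return a `pca_result`: `loadings` (genes x components, orthonormal),
#'   `scores` (samples x components), `variance_fraction`, `center` (gene
#'   means), `scale` (gene sds or NULL)
#' @export
pca_fit <- function(m, use_correlation = FALSE) {
  if (ncol(m) < 2L || nrow(m) < 2L) {
    stop("PCA needs >= 2 genes and >= 2 samples", call. = FALSE)
  }
  x <- t(unclass(m))                    # samples x genes
  if (all(apply(x, 2L, stats::sd) == 0)) {
    stop("degenerate input: all genes constant", call. = FALSE)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = use_correlation)
  flip <- apply(pr$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  pr$rotation <- sweep(pr$rotation, 2L, flip, `*`)
  pr$x <- sweep(pr$x, 2L, flip, `*`)
  structure(list(loadings = pr$rotation, scores = pr$x,
                 variance_fraction = pr$sdev^2 / sum(pr$sdev^2),
                 center = pr$center,
                 scale = if (use_correlation) pr$scale else NULL),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result: ", nrow(x$loadings), " genes, ", ncol(x$loadings),
      " components; var fractions ",
      paste(round(utils::head(x$variance_fraction, 4L), 3),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Bootstrap noise thresholds for PC projections
#'
#' Synthetic samples are drawn value-wise (with replacement) from the pool
#' of all expression values, centered with the training gene means, and
#' projected onto the fitted loadings. The spread of these projections
#' marks how far a biplot point must lie from the origin before it exceeds
#' expression noise; ellipse radii are reported at 1, 2, 3, 5, and 7 sd.
#'
#' @param m the training [expression_matrix()]
#' @param pca the fitted `pca_result`
#' @param B number of synthetic samples (default 1000)
#' @param seed integer seed
#' @param sd_multiples radii multipliers (default `c(1, 2, 3, 5, 7)`)
#' @return list with `median`, `sd` (per component), `radii` (multiples x
#'   components matrix), `projections` (B x components), `seed`
#' @export
pca_noise_thresholds <- function(m, pca, B = 1000L, seed = 1L,
                                 sd_multiples = c(1, 2, 3, 5, 7)) {
  set.seed(seed)
  pool <- as.numeric(unclass(m))
  G <- nrow(pca$loadings)
  synth <- matrix(sample(pool, B * G, replace = TRUE), nrow = B)
  colnames(synth) <- rownames(pca$loadings)
  synth <- sweep(synth, 2L, pca$center)
  if (!is.null(pca$scale)) synth <- sweep(synth, 2L, pca$scale, `/`)
  proj <- synth %*% pca$loadings
  med <- apply(proj, 2L, stats::median)
  sdv <- apply(proj, 2L, stats::sd)
  radii <- outer(sd_multiples, sdv)
  dimnames(radii) <- list(paste0(sd_multiples, "sd"), colnames(pca$loadings))
  list(median = med, sd = sdv, radii = radii, projections = proj,
       seed = seed)
}

#' Project an external expression matrix onto fitted loadings
#'
#' External values are matched by gene symbol, centered with the *training*
#' gene means, and multiplied by the loadings. Genes missing from the
#' external study contribute 0 after centering (with a warning); less than
#' 50% overlap is an error.
#'
#' @param m external [expression_matrix()] (genes x samples)
#' @param pca fitted `pca_result`
#' @return samples x components score matrix
#' @export
project_onto_loadings <- function(m, pca) {
  genes <- rownames(pca$loadings)
  present <- intersect(genes, rownames(m))
  if (length(present) < 0.5 * length(genes)) {
    stop("external matrix shares only ", length(present), "/",
         length(genes), " loading genes (< 50%)", call. = FALSE)
  }
  if (length(present) < length(genes)) {
    warning("loading gene(s) absent from external matrix contribute 0: ",
            paste(setdiff(genes, present), collapse = ", "), call. = FALSE)
  }
  x <- matrix(0, ncol(m), length(genes),
              dimnames = list(colnames(m), genes))
  x[, present] <- t(unclass(m)[present, , drop = FALSE]) -
    rep(pca$center[present], each = ncol(m))
  if (!is.null(pca$scale)) x <- sweep(x, 2L, pca$scale, `/`)
  x %*% pca$loadings
}
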