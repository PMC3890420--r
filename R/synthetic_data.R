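#' Synthetic cohorts and stained images
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' cohort of normal-like, group-1-like, and group-2-like samples that differ
#' in planted T-helper / macrophage polarization bias (amplitudes added to
#' the exclusive genes of each subset, in z-units on the log2-ratio scale),
#' immune-infiltration offsets on the marker genes, a latent factor tying
#' WISP1 positively to GATA3 and negatively to PPARG, an elevated
#' IL12RB2/IL12RB1 log-ratio in group 2, and exponential survival whose
#' log-hazard decreases with the planted type-1 bias, under independent
#' exponential censoring calibrated to a target rate.
#'
#' @name synthetic-data
NULL

#' Synthetic cohort configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 50 samples per group, a strong type-1 bias (Th1 amplitude 1.5,
#' M1 1.0) in group 2, a type-2/type-17 mix in group 1, a Th2/M2 bias in
#' normal tissue, infiltration offsets -1 / +1 for groups 1 / 2, latent
#' WISP1-GATA3 loading 1 (implied Pearson r = 0.5 at noise sd 1), an
#' IL12RB2-IL12RB1 log-ratio offset of +1.5 in group 2, unit expression
#' noise, baseline hazard 0.02 per month, log-HR -1.5 per unit planted Th1
#' bias, and 30% censoring.
#'
#' @param n_normal,n_group1,n_group2 group sizes
#' @param amplitudes named list per group: named numeric vectors of
#'   polarization amplitudes per subset (z-units)
#' @param infiltration_offsets named numeric vector of per-group offsets
#'   added to the infiltration marker genes
#' @param wisp1_gata3_loading latent-factor loading tying WISP1 and GATA3
#'   (+) and PPARG (-); implied pairwise correlation is
#'   `loading^2 / (loading^2 + noise_sd^2)`
#' @param il12_ratio_offset log2-ratio offset split between IL12RB2 (+) and
#'   IL12RB1 (-) in group 2
#' @param noise_sd i.i.d. Gaussian noise sd on the log2 scale
#' @param baseline_hazard events per month at zero Th1 bias
#' @param log_hr_th1 log hazard ratio per unit planted Th1 amplitude
#'   (negative = protective)
#' @param censoring_rate target fraction censored, in \[0, 1)
#' @param seed integer seed
#' @return a `synthetic_cohort_config` list
#' @export
synthetic_cohort_config <- function(
    n_normal = 50L, n_group1 = 50L, n_group2 = 50L,
    amplitudes = list(
      normal = c(Th2 = 1.0, M2 = 1.0),
      group1 = c(Th2 = 1.0, Th17 = 0.7, M2 = 0.5),
      group2 = c(Th1 = 1.5, M1 = 1.0)),
    infiltration_offsets = c(normal = 0, group1 = -1, group2 = 1),
    wisp1_gata3_loading = 1,
    il12_ratio_offset = 1.5,
    noise_sd = 1,
    baseline_hazard = 0.02,
    log_hr_th1 = -1.5,
    censoring_rate = 0.3,
    seed = 1L) {
  stopifnot(n_normal >= 0, n_group1 >= 0, n_group2 >= 0,
            n_normal + n_group1 + n_group2 >= 2,
            noise_sd > 0, censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0)
  structure(list(n_normal = n_normal, n_group1 = n_group1,
                 n_group2 = n_group2, amplitudes = amplitudes,
                 infiltration_offsets = infiltration_offsets,
                 wisp1_gata3_loading = wisp1_gata3_loading,
                 il12_ratio_offset = il12_ratio_offset,
                 noise_sd = noise_sd, baseline_hazard = baseline_hazard,
                 log_hr_th1 = log_hr_th1, censoring_rate = censoring_rate,
                 seed = seed),
            class = "synthetic_cohort_config")
}

# Solve the censoring hazard so the expected censored fraction matches the
# target: with T ~ Exp(h_i) and C ~ Exp(c), P(C < T | i) = c / (c + h_i).
solve_censoring_rate <- function(hazards, target) {
  if (target == 0) return(0)
  f <- function(cc) mean(cc / (cc + hazards)) - target
  stats::uniroot(f, lower = 1e-10, upper = 1e6, tol = 1e-12)$root
}

#' Generate a synthetic expression cohort with survival outcomes
#'
#' @param cfg a [synthetic_cohort_config()]
#' @param panel gene panel (default packaged panel); expression is generated
#'   for the union of all panel genes on the `log2_median_ratio` scale
#' @return list with `expression` (an [expression_matrix()]), `clinical`
#'   (data.frame: sample, pathology, os_months, os_event, group), and
#'   `truth` (group labels, per-sample planted Th1 level, per-subset
#'   amplitudes, true log-HR, censoring hazard used)
#' @export
generate_cohort <- function(cfg = synthetic_cohort_config(),
                            panel = load_panel()) {
  set.seed(cfg$seed)
  groups <- rep(c("normal", "group1", "group2"),
                c(cfg$n_normal, cfg$n_group1, cfg$n_group2))
  n <- length(groups)
  samples <- sprintf("S%03d", seq_len(n))
  genes <- unique(unlist(lapply(panel, family_genes), use.names = FALSE))

  th <- reduce_to_exclusive(panel[["Thelper"]])
  mph <- reduce_to_exclusive(panel[["macrophage"]])
  subset_genes <- c(th$exclusive, mph$exclusive)
  unknown <- setdiff(unlist(lapply(cfg$amplitudes, names)),
                     names(subset_genes))
  if (length(unknown)) {
    stop("amplitude for unknown subset(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  infil <- unique(unlist(infiltration_markers(), use.names = FALSE))
  if (!all(c("WISP1", "GATA3", "PPARG", "IL12RB1", "IL12RB2") %in% genes)) {
    stop("panel must contain WISP1, GATA3, PPARG, IL12RB1, IL12RB2",
         call. = FALSE)
  }

  mu <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  for (g in unique(groups)) {
    idx <- groups == g
    amps <- cfg$amplitudes[[g]]
    for (sub in names(amps)) {
      mu[subset_genes[[sub]], idx] <- mu[subset_genes[[sub]], idx] +
        amps[[sub]]
    }
    mu[infil, idx] <- mu[infil, idx] + cfg$infiltration_offsets[[g]]
  }
  mu["IL12RB2", groups == "group2"] <- mu["IL12RB2", groups == "group2"] +
    cfg$il12_ratio_offset / 2
  mu["IL12RB1", groups == "group2"] <- mu["IL12RB1", groups == "group2"] -
    cfg$il12_ratio_offset / 2

  x <- mu + matrix(stats::rnorm(length(mu), sd = cfg$noise_sd),
                   nrow(mu), ncol(mu))
  lat <- stats::rnorm(n)
  lam <- cfg$wisp1_gata3_loading
  x["WISP1", ] <- x["WISP1", ] + lam * lat
  x["GATA3", ] <- x["GATA3", ] + lam * lat
  x["PPARG", ] <- x["PPARG", ] - lam * lat

  expr <- expression_matrix(x, scale = "log2_median_ratio")

  th1_level <- vapply(groups, function(g) {
    a <- cfg$amplitudes[[g]]
    if ("Th1" %in% names(a)) unname(a[["Th1"]]) else 0
  }, 0)
  hazards <- cfg$baseline_hazard * exp(cfg$log_hr_th1 * th1_level)
  t_event <- stats::rexp(n, rate = hazards)
  c_haz <- solve_censoring_rate(hazards, cfg$censoring_rate)
  t_cens <- if (c_haz > 0) stats::rexp(n, rate = c_haz) else rep(Inf, n)
  os <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  pathology <- vapply(groups, function(g) {
    switch(g,
           normal = "normal",
           group1 = sample(c("ER+/PR+", "HER2+", "TN"), 1L,
                           prob = c(0.80, 0.13, 0.07)),
           group2 = sample(c("ER+/PR+", "HER2+", "TN"), 1L,
                           prob = c(0.46, 0.17, 0.37)))
  }, "")

  clinical <- data.frame(sample = samples, pathology = pathology,
                         os_months = os, os_event = event, group = groups,
                         stringsAsFactors = FALSE)
  truth <- list(group = stats::setNames(groups, samples),
                th1_level = stats::setNames(th1_level, samples),
                amplitudes = cfg$amplitudes,
                log_hr_th1 = cfg$log_hr_th1,
                censoring_hazard = c_haz,
                latent_factor = stats::setNames(lat, samples))
  list(expression = expr, clinical = clinical, truth = truth)
}

#' Generate a synthetic stained tissue image
#'
#' Composes pixels through the forward stain model: per-pixel densities of
#' the two stains are multiplied by the stain matrix to give OD, converted
#' to intensities, and perturbed by Gaussian pixel noise (clipped to
#' \[0, 255\]).
#'
#' @param stain1_density,stain2_density H x W matrices of planted densities
#'   (>= 0), or scalars (uniform field, default size 64 x 64)
#' @param size image size when densities are scalars
#' @param noise_sd pixel noise sd in intensity units (default 0)
#' @param stains a [stain_matrix()]
#' @param seed integer seed
#' @return list with `image` (H x W x 3, 8-bit scale) and `truth` (the two
#'   density maps)
#' @export
generate_ihc_image <- function(stain1_density, stain2_density,
                               size = c(64L, 64L), noise_sd = 0,
                               stains = default_stain_matrix(), seed = 1L) {
  expand <- function(d) {
    if (is.matrix(d)) d else matrix(d, size[1], size[2])
  }
  d1 <- expand(stain1_density); d2 <- expand(stain2_density)
  if (any(d1 < 0) || any(d2 < 0)) stop("densities must be >= 0", call. = FALSE)
  stopifnot(all(dim(d1) == dim(d2)))
  dens <- cbind(as.numeric(d1), as.numeric(d2), 0)
  od <- dens %*% stains
  img <- array(od_to_rgb(array(od, c(dim(d1), 3L))), c(dim(d1), 3L))
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + array(stats::rnorm(length(img), sd = noise_sd), dim(img))
    img[img < 0] <- 0
    img[img > 255] <- 255
  }
  list(image = img, truth = list(stain1 = d1, stain2 = d2))
}
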