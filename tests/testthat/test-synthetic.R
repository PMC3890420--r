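test_that("generation is a pure function of the seed", {
  a <- generate_cohort(synthetic_cohort_config(seed = 9L))
  b <- generate_cohort(synthetic_cohort_config(seed = 9L))
  expect_identical(unclass(a$expression), unclass(b$expression))
  expect_identical(a$clinical, b$clinical)
  c <- generate_cohort(synthetic_cohort_config(seed = 10L))
  expect_false(identical(unclass(a$expression), unclass(c$expression)))
})

test_that("planted polarization amplitude appears in the group gene means", {
  cc <- generate_cohort(synthetic_cohort_config(seed = 1L))
  th <- reduce_to_exclusive(load_panel()$Thelper)
  g2 <- cc$clinical$sample[cc$clinical$group == "group2"]
  for (g in th$exclusive$Th1) {
    expect_equal(mean(unclass(cc$expression)[g, g2]), 1.5,
                 tolerance = 3 / sqrt(50))
  }
  # groups without the planted subset stay near baseline
  g1 <- cc$clinical$sample[cc$clinical$group == "group1"]
  expect_lt(abs(mean(unclass(cc$expression)[th$exclusive$Th1, g1])), 0.5)
})

test_that("null configuration yields exchangeable groups", {
  cfg <- synthetic_cohort_config(
    amplitudes = list(normal = c(Th1 = 0), group1 = c(Th1 = 0),
                      group2 = c(Th1 = 0)),
    infiltration_offsets = c(normal = 0, group1 = 0, group2 = 0),
    il12_ratio_offset = 0, seed = 2L)
  cc <- generate_cohort(cfg)
  asg <- ward_cluster(cc$expression, 2)
  agree <- mean((asg$groups[cc$clinical$sample] == 1) ==
                  (cc$clinical$group == "group1"))
  expect_lt(abs(agree - 0.5), 0.25)   # clustering accuracy ~ chance
})

test_that("latent factor implies the configured WISP1 correlations", {
  cfg <- synthetic_cohort_config(n_normal = 0L, n_group1 = 500L,
                                 n_group2 = 0L, seed = 3L)
  cc <- generate_cohort(cfg)
  x <- unclass(cc$expression)
  implied <- cfg$wisp1_gata3_loading^2 /
    (cfg$wisp1_gata3_loading^2 + cfg$noise_sd^2)
  expect_equal(cor(x["WISP1", ], x["GATA3", ]), implied, tolerance = 0.05)
  expect_equal(cor(x["WISP1", ], x["PPARG", ]), -implied, tolerance = 0.05)
  # one-sided tests point in the planted directions
  expect_lt(pearson_correlation(x["WISP1", ], x["GATA3", ],
                                "positive")$p_value, 1e-6)
  expect_lt(pearson_correlation(x["WISP1", ], x["PPARG", ],
                                "negative")$p_value, 1e-6)
})

test_that("IL12 receptor ratio is elevated only in group 2", {
  cc <- generate_cohort(synthetic_cohort_config(seed = 4L))
  x <- unclass(cc$expression)
  ratio <- x["IL12RB2", ] - x["IL12RB1", ]
  g <- cc$clinical$group
  expect_equal(mean(ratio[g == "group2"]) - mean(ratio[g == "group1"]),
               1.5, tolerance = 3 * sqrt(2 * 2 / 50))
})

test_that("censoring calibration hits the target rate in expectation", {
  cfg <- synthetic_cohort_config(n_normal = 200L, n_group1 = 200L,
                                 n_group2 = 200L, censoring_rate = 0.4,
                                 seed = 5L)
  cc <- generate_cohort(cfg)
  expect_equal(mean(1 - cc$clinical$os_event), 0.4,
               tolerance = 3 * sqrt(0.4 * 0.6 / 600))
  # no censoring when rate is 0
  cfg0 <- synthetic_cohort_config(censoring_rate = 0, seed = 5L)
  expect_true(all(generate_cohort(cfg0)$clinical$os_event == 1))
})

test_that("unknown subsets and invalid sizes are rejected", {
  expect_error(generate_cohort(synthetic_cohort_config(
    amplitudes = list(normal = c(Th9 = 1), group1 = c(Th2 = 1),
                      group2 = c(Th1 = 1)))), "Th9")
  expect_error(synthetic_cohort_config(n_normal = 0L, n_group1 = 0L,
                                       n_group2 = 1L))
  expect_error(synthetic_cohort_config(censoring_rate = 1))
})

test_that("pipeline recovers partition, polarization, and hazard over replicates", {
  th <- reduce_to_exclusive(load_panel()$Thelper)
  agreements <- numeric(0)
  ok_argmax <- ok_hr <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    cc <- generate_cohort(synthetic_cohort_config(seed = 100L + s))
    zm <- suppressWarnings(zscore(cc$expression))
    truth_g2 <- cc$clinical$group == "group2"
    asg <- ward_cluster(cc$expression, 2)
    got_minor <- asg$groups[cc$clinical$sample] == 2
    agree <- max(mean(got_minor == truth_g2), mean(!got_minor == truth_g2))
    agreements <- c(agreements, agree)
    cm <- cohort_mean_posterior(zm, th,
                                membership = cc$clinical$group)
    if (colnames(cm)[which.max(cm["group2", ])] == "Th1")
      ok_argmax <- ok_argmax + 1L
    post <- posterior_matrix(zm, th)
    tum <- cc$clinical$pathology != "normal"
    df <- data.frame(os_months = cc$clinical$os_months[tum],
                     os_event = cc$clinical$os_event[tum],
                     th1 = cc$truth$th1_level[tum] / 1.5)
    fit <- tryCatch(cox_fit(df, "th1"), error = function(e) NULL)
    if (!is.null(fit)) {
      # planted log-HR per unit th1 (scaled to the 1.5 amplitude)
      est <- log(fit$coefficients$hr[1])
      se <- sqrt(diag(fit$fit$var))[1]
      if (abs(est - 1.5 * cc$truth$log_hr_th1) <= 2 * se)
        ok_hr <- ok_hr + 1L
    }
  }
  expect_gte(mean(agreements), 0.95)   # planted partition recovered
  expect_gte(min(agreements), 0.85)
  expect_equal(ok_argmax, n_rep)
  expect_gte(ok_hr, 18L)    # ~95% nominal coverage of the planted effect
})
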