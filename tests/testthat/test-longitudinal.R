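test_that("a noiseless injected interaction is recovered exactly", {
  delta <- 0.004  # CHR-P vs HC slope difference, units/year
  dd <- cohort_design(n_per_group = c("HC" = 6, "CHR-NP" = 6, "CHR-P" = 6),
                      baseline_offsets = c("HC" = 0, "CHR-NP" = 0, "CHR-P" = 0),
                      slope = c("HC" = 0.001, "CHR-NP" = 0.001,
                                "CHR-P" = 0.001 + delta),
                      residual_sd = 0, ranef_sd = 0.01,
                      schedule = c(0, 1, 2), rois = "LTC", seed = 2)
  co <- simulate_cohort(dd)
  # a zero-residual fit is numerically extreme by design; the point is the
  # estimate, not the optimizer diagnostics
  fit <- suppressWarnings(fit_lme(co$table, "LTC"))
  est <- lme4::fixef(fit$model)[["groupCHR-P:timepoint_years"]]
  expect_lt(abs(est - delta), 1e-8)
  # and the marginal-slope contrast sees the same difference
  pw <- suppressWarnings(posthoc_pairwise(fit, "interaction"))
  expect_equal(pw$estimate[pw$contrast == "CHR-P - HC"], delta,
               tolerance = 1e-6)
})

test_that("group effect is read at baseline and covariate checks hold", {
  dd <- cohort_design(n_per_group = c("HC" = 8, "CHR-NP" = 8, "CHR-P" = 8),
                      baseline_offsets = c("HC" = 0, "CHR-NP" = 0.02,
                                           "CHR-P" = 0.02),
                      slope = c("HC" = 0, "CHR-NP" = 0, "CHR-P" = 0),
                      residual_sd = 1e-8, ranef_sd = 0,
                      schedule = c(0, 1), rois = "LTC", seed = 4)
  co <- simulate_cohort(dd)
  fit <- suppressWarnings(fit_lme(co$table, "LTC"))
  pw <- suppressWarnings(posthoc_pairwise(fit, "group"))
  expect_equal(pw$estimate[pw$contrast == "CHR-NP - HC"], 0.02,
               tolerance = 1e-5)
  # missing covariates are dropped with a message, not silently
  tab <- co$table
  tab$age[1] <- NA
  expect_message(suppressWarnings(fit_lme(tab, "LTC")), "dropped 1")
})

test_that("degenerate designs are refused with informative errors", {
  co <- simulate_cohort(null_design(seed = 6, schedule = c(0, 1)))
  one_tp <- co$table[co$table$timepoint_years == 0, ]
  expect_error(fit_lme(one_tp, "LTC"), "one distinct timepoint")
  few <- co$table[co$table$subject_id %in%
                    unique(co$table$subject_id)[1:5], ]
  expect_error(fit_lme(few, "LTC"), "3 subjects")
  expect_error(fit_lme(co$table, "NOPE"), "no rows")
})

test_that("post hoc contrasts: identical groups are null, estimates are coherent", {
  co <- simulate_cohort(null_design(seed = 8,
                                    n = c("HC" = 20, "CHR-NP" = 20,
                                          "CHR-P" = 20)))
  fit <- fit_lme(co$table, "LTC")
  pw <- posthoc_pairwise(fit, "group")
  expect_equal(nrow(pw), 3)
  expect_setequal(pw$contrast,
                  c("CHR-NP - HC", "CHR-P - HC", "CHR-P - CHR-NP"))
  # groups built identical: small estimates, adjusted p not significant
  expect_true(all(abs(pw$estimate) < 0.05))
  expect_true(all(pw$p_adjusted > 0.05))
  # contrast arithmetic: (P - NP) = (P - HC) - (NP - HC)
  expect_equal(pw$estimate[pw$contrast == "CHR-P - CHR-NP"],
               pw$estimate[pw$contrast == "CHR-P - HC"] -
                 pw$estimate[pw$contrast == "CHR-NP - HC"],
               tolerance = 1e-10)
})

test_that("a CHR-P-only slope shows up in exactly the paper-style contrasts", {
  dd <- cohort_design(n_per_group = c("HC" = 40, "CHR-NP" = 40, "CHR-P" = 30),
                      baseline_offsets = c("HC" = 0, "CHR-NP" = 0, "CHR-P" = 0),
                      slope = c("HC" = 0, "CHR-NP" = 0, "CHR-P" = 0.06),
                      residual_sd = 0.02, ranef_sd = 0.03,
                      schedule = c(0, 1, 2), rois = "LTC", seed = 10)
  co <- simulate_cohort(dd)
  fit <- fit_lme(co$table, "LTC")
  pw <- posthoc_pairwise(fit, "interaction")
  expect_lt(pw$p_adjusted[pw$contrast == "CHR-P - HC"], 0.001)
  expect_lt(pw$p_adjusted[pw$contrast == "CHR-P - CHR-NP"], 0.001)
  expect_gt(pw$p_adjusted[pw$contrast == "CHR-NP - HC"], 0.05)
})

test_that("BH adjustment matches the step-up definition and its invariants", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2, 0.5, 0.7, 0.9)
  adj <- fdr_adjust(p)
  expect_equal(adj$p_adjusted, bh_stepup_oracle(p), tolerance = 1e-15)

  expect_equal(fdr_adjust(rep(1, 8))$p_adjusted, rep(1, 8))
  expect_false(any(fdr_adjust(rep(1, 8))$reject))
  expect_equal(fdr_adjust(0.03)$p_adjusted, 0.03)

  set.seed(14)
  for (i in 1:20) {
    p <- runif(8)
    a <- fdr_adjust(p)$p_adjusted
    expect_true(all(a >= p & a <= 1))              # never below raw
    expect_true(all(diff(a[order(p)]) >= -1e-15))  # monotone after sorting
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "within")
})

test_that("per-subject slopes equal closed-form OLS and apply inclusion rules", {
  tab <- data.frame(
    subject_id = c("a", "a", "b", "b", "b", "b", "c", "c", "d"),
    roi = "LTC", measure_name = "ifw",
    timepoint_years = c(0, 1, 0, 0.3, 1.1, 2.4, 0, 1, 0),
    value = c(1.0, 1.2, 0.5, 0.52, 0.61, 0.70, 0.4, 0.4, 9))
  expect_message(sl <- subject_slopes(tab, "ifw", "LTC"), "excluded 1")
  expect_equal(nrow(sl), 3)          # d has a single timepoint
  expect_equal(sl$slope[sl$subject_id == "a"], 0.2, tolerance = 1e-12)
  expect_equal(sl$slope[sl$subject_id == "c"], 0)  # constant series
  b <- tab[tab$subject_id == "b", ]
  expect_equal(sl$slope[sl$subject_id == "b"],
               ols_slope_oracle(b$timepoint_years, b$value), tolerance = 1e-10)
})

test_that("Spearman association handles monotone, tied and constant inputs", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_assoc(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_assoc(x, -x)$rho, -1)
  # tie-corrected: rank then Pearson on mid-ranks is the oracle
  y <- c(2, 2, 5, 1, 9, 9)
  expect_equal(spearman_assoc(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_warning(r <- spearman_assoc(x, rep(3, 6)), "constant")
  expect_true(is.na(r$rho))
  expect_error(spearman_assoc(1:3, 1:3), "at least 4")
})

test_that("Fisher z comparison matches the formula and its symmetries", {
  # equal correlations: z exactly 0, p exactly 1
  eq <- compare_correlations(0.5, 30, 0.5, 50)
  expect_identical(eq$z, 0)
  expect_identical(eq$p, 1)
  # swapping groups negates z, leaves p unchanged
  a <- compare_correlations(0.8, 17, 0.4, 66)
  b <- compare_correlations(0.4, 66, 0.8, 17)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # independent hand evaluation of the statistic
  z_hand <- (atanh(0.8) - atanh(0.4)) / sqrt(1 / (17 - 3) + 1 / (66 - 3))
  expect_equal(a$z, z_hand, tolerance = 1e-15)
  expect_equal(a$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-15)
  expect_error(compare_correlations(1, 10, 0.5, 10), "undefined")
  expect_error(compare_correlations(0.2, 3, 0.5, 10), "n >= 4")
})

test_that("interaction test keeps its size under the null", {
  # 500 small null cohorts; rejection rate at alpha = 0.05 must stay
  # below 1.5x nominal
  n_rep <- 500
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    co <- simulate_cohort(null_design(
      seed = 20000 + i, n = c("HC" = 15, "CHR-NP" = 20, "CHR-P" = 8)))
    fit <- suppressMessages(suppressWarnings(fit_lme(co$table, "LTC")))
    rej[i] <- fit$tests$p[fit$tests$effect == "interaction"] < 0.05
  }
  expect_lte(mean(rej), 1.5 * 0.05)
})

test_that("the full per-ROI analysis assembles effects, FDR and post hocs", {
  dd <- cohort_design(n_per_group = c("HC" = 15, "CHR-NP" = 15, "CHR-P" = 12),
                      slope = c("HC" = 0, "CHR-NP" = 0, "CHR-P" = 0.08),
                      residual_sd = 0.02, ranef_sd = 0.03,
                      schedule = c(0, 1, 2),
                      rois = c("LTC", "MPFC", "OCC"), seed = 12)
  co <- simulate_cohort(dd)
  res <- longitudinal_analysis(co$table)
  expect_s3_class(res, "longitudinal_result")
  expect_equal(nrow(res$effects), 6)  # 3 ROIs x 2 effects
  expect_true(all(res$effects$p_fdr >= res$effects$p - 1e-15))
  expect_true(all(res$effects$p_fdr >= 0 & res$effects$p_fdr <= 1))
  # the injected interaction is detected and produces 3 contrasts per ROI
  int <- res$effects[res$effects$effect == "interaction", ]
  expect_true(all(int$significant))
  ph <- res$posthoc[res$posthoc$effect == "interaction", ]
  expect_equal(nrow(ph), 9)

  dir <- withr::local_tempdir()
  write_longitudinal(res, dir)
  expect_true(all(file.exists(file.path(dir, c("effects.tsv", "posthoc.tsv",
                                               "results.json")))))
})
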