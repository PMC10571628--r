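test_that("the default multi-shell scheme has the right shell structure", {
  sch <- paper_scheme()
  expect_s3_class(sch, "acquisition_scheme")
  expect_equal(length(sch), 44)
  expect_equal(sum(sch$bvals == 0), 5)
  expect_equal(sum(sch$bvals == 200), 3)
  expect_equal(sum(sch$bvals == 500), 6)
  expect_equal(sum(sch$bvals == 1000), 30)
  expect_equal(sch$echo_time, 109)
  nrm <- sqrt(rowSums(sch$bvecs^2))
  expect_true(all(abs(nrm[sch$bvals > 0] - 1) < 1e-9))
  # deterministic: two calls agree exactly
  expect_identical(paper_scheme(), sch)
})

test_that("repulsion direction sets are spread, unit-norm and seed-stable", {
  g <- spherical_directions(30, seed = 42)
  expect_equal(dim(g), c(30, 3))
  expect_true(all(abs(sqrt(rowSums(g^2)) - 1) < 1e-12))
  # antipodally-aware spread: no two directions (or antipodes) nearly collinear
  cosang <- abs(tcrossprod(g))
  diag(cosang) <- 0
  expect_lt(max(cosang), 0.999)
  expect_identical(spherical_directions(30, seed = 42), g)
  # generating directions must not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(spherical_directions(6)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("simulate_voxel reproduces the relaxation-weighted baseline signal", {
  sch <- paper_scheme()
  tr <- voxel_truth(f_interstitial = 0, f_csf = 0, s0 = 1000,
                    t2_tissue = 90, t2_free = 2000)
  s <- simulate_voxel(tr, sch, snr = Inf)
  b0 <- sch$bvals == 0
  expect_equal(unique(s[b0]), 1000 * exp(-109 / 90), tolerance = 1e-12)
})

test_that("noise realizations are seed-reproducible and SNR-calibrated", {
  sch <- paper_scheme()
  tr <- voxel_truth(0.2, 0.1, s0 = 500)
  s1 <- simulate_voxel(tr, sch, snr = 30, seed = 7)
  s2 <- simulate_voxel(tr, sch, snr = 30, seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_voxel(tr, sch, snr = 30, seed = 8)))

  # empirical SNR of b = 0 signals within 10% of the request at n = 1000
  b0 <- which(sch$bvals == 0)
  sig <- unlist(lapply(1:200, function(i)
    simulate_voxel(tr, sch, snr = 30, seed = i)[b0]))
  snr_emp <- mean(sig) / sd(sig)
  expect_lt(abs(snr_emp - 30) / 30, 0.1)
})

test_that("infeasible volume fractions are rejected", {
  expect_error(voxel_truth(f_interstitial = 0.7, f_csf = 0.5))
  expect_error(voxel_truth(f_interstitial = -0.1))
})

test_that("fit + T2 correction + CSF subtraction recovers interstitial truth", {
  sch <- paper_scheme()
  pars <- relaxation_params(te = sch$echo_time)
  grid <- expand.grid(f_int = seq(0, 0.5, by = 0.1), f_csf = seq(0, 0.5, by = 0.1))
  for (k in seq_len(nrow(grid))) {
    tr <- voxel_truth(grid$f_int[k], grid$f_csf[k],
                      tensor = diag(c(1.2e-3, 0.5e-3, 0.5e-3)),
                      t2_tissue = pars$t2_tissue, t2_free = pars$t2_free)
    s <- simulate_voxel(tr, sch, snr = Inf)
    fit <- fit_voxel(s, sch)
    ifw <- max(t2_correct(fit$f_fw, pars) - grid$f_csf[k], 0)
    expect_lt(abs(ifw - grid$f_int[k]), 1e-2)
  }
})

test_that("phantom volumes carry ground truth and serialize with it", {
  f_int <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  f_csf <- matrix(0.1, 2, 2)
  ph <- simulate_volume(f_int, f_csf, snr = Inf)
  expect_s3_class(ph$data, "dwi_dataset")
  expect_equal(dim(ph$data$signal), c(2, 2, 1, 44))
  expect_equal(as.vector(ph$truth$f_interstitial$values), as.vector(f_int))
  # the recorded apparent fraction matches the compartmental T2 weighting
  wt <- exp(-109 / 90); wf <- exp(-109 / 2000)
  ff <- f_int[1, 1] + f_csf[1, 1]
  expect_equal(ph$truth$fw_apparent$values[1, 1, 1],
               wf * ff / (wt * (1 - ff) + wf * ff), tolerance = 1e-12)

  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "dwi.nii.gz", "dwi.bval", "dwi.bvec",
    "truth_f_interstitial.nii.gz", "csfv.nii.gz", "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$echo_time, 109)
})

test_that("simulated cohorts honor the design in the noiseless limit", {
  # all offsets and slopes zero: a null cohort with no group structure
  d0 <- null_design(seed = 3)
  co <- simulate_cohort(d0)
  expect_setequal(unique(co$table$group), c("HC", "CHR-NP", "CHR-P"))
  expect_equal(nrow(co$table), (30 + 40 + 10) * 2)
  expect_true(all(co$table$age >= 12 & co$table$age <= 35))

  # zero variance: per-subject slopes equal the group slope exactly
  dd <- cohort_design(n_per_group = c("HC" = 4, "CHR-NP" = 4, "CHR-P" = 4),
                      slope = c("HC" = 0, "CHR-NP" = 0.001, "CHR-P" = 0.005),
                      residual_sd = 0, ranef_sd = 0,
                      schedule = c(0, 1, 2), rois = "LTC", seed = 5)
  co2 <- simulate_cohort(dd)
  sl <- subject_slopes(co2$table, "ifw", "LTC")
  grp <- co2$table$group[match(sl$subject_id, co2$table$subject_id)]
  expect_equal(sl$slope, unname(c("HC" = 0, "CHR-NP" = 0.001,
                                  "CHR-P" = 0.005)[grp]), tolerance = 1e-12)

  # same seed reproduces the table exactly
  expect_identical(simulate_cohort(d0)$table, co$table)
})

test_that("cohort tables and truth records round trip through disk", {
  co <- simulate_cohort(cohort_design(
    n_per_group = c("HC" = 3, "CHR-NP" = 3, "CHR-P" = 3),
    rois = c("LTC", "OCC"), seed = 11))
  dir <- withr::local_tempdir()
  write_cohort(co, file.path(dir, "cohort"))
  back <- utils::read.delim(file.path(dir, "cohort.tsv"))
  expect_equal(nrow(back), nrow(co$table))
  expect_equal(back$value, co$table$value, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "cohort_truth.json"))
  expect_equal(truth$residual_sd, co$truth$residual_sd)
})
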