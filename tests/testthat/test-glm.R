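test_that("design matrices have the documented structure", {
  # blank-only design: intercept + drift columns only
  d <- make_design(6, 1.0, seed = 1)
  d$trials$category <- rep("blank", 6)
  dm <- build_design_matrix(d)
  expect_length(dm$categories, 0)
  expect_setequal(colnames(dm$X), c("run1_drift0", "run1_drift1"))

  # two runs: shared category columns, block-diagonal drift
  d1 <- make_design(12, 1.0, seed = 1, run_id = 1)
  d2 <- make_design(12, 1.0, seed = 2, run_id = 2)
  dm2 <- build_design_matrix(list(d1, d2))
  expect_setequal(dm2$categories, setdiff(localizer_categories(), "blank"))
  r1 <- seq_len(d1$n_volumes)
  expect_true(all(dm2$X[r1, "run2_drift0"] == 0))
  expect_true(all(dm2$X[-r1, "run1_drift0"] == 0))
  expect_true(all(dm2$X[-r1, "run1_drift1"] == 0))
  # category column in run 2 equals that run's own convolution
  expect_equal(dm2$X[-r1, "text"],
               votcsim:::convolve_regressor(d2, "text"))
})

test_that("noise-free fits recover the simulated amplitudes exactly", {
  mesh <- std_mesh()
  mask <- std_mask(mesh)
  lay <- sample_population(mesh, mask, n_subjects = 1,
                           config = cohort_config("adults", noise_sd = 0,
                                                  oneback_gain = 1),
                           seed = 3)[[1]]
  runs <- simulate_subject_runs(mesh, mask, lay, seed = 10,
                                runs_per_task = 1, n_trials = 30)
  fit <- fit_glm(runs$ts, build_design_matrix(runs$designs))
  cats <- setdiff(localizer_categories(), "blank")
  for (cc in cats) {
    truth <- amplitude_field(mesh, mask, lay, cc, "fixation")
    est <- psc_map(fit, cc)$values
    expect_lt(max(abs(est - truth)), 1e-6 * max(1, max(abs(truth))))
  }
  # residual orthogonality: X'(y - Xb) = 0
  Y <- t(do.call(cbind, lapply(runs$ts, function(r) r$data[1:50, ])))
  B <- qr.coef(qr(fit$dm$X), Y)
  expect_lt(max(abs(crossprod(fit$dm$X, Y - fit$dm$X %*% B))), 1e-6)
})

test_that("the GLM is invariant to a constant signal shift", {
  mesh <- make_mesh("grid", 10)
  mask <- make_votc_mask(mesh, x_range = c(0, 9), y_range = c(0, 9),
                         split_y = 4)
  cfg <- cohort_config("adults")
  cfg$patches <- list(text = list(subregion = "ots", center = c(4, 6),
                                  radius = 2, jitter = 0, amp = 1.2))
  lay <- sample_population(mesh, mask, n_subjects = 1, config = cfg,
                           seed = 1)[[1]]
  d <- make_design(20, 1.19, seed = 1)
  ts <- simulate_timeseries(mesh, mask, lay, d, seed = 2)
  dm <- build_design_matrix(d)
  fit1 <- fit_glm(ts, dm)
  ts$data <- ts$data + 50
  fit2 <- fit_glm(ts, dm)
  expect_equal(fit1$betas["text", ], fit2$betas["text", ], tolerance = 1e-9)
})

test_that("pure-noise betas and t-statistics have the nominal null behavior", {
  mesh <- std_mesh()
  mask <- std_mask(mesh)
  cfg <- cohort_config("adults", common_response = 0)
  for (nm in names(cfg$patches)) cfg$patches[[nm]]$amp <- 0
  lay <- sample_population(mesh, mask, n_subjects = 1, config = cfg,
                           seed = 5)[[1]]
  runs <- simulate_subject_runs(mesh, mask, lay, seed = 20)
  fit <- fit_glm(runs$ts, build_design_matrix(runs$designs))
  tmap <- contrast_t(fit, vs_other_weights("text"))

  # beta z-scores against their analytic sampling sd
  w <- "text" == rownames(fit$betas)
  sd_beta <- sqrt(mean(fit$sigma2) * fit$xtx_inv[which(w), which(w)])
  expect_lt(max(abs(fit$betas["text", ])) / sd_beta, 6)

  # |t| > 3 tail frequency matches the Student-t tail at the fit dof
  p_nom <- 2 * stats::pt(-3, fit$dof)
  p_obs <- mean(abs(tmap$values) > 3)
  mc_se <- sqrt(p_nom * (1 - p_nom) / length(tmap$values))
  expect_lt(abs(p_obs - p_nom), 3 * mc_se)
})

test_that("contrast maps behave as contrasts should", {
  w <- vs_other_weights("text")
  expect_equal(sum(w), 0)
  expect_equal(unname(w["text"]), 1)
  # applied to betas (1, 0, 0, 0, 0) the contrast value is 1
  expect_equal(sum(w * c(text = 1, pseudofont = 0, face = 0, object = 0,
                         limb = 0)), 1)

  # vs-other contrasts are invariant to a common additive response:
  # simulate two subjects differing only by a constant added to every
  # stimulus category's amplitude
  mesh <- std_mesh()
  mask <- std_mask(mesh)
  base <- cohort_config("adults", noise_sd = 0, amp_cv = 0,
                        oneback_gain = 1)
  plus <- base
  plus$common_response <- base$common_response + 0.7
  lay1 <- sample_population(mesh, mask, n_subjects = 1, config = base,
                            seed = 6)[[1]]
  lay2 <- sample_population(mesh, mask, n_subjects = 1, config = plus,
                            seed = 6)[[1]]
  runs1 <- simulate_subject_runs(mesh, mask, lay1, seed = 30,
                                 runs_per_task = 1, n_trials = 24)
  runs2 <- simulate_subject_runs(mesh, mask, lay2, seed = 30,
                                 runs_per_task = 1, n_trials = 24)
  dm <- build_design_matrix(runs1$designs)
  f1 <- fit_glm(runs1$ts, dm)
  f2 <- fit_glm(runs2$ts, dm)
  c1 <- drop(crossprod(c(vs_other_weights("text"),
                         numeric(nrow(f1$betas) - 5)), f1$betas))
  c2 <- drop(crossprod(c(vs_other_weights("text"),
                         numeric(nrow(f2$betas) - 5)), f2$betas))
  expect_equal(c1, c2, tolerance = 1e-8)

  # doubling the text amplitude at fixed noise increases in-patch t
  cfgA <- cohort_config("adults", amp_cv = 0)
  cfgB <- cfgA
  cfgB$patches$text$amp <- cfgA$patches$text$amp * 2
  layA <- sample_population(mesh, mask, n_subjects = 1, config = cfgA,
                            seed = 8)[[1]]
  layB <- sample_population(mesh, mask, n_subjects = 1, config = cfgB,
                            seed = 8)[[1]]
  runsA <- simulate_subject_runs(mesh, mask, layA, seed = 40,
                                 runs_per_task = 1)
  runsB <- simulate_subject_runs(mesh, mask, layB, seed = 40,
                                 runs_per_task = 1)
  dm2 <- build_design_matrix(runsA$designs)
  tA <- contrast_t(fit_glm(runsA$ts, dm2), vs_other_weights("text"))
  tB <- contrast_t(fit_glm(runsB$ts, dm2), vs_other_weights("text"))
  core <- true_patch(mesh, mask, layA, "text")
  expect_gt(mean(tB$values[core]), mean(tA$values[core]))
})

test_that("zero-variance vertices get the signed-infinity sentinel", {
  mesh <- std_mesh()
  mask <- std_mask(mesh)
  lay <- sample_population(mesh, mask, n_subjects = 1,
                           config = cohort_config("adults", noise_sd = 0,
                                                  amp_cv = 0,
                                                  oneback_gain = 1),
                           seed = 9)[[1]]
  runs <- simulate_subject_runs(mesh, mask, lay, seed = 50,
                                runs_per_task = 1, n_trials = 24)
  fit <- fit_glm(runs$ts, build_design_matrix(runs$designs))
  expect_warning(tm <- contrast_t(fit, vs_other_weights("text")),
                 "zero-variance")
  core <- true_patch(mesh, mask, lay, "text")
  expect_true(all(tm$values[core] == Inf))
  # far from any patch the contrast is exactly zero: sentinel 0
  far <- setdiff(seq_len(mesh$n_vertices), mask$votc)[1:10]
  expect_true(all(tm$values[far] == 0))
})

test_that("PSC maps are scale-invariant and zero for blank", {
  mesh <- make_mesh("grid", 10)
  mask <- make_votc_mask(mesh, x_range = c(0, 9), y_range = c(0, 9),
                         split_y = 4)
  cfg <- cohort_config("adults")
  cfg$patches <- list(text = list(subregion = "ots", center = c(4, 6),
                                  radius = 2, jitter = 0, amp = 1.2))
  lay <- sample_population(mesh, mask, n_subjects = 1, config = cfg,
                           seed = 2)[[1]]
  d <- make_design(20, 1.19, seed = 4)
  ts <- simulate_timeseries(mesh, mask, lay, d, seed = 5)
  dm <- build_design_matrix(d)
  p1 <- psc_map(fit_glm(ts, dm), "text")
  ts$data <- ts$data * 3.7
  p2 <- psc_map(fit_glm(ts, dm), "text")
  expect_equal(p1$values, p2$values, tolerance = 1e-9)
  expect_true(all(psc_map(fit_glm(ts, dm), "blank")$values == 0))
})

test_that("degenerate designs are rejected", {
  d <- make_design(12, 1.0, seed = 1)
  dm <- build_design_matrix(d)
  dm$X <- cbind(dm$X, dup = dm$X[, "text"])
  mesh <- make_mesh("grid", 4)
  ts <- structure(list(subject_id = "s", data = matrix(1, 16, d$n_volumes),
                       design = d, noise_sd = 0),
                  class = "bold_timeseries")
  expect_error(fit_glm(ts, dm), "degenerate design")
})
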