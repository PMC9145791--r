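test_that("covariate sampler matches the cohort distributions", {
  cov <- sample_covariates(10000, seed = 42)
  expect_lt(abs(mean(cov$sex) - 0.266), 0.02)
  expect_lt(abs(mean(cov$dm) - 0.185), 0.02)
  expect_true(all(cov$bsa >= 1.24 & cov$bsa <= 2.30))
  expect_lt(abs(mean(cov$bsa) - 1.70), 0.01)
  expect_true(all(cov$age >= 38 & cov$age <= 82))
  expect_lt(abs(mean(cov$htn) - 0.491), 0.02)
  expect_lt(abs(median(cov$alt) - 16), 1.5)
  expect_true(all(cov$smoking %in% 0:2))
})

test_that("exponential IIV construction has the right scale and median", {
  pop <- reference_population()
  cov <- sample_covariates(1e5, seed = 7)
  ip <- sample_individual_params(pop, cov, seed = 8)
  # log-scale SD of circ0 within 2% of omega = 0.23
  expect_lt(abs(sd(log(ip$values[, "circ0"])) - 0.23) / 0.23, 0.02)
  # log-normal median equals the typical value
  expect_lt(abs(median(ip$values[, "circ0"]) - 5.34) / 5.34, 0.01)
  # degenerate IIV: individual values equal typicals
  pop0 <- population_model(theta = kpd_params(),
                           omega2 = c(circ0 = 0, mtt = 0, ir50 = 0,
                                      kde_p = 0, kde_c = 0),
                           sigma_prop = 0.3, sigma_add = 0.5)
  ip0 <- sample_individual_params(pop0, cov[1:50, ], seed = 9)
  tv <- neutkpd:::typical_values(pop0, cov[1:50, ])
  expect_equal(ip0$values, tv)
  expect_true(all(ip0$etas == 0))
  # IR50 typicals pass through the covariate model first
  ipc <- sample_individual_params(pop, cov[1:1000, ], seed = 10)
  male <- cov$sex[1:1000] == 0 & cov$dm[1:1000] == 0
  expect_lt(abs(median(ipc$values[male, "ir50_p"]) - 88.9) / 88.9, 0.08)
})

test_that("combined residual error has the stated variance and floor", {
  pop <- reference_population()
  y <- apply_residual_error(rep(5, 1e5), pop, seed = 11)
  expect_lt(abs(var(y) - (25 * 0.09 + 0.527^2)) / (25 * 0.09 + 0.527^2), 0.03)
  expect_lt(abs(mean(y) - 5) / 5, 0.01)
  # zero noise: identity
  pop0 <- population_model(sigma_prop = 0, sigma_add = 1e-12)
  expect_equal(apply_residual_error(c(1, 2, 3), pop0, seed = 1), c(1, 2, 3),
               tolerance = 1e-6)
  # zero prediction: pure additive draws, resample-once-then-floor leaves an
  # atom of about 25% at the floor
  y0 <- apply_residual_error(rep(0, 2e4), pop, seed = 12)
  expect_true(all(y0 > 0))
  expect_lt(abs(mean(y0 == 0.001) - 0.25), 0.02)
  expect_error(apply_residual_error(-1, pop), "non-negative")
})

test_that("generated cohorts are reproducible and structurally correct", {
  pop <- reference_population(gcsf = FALSE)
  des <- study_design(6, seed = 33, n_cycles = 6, gcsf_policy = FALSE)
  ds1 <- generate_dataset(des, pop)
  ds2 <- generate_dataset(des, pop)
  expect_identical(ds1, ds2)
  # 2 samples x 6 cycles, no G-CSF extras
  expect_true(all(vapply(ds1, function(s) nrow(s$observations), integer(1))
                  == 12))
  expect_true(all(vapply(ds1, function(s) all(is.finite(s$observations$anc) &
                                                s$observations$anc > 0),
                         logical(1))))
  expect_true(all(vapply(ds1, function(s) !is.null(s$etas_true),
                         logical(1))))
  # different seed changes the data
  ds3 <- generate_dataset(study_design(6, seed = 34, n_cycles = 6,
                                       gcsf_policy = FALSE), pop)
  expect_false(identical(ds1[[1]]$observations, ds3[[1]]$observations))
})

test_that("pre-treatment observations centre on the baseline count", {
  pop <- reference_population(gcsf = FALSE)
  ds <- generate_dataset(study_design(400, seed = 55, n_cycles = 2,
                                      gcsf_policy = FALSE), pop)
  pre <- vapply(ds, function(s) s$observations$anc[s$observations$time == 0][1],
                numeric(1))
  # the geometric mean of y = circ0*(1+e1)+e2 sits below circ0 by about
  # var/(2*mean^2) (Jensen), here ~5%; allow that plus sampling noise
  expect_lt(abs(exp(mean(log(pre))) - 5.34) / 5.34, 0.08)
  expect_lt(abs(mean(pre) - 5.34 * exp(0.23^2 / 2)) / 5.34, 0.05)
})

test_that("grade-4 observations trigger the G-CSF policy in some subjects", {
  pop <- reference_population(gcsf = TRUE)
  ds <- generate_dataset(study_design(60, seed = 66, n_cycles = "cohort",
                                      gcsf_policy = TRUE), pop)
  n_g <- sum(vapply(ds, function(s) length(s$gcsf_times) > 0, logical(1)))
  expect_gt(n_g, 0)
  # G-CSF events land on grade-4 observation times and add the extra sample
  one <- ds[[which(vapply(ds, function(s) length(s$gcsf_times) > 0,
                          logical(1)))[1]]]
  tg <- one$gcsf_times[1]
  expect_true(any(abs(one$observations$time - tg) < 1e-9))
  expect_true(any(abs(one$observations$time - (tg + 1)) < 1e-9))
  expect_true("gcsf" %in% one$doses$drug)
  # dose reduction recorded for later cycles
  trig_cycle <- floor(tg / 28) + 1
  if (trig_cycle < one$n_cycles)
    expect_true(all(one$reduced_cycles > trig_cycle))
})

test_that("a drug-insensitive population yields baseline-level data", {
  pop <- population_model(theta = kpd_params(ir50_tv = 1e9),
                          omega2 = c(circ0 = 0.05^2, mtt = 0, ir50 = 0,
                                     kde_p = 0, kde_c = 0),
                          sigma_prop = 0.05, sigma_add = 0.05,
                          config = kpd_config(gcsf_effect_model = "none"))
  ds <- generate_dataset(study_design(20, seed = 77, n_cycles = 3,
                                      gcsf_policy = FALSE,
                                      grade4_threshold = 0), pop)
  ys <- unlist(lapply(ds, function(s) s$observations$anc))
  expect_lt(abs(mean(ys) - 5.34) / 5.34, 0.05)
})

test_that("design validation", {
  expect_error(study_design(10), "seed")
  expect_error(study_design(0, seed = 1), "n_subjects")
  expect_error(study_design(5, seed = 1, n_cycles = 9), "1..6")
  expect_error(study_design(5, seed = 1, samples_per_cycle = 0),
               "samples_per_cycle")
})
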