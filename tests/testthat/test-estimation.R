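stub_fit <- function(ofv, k, n_transit = 3L, sig = c(n = 10, nobs = 100,
                                                     sum_y = 1, sum_t = 1)) {
  structure(list(ofv = ofv, k = k, aic = ofv + 2 * k,
                 pop = list(config = list(n_transit = n_transit)),
                 data_sig = sig), class = "kpd_fit")
}

test_that("joint -2 log-likelihood matches a hand-evaluated Gaussian", {
  # no doses: prediction is circ0 * exp(eta1) at every time, so the joint
  # density is available in closed form
  pop <- population_model(theta = kpd_params(),
                          omega2 = c(circ0 = 0.04, mtt = 0, ir50 = 0,
                                     kde_p = 0, kde_c = 0),
                          sigma_prop = 0.2, sigma_add = 0.3,
                          config = kpd_config(n_transit = 1,
                                              gcsf_effect_model = "none"))
  subj <- structure(list(
    id = 1, covariates = data.frame(sex = 0, dm = 0, bsa = 1.7),
    doses = data.frame(time = numeric(), drug = character(),
                       amount = numeric()),
    observations = data.frame(time = c(0, 7), anc = c(5.1, 6.0))),
    class = "kpd_subject")
  eta <- c(0.13, 0, 0, 0, 0)
  f <- 5.34 * exp(0.13)
  v <- f^2 * 0.04 + 0.09
  hand <- sum(log(2 * pi * v) + (c(5.1, 6.0) - f)^2 / v) +
    0.13^2 / 0.04 + log(2 * pi * 0.04)
  expect_equal(joint_neg2ll(pop, subj, eta), hand, tolerance = 1e-8)
  # quadratic growth: doubling the residual quadruples the data term
  popa <- population_model(theta = kpd_params(), sigma_prop = 0,
                           sigma_add = 1,
                           config = kpd_config(gcsf_effect_model = "none"))
  s1 <- subj; s1$observations <- data.frame(time = 0, anc = 5.34 + 1)
  s2 <- subj; s2$observations <- data.frame(time = 0, anc = 5.34 + 2)
  base <- log(2 * pi)
  expect_equal(joint_neg2ll(popa, s2) - base,
               4 * (joint_neg2ll(popa, s1) - base), tolerance = 1e-8)
})

test_that("Laplace equals the exact marginal for a Gaussian-linear toy", {
  a <- 2; b <- 1.5; om2 <- 0.3; sa <- 0.7
  for (y in c(1.2, 3.1, 4.5)) {
    subj <- list(list(y = y))
    lap <- laplace_ofv_generic(subj, function(s, e) a + b * e[1],
                               omega2 = om2, sigma_prop = 0, sigma_add = sa)
    exact <- -2 * dnorm(y, a, sqrt(sa^2 + b^2 * om2), log = TRUE)
    expect_equal(lap$ofv, exact, tolerance = 1e-6)
  }
})

test_that("Laplace is within 0.1 of 32-node quadrature on nonlinear toys", {
  set.seed(21)
  for (r in 1:5) {
    theta <- runif(1, 3, 8)
    om2 <- runif(1, 0.1, 0.3)
    pred1 <- function(eta) theta / (1 + exp(-eta))   # logistic in eta
    y <- pred1(rnorm(1, 0, sqrt(om2))) *
      (1 + rnorm(8, 0, 0.15)) + rnorm(8, 0, 0.15)
    lap <- laplace_ofv_generic(list(list(y = y)),
                               function(s, e) rep(pred1(e[1]), length(y)),
                               omega2 = om2, sigma_prop = 0.15,
                               sigma_add = 0.15)
    quad <- quad_neg2ll_1d(y, function(e) rep(pred1(e), length(y)),
                           omega2 = om2, sigma_prop = 0.15, sigma_add = 0.15,
                           center = lap$eta[1, 1])
    expect_lt(abs(lap$ofv - quad), 0.1)
  }
})

test_that("compiled Laplace agrees with the generic R implementation", {
  pop <- reference_population(gcsf = FALSE)
  ds <- generate_dataset(study_design(4, seed = 91, n_cycles = 2,
                                      gcsf_policy = FALSE), pop)
  covs <- neutkpd:::dataset_covariates(ds)
  tv <- neutkpd:::typical_values(pop, covs)
  cppofv <- laplace_ofv(pop, ds, inner_maxit = 30, inner_gtol = 1e-5)
  # generic path: prediction through the same simulator, but mode search,
  # Hessian and assembly done independently in R
  subjects <- lapply(seq_along(ds), function(i) {
    list(y = ds[[i]]$observations$anc, i = i)
  })
  pred_fn <- function(s, e) {
    i <- s$i
    tvi <- tv[i, ]
    vals <- tvi
    vals[c("circ0", "mtt", "kde_p", "kde_c")] <-
      tvi[c("circ0", "mtt", "kde_p", "kde_c")] * exp(e[c(1, 2, 4, 5)])
    vals[c("ir50_p", "ir50_c")] <- tvi[c("ir50_p", "ir50_c")] * exp(e[3])
    neutkpd:::simulate_values(vals, pop, ds[[i]]$doses,
                              ds[[i]]$observations$time)
  }
  ref <- laplace_ofv_generic(subjects, pred_fn, omega2 = pop$omega2,
                             sigma_prop = pop$sigma_prop,
                             sigma_add = pop$sigma_add)
  expect_lt(abs(cppofv$ofv - ref$ofv), 0.1)
  expect_lt(max(abs(cppofv$eta - ref$eta)), 0.02)
})

test_that("vanishing IIV collapses the OFV to the eta = 0 residual -2LL", {
  pop <- reference_population(gcsf = FALSE)
  pop$omega2 <- pop$omega2 * 0 + 1e-8
  ds <- generate_dataset(study_design(3, seed = 92, n_cycles = 2,
                                      gcsf_policy = FALSE),
                         reference_population(gcsf = FALSE))
  o <- laplace_ofv(pop, ds, inner_maxit = 30)
  direct <- sum(vapply(ds, function(s) {
    g <- joint_neg2ll(pop, s, rep(0, 5))
    # subtract the prior terms, leaving the pure residual -2LL
    g - sum(log(2 * pi * pop$omega2))
  }, numeric(1)))
  expect_equal(o$ofv, direct, tolerance = 1e-3)
})

test_that("fit never ends above its starting objective", {
  pop <- reference_population(gcsf = FALSE)
  ds <- generate_dataset(study_design(8, seed = 93, n_cycles = 3,
                                      gcsf_policy = FALSE), pop)
  fit <- fit_population(ds, init = pop,
                        options = list(nm_maxit = 25, bfgs_maxit = 4,
                                       bfgs_restarts = 1))
  expect_lte(fit$ofv, fit$ofv_init + 1e-6)
  expect_s3_class(fit, "kpd_fit")
  expect_equal(fit$aic, fit$ofv + 2 * fit$k)
})

test_that("drug parameters are fixable at the identifiability boundary", {
  # with a drug-insensitive truth the drug parameters carry no information;
  # fixing them leaves baseline and noise recoverable
  pop <- population_model(
    theta = kpd_params(theta_sex = 0, theta_dm = 0, ir50_tv = 1e9),
    omega2 = c(circ0 = 0.23^2, mtt = 0, ir50 = 0, kde_p = 0, kde_c = 0),
    sigma_prop = 0.2, sigma_add = 0.3,
    config = kpd_config(gcsf_effect_model = "none"))
  ds <- generate_dataset(study_design(25, seed = 94, n_cycles = 3,
                                      samples_per_cycle = 2,
                                      gcsf_policy = FALSE,
                                      grade4_threshold = 0), pop)
  init <- pop
  init$theta$circ0 <- 4
  fit <- fit_population(ds, init = init,
                        fixed = c("mtt", "gamma", "ir50_tv", "kde_p",
                                  "kde_c"),
                        options = list(nm_maxit = 150, bfgs_maxit = 20))
  expect_lt(abs(coef(fit)["circ0"] - 5.34) / 5.34, 0.1)
})

test_that("model ranking is by AIC with parameter-count tie-breaks", {
  f1 <- stub_fit(1000, 10)           # aic 1020
  f2 <- stub_fit(1004, 7)            # aic 1018 -> best
  f3 <- stub_fit(1000, 9)            # aic 1018, fewer params than f2? no: 9>7
  r <- compare_models(a = f1, b = f2, c = f3)
  expect_equal(r$aic[1], 1018)
  expect_equal(r$model[1], "b")      # tie broken by fewer parameters
  expect_equal(r$delta_aic[1], 0)
  # AIC ranking invariant to a constant shift of every ofv
  r2 <- compare_models(a = stub_fit(1100, 10), b = stub_fit(1104, 7),
                       c = stub_fit(1100, 9))
  expect_equal(r2$model, r$model)
  # k = 10, ofv = 1000 -> aic = 1020
  expect_equal(stub_fit(1000, 10)$aic, 1020)
  expect_error(compare_models(f1, stub_fit(900, 2, sig = c(n = 9, nobs = 100,
                                                           sum_y = 1,
                                                           sum_t = 1))),
               "identical dataset")
})
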