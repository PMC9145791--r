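test_that("baseline rate constants derive from the mean transit time", {
  r <- derive_rates(kpd_params(mtt = 4.64), kpd_config(n_transit = 3))
  expect_equal(r$ktr0, 4 / 4.64, tolerance = 1e-12)
  expect_equal(r$ktr0, 0.8621, tolerance = 1e-4)
  r2 <- derive_rates(kpd_params(mtt = 4), kpd_config(n_transit = 3))
  expect_equal(r2$ktr0, 1.0)
  for (nt in 1:3) {
    p <- kpd_params(mtt = runif(1, 2, 8))
    r3 <- derive_rates(p, kpd_config(n_transit = nt))
    expect_equal(r3$kprol0, r3$ktr0)
    expect_equal(r3$kcirc, r3$ktr0)
    expect_equal(r3$ktr0, (nt + 1) / p$mtt)
  }
  expect_error(derive_rates(list(mtt = -1)), "positive")
})

test_that("IR50 covariate model reproduces the sex and DM shifts", {
  p <- kpd_params(ir50_tv = 88.9, theta_sex = -0.334, theta_dm = 0.485)
  expect_equal(covariate_ir50(p, 0, 0), 88.9)
  expect_equal(covariate_ir50(p, 1, 0), 88.9 * 0.666)
  expect_equal(covariate_ir50(p, 0, 1), 88.9 * 1.485)
  expect_equal(covariate_ir50(p, 1, 1), 88.9 * 0.666 * 1.485)
  # vectorised
  expect_equal(covariate_ir50(p, c(0, 1), c(1, 0)),
               c(88.9 * 1.485, 88.9 * 0.666))
  expect_error(covariate_ir50(p, 2, 0), "0/1")
  expect_error(covariate_ir50(p, 0, 0.5), "0/1")
})

test_that("virtual infusion rate is KDE times amount", {
  expect_equal(virtual_infusion_rate(0, 0.0326), 0)
  expect_equal(virtual_infusion_rate(297.5, 0.0326), 9.6985)
  expect_error(virtual_infusion_rate(-1, 0.1), "non-negative")
  expect_error(virtual_infusion_rate(1, 0), "positive")
  # exponential decay of the virtual amount: at t = 1/kde, a factor 1/e
  p <- kpd_params()
  s <- c(prol = 5.34, transit1 = 5.34, transit2 = 5.34, transit3 = 5.34,
         circ = 5.34, a_p = 100, a_c = 0)
  expect_equal(ode_rhs(0, s, p)[["a_p"]], -p$kde_p * 100)
})

test_that("drug effect: identity, half-effect, saturation, nesting", {
  p <- kpd_params()
  expect_equal(drug_effect(0, 0, p), 1)
  # U = u50 -> half effect (u50 = 1, vir_p = IR50)
  expect_equal(drug_effect(88.9, 0, p), 0.5)
  expect_equal(drug_effect(0, 88.9, p), 0.5)
  expect_lt(drug_effect(1e9, 0, p), 1e-6)
  # additive-surface nesting: u50 = p_steep = 1, one drug absent
  vir <- seq(0, 300, by = 50)
  u <- vir / 88.9
  expect_equal(drug_effect(vir, 0, p), 1 - u / (1 + u))
  # log-linear with zero scales is the no-effect identity
  cfg_ll <- kpd_config(drug_effect_model = "log_linear")
  expect_equal(drug_effect(vir, vir, kpd_params(scale1 = 0, scale2 = 0),
                           cfg_ll), rep(1, length(vir)))
  expect_equal(drug_effect(10, 5, kpd_params(scale1 = 0.02, scale2 = 0.01),
                           cfg_ll), exp(-0.02 * 10 - 0.01 * 5))
  expect_error(drug_effect(-1, 0, p), "non-negative")
})

test_that("G-CSF effect multipliers follow the split constant model", {
  p <- kpd_params(theta_ktr = 3.50, theta_prol = 0.217)
  off <- gcsf_effect(0, p)
  expect_equal(off$eg_ktr, 1)
  expect_equal(off$eg_kprol, 1)
  on <- gcsf_effect(1, p)
  expect_equal(on$eg_ktr, 4.50)
  expect_equal(on$eg_kprol, 4.50 * 1.217)
  expect_equal(on$eg_kprol, 5.4765)
  # theta_prol = 0 collapses the split model onto the plain constant model
  p0 <- kpd_params(theta_ktr = 3.50, theta_prol = 0)
  on0 <- gcsf_effect(1, p0)
  expect_equal(on0$eg_kprol, on0$eg_ktr)
  # unsplit constant model: independent multipliers
  onc <- gcsf_effect(1, p, kpd_config(gcsf_effect_model = "constant"))
  expect_equal(onc$eg_ktr, 4.50)
  expect_equal(onc$eg_kprol, 1.217)
  expect_error(gcsf_effect(2, p), "indicator")
})

test_that("ODE right-hand side: steady state, feedback, gamma = 0", {
  p <- kpd_params()
  s <- c(prol = p$circ0, transit1 = p$circ0, transit2 = p$circ0,
         transit3 = p$circ0, circ = p$circ0, a_p = 0, a_c = 0)
  expect_equal(unname(ode_rhs(0, s, p)), rep(0, 7), tolerance = 1e-12)
  # circ below baseline amplifies proliferation beyond turnover
  s2 <- s
  s2[["circ"]] <- p$circ0 / 2
  d <- ode_rhs(0, s2, p)
  rates <- derive_rates(p)
  expect_gt(d[["prol"]] + rates$ktr0 * s2[["prol"]],
            rates$kprol0 * s2[["prol"]])
  # gamma = 0 removes the feedback entirely
  p0 <- kpd_params(gamma = 0)
  d0 <- ode_rhs(0, s2, p0)
  expect_equal(d0[["prol"]], rates$kprol0 * s2[["prol"]] -
                 rates$ktr0 * s2[["prol"]])
  expect_error(ode_rhs(0, replace(s, 1, NaN), p), "finite")
})

test_that("parameter and configuration validation rejects bad inputs", {
  expect_error(kpd_params(circ0 = -1), "circ0")
  expect_error(kpd_params(mtt = 0), "mtt")
  expect_error(kpd_params(gamma = -0.1), "gamma")
  expect_error(kpd_params(theta_sex = -1), "theta_sex")
  expect_error(kpd_config(n_transit = 4), "n_transit")
  expect_error(kpd_config(gcsf_window = 0), "gcsf_window")
  expect_error(kpd_config(drug_effect_model = "nope"))
})
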