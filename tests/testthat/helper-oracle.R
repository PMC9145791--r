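# Independent oracles and shared (cached) heavy fixtures for the test suite.

# --- fixed-step RK4 reference integrator -----------------------------------
# Self-contained re-statement of the model (virtual drug amounts integrated
# as ODE states, not analytically), deliberately independent of the package
# solver.

oracle_rhs <- function(t, y, pr, n_transit, gcsf_fun) {
  nt <- n_transit
  ap <- y[nt + 3]
  ac <- y[nt + 4]
  vir_p <- pr$kde_p * ap
  vir_c <- pr$kde_c * ac
  u <- vir_p / pr$ir50_p + vir_c / pr$ir50_c
  ed <- if (u > 0) {
    x <- (u / pr$u50)^pr$p_steep
    1 - x / (1 + x)
  } else 1
  g <- gcsf_fun(t)
  eg_ktr <- 1 + pr$theta_ktr * g
  eg_kprol <- eg_ktr * (1 + pr$theta_prol * g)
  ktr0 <- (nt + 1) / pr$mtt
  ktr <- ktr0 * eg_ktr
  kprol <- ktr0 * eg_kprol
  circ <- y[nt + 2]
  fb <- if (pr$gamma == 0) 1 else
    (pr$circ0 / max(circ, 1e-6 * pr$circ0))^pr$gamma
  d <- numeric(length(y))
  d[1] <- kprol * y[1] * ed * fb - ktr * y[1]
  for (i in 2:(nt + 1)) d[i] <- ktr * (y[i - 1] - y[i])
  d[nt + 2] <- ktr * y[nt + 1] - ktr0 * circ
  d[nt + 3] <- -pr$kde_p * ap
  d[nt + 4] <- -pr$kde_c * ac
  d
}

# doses: data.frame(time, drug, amount); returns circ at `times`
oracle_simulate <- function(pr, doses, times, n_transit = 3, window = 1.5,
                            h = 0.001) {
  gtimes <- doses$time[doses$drug == "gcsf"]
  gcsf_fun <- function(t) {
    if (!length(gtimes)) return(0)
    as.integer(any(gtimes <= t & t < gtimes + window))
  }
  bp <- sort(unique(c(0, doses$time, gtimes + window, times)))
  y <- c(rep(pr$circ0, n_transit + 2), 0, 0)
  out <- numeric(length(times))
  record <- function(tq) {
    hit <- which(abs(times - tq) < 1e-9)
    if (length(hit)) out[hit] <<- y[n_transit + 2]
  }
  apply_dose <- function(tq) {
    rows <- which(abs(doses$time - tq) < 1e-9)
    for (r in rows) {
      if (doses$drug[r] == "paclitaxel") y[n_transit + 3] <<-
          y[n_transit + 3] + doses$amount[r]
      if (doses$drug[r] == "cisplatin") y[n_transit + 4] <<-
          y[n_transit + 4] + doses$amount[r]
    }
  }
  apply_dose(bp[1])
  record(bp[1])
  for (s in seq_len(length(bp) - 1)) {
    t0 <- bp[s]
    t1 <- bp[s + 1]
    nstep <- max(1L, ceiling((t1 - t0) / h))
    hh <- (t1 - t0) / nstep
    tt <- t0
    for (k in seq_len(nstep)) {
      k1 <- oracle_rhs(tt, y, pr, n_transit, gcsf_fun)
      k2 <- oracle_rhs(tt + hh / 2, y + hh / 2 * k1, pr, n_transit, gcsf_fun)
      k3 <- oracle_rhs(tt + hh / 2, y + hh / 2 * k2, pr, n_transit, gcsf_fun)
      k4 <- oracle_rhs(tt + hh, y + hh * k3, pr, n_transit, gcsf_fun)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + hh
    }
    record(t1)
    apply_dose(t1)
  }
  out
}

oracle_pars <- function(params = kpd_params(), sex = 0, dm = 0) {
  ir50 <- params$ir50_tv * (1 + params$theta_sex * sex) *
    (1 + params$theta_dm * dm)
  list(circ0 = params$circ0, mtt = params$mtt, gamma = params$gamma,
       ir50_p = ir50, ir50_c = ir50, kde_p = params$kde_p,
       kde_c = params$kde_c, theta_ktr = params$theta_ktr,
       theta_prol = params$theta_prol, u50 = params$u50,
       p_steep = params$p_steep)
}

# --- Gauss-Hermite nodes for a standard normal (Golub-Welsch) --------------
gauss_hermite_normal <- function(n) {
  J <- matrix(0, n, n)
  for (i in seq_len(n - 1)) J[i, i + 1] <- J[i + 1, i] <- sqrt(i)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

# exact marginal -2 log-likelihood of a 1-eta model by 32-node adaptive
# Gauss-Hermite quadrature (proposal centred at the joint mode with the
# posterior-curvature scale)
quad_neg2ll_1d <- function(y, pred_fn, omega2, sigma_prop, sigma_add,
                           n_nodes = 32, center = NULL, scale = NULL) {
  ll <- function(eta) {
    f <- pred_fn(eta)
    v <- f^2 * sigma_prop^2 + sigma_add^2
    sum(dnorm(y, f, sqrt(v), log = TRUE)) +
      dnorm(eta, 0, sqrt(omega2), log = TRUE)
  }
  if (is.null(center))
    center <- optimize(function(e) -ll(e), c(-6, 6) * sqrt(omega2))$minimum
  if (is.null(scale)) {
    h <- 1e-4
    H <- -(ll(center + h) - 2 * ll(center) + ll(center - h)) / h^2
    scale <- if (is.finite(H) && H > 0) 1 / sqrt(H) else sqrt(omega2)
  }
  gh <- gauss_hermite_normal(n_nodes)
  ll_k <- vapply(seq_len(n_nodes), function(k) {
    eta <- center + scale * gh$nodes[k]
    ll(eta) - dnorm(eta, center, scale, log = TRUE)
  }, numeric(1))
  m <- max(ll_k)
  -2 * (m + log(sum(gh$weights * exp(ll_k - m))))
}

# --- shared fixture cache ---------------------------------------------------
.kpd_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .kpd_cache)) {
    assign(key, force(expr), envir = .kpd_cache)
  }
  get(key, envir = .kpd_cache)
}

# scaled-down recovery cohort + fit (acceptance criterion: 60 subjects,
# +/-20%); multi-start so estimates are not anchored to the initial IR50
acc_fit60 <- function() {
  cache_get("fit60", {
    pop <- reference_population(gcsf = FALSE)
    ds <- generate_dataset(study_design(60, seed = 401, n_cycles = 6,
                                        gcsf_policy = FALSE), pop)
    init <- initial_population(ds, kpd_config(gcsf_effect_model = "none"))
    fit <- fit_population(ds, init = init,
                          options = list(nm_maxit = 150, bfgs_maxit = 40,
                                         starts = list(list(ir50_tv = 60),
                                                       list(ir50_tv = 150))))
    list(dataset = ds, fit = fit, truth = pop)
  })
}

# G-CSF recovery cohort + full-model fit (173 subjects)
acc_fit_gcsf <- function() {
  cache_get("fit_gcsf", {
    pop <- reference_population(gcsf = TRUE)
    ds <- generate_dataset(study_design(173, seed = 2001,
                                        n_cycles = "cohort",
                                        gcsf_policy = TRUE), pop)
    init <- initial_population(ds,
                               kpd_config(gcsf_effect_model = "constant_split"))
    fit <- fit_population(ds, init = init,
                          options = list(nm_maxit = 300, bfgs_maxit = 30))
    list(dataset = ds, fit = fit, truth = pop)
  })
}

# transit-number selection: data generated with 3 transit compartments
# (covariate-free basic model), fitted with 1/2/3. Run at the 136-subject
# basic-model size: at 60 subjects the 2- vs 3-compartment AIC difference
# (~0.4) is inside optimizer noise, while at 136 the 3-compartment chain
# wins by ~8 AIC units.
acc_fits_transit <- function() {
  cache_get("fits_transit", {
    pop <- population_model(
      theta = kpd_params(theta_sex = 0, theta_dm = 0),
      omega2 = c(circ0 = 0.230^2, mtt = 0.162^2, ir50 = 0.233^2,
                 kde_p = 0.956^2, kde_c = 0.920^2),
      sigma_prop = 0.300, sigma_add = 0.527,
      config = kpd_config(gcsf_effect_model = "none"))
    ds <- generate_dataset(study_design(136, seed = 402, n_cycles = 6,
                                        gcsf_policy = FALSE), pop)
    fits <- lapply(1:3, function(nt) {
      init <- initial_population(ds,
                                 kpd_config(n_transit = nt,
                                            gcsf_effect_model = "none"),
                                 covariates = FALSE)
      # pure Laplace (quad_axes 0): the ranking compares OFVs computed
      # identically across the three structural variants
      fit_population(ds, init = init,
                     options = list(nm_maxit = 150, bfgs_maxit = 20,
                                    quad_axes = 0L))
    })
    names(fits) <- paste0("transit", 1:3)
    list(dataset = ds, fits = fits, truth = pop)
  })
}

# ODE oracle-equivalence summary over randomized draws (shared by the module
# test and the acceptance suite)
oracle_equiv_result <- function() {
  cache_get("oracle_equiv", {
    set.seed(31)
    worst <- 0
    for (r in 1:20) {
      p <- kpd_params(
        circ0 = 5.34 * exp(rnorm(1, 0, 0.2)),
        mtt = 4.64 * exp(rnorm(1, 0, 0.15)),
        gamma = 0.188 * exp(rnorm(1, 0, 0.2)),
        ir50_tv = 88.9 * exp(rnorm(1, 0, 0.2)),
        kde_p = 0.0326 * exp(rnorm(1, 0, 0.3)),
        kde_c = 0.188 * exp(rnorm(1, 0, 0.3)))
      doses <- data.frame(
        time = c(0, 1, if (r %% 4 == 0) 9.5),
        drug = c("paclitaxel", "cisplatin", if (r %% 4 == 0) "gcsf"),
        amount = c(runif(1, 100, 450), runif(1, 50, 160),
                   if (r %% 4 == 0) 1))
      tt <- sort(runif(6, 0.5, 28))
      a <- simulate_individual(p, doses, tt)
      b <- oracle_simulate(oracle_pars(p), doses, tt, h = 0.001)
      worst <- max(worst, max(abs(a - b) / pmax(abs(b), 1e-6)))
    }
    worst
  })
}

# null-covariate SCM calibration on an analytic nonlinear mixed-effects toy
scm_null_result <- function() {
  cache_get("scm_null", {
    set.seed(601)
    n_rep <- 200
    n_sub <- 20
    n_obs <- 4
    omega2 <- 0.09
    sp <- 0.15
    sa <- 0.1
    theta_true <- 5
    rejections <- 0L
    deltas <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      x <- rnorm(n_sub)                      # covariate with zero true effect
      eta <- rnorm(n_sub, 0, sqrt(omega2))
      subjects <- lapply(seq_len(n_sub), function(i) {
        f <- theta_true * exp(eta[i])
        list(y = f * (1 + rnorm(n_obs, 0, sp)) + rnorm(n_obs, 0, sa),
             x = x[i])
      })
      base_of <- function(th) laplace_ofv_generic(
        subjects, function(s, e) rep(th * exp(e[1]), n_obs),
        omega2, sp, sa)$ofv
      ext_of <- function(par) laplace_ofv_generic(
        subjects,
        function(s, e) rep(par[1] * (1 + par[2] * s$x) * exp(e[1]), n_obs),
        omega2, sp, sa)$ofv
      o_base <- optimize(base_of, c(2, 10))
      o_ext <- optim(c(o_base$minimum, 0), ext_of, method = "Nelder-Mead",
                     control = list(maxit = 200, reltol = 1e-10))
      deltas[r] <- o_base$objective - o_ext$value
      if (deltas[r] >= 6.635) rejections <- rejections + 1L
    }
    list(rejections = rejections, n_rep = n_rep, deltas = deltas)
  })
}

# prior-limit MCMC check (no observations): draw covariance vs Omega
prior_mcmc_result <- function() {
  cache_get("prior_mcmc", {
    pop <- reference_population()
    subj <- structure(list(
      id = 1,
      covariates = data.frame(sex = 0, dm = 0, bsa = 1.7),
      doses = data.frame(time = numeric(), drug = character(),
                         amount = numeric()),
      observations = data.frame(time = numeric(), anc = numeric())),
      class = "kpd_subject")
    dr <- sample_posterior(subj, pop, n_draws = 20000, seed = 88,
                           chains = 4, burn = 1500)
    list(draws = dr, omega2 = pop$omega2)
  })
}

# small posterior for risk tests: a moderately susceptible patient with two
# observed cycles
risk_draws <- function() {
  cache_get("risk_draws", {
    pop <- reference_population(gcsf = FALSE)
    reg <- build_regimen(regimen_spec(bsa = 1.7, n_cycles = 2))
    p_true <- kpd_params(circ0 = 4.2, ir50_tv = 88.9 * 0.666)  # female-typical
    anc <- simulate_individual(p_true, reg, times = c(0, 11, 28, 39), sex = 1)
    subj <- structure(list(
      id = 1,
      covariates = data.frame(sex = 1, dm = 0, bsa = 1.7),
      doses = reg,
      observations = data.frame(time = c(0, 11, 28, 39),
                                anc = anc * c(0.95, 0.9, 1.05, 0.85))),
      class = "kpd_subject")
    sample_posterior(subj, pop, n_draws = 2000, seed = 99, chains = 2,
                     burn = 600)
  })
}
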