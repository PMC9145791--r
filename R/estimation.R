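# Population estimation: Laplace approximation to the marginal likelihood,
# outer optimisation over fixed effects and variance components.

dataset_covariates <- function(dataset) {
  do.call(rbind, lapply(dataset, function(s) s$covariates))
}

# Per-subject data in the layout the C++ layer expects. The tv slot is a
# placeholder; cpp_pop_ofv receives typical values as a separate matrix.
cpp_subject <- function(subject, config) {
  obs <- subject$observations
  list(doses = dose_matrix(subject$doses),
       gcsf_window = config$gcsf_window,
       obs_t = as.numeric(obs$time),
       obs_y = as.numeric(obs$anc),
       tv = numeric(7))
}

dataset_signature <- function(dataset) {
  c(n = length(dataset),
    nobs = sum(vapply(dataset, function(s) nrow(s$observations), integer(1))),
    sum_y = sum(vapply(dataset, function(s) sum(s$observations$anc),
                       numeric(1))),
    sum_t = sum(vapply(dataset, function(s) sum(s$observations$time),
                       numeric(1))))
}

#' Joint -2 log-likelihood of one subject's data and random effects
#'
#' Evaluates
#' `sum_j [ log(2*pi*v_ij) + (y_ij - f_ij)^2 / v_ij ] + eta' Omega^-1 eta +
#' log det(2*pi*Omega)` where `f_ij` is the model prediction under `eta` and
#' `v_ij = f_ij^2 sigma_prop^2 + sigma_add^2`. This is the objective the
#' inner Laplace step minimises over `eta`, and (times -1/2) the individual
#' log-posterior kernel used for MAP/MCMC estimation.
#'
#' @param pop a [population_model()].
#' @param subject a subject record (list with `covariates`, `doses`,
#'   `observations`).
#' @param eta random-effect vector, length 5 in the order `circ0`, `mtt`,
#'   `ir50`, `kde_p`, `kde_c`; entries whose `omega2` is 0 must be 0.
#' @param rtol,atol optional solver tolerance overrides.
#' @return The joint -2 log-likelihood (numeric scalar).
#' @export
joint_neg2ll <- function(pop, subject, eta = rep(0, 5), rtol = NULL,
                         atol = NULL) {
  if (nrow(subject$observations) < 1L)
    stop("subject has no observations", call. = FALSE)
  sub <- cpp_subject(subject, pop$config)
  sub$tv <- as.numeric(typical_values(pop, subject$covariates)[1, ])
  cpp_subject_neg2ll(sub, cpp_common(pop), cpp_spec(pop$config, rtol, atol),
                     pop$omega2, pop$sigma_prop, pop$sigma_add,
                     as.numeric(eta))
}

#' Laplace-approximate marginal -2 log-likelihood (OFV)
#'
#' For each subject the joint -2 log-likelihood `g(eta)` is minimised over
#' the random effects by a damped Newton method (finite-difference gradient
#' and Hessian), and the subject's contribution is
#' `g(eta_hat) + log det H - d*log(4*pi)` with `H` the Hessian of `g` at the
#' mode. All `2*pi` constants are included, so absolute values are not
#' comparable with software that drops constants; differences (delta-OFV)
#' are.
#'
#' @param pop a [population_model()].
#' @param dataset a list of subject records ([generate_dataset()] output or
#'   [read_dataset()]).
#' @param eta_start optional warm-start matrix (n_subjects x 5).
#' @param rtol,atol solver tolerance overrides (defaults: the config's).
#' @param inner_maxit,inner_gtol inner Newton controls.
#' @param quad_axes refine the Gaussian (Laplace) approximation with a
#'   3-node Gauss-Hermite product rule over this many trailing whitened
#'   axes of the mode (0 = pure Laplace). The trailing axes cover the
#'   strongly nonlinear virtual-elimination random effects.
#' @return A list of class `"kpd_ofv"`: `ofv` (total), `indiv` (per-subject
#'   contributions), `eta` (modes, n x 5), `flags` (0 = clean).
#' @export
laplace_ofv <- function(pop, dataset, eta_start = NULL, rtol = NULL,
                        atol = NULL, inner_maxit = 10L, inner_gtol = 1e-3,
                        quad_axes = 0L) {
  subs <- lapply(dataset, cpp_subject, config = pop$config)
  covs <- dataset_covariates(dataset)
  tv <- typical_values(pop, covs)
  if (is.null(eta_start)) eta_start <- matrix(0, length(dataset), 5)
  r <- cpp_pop_ofv(subs, tv, cpp_common(pop),
                   cpp_spec(pop$config, rtol, atol), pop$omega2,
                   pop$sigma_prop, pop$sigma_add, eta_start,
                   as.integer(inner_maxit), inner_gtol,
                   as.integer(quad_axes))
  structure(list(ofv = r$ofv, indiv = as.numeric(r$indiv), eta = r$eta,
                 flags = r$flags), class = "kpd_ofv")
}

# ---------------------------------------------------------------------------
# Generic (model-agnostic) Laplace machinery.
# ---------------------------------------------------------------------------

fd_hessian <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  fp <- fm <- numeric(d)
  for (i in seq_len(d)) {
    e <- x; e[i] <- x[i] + h; fp[i] <- fn(e)
    e[i] <- x[i] - h; fm[i] <- fn(e)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (d > 1) {
    for (i in 1:(d - 1)) for (j in (i + 1):d) {
      e <- x; e[i] <- x[i] + h; e[j] <- x[j] + h
      H[i, j] <- H[j, i] <- (fn(e) - fp[i] - fp[j] + f0) / h^2
    }
  }
  H
}

#' Laplace marginal -2 log-likelihood for a user-supplied prediction model
#'
#' The same Laplace construction as [laplace_ofv()], but for an arbitrary
#' prediction function instead of the built-in ODE model. Intended for
#' analytic test models and for calibration studies of the estimation
#' machinery (it is how the package verifies its Laplace approximation
#' against exact marginals and quadrature).
#'
#' @param subjects list of subjects; each must carry a numeric vector `y`
#'   plus whatever `pred_fn` needs.
#' @param pred_fn function `(subject, eta) -> predictions` (same length as
#'   `subject$y`).
#' @param omega2 random-effect variances (length = dimension of `eta`).
#' @param sigma_prop,sigma_add combined residual-error SDs.
#' @return A list with `ofv`, `indiv` and `eta` (matrix of modes).
#' @export
laplace_ofv_generic <- function(subjects, pred_fn, omega2, sigma_prop,
                                sigma_add) {
  d <- length(omega2)
  if (any(omega2 <= 0)) stop("omega2 must be positive here", call. = FALSE)
  g <- function(subject, eta) {
    f <- pred_fn(subject, eta)
    v <- pmax(f^2 * sigma_prop^2 + sigma_add^2, 1e-12)
    sum(log(2 * pi * v) + (subject$y - f)^2 / v) +
      sum(eta^2 / omega2 + log(2 * pi * omega2))
  }
  indiv <- numeric(length(subjects))
  etas <- matrix(0, length(subjects), d)
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    gi <- function(e) g(s, e)
    opt <- optim(rep(0, d), gi, method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 200))
    H <- fd_hessian(gi, opt$par, h = 1e-4)
    ld <- determinant(H, logarithm = TRUE)
    indiv[i] <- opt$value + as.numeric(ld$modulus) - d * log(4 * pi)
    etas[i, ] <- opt$par
  }
  list(ofv = sum(indiv), indiv = indiv, eta = etas)
}

# ---------------------------------------------------------------------------
# Outer optimisation
# ---------------------------------------------------------------------------

# Transform registry for the outer parameter vector.
t_fwd <- function(x, tr) switch(tr, log = log(x), log1p = log(1 + x),
                                identity = x)
t_inv <- function(x, tr) switch(tr, log = exp(x), log1p = exp(x) - 1,
                                identity = x)

# Parameter table: every potentially estimable scalar of a population model.
fit_param_table <- function(pop) {
  th <- pop$theta
  fe <- data.frame(
    name = c("circ0", "mtt", "gamma", "ir50_tv", "theta_sex", "theta_dm",
             "kde_p", "kde_c", "theta_ktr", "theta_prol", "u50", "p_steep",
             "scale1", "scale2", "scale3", "kde_g", "ir50_g"),
    value = c(th$circ0, th$mtt, th$gamma, th$ir50_tv, th$theta_sex,
              th$theta_dm, th$kde_p, th$kde_c, th$theta_ktr, th$theta_prol,
              th$u50, th$p_steep, th$scale1, th$scale2, th$scale3, th$kde_g,
              th$ir50_g),
    transform = c("log", "log", "log", "log", "log1p", "log1p", "log", "log",
                  "log", "log", "log", "log", "identity", "identity",
                  "identity", "log", "log"),
    block = "theta", stringsAsFactors = FALSE)
  rel <- if (length(pop$relations)) data.frame(
    name = vapply(pop$relations, relation_label, ""),
    value = vapply(pop$relations, function(r) r$theta, numeric(1)),
    transform = "identity", block = "relation", stringsAsFactors = FALSE)
  om <- data.frame(
    name = paste0("omega_", names(pop$omega2)),
    value = sqrt(pop$omega2), transform = "log", block = "omega",
    stringsAsFactors = FALSE)
  sg <- data.frame(name = c("sigma_prop", "sigma_add"),
                   value = c(pop$sigma_prop, pop$sigma_add),
                   transform = "log", block = "sigma",
                   stringsAsFactors = FALSE)
  out <- rbind(fe, if (length(pop$relations)) rel, om, sg)
  rownames(out) <- NULL
  out
}

# Names fixed automatically: structural constants of the selected model,
# submodel parameters not in play, zero variance components, and any theta
# whose positivity transform cannot represent the initial value.
auto_fixed <- function(pop, tab) {
  fx <- c("u50", "p_steep", "scale1", "scale2", "scale3", "kde_g", "ir50_g")
  if (pop$config$gcsf_effect_model %in% c("none"))
    fx <- c(fx, "theta_ktr", "theta_prol")
  if (pop$config$gcsf_effect_model %in% c("linear", "emax"))
    fx <- c(fx, "theta_ktr", "theta_prol")
  if (pop$config$drug_effect_model == "log_linear")
    fx <- c(fx, "ir50_tv", "theta_sex", "theta_dm")
  if (pop$theta$gamma == 0) fx <- c(fx, "gamma")
  if (pop$theta$theta_sex == 0) fx <- c(fx, "theta_sex")
  if (pop$theta$theta_dm == 0) fx <- c(fx, "theta_dm")
  if (pop$theta$theta_ktr == 0) fx <- c(fx, "theta_ktr")
  if (pop$theta$theta_prol == 0) fx <- c(fx, "theta_prol")
  zero_om <- tab$name[tab$block == "omega" & tab$value == 0]
  zero_sg <- tab$name[tab$block == "sigma" & tab$value == 0]
  unique(c(fx, zero_om, zero_sg))
}

set_param <- function(pop, name, value) {
  tabfe <- c("circ0", "mtt", "gamma", "ir50_tv", "theta_sex", "theta_dm",
             "kde_p", "kde_c", "theta_ktr", "theta_prol", "u50", "p_steep",
             "scale1", "scale2", "scale3", "kde_g", "ir50_g")
  if (name %in% tabfe) {
    pop$theta[[name]] <- value
  } else if (grepl("^omega_", name)) {
    pop$omega2[[sub("^omega_", "", name)]] <- value^2
  } else if (name == "sigma_prop") {
    pop$sigma_prop <- value
  } else if (name == "sigma_add") {
    pop$sigma_add <- value
  } else {
    hit <- FALSE
    for (k in seq_along(pop$relations)) {
      if (relation_label(pop$relations[[k]]) == name) {
        pop$relations[[k]]$theta <- value
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("unknown parameter: ", name, call. = FALSE)
  }
  pop
}

unpack_pop <- function(pv, free_tab, pop) {
  for (k in seq_along(pv)) {
    pop <- set_param(pop, free_tab$name[k],
                     t_inv(pv[k], free_tab$transform[k]))
  }
  pop
}

fit_options <- function(options) {
  o <- list(nm_maxit = 100L, bfgs_maxit = 40L, bfgs_restarts = 4L,
            restart_tol = 0.05, rtol = 1e-6, atol = 1e-8,
            solver = "fixed", h_base = 1, h_gcsf = 0.25,
            inner_maxit = 10L, inner_gtol = 1e-3, quad_axes = 2L,
            reltol = 1e-9, method = "nmbfgs", starts = NULL, trace = 0L,
            se = FALSE)
  for (nm in names(options)) {
    if (!nm %in% names(o)) stop("unknown option: ", nm, call. = FALSE)
    o[[nm]] <- options[[nm]]
  }
  o
}

#' Fit the population model by Laplace-approximate maximum likelihood
#'
#' Minimises the Laplace marginal -2 log-likelihood ([laplace_ofv()]) over
#' the free parameters, carried internally on unconstrained scales (log for
#' positive parameters and variance components, `log(1 + theta)` for the
#' binary covariate factors). The outer search runs a derivative-free
#' Nelder-Mead stage followed by a BFGS polish with finite-difference
#' gradients; per-subject random-effect modes are warm-started across
#' objective evaluations. The best evaluated point is always kept, so the
#' final OFV never exceeds the initial one.
#'
#' @param dataset list of subject records.
#' @param init initial [population_model()]; also fixes the model structure
#'   (transit count, submodels, covariate relations).
#' @param fixed character vector of parameter names to fix in addition to
#'   the automatic set (structural constants of the selected submodels, zero
#'   variance components). Names as in the printed fit summary, e.g.
#'   `"gamma"`, `"omega_kde_c"`, `"ir50:age"`.
#' @param options list of controls: `nm_maxit` (Nelder-Mead iterations per
#'   start, default 100), `starts` (extra starting points: a list of named
#'   lists of parameter overrides, each seeding its own Nelder-Mead stage;
#'   useful along weakly identified directions), `bfgs_maxit` /
#'   `bfgs_restarts` / `restart_tol` (BFGS polish rounds; each round
#'   restarts from the best point until the OFV improves by less than
#'   `restart_tol`), `method` (`"nmbfgs"`, `"nm"`, `"bfgs"`), `solver`
#'   (`"fixed"` default: equidistant-step likelihood integration, smooth in
#'   the parameters; `"adaptive"` uses `rtol`/`atol`), `h_base`/`h_gcsf`
#'   (fixed step sizes, days), `inner_maxit`/`inner_gtol` (inner Newton),
#'   `quad_axes` (Gauss-Hermite refinement of the Laplace value, default 2),
#'   `se` (asymptotic standard errors by a finite-difference Hessian; off by
#'   default), `trace`.
#' @return An object of class `"kpd_fit"` with the estimated
#'   [population_model()] in `$pop`, `$ofv`, `$aic = ofv + 2k`, `$k`,
#'   per-subject random-effect modes in `$eta`, convergence information, and
#'   optionally `$se`/`$vcov`. Methods: `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `residuals`, `simulate`, `plot`.
#' @examples
#' \donttest{
#' pop <- reference_population(gcsf = FALSE)
#' ds <- generate_dataset(study_design(12, seed = 7, gcsf_policy = FALSE), pop)
#' fit <- fit_population(ds, init = pop,
#'                       fixed = c("gamma", "theta_sex", "theta_dm"),
#'                       options = list(nm_maxit = 30, bfgs_maxit = 5))
#' coef(fit)["mtt"]
#' }
#' @export
fit_population <- function(dataset, init = reference_population(),
                           fixed = NULL, options = list()) {
  stopifnot(inherits(init, "kpd_population"))
  if (length(dataset) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (any(vapply(dataset, function(s) nrow(s$observations) == 0, logical(1))))
    stop("every subject needs at least one observation", call. = FALSE)
  opts <- fit_options(options)

  tab <- fit_param_table(init)
  fx <- union(auto_fixed(init, tab), fixed)
  bad <- setdiff(fixed, tab$name)
  if (length(bad)) stop("unknown parameter in fixed: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  free_tab <- tab[!tab$name %in% fx, , drop = FALSE]
  if (nrow(free_tab) == 0L) stop("no free parameters", call. = FALSE)
  pv0 <- mapply(t_fwd, free_tab$value, free_tab$transform)

  subs <- lapply(dataset, cpp_subject, config = init$config)
  covs <- dataset_covariates(dataset)
  spec <- cpp_spec(init$config, opts$rtol, opts$atol,
                   fixed_step = identical(opts$solver, "fixed"),
                   h_base = opts$h_base, h_gcsf = opts$h_gcsf)
  env <- new.env(parent = emptyenv())
  env$eta <- matrix(0, length(dataset), 5)
  env$best <- Inf
  env$best_pv <- pv0
  env$neval <- 0L

  obj <- function(pv) {
    env$neval <- env$neval + 1L
    pop <- tryCatch(unpack_pop(pv, free_tab, init), error = function(e) NULL)
    if (is.null(pop)) return(1e10)
    tv <- tryCatch(typical_values(pop, covs), error = function(e) NULL)
    if (is.null(tv)) return(1e10)
    r <- cpp_pop_ofv(subs, tv, cpp_common(pop), spec, pop$omega2,
                     pop$sigma_prop, pop$sigma_add, env$eta,
                     as.integer(opts$inner_maxit), opts$inner_gtol,
                     as.integer(opts$quad_axes))
    if (!is.finite(r$ofv) || r$ofv >= 1e9) return(1e10)
    env$eta <- r$eta
    if (r$ofv < env$best) {
      env$best <- r$ofv
      env$best_pv <- pv
      if (opts$trace > 0)
        cat(sprintf("eval %5d  ofv %.4f\n", env$neval, r$ofv))
    }
    env$last_pv <- pv
    env$last_val <- r$ofv
    r$ofv
  }

  # forward-difference gradient (reuses the cached objective value at pv)
  grd <- function(pv) {
    f0 <- if (!is.null(env$last_pv) && isTRUE(all(pv == env$last_pv)))
      env$last_val else obj(pv)
    h <- 1e-3
    vapply(seq_along(pv), function(i) {
      p2 <- pv
      p2[i] <- pv[i] + h
      (obj(p2) - f0) / h
    }, numeric(1))
  }

  ofv_init <- obj(pv0)
  conv <- c(nm = NA_integer_, bfgs = NA_integer_)
  if (opts$method %in% c("nmbfgs", "nm") && length(pv0) > 1L &&
      opts$nm_maxit > 0) {
    # additional starting points: each entry is a named list of theta
    # overrides; a Nelder-Mead stage runs from each and the best point wins
    # (weakly identified directions would otherwise anchor to the single
    # initial value)
    start_pvs <- list(pv0)
    for (s in opts$starts) {
      pop_s <- init
      for (nm_s in names(s)) pop_s <- set_param(pop_s, nm_s, s[[nm_s]])
      tab_s <- fit_param_table(pop_s)
      tab_s <- tab_s[match(free_tab$name, tab_s$name), ]
      start_pvs <- c(start_pvs,
                     list(mapply(t_fwd, tab_s$value, tab_s$transform)))
    }
    for (pv_s in start_pvs) {
      o1 <- tryCatch(optim(pv_s, obj, method = "Nelder-Mead",
                           control = list(maxit = opts$nm_maxit)),
                     error = function(e) NULL)
      if (!is.null(o1)) conv["nm"] <- o1$convergence
    }
  }
  if (opts$method %in% c("nmbfgs", "bfgs") && opts$bfgs_maxit > 0) {
    # restarted BFGS: each round resets the Hessian approximation, which
    # reliably escapes the premature flat-stretch stops of a single run
    for (round in seq_len(opts$bfgs_restarts)) {
      ofv_before <- env$best
      o2 <- tryCatch(optim(env$best_pv, obj, gr = grd, method = "BFGS",
                           control = list(maxit = opts$bfgs_maxit,
                                          reltol = opts$reltol)),
                     error = function(e) NULL)
      if (!is.null(o2)) conv["bfgs"] <- o2$convergence
      if (!is.finite(ofv_before) ||
          ofv_before - env$best < opts$restart_tol) break
    }
  }

  pv_hat <- env$best_pv
  ofv <- obj(pv_hat)          # refresh eta modes at the optimum
  ofv <- min(ofv, env$best)
  pop_hat <- unpack_pop(pv_hat, free_tab, init)
  k <- nrow(free_tab)

  se <- vcov <- NULL
  if (isTRUE(opts$se)) {
    H <- tryCatch(fd_hessian(obj, pv_hat, h = 1e-3), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(2 * solve(H), error = function(e) NULL)  # ofv = -2ll
      if (!is.null(V) && all(diag(V) > 0)) {
        # delta method back to the natural scale
        grad <- vapply(seq_len(k), function(i) {
          switch(free_tab$transform[i],
                 log = exp(pv_hat[i]), log1p = exp(pv_hat[i]), identity = 1)
        }, numeric(1))
        vcov <- V * tcrossprod(grad)
        dimnames(vcov) <- list(free_tab$name, free_tab$name)
        se <- sqrt(diag(vcov))
      }
    }
  }

  structure(list(pop = pop_hat, ofv = ofv, aic = ofv + 2 * k, k = k,
                 ofv_init = ofv_init, free = free_tab$name, fixed = fx,
                 eta = env$eta, convergence = conv, n_eval = env$neval,
                 se = se, vcov = vcov, data_sig = dataset_signature(dataset),
                 n_subjects = length(dataset), options = opts,
                 call = match.call()),
            class = "kpd_fit")
}

#' Rank fitted models by AIC
#'
#' @param ... `kpd_fit` objects (optionally named), or a single list of them.
#' @return A data.frame ranked by ascending `AIC = OFV + 2k`; ties broken by
#'   fewer parameters. All fits must be on the identical dataset.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "kpd_fit"))
    fits <- fits[[1]]
  if (!all(vapply(fits, inherits, logical(1), "kpd_fit")))
    stop("all arguments must be kpd_fit objects", call. = FALSE)
  if (length(fits) < 2L) stop("need at least two fits", call. = FALSE)
  sigs <- vapply(fits, function(f) f$data_sig, numeric(4))
  if (any(apply(sigs, 1, function(x) max(x) - min(x)) > 1e-8))
    stop("fits are not on the identical dataset", call. = FALSE)
  nm <- names(fits)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("model", seq_along(fits))
  out <- data.frame(model = nm,
                    n_transit = vapply(fits, function(f)
                      f$pop$config$n_transit, integer(1)),
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    ofv = vapply(fits, function(f) f$ofv, numeric(1)))
  out$aic <- out$ofv + 2 * out$k
  out <- out[order(out$aic, out$k), ]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}
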