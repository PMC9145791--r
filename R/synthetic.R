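# Synthetic sparse-EMR cohort generation.

#' Study design for synthetic cohorts
#'
#' Describes the sampling design used by [generate_dataset()]: cohort size,
#' per-subject cycle counts, the sparse ANC sampling rule (one pre-dose
#' sample on day 0 of each cycle plus one mid-cycle sample on a uniform day
#' in `midcycle_range`), and the toxicity policy. When `gcsf_policy` is on,
#' an observation below the grade-4 threshold triggers a G-CSF
#' administration at that observation time, one extra monitoring sample the
#' day after, and the 25% dose reduction from the next cycle on.
#'
#' @param n_subjects number of virtual patients.
#' @param seed integer seed; required, the generator has no silent default.
#' @param n_cycles `"cohort"` to draw per-subject cycle counts from the
#'   observed cohort distribution (2:6 with weights 8/37/27/12/89), or a
#'   fixed integer 1-6.
#' @param samples_per_cycle scheduled ANC samples per cycle (2 = the sparse
#'   EMR design; larger values add further uniform mid-cycle samples).
#' @param midcycle_range day range (within a cycle) of the mid-cycle sample.
#' @param gcsf_policy trigger G-CSF on observed grade-4 neutropenia.
#' @param gcsf_extra_sample add one monitoring sample 1 day after each
#'   G-CSF administration (the EMR cohort had extra samples tied to G-CSF
#'   treatment).
#' @param grade4_threshold ANC threshold, 1e9 cells/L.
#' @return An object of class `"kpd_design"`.
#' @export
study_design <- function(n_subjects, seed, n_cycles = "cohort",
                         samples_per_cycle = 2, midcycle_range = c(8, 15),
                         gcsf_policy = TRUE, gcsf_extra_sample = TRUE,
                         grade4_threshold = 0.5) {
  if (missing(seed) || is.null(seed))
    stop("study_design requires an explicit seed", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (samples_per_cycle < 1)
    stop("samples_per_cycle must be >= 1", call. = FALSE)
  if (!identical(n_cycles, "cohort")) {
    n_cycles <- as.integer(n_cycles)
    if (n_cycles < 1L || n_cycles > 6L)
      stop("fixed n_cycles must be in 1..6", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 n_cycles = n_cycles,
                 samples_per_cycle = as.integer(samples_per_cycle),
                 midcycle_range = midcycle_range,
                 gcsf_policy = isTRUE(gcsf_policy),
                 gcsf_extra_sample = isTRUE(gcsf_extra_sample),
                 grade4_threshold = grade4_threshold),
            class = "kpd_design")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Sample virtual-patient covariates
#'
#' Draws covariates matching the NSCLC cohort summaries: 26.6% female,
#' 18.5% diabetic, BSA ~ Normal(1.70, 0.18) truncated to the observed range
#' (1.24, 2.30) m2, age ~ Normal(61.0, 9.2) truncated to (38, 82) years,
#' ALT log-normal with median 16 IU/L and mean 21 IU/L, creatinine
#' clearance ~ Normal(81.0, 23.6) truncated to (36.8, 153.6) mL/min, and
#' binary/categorical rates for hypertension (49.1%), tuberculosis (12.1%),
#' smoking status (29.5/41.6/28.9% never/current/ex) and ECOG 1 (13.9%).
#'
#' @param n number of subjects.
#' @param seed optional seed; omit to use the current RNG state (as
#'   [generate_dataset()] does).
#' @return `data.frame` with columns `sex`, `dm`, `bsa`, `age`, `alt`,
#'   `clcr`, `htn`, `tb`, `smoking` (0 never / 1 current / 2 ex), `ecog`.
#' @export
sample_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    sex = rbinom(n, 1, 0.266),
    dm = rbinom(n, 1, 0.185),
    bsa = rtrunc_norm(n, 1.70, 0.18, 1.24, 2.30),
    age = rtrunc_norm(n, 61.0, 9.2, 38, 82),
    alt = exp(rnorm(n, log(16), 0.738)),
    clcr = rtrunc_norm(n, 81.0, 23.6, 36.8, 153.6),
    htn = rbinom(n, 1, 0.491),
    tb = rbinom(n, 1, 0.121),
    smoking = sample(0:2, n, replace = TRUE, prob = c(0.295, 0.416, 0.289)),
    ecog = rbinom(n, 1, 0.139))
}

#' Sample individual parameters under the exponential IIV model
#'
#' For each IIV-bearing parameter `P`, the individual value is
#' `P_i = P_typical(covariates) * exp(eta_P)` with independent
#' `eta_P ~ Normal(0, omega2_P)`. The typical IR50 passes through the
#' covariate model first.
#'
#' @param pop a [population_model()].
#' @param covariates data.frame of subject covariates (one row per subject).
#' @param seed optional seed; omit to use the current RNG state.
#' @return A list with `etas` (n x 5 matrix, columns `circ0`, `mtt`, `ir50`,
#'   `kde_p`, `kde_c`) and `values` (n x 7 matrix of individual parameter
#'   values: `circ0`, `mtt`, `gamma`, `ir50_p`, `ir50_c`, `kde_p`, `kde_c`).
#' @export
sample_individual_params <- function(pop, covariates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  om <- pop$omega2
  etas <- vapply(names(om), function(k) rnorm(n, 0, sqrt(om[[k]])),
                 numeric(n))
  etas <- matrix(etas, nrow = n,
                 dimnames = list(NULL, names(om)))
  tv <- typical_values(pop, covariates)
  values <- tv
  values[, "circ0"] <- tv[, "circ0"] * exp(etas[, "circ0"])
  values[, "mtt"] <- tv[, "mtt"] * exp(etas[, "mtt"])
  values[, "ir50_p"] <- tv[, "ir50_p"] * exp(etas[, "ir50"])
  values[, "ir50_c"] <- tv[, "ir50_c"] * exp(etas[, "ir50"])
  values[, "kde_p"] <- tv[, "kde_p"] * exp(etas[, "kde_p"])
  values[, "kde_c"] <- tv[, "kde_c"] * exp(etas[, "kde_c"])
  list(etas = etas, values = values)
}

#' Apply combined residual error to model predictions
#'
#' `y = pred * (1 + e1) + e2` with `e1 ~ N(0, sigma_prop^2)` and
#' `e2 ~ N(0, sigma_add^2)`. A non-positive draw is resampled once and then
#' floored at 0.001 (ANC observations are positive).
#'
#' @param pred model-predicted ANC, 1e9 cells/L (vectorised).
#' @param pop a [population_model()] (only the sigmas are used).
#' @param seed optional seed; omit to use the current RNG state.
#' @return Observed ANC values, same length as `pred`.
#' @export
apply_residual_error <- function(pred, pop, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(pred < 0)) stop("pred must be non-negative", call. = FALSE)
  n <- length(pred)
  draw <- function(idx) pred[idx] * (1 + rnorm(length(idx), 0, pop$sigma_prop)) +
    rnorm(length(idx), 0, pop$sigma_add)
  y <- draw(seq_len(n))
  bad <- which(y <= 0)
  if (length(bad)) {
    y[bad] <- draw(bad)
    y[y <= 0] <- 0.001
  }
  y
}

# Simulate one subject's true ANC at given times from individual values.
simulate_values <- function(values, pop, doses, times, rtol = NULL,
                            atol = NULL) {
  pars <- cpp_pars(values[["circ0"]], values[["mtt"]], values[["gamma"]],
                   values[["ir50_p"]], values[["ir50_c"]],
                   values[["kde_p"]], values[["kde_c"]], pop$theta)
  st <- cpp_simulate(as.numeric(times), dose_matrix(doses),
                     pop$config$gcsf_window, pars,
                     cpp_spec(pop$config, rtol, atol))
  st[, pop$config$n_transit + 2L]
}

#' Generate a synthetic sparse cohort
#'
#' Simulates virtual patients cycle by cycle under the treatment protocol:
#' covariates and random effects are drawn, each cycle's scheduled ANC
#' samples are generated from the individual trajectory with residual error,
#' and observed grade-4 neutropenia feeds back on management (G-CSF at the
#' observation time, an extra monitoring sample the next day, 25% dose
#' reduction from the following cycle on). Everything is reproducible from
#' `design$seed`.
#'
#' @param design a [study_design()].
#' @param pop the generating [population_model()].
#' @return An object of class `"kpd_dataset"`: a list of subject records
#'   (`id`, `covariates`, `doses`, `observations`, `etas_true`,
#'   `reduced_cycles`, `gcsf_times`), with the generating truth attached as
#'   attributes (`etas`, `covariates`, `design`).
#' @examples
#' pop <- reference_population(gcsf = FALSE)
#' ds <- generate_dataset(study_design(3, seed = 42, gcsf_policy = FALSE), pop)
#' length(ds); nrow(ds[[1]]$observations)
#' @export
generate_dataset <- function(design, pop) {
  stopifnot(inherits(design, "kpd_design"), inherits(pop, "kpd_population"))
  set.seed(design$seed)
  n <- design$n_subjects
  cov <- sample_covariates(n)
  ncyc <- if (identical(design$n_cycles, "cohort"))
    sample(2:6, n, replace = TRUE, prob = c(8, 37, 27, 12, 89) / 173)
  else rep(design$n_cycles, n)
  ip <- sample_individual_params(pop, cov)

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    rspec <- regimen_spec(bsa = cov$bsa[i], n_cycles = ncyc[i],
                          grade4_threshold = design$grade4_threshold)
    reduced <- integer()
    gcsf_times <- numeric()
    obs_t <- obs_y <- numeric()
    for (cc in seq_len(ncyc[i])) {
      t0 <- (cc - 1) * rspec$cycle_length
      extra_mid <- design$samples_per_cycle - 1L
      t_sched <- c(t0, if (extra_mid > 0)
        t0 + sort(runif(extra_mid, design$midcycle_range[1],
                        design$midcycle_range[2])))
      reg <- build_regimen(rspec, reduced, gcsf_times)
      pred <- simulate_values(ip$values[i, ], pop, reg, t_sched)
      y <- apply_residual_error(pred, pop)
      obs_t <- c(obs_t, t_sched)
      obs_y <- c(obs_y, y)
      g4 <- which(y < design$grade4_threshold)
      if (length(g4) && design$gcsf_policy) {
        tg <- t_sched[g4[1]]
        gcsf_times <- c(gcsf_times, tg)
        if (design$gcsf_extra_sample) {
          regg <- build_regimen(rspec, reduced, gcsf_times)
          pm <- simulate_values(ip$values[i, ], pop, regg, tg + 1)
          obs_t <- c(obs_t, tg + 1)
          obs_y <- c(obs_y, apply_residual_error(pm, pop))
        }
      }
      if (length(g4) && cc < ncyc[i])
        reduced <- sort(unique(c(reduced, seq.int(cc + 1L, ncyc[i]))))
    }
    ord <- order(obs_t)
    subjects[[i]] <- structure(list(
      id = i,
      covariates = cov[i, , drop = FALSE],
      doses = build_regimen(rspec, reduced, gcsf_times),
      observations = data.frame(time = obs_t[ord], anc = obs_y[ord]),
      etas_true = ip$etas[i, ],
      reduced_cycles = reduced,
      gcsf_times = gcsf_times,
      n_cycles = ncyc[i]), class = "kpd_subject")
  }
  structure(subjects, class = "kpd_dataset", etas = ip$etas,
            covariates = cov, design = design)
}

#' @export
print.kpd_dataset <- function(x, ...) {
  nobs <- sum(vapply(x, function(s) nrow(s$observations), integer(1)))
  ng <- sum(vapply(x, function(s) length(s$gcsf_times) > 0, logical(1)))
  cat("Synthetic cohort:", length(x), "subjects,", nobs, "ANC observations,",
      ng, "subjects with G-CSF rescue\n")
  invisible(x)
}
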