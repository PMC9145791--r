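#' Structural model parameters
#'
#' Constructs and validates the fixed-effect parameter set of the
#' myelosuppression model. Defaults are the published final-model estimates
#' for the NSCLC paclitaxel/cisplatin cohort; every value can be overridden.
#'
#' @param circ0 baseline circulating neutrophil count, 1e9 cells/L.
#' @param mtt mean transit time through the maturation chain, days. The
#'   baseline transit rate constant is `ktr0 = (n_transit + 1)/mtt` and the
#'   proliferation and circulation loss rate constants equal `ktr0` at
#'   baseline.
#' @param gamma feedback exponent on `(circ0/circ)`; `0` switches the
#'   feedback off.
#' @param ir50_tv typical virtual infusion rate producing half-maximal drug
#'   effect, mg/day (shared between paclitaxel and cisplatin in the final
#'   model).
#' @param theta_sex,theta_dm fractional shifts of `ir50_tv` for female sex
#'   and diabetes mellitus: `IR50 = ir50_tv * (1 + theta_sex*SEX) *
#'   (1 + theta_dm*DM)`.
#' @param kde_p,kde_c virtual elimination rate constants of the paclitaxel
#'   and cisplatin K-PD compartments, /day.
#' @param theta_ktr,theta_prol G-CSF constant-model multipliers: while the
#'   G-CSF indicator is 1, `Ktr = ktr0 * (1 + theta_ktr)` and (split
#'   parameterisation) `Kprol = ktr0 * (1 + theta_ktr) * (1 + theta_prol)`.
#' @param u50,p_steep response-surface interaction parameters (units at
#'   half-maximal combined effect, and steepness). Fixed at 1 in the final
#'   model, giving the additive surface `Ed = 1 - U/(1 + U)` with
#'   `U = VIR_p/IR50_p + VIR_c/IR50_c`.
#' @param scale1,scale2 log-linear drug-effect slopes, day/mg (alternative
#'   drug-effect model).
#' @param scale3,kde_g,ir50_g parameters of the optional K-PD G-CSF effect
#'   models (linear slope, virtual elimination rate /day, half-effect
#'   infusion rate).
#' @param ir50_c_tv optional separate typical IR50 for cisplatin; `NULL`
#'   (default) shares `ir50_tv` between both drugs.
#'
#' @return An object of class `"kpd_params"` (named list).
#' @examples
#' p <- kpd_params()
#' p$mtt
#' kpd_params(gamma = 0)  # feedback switched off
#' @export
kpd_params <- function(circ0 = 5.34, mtt = 4.64, gamma = 0.188,
                       ir50_tv = 88.9, theta_sex = -0.334, theta_dm = 0.485,
                       kde_p = 0.0326, kde_c = 0.188,
                       theta_ktr = 3.50, theta_prol = 0.217,
                       u50 = 1, p_steep = 1,
                       scale1 = 0, scale2 = 0,
                       scale3 = 0, kde_g = 0.693, ir50_g = 1,
                       ir50_c_tv = NULL) {
  p <- list(circ0 = circ0, mtt = mtt, gamma = gamma, ir50_tv = ir50_tv,
            theta_sex = theta_sex, theta_dm = theta_dm,
            kde_p = kde_p, kde_c = kde_c,
            theta_ktr = theta_ktr, theta_prol = theta_prol,
            u50 = u50, p_steep = p_steep,
            scale1 = scale1, scale2 = scale2, scale3 = scale3,
            kde_g = kde_g, ir50_g = ir50_g, ir50_c_tv = ir50_c_tv)
  validate_kpd_params(p)
  structure(p, class = "kpd_params")
}

validate_kpd_params <- function(p) {
  stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in setdiff(names(p), "ir50_c_tv")) {
    stop_if(!num1(p[[nm]]), sprintf("parameter '%s' must be a finite number", nm))
  }
  stop_if(p$circ0 <= 0, "circ0 must be positive")
  stop_if(p$mtt <= 0, "mtt must be positive")
  stop_if(p$gamma < 0, "gamma must be non-negative")
  stop_if(p$ir50_tv <= 0, "ir50_tv must be positive")
  stop_if(p$kde_p <= 0, "kde_p must be positive")
  stop_if(p$kde_c <= 0, "kde_c must be positive")
  stop_if(p$kde_g <= 0, "kde_g must be positive")
  stop_if(p$ir50_g <= 0, "ir50_g must be positive")
  stop_if(p$u50 <= 0, "u50 must be positive")
  stop_if(p$p_steep <= 0, "p_steep must be positive")
  stop_if(p$theta_ktr < 0, "theta_ktr must be non-negative")
  stop_if(p$theta_prol < 0, "theta_prol must be non-negative")
  stop_if(1 + p$theta_sex <= 0, "1 + theta_sex must be positive")
  stop_if(1 + p$theta_dm <= 0, "1 + theta_dm must be positive")
  if (!is.null(p$ir50_c_tv))
    stop_if(!num1(p$ir50_c_tv) || p$ir50_c_tv <= 0,
            "ir50_c_tv must be a positive number or NULL")
  invisible(p)
}

#' Structural model configuration
#'
#' Model-structure switches: number of transit compartments, the drug-effect
#' and G-CSF-effect submodels, and numerical controls for the ODE solver.
#'
#' @param n_transit number of transit (maturation) compartments, 1-3.
#' @param drug_effect_model `"response_surface"` (default; additive surface
#'   when `u50 = p_steep = 1`) or `"log_linear"`.
#' @param gcsf_effect_model one of `"constant_split"` (default; the split
#'   constant model finally selected), `"constant"`, `"linear"`, `"emax"`,
#'   `"none"`.
#' @param shared_ir50 logical; share the typical IR50 between paclitaxel and
#'   cisplatin (final model: `TRUE`).
#' @param gcsf_window days the G-CSF indicator stays 1 after each G-CSF
#'   administration (constant models). Default 1.5 days.
#' @param rtol,atol relative/absolute tolerances of the adaptive
#'   Dormand-Prince integrator used by [simulate_individual()].
#' @param circ_floor_frac the feedback term evaluates `circ` floored at
#'   `circ_floor_frac * circ0` to avoid a singularity at deep nadirs.
#'
#' @return An object of class `"kpd_config"`.
#' @examples
#' kpd_config(n_transit = 2)
#' @export
kpd_config <- function(n_transit = 3, drug_effect_model = "response_surface",
                       gcsf_effect_model = "constant_split",
                       shared_ir50 = TRUE, gcsf_window = 1.5,
                       rtol = 1e-8, atol = 1e-10, circ_floor_frac = 1e-6) {
  n_transit <- as.integer(n_transit)
  if (!n_transit %in% 1:3) stop("n_transit must be 1, 2 or 3", call. = FALSE)
  drug_effect_model <- match.arg(drug_effect_model,
                                 names(.kpd_drug_models))
  gcsf_effect_model <- match.arg(gcsf_effect_model,
                                 names(.kpd_gcsf_models))
  if (!is.numeric(gcsf_window) || gcsf_window <= 0)
    stop("gcsf_window must be positive", call. = FALSE)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  structure(list(n_transit = n_transit,
                 drug_effect_model = drug_effect_model,
                 gcsf_effect_model = gcsf_effect_model,
                 shared_ir50 = isTRUE(shared_ir50),
                 gcsf_window = gcsf_window,
                 rtol = rtol, atol = atol,
                 circ_floor_frac = circ_floor_frac),
            class = "kpd_config")
}

# C++ solver spec list; tolerances can be overridden (the population fit uses
# looser tolerances than trajectory simulation).
cpp_spec <- function(config, rtol = NULL, atol = NULL, fixed_step = FALSE,
                     h_base = 0.5, h_gcsf = 0.125) {
  list(n_transit = config$n_transit,
       drug_model = .kpd_drug_models[[config$drug_effect_model]],
       gcsf_model = .kpd_gcsf_models[[config$gcsf_effect_model]],
       rtol = if (is.null(rtol)) config$rtol else rtol,
       atol = if (is.null(atol)) config$atol else atol,
       circ_floor_frac = config$circ_floor_frac,
       max_steps = 200000L,
       fixed_step = as.integer(fixed_step),
       h_base = h_base, h_gcsf = h_gcsf)
}

# C++ parameter list for one individual (natural scale, after covariates/etas)
cpp_pars <- function(circ0, mtt, gamma, ir50_p, ir50_c, kde_p, kde_c, p) {
  list(circ0 = circ0, mtt = mtt, gamma = gamma, ir50_p = ir50_p,
       ir50_c = ir50_c, kde_p = kde_p, kde_c = kde_c,
       theta_ktr = p$theta_ktr, theta_prol = p$theta_prol,
       u50 = p$u50, p_steep = p$p_steep, scale1 = p$scale1,
       scale2 = p$scale2, scale3 = p$scale3, kde_g = p$kde_g,
       ir50_g = p$ir50_g)
}

#' Derive baseline rate constants from the mean transit time
#'
#' At steady state without treatment `dProl/dt = 0`, which forces
#' `kprol0 = ktr0`, and the circulation loss rate is tied to the transit rate
#' (`kcirc = ktr0`). The transit rate itself is parameterised through the
#' mean transit time: `ktr0 = (n_transit + 1)/mtt`.
#'
#' @param params a [kpd_params()] object (only `mtt` is used).
#' @param config a [kpd_config()] object (only `n_transit` is used).
#' @return A list with `ktr0`, `kprol0`, `kcirc` (all /day, all equal).
#' @examples
#' derive_rates(kpd_params(mtt = 4), kpd_config(n_transit = 3))$ktr0  # 1.0
#' @export
derive_rates <- function(params, config = kpd_config()) {
  if (!is.numeric(params$mtt) || params$mtt <= 0)
    stop("mtt must be positive", call. = FALSE)
  ktr0 <- (config$n_transit + 1) / params$mtt
  list(ktr0 = ktr0, kprol0 = ktr0, kcirc = ktr0)
}

#' Covariate model for the half-effect infusion rate
#'
#' Evaluates `IR50 = ir50_tv * (1 + theta_sex*sex) * (1 + theta_dm*dm)`, the
#' final covariate model: female sex lowers IR50 (more susceptible to
#' myelosuppression), diabetes mellitus raises it.
#'
#' @param params a [kpd_params()] object.
#' @param sex 0 = male, 1 = female (vectorised).
#' @param dm 0 = no diabetes, 1 = diabetes (vectorised).
#' @return IR50 in mg/day.
#' @examples
#' covariate_ir50(kpd_params(), sex = 0, dm = 0)  # 88.9
#' covariate_ir50(kpd_params(), sex = 1, dm = 0)  # 33.4% lower
#' @export
covariate_ir50 <- function(params, sex, dm) {
  if (!all(sex %in% c(0, 1)) || !all(dm %in% c(0, 1)))
    stop("sex and dm must be 0/1 indicators", call. = FALSE)
  params$ir50_tv * (1 + params$theta_sex * sex) * (1 + params$theta_dm * dm)
}
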