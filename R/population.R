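#' Population model: fixed effects, variability, structure
#'
#' Bundles the structural fixed effects, the interindividual variability
#' (IIV) variances, the residual-error magnitudes and the model-structure
#' switches. IIV uses an exponential (log-normal) model on `circ0`, `mtt`,
#' the shared `ir50` and the two `kde` parameters; residual error is the
#' combined model `y = f*(1 + e1) + e2`.
#'
#' @param theta a [kpd_params()] object (typical values).
#' @param omega2 named numeric vector of log-scale IIV variances for
#'   `circ0`, `mtt`, `ir50`, `kde_p`, `kde_c`. An entry of 0 removes that
#'   random effect. The conventional "IIV CV%" reporting maps as
#'   `omega = CV/100`.
#' @param sigma_prop proportional residual SD (fraction).
#' @param sigma_add additive residual SD, 1e9 cells/L.
#' @param config a [kpd_config()] object.
#' @param relations optional list of extra covariate relations created by
#'   [covariate_relation()]; the sex/DM effects on IR50 live in `theta` and
#'   need not be listed here.
#' @return An object of class `"kpd_population"`.
#' @seealso [reference_population()] for the published final-model values.
#' @export
population_model <- function(theta = kpd_params(),
                             omega2 = c(circ0 = 0, mtt = 0, ir50 = 0,
                                        kde_p = 0, kde_c = 0),
                             sigma_prop = 0.3, sigma_add = 0.5,
                             config = kpd_config(), relations = list()) {
  full <- c(circ0 = 0, mtt = 0, ir50 = 0, kde_p = 0, kde_c = 0)
  if (is.null(names(omega2)) && length(omega2) == 5L) names(omega2) <- names(full)
  if (!all(names(omega2) %in% names(full)))
    stop("omega2 names must be among ", paste(names(full), collapse = ", "),
         call. = FALSE)
  full[names(omega2)] <- omega2
  if (any(full < 0)) stop("omega2 entries must be >= 0", call. = FALSE)
  if (sigma_prop < 0 || sigma_add < 0)
    stop("residual SDs must be >= 0", call. = FALSE)
  if (sigma_prop == 0 && sigma_add == 0)
    stop("at least one residual SD must be positive", call. = FALSE)
  validate_kpd_params(theta)
  structure(list(theta = theta, omega2 = full, sigma_prop = sigma_prop,
                 sigma_add = sigma_add, config = config,
                 relations = relations),
            class = "kpd_population")
}

#' Published final-model population parameters
#'
#' The fixed effects, IIV magnitudes and residual-error estimates of the
#' final NSCLC paclitaxel/cisplatin model (3 transit compartments, shared
#' IR50 additive response surface, split constant G-CSF model, sex and DM on
#' IR50). IIV CV% values 23.0/16.2/23.3/95.6/92.0 map to log-scale SDs
#' 0.230/0.162/0.233/0.956/0.920; residual error is 30.0% proportional plus
#' 0.527e9 cells/L additive.
#'
#' @param gcsf include the G-CSF submodel (default TRUE); with `FALSE` the
#'   configuration is the 136-patient basic model without G-CSF.
#' @return A [population_model()] object.
#' @examples
#' pop <- reference_population()
#' pop$theta$mtt
#' @export
reference_population <- function(gcsf = TRUE) {
  population_model(
    theta = kpd_params(),
    omega2 = c(circ0 = 0.230^2, mtt = 0.162^2, ir50 = 0.233^2,
               kde_p = 0.956^2, kde_c = 0.920^2),
    sigma_prop = 0.300, sigma_add = 0.527,
    config = kpd_config(gcsf_effect_model =
                          if (gcsf) "constant_split" else "none"))
}

#' Data-driven starting values for a population fit
#'
#' Generic initial estimates: the baseline count starts at the geometric
#' mean of the pre-treatment (day 0) observations; the remaining parameters
#' start at round mid-range values typical for transit-compartment
#' myelosuppression models (MTT 5 days, weak feedback, moderate potency and
#' variability). Deliberately agnostic: fits in this package are started
#' here, never at known truths.
#'
#' @param dataset list of subject records.
#' @param config a [kpd_config()].
#' @param covariates start the sex/DM IR50 covariate coefficients at small
#'   non-zero values so they are estimated (`TRUE`), or at zero/fixed
#'   (`FALSE`).
#' @return A [population_model()] usable as `init` in [fit_population()].
#' @export
initial_population <- function(dataset, config = kpd_config(),
                               covariates = TRUE) {
  base <- vapply(dataset, function(s) {
    o <- s$observations
    pre <- o$anc[o$time <= 0.5]
    if (length(pre)) pre[1] else o$anc[1]
  }, numeric(1))
  circ0 <- exp(mean(log(pmax(base, 0.1))))
  population_model(
    theta = kpd_params(circ0 = circ0, mtt = 5, gamma = 0.15, ir50_tv = 120,
                       theta_sex = if (covariates) -0.2 else 0,
                       theta_dm = if (covariates) 0.2 else 0,
                       kde_p = 0.05, kde_c = 0.1,
                       theta_ktr = 2, theta_prol = 0.1),
    omega2 = c(circ0 = 0.2^2, mtt = 0.2^2, ir50 = 0.3^2, kde_p = 0.5^2,
               kde_c = 0.5^2),
    sigma_prop = 0.25, sigma_add = 0.6, config = config)
}

#' Covariate relation for stepwise covariate modelling
#'
#' Describes one parameter-covariate relation. Continuous covariates are
#' centred at a reference value (cohort median): linear
#' `1 + theta*(x - ref)`, power `(x/ref)^theta`, exponential
#' `exp(theta*(x - ref))`. Binary covariates use the linear form with
#' `ref = 0`, i.e. `1 + theta*x`.
#'
#' @param param one of `circ0`, `mtt`, `gamma`, `ir50`, `kde_p`, `kde_c`.
#' @param covariate covariate name (column of the subject covariates).
#' @param form `"linear"`, `"power"` or `"exponential"`.
#' @param theta coefficient value.
#' @param ref centring value for continuous covariates (`0` for binary).
#' @return A list of class `"kpd_relation"`.
#' @export
covariate_relation <- function(param, covariate, form = "linear", theta = 0,
                               ref = 0) {
  param <- match.arg(param, c("circ0", "mtt", "gamma", "ir50", "kde_p",
                              "kde_c"))
  form <- match.arg(form, c("linear", "power", "exponential"))
  structure(list(param = param, covariate = covariate, form = form,
                 theta = theta, ref = ref),
            class = "kpd_relation")
}

relation_effect <- function(rel, x) {
  switch(rel$form,
         linear = 1 + rel$theta * (x - rel$ref),
         power = (x / rel$ref)^rel$theta,
         exponential = exp(rel$theta * (x - rel$ref)))
}

relation_label <- function(rel) paste0(rel$param, ":", rel$covariate)

# Per-subject typical values on the natural scale after the covariate model:
# matrix with columns circ0, mtt, gamma, ir50_p, ir50_c, kde_p, kde_c.
typical_values <- function(pop, covariates) {
  th <- pop$theta
  n <- nrow(covariates)
  sex <- covariates$sex
  dm <- covariates$dm
  ir50 <- covariate_ir50(th, sex, dm)
  ir50_c <- if (pop$config$shared_ir50 || is.null(th$ir50_c_tv)) ir50
            else th$ir50_c_tv * (1 + th$theta_sex * sex) *
                 (1 + th$theta_dm * dm)
  tv <- cbind(circ0 = rep(th$circ0, n), mtt = rep(th$mtt, n),
              gamma = rep(th$gamma, n), ir50_p = ir50, ir50_c = ir50_c,
              kde_p = rep(th$kde_p, n), kde_c = rep(th$kde_c, n))
  for (rel in pop$relations) {
    x <- covariates[[rel$covariate]]
    if (is.null(x))
      stop("covariate '", rel$covariate, "' missing from subjects",
           call. = FALSE)
    eff <- relation_effect(rel, x)
    if (any(!is.finite(eff)) || any(eff <= 0))
      stop("covariate relation ", relation_label(rel),
           " produces non-positive typical values", call. = FALSE)
    if (rel$param == "ir50") {
      tv[, "ir50_p"] <- tv[, "ir50_p"] * eff
      tv[, "ir50_c"] <- tv[, "ir50_c"] * eff
    } else {
      tv[, rel$param] <- tv[, rel$param] * eff
    }
  }
  tv
}

# Common (non-subject-varying) parameters handed to the C++ layer.
cpp_common <- function(pop) {
  th <- pop$theta
  list(theta_ktr = th$theta_ktr, theta_prol = th$theta_prol, u50 = th$u50,
       p_steep = th$p_steep, scale1 = th$scale1, scale2 = th$scale2,
       scale3 = th$scale3, kde_g = th$kde_g, ir50_g = th$ir50_g)
}

#' @export
print.kpd_population <- function(x, ...) {
  cat("Population model (", x$config$n_transit, " transit compartments, ",
      x$config$drug_effect_model, " drug effect, G-CSF ",
      x$config$gcsf_effect_model, ")\n", sep = "")
  th <- x$theta
  cat(sprintf("  circ0 %.3g  mtt %.3g d  gamma %.3g  ir50 %.3g mg/d\n",
              th$circ0, th$mtt, th$gamma, th$ir50_tv))
  cat(sprintf("  theta_sex %.3g  theta_dm %.3g  kde_p %.3g /d  kde_c %.3g /d\n",
              th$theta_sex, th$theta_dm, th$kde_p, th$kde_c))
  if (x$config$gcsf_effect_model != "none")
    cat(sprintf("  theta_ktr %.3g  theta_prol %.3g\n",
                th$theta_ktr, th$theta_prol))
  cat("  IIV CV%:", paste(sprintf("%s %.1f", names(x$omega2),
                                  100 * sqrt(x$omega2)), collapse = ", "),
      "\n")
  cat(sprintf("  residual: %.1f%% proportional + %.3g additive\n",
              100 * x$sigma_prop, x$sigma_add))
  if (length(x$relations))
    cat("  extra relations:",
        paste(vapply(x$relations, relation_label, ""), collapse = ", "), "\n")
  invisible(x)
}
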