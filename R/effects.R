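#' Virtual infusion rate of a K-PD compartment
#'
#' The K-PD model replaces unobserved drug concentrations with a virtual
#' one-compartment amount `A` that receives doses as boluses and decays as
#' `dA/dt = -KDE * A`; the quantity driving the effect model is the virtual
#' infusion rate `VIR = KDE * A` (mg/day).
#'
#' @param amount amount in the virtual compartment, mg (vectorised).
#' @param kde virtual elimination rate constant, /day.
#' @return `kde * amount`.
#' @examples
#' virtual_infusion_rate(297.5, 0.0326)
#' @export
virtual_infusion_rate <- function(amount, kde) {
  if (any(amount < 0)) stop("amount must be non-negative", call. = FALSE)
  if (any(kde <= 0)) stop("kde must be positive", call. = FALSE)
  kde * amount
}

#' Combined drug effect on proliferation
#'
#' Fractional multiplier `Ed` in `(0, 1]` applied to the proliferation rate.
#' Under the response-surface model the drugs combine through
#' `U = VIR_p/IR50_p + VIR_c/IR50_c` and
#' `Ed = 1 - (U/U50)^p / (1 + (U/U50)^p)`; with `u50 = p_steep = 1` this is
#' the additive surface `1/(1 + U)`. The log-linear alternative is
#' `Ed = exp(-scale1*VIR_p - scale2*VIR_c)`.
#'
#' @param vir_p,vir_c virtual infusion rates of paclitaxel and cisplatin,
#'   mg/day (vectorised in parallel).
#' @param params a [kpd_params()] object.
#' @param config a [kpd_config()] object selecting the drug-effect model.
#' @param sex,dm covariate indicators used to evaluate IR50 (default typical
#'   male non-diabetic patient).
#' @return `Ed` values in `(0, 1]`.
#' @examples
#' drug_effect(0, 0, kpd_params())       # 1: no drug
#' drug_effect(88.9, 0, kpd_params())    # 0.5: half-effect at U = u50 = 1
#' @export
drug_effect <- function(vir_p, vir_c, params, config = kpd_config(),
                        sex = 0, dm = 0) {
  if (any(vir_p < 0) || any(vir_c < 0))
    stop("virtual infusion rates must be non-negative", call. = FALSE)
  if (config$drug_effect_model == "log_linear")
    return(exp(-params$scale1 * vir_p - params$scale2 * vir_c))
  ir50_p <- covariate_ir50(params, sex, dm)
  ir50_c <- if (config$shared_ir50 || is.null(params$ir50_c_tv)) ir50_p
            else params$ir50_c_tv *
                 (1 + params$theta_sex * sex) * (1 + params$theta_dm * dm)
  u <- vir_p / ir50_p + vir_c / ir50_c
  x <- (u / params$u50)^params$p_steep
  ifelse(u > 0, 1 - x / (1 + x), 1)
}

#' G-CSF effect multipliers on maturation and proliferation
#'
#' Returns the multiplicative stimulation `(EG_ktr, EG_kprol)` applied to
#' `Ktr` and `Kprol` while the G-CSF indicator is on. Under the selected
#' split constant model `EG_ktr = 1 + theta_ktr * G` and
#' `EG_kprol = (1 + theta_ktr * G) * (1 + theta_prol * G)`, separating the
#' proliferation stimulation into the part shared with maturation and the
#' part specific to proliferation (this removes the strong estimation
#' correlation of the unsplit constant model).
#'
#' @param gcsf_on indicator, 0 or 1 (vectorised).
#' @param params a [kpd_params()] object.
#' @param config a [kpd_config()] object; for `"linear"`/`"emax"` models
#'   supply `vir_g`.
#' @param vir_g G-CSF virtual infusion rate (only for the K-PD G-CSF models).
#' @return A list with components `eg_ktr` and `eg_kprol` (both `>= 1`).
#' @examples
#' gcsf_effect(1, kpd_params(theta_ktr = 3.5, theta_prol = 0.217))
#' @export
gcsf_effect <- function(gcsf_on, params, config = kpd_config(), vir_g = 0) {
  if (!all(gcsf_on %in% c(0, 1)))
    stop("gcsf_on must be a 0/1 indicator", call. = FALSE)
  switch(config$gcsf_effect_model,
    none = list(eg_ktr = rep(1, length(gcsf_on)),
                eg_kprol = rep(1, length(gcsf_on))),
    constant_split = {
      eg_ktr <- 1 + params$theta_ktr * gcsf_on
      list(eg_ktr = eg_ktr,
           eg_kprol = eg_ktr * (1 + params$theta_prol * gcsf_on))
    },
    constant = list(eg_ktr = 1 + params$theta_ktr * gcsf_on,
                    eg_kprol = 1 + params$theta_prol * gcsf_on),
    linear = {
      e <- 1 + params$scale3 * vir_g
      list(eg_ktr = e, eg_kprol = e)
    },
    emax = {
      e <- 1 + vir_g / (vir_g + params$ir50_g)
      list(eg_ktr = e, eg_kprol = e)
    })
}

#' Right-hand side of the myelosuppression ODE system
#'
#' Time derivative of the PD state. The state carries the proliferative pool,
#' `n_transit` maturation compartments, circulating neutrophils, and the
#' virtual drug amounts. Proliferation is inhibited by the drug effect and
#' amplified by the feedback term `(circ0/circ)^gamma`; maturation and
#' proliferation are stimulated by G-CSF while its indicator is on.
#'
#' This R implementation mirrors the compiled solver and exists for
#' inspection, testing and use with external integrators; simulation should
#' go through [simulate_individual()].
#'
#' @param t time, days (used only through `gcsf_on` when supplied as a
#'   function).
#' @param state named numeric vector: `prol`, `transit1..n`, `circ`, `a_p`,
#'   `a_c` and optionally `a_g`.
#' @param params a [kpd_params()] object (individual values).
#' @param config a [kpd_config()] object.
#' @param sex,dm covariate indicators for the IR50 covariate model.
#' @param gcsf_on G-CSF indicator at `t` (0/1), or a function of `t`.
#' @return Named vector of derivatives, same layout as `state`.
#' @examples
#' p <- kpd_params()
#' s <- c(prol = p$circ0, transit1 = p$circ0, transit2 = p$circ0,
#'        transit3 = p$circ0, circ = p$circ0, a_p = 0, a_c = 0)
#' ode_rhs(0, s, p)  # all zero: steady state
#' @export
ode_rhs <- function(t, state, params, config = kpd_config(), sex = 0, dm = 0,
                    gcsf_on = 0) {
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  n <- config$n_transit
  nm <- c("prol", paste0("transit", seq_len(n)), "circ", "a_p", "a_c")
  has_g <- "a_g" %in% names(state)
  if (has_g) nm <- c(nm, "a_g")
  if (!all(nm %in% names(state)))
    stop("state must contain ", paste(nm, collapse = ", "), call. = FALSE)
  g <- if (is.function(gcsf_on)) gcsf_on(t) else gcsf_on

  vir_p <- virtual_infusion_rate(state[["a_p"]], params$kde_p)
  vir_c <- virtual_infusion_rate(state[["a_c"]], params$kde_c)
  vir_g <- if (has_g) virtual_infusion_rate(state[["a_g"]], params$kde_g) else 0
  ed <- drug_effect(vir_p, vir_c, params, config, sex = sex, dm = dm)
  eg <- gcsf_effect(g, params, config, vir_g = vir_g)
  rates <- derive_rates(params, config)
  ktr <- rates$ktr0 * eg$eg_ktr
  kprol <- rates$kprol0 * eg$eg_kprol

  circ <- max(state[["circ"]], config$circ_floor_frac * params$circ0)
  fb <- if (params$gamma == 0) 1 else (params$circ0 / circ)^params$gamma

  d <- numeric(length(state))
  names(d) <- names(state)
  d[["prol"]] <- kprol * state[["prol"]] * ed * fb - ktr * state[["prol"]]
  up <- state[["prol"]]
  for (i in seq_len(n)) {
    d[[paste0("transit", i)]] <- ktr * (up - state[[paste0("transit", i)]])
    up <- state[[paste0("transit", i)]]
  }
  d[["circ"]] <- ktr * state[[paste0("transit", n)]] -
    rates$kcirc * state[["circ"]]
  d[["a_p"]] <- -params$kde_p * state[["a_p"]]
  d[["a_c"]] <- -params$kde_c * state[["a_c"]]
  if (has_g) d[["a_g"]] <- -params$kde_g * state[["a_g"]]
  d
}
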