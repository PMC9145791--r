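# Forward simulation of individual ANC trajectories.

# Convert a regimen/dose data.frame into the C++ dose matrix.
dose_matrix <- function(regimen) {
  if (is.null(regimen) || nrow(regimen) == 0L)
    return(matrix(numeric(0), 0, 3))
  if (!all(c("time", "drug", "amount") %in% names(regimen)))
    stop("regimen needs columns time, drug, amount", call. = FALSE)
  if (!all(regimen$drug %in% names(.kpd_drug_codes)))
    stop("unknown drug label: ",
         paste(setdiff(regimen$drug, names(.kpd_drug_codes)), collapse = ", "),
         call. = FALSE)
  if (any(regimen$time < 0)) stop("dose times must be >= 0", call. = FALSE)
  if (any(regimen$amount < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  cbind(regimen$time, regimen$amount,
        unname(.kpd_drug_codes[regimen$drug]))
}

#' Simulate an individual ANC trajectory
#'
#' Deterministic forward solve of the myelosuppression system for one
#' individual. The PD compartments start at the steady state `circ0`; each
#' dose enters its virtual compartment as a bolus at the event time; the
#' system is integrated piecewise with an adaptive embedded Runge-Kutta pair,
#' restarting at every dose event and G-CSF indicator switch (the right-hand
#' side is discontinuous there). Virtual drug amounts are propagated
#' analytically (exponential decay with bolus superposition).
#'
#' @param params a [kpd_params()] object holding this individual's parameter
#'   values (apply covariates/random effects before calling, or use `sex`,
#'   `dm` for the IR50 covariate model).
#' @param regimen dose events: a [build_regimen()] data.frame or any
#'   data.frame with `time`, `drug`, `amount`.
#' @param times sorted non-negative times at which ANC is requested, days.
#' @param config a [kpd_config()] object.
#' @param sex,dm covariate indicators used to evaluate IR50.
#' @param full_state return all PD compartments instead of ANC only.
#' @return Numeric vector of ANC (1e9 cells/L) at `times`, or with
#'   `full_state = TRUE` a matrix with columns `prol`, `transit*`, `circ`.
#' @examples
#' reg <- build_regimen(regimen_spec(bsa = 1.70, n_cycles = 1))
#' anc <- simulate_individual(kpd_params(), reg, times = 0:28)
#' round(range(anc), 2)
#' @export
simulate_individual <- function(params, regimen, times, config = kpd_config(),
                                sex = 0, dm = 0, full_state = FALSE) {
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  ir50 <- covariate_ir50(params, sex, dm)
  ir50_c <- if (config$shared_ir50 || is.null(params$ir50_c_tv)) ir50
            else params$ir50_c_tv *
                 (1 + params$theta_sex * sex) * (1 + params$theta_dm * dm)
  pars <- cpp_pars(params$circ0, params$mtt, params$gamma, ir50, ir50_c,
                   params$kde_p, params$kde_c, params)
  st <- cpp_simulate(as.numeric(times), dose_matrix(regimen),
                     config$gcsf_window, pars, cpp_spec(config))
  if (full_state) {
    colnames(st) <- c("prol", paste0("transit", seq_len(config$n_transit)),
                      "circ")
    st
  } else st[, config$n_transit + 2L]
}
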