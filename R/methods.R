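# S3 methods for the fitted population model.

#' @export
coef.kpd_fit <- function(object, ...) {
  tab <- fit_param_table(object$pop)
  setNames(tab$value, tab$name)
}

#' @export
logLik.kpd_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$k, nobs = object$data_sig[["nobs"]],
            class = "logLik")
}

#' @export
print.kpd_fit <- function(x, ...) {
  cat("Population K-PD myelosuppression fit (Laplace)\n")
  cat(sprintf("  %d subjects, %d observations, %d free parameters\n",
              x$n_subjects, x$data_sig[["nobs"]], x$k))
  cat(sprintf("  OFV %.3f (initial %.3f)   AIC %.3f\n", x$ofv, x$ofv_init,
              x$aic))
  est <- coef(x)[x$free]
  cat("  estimates:\n")
  print(round(est, 4))
  invisible(x)
}

#' @export
summary.kpd_fit <- function(object, ...) {
  est <- coef(object)[object$free]
  out <- data.frame(parameter = names(est), estimate = unname(est))
  if (!is.null(object$se)) out$se <- object$se[names(est)]
  om <- object$pop$omega2
  iiv <- data.frame(parameter = paste0("IIV_", names(om), "_CVpct"),
                    estimate = 100 * sqrt(om))
  if (!is.null(object$se)) iiv$se <- NA_real_
  res <- structure(list(table = rbind(out, iiv), ofv = object$ofv,
                        aic = object$aic, k = object$k,
                        convergence = object$convergence,
                        n_eval = object$n_eval,
                        sigma = c(prop = object$pop$sigma_prop,
                                  add = object$pop$sigma_add)),
                   class = "summary.kpd_fit")
  res
}

#' @export
print.summary.kpd_fit <- function(x, ...) {
  cat(sprintf("OFV %.3f  AIC %.3f  (k = %d, %d objective evaluations)\n",
              x$ofv, x$aic, x$k, x$n_eval))
  cat(sprintf("residual error: %.1f%% proportional + %.3g additive\n",
              100 * x$sigma[["prop"]], x$sigma[["add"]]))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Predictions from a population fit
#'
#' @param object a `kpd_fit`.
#' @param newdata list of subject records; defaults must be supplied (the
#'   fit does not store the data).
#' @param type `"ipred"` (individual, at the per-subject random-effect
#'   modes; only valid for the fitting dataset) or `"pred"`
#'   (typical-covariate, random effects at zero).
#' @param ... unused.
#' @return `data.frame` with `id`, `time` and the prediction column.
#' @export
predict.kpd_fit <- function(object, newdata, type = c("ipred", "pred"), ...) {
  type <- match.arg(type)
  if (type == "ipred") {
    sig <- dataset_signature(newdata)
    if (any(abs(sig - object$data_sig) > 1e-8))
      stop("type = 'ipred' requires the dataset the model was fitted to",
           call. = FALSE)
  }
  g <- gof_table(newdata, object)
  g[, c("id", "time", if (type == "pred") "pred" else "ipred")]
}

#' @export
fitted.kpd_fit <- function(object, newdata, ...) {
  predict(object, newdata, type = "ipred")$ipred
}

#' Conditional weighted residuals of a fit
#'
#' @param object a `kpd_fit`.
#' @param newdata the fitting dataset.
#' @param ... unused.
#' @return Numeric vector of IPRED-standardised conditional residuals.
#' @export
residuals.kpd_fit <- function(object, newdata, ...) {
  gof_table(newdata, object)$cwres
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws fresh random effects and residual errors on the design of
#' `newdata` (same covariates, doses and observation times), as used for
#' posterior-predictive style checks.
#'
#' @param object a `kpd_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (required).
#' @param newdata list of subject records providing the design.
#' @param ... unused.
#' @return List of `nsim` datasets (lists of subject records with simulated
#'   `observations`).
#' @export
simulate.kpd_fit <- function(object, nsim = 1, seed, newdata, ...) {
  if (missing(seed) || is.null(seed))
    stop("simulate requires an explicit seed", call. = FALSE)
  set.seed(seed)
  pop <- object$pop
  covs <- dataset_covariates(newdata)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    ip <- sample_individual_params(pop, covs)
    ds <- newdata
    for (i in seq_along(ds)) {
      pr <- simulate_values(ip$values[i, ], pop, ds[[i]]$doses,
                            ds[[i]]$observations$time)
      ds[[i]]$observations$anc <- apply_residual_error(pr, pop)
      ds[[i]]$etas_true <- ip$etas[i, ]
    }
    attr(ds, "etas") <- ip$etas
    out[[r]] <- ds
  }
  if (nsim == 1) out[[1]] else out
}

#' Goodness-of-fit panels for a population fit
#'
#' Four base-graphics panels: observations against population and individual
#' predictions (identity line), and conditional weighted residuals against
#' time and against population predictions (zero line).
#'
#' @param x a `kpd_fit`.
#' @param newdata the fitting dataset.
#' @param ... passed to `plot`.
#' @return The GOF table, invisibly.
#' @export
plot.kpd_fit <- function(x, newdata, ...) {
  g <- gof_table(newdata, x)
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 0.5))
  on.exit(par(op))
  lim <- range(c(g$dv, g$pred, g$ipred))
  plot(g$pred, g$dv, xlab = "PRED", ylab = "DV", xlim = lim, ylim = lim, ...)
  abline(0, 1, col = "red3")
  plot(g$ipred, g$dv, xlab = "IPRED", ylab = "DV", xlim = lim, ylim = lim,
       ...)
  abline(0, 1, col = "red3")
  plot(g$time, g$cwres, xlab = "time (days)", ylab = "CWRES", ...)
  abline(h = 0, col = "red3")
  plot(g$pred, g$cwres, xlab = "PRED", ylab = "CWRES", ...)
  abline(h = 0, col = "red3")
  invisible(g)
}

#' @export
print.kpd_params <- function(x, ...) {
  cat("Structural parameters:\n")
  v <- unlist(x[!vapply(x, is.null, logical(1))])
  print(round(v, 4))
  invisible(x)
}

#' @export
print.kpd_config <- function(x, ...) {
  cat(sprintf("Model: %d transit compartments, %s drug effect, %s G-CSF effect\n",
              x$n_transit, x$drug_effect_model, x$gcsf_effect_model))
  cat(sprintf("  shared IR50: %s, G-CSF window %.2g d, solver rtol %.1e atol %.1e\n",
              x$shared_ir50, x$gcsf_window, x$rtol, x$atol))
  invisible(x)
}
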