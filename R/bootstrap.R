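#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits each replicate starting from
#' the supplied estimates, and summarises the replicate estimates per
#' parameter (median, percentile confidence interval, relative standard
#' error). Replicates whose fit fails are dropped and counted; more than 20%
#' failures flags the summary as unreliable.
#'
#' @param dataset list of subject records.
#' @param final fitted [population_model()] used both as the refit starting
#'   point and as the reference column of the summary (pass `fit$pop`).
#' @param n_replicates number of bootstrap replicates.
#' @param seed integer seed (required).
#' @param fixed,options passed to the fitter.
#' @param fitter fitting function with the signature of [fit_population()].
#' @return An object of class `"kpd_boot"`: `summary` (data.frame with
#'   `estimate`, `median`, `lo2.5`, `hi97.5`, `rse_pct`), `estimates`
#'   (replicate x parameter matrix), `n_fail`, `reliable`.
#' @export
bootstrap_fit <- function(dataset, final, n_replicates, seed, fixed = NULL,
                          options = list(), fitter = fit_population) {
  if (missing(seed) || is.null(seed))
    stop("bootstrap_fit requires an explicit seed", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- length(dataset)
  idx <- replicate(n_replicates, sample.int(n, n, replace = TRUE),
                   simplify = FALSE)

  tab <- fit_param_table(final)
  fx <- union(auto_fixed(final, tab), fixed)
  free_names <- tab$name[!tab$name %in% fx]

  rows <- vector("list", n_replicates)
  n_fail <- 0L
  for (r in seq_len(n_replicates)) {
    ds_r <- dataset[idx[[r]]]
    for (j in seq_along(ds_r)) ds_r[[j]]$id <- j
    f <- tryCatch(fitter(ds_r, init = final, fixed = fixed,
                         options = options),
                  error = function(e) NULL)
    if (is.null(f)) {
      n_fail <- n_fail + 1L
      next
    }
    est <- coef(f)
    rows[[r]] <- est[free_names]
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("all bootstrap replicates failed", call. = FALSE)
  est_mat <- do.call(rbind, rows[keep])
  colnames(est_mat) <- free_names

  med <- apply(est_mat, 2, median)
  lo <- apply(est_mat, 2, quantile, probs = 0.025, names = FALSE)
  hi <- apply(est_mat, 2, quantile, probs = 0.975, names = FALSE)
  sdv <- apply(est_mat, 2, sd)
  tab_f <- tab[match(free_names, tab$name), ]
  out <- data.frame(parameter = free_names, estimate = tab_f$value,
                    median = med, lo2.5 = lo, hi97.5 = hi,
                    rse_pct = 100 * sdv / abs(med), row.names = NULL)
  structure(list(summary = out, estimates = est_mat, n_fail = n_fail,
                 n_replicates = n_replicates,
                 reliable = n_fail <= 0.2 * n_replicates, seed = seed),
            class = "kpd_boot")
}

#' @export
print.kpd_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap:", nrow(x$estimates), "successful /", x$n_replicates,
      "replicates", if (!x$reliable) "(UNRELIABLE: >20% failures)", "\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
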