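# Goodness-of-fit tables and visual predictive checks.

#' Goodness-of-fit table
#'
#' For every observation: the typical-covariate population prediction
#' (`pred`, all random effects at 0), the individual prediction at the
#' subject's random-effect mode (`ipred`), and a conditional weighted
#' residual standardised by the combined-error variance at `ipred`:
#' `cwres = (dv - ipred) / sqrt(ipred^2 sigma_prop^2 + sigma_add^2)`. This
#' IPRED-standardised residual is used in place of the FOCE-linearised
#' CWRES; under the true model it is zero-centred with unit scale.
#'
#' @param dataset list of subject records.
#' @param fit a [fit_population()] result (its `$pop` and `$eta` are used).
#' @return `data.frame` with `id`, `time`, `dv`, `pred`, `ipred`, `cwres`.
#' @export
gof_table <- function(dataset, fit) {
  stopifnot(inherits(fit, "kpd_fit"))
  pop <- fit$pop
  covs <- dataset_covariates(dataset)
  tv <- typical_values(pop, covs)
  rows <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    tt <- s$observations$time
    tvi <- tv[i, ]
    pred <- simulate_values(tvi, pop, s$doses, tt)
    e <- fit$eta[i, ]
    vals <- tvi
    vals[c("circ0", "mtt", "kde_p", "kde_c")] <-
      tvi[c("circ0", "mtt", "kde_p", "kde_c")] * exp(e[c(1, 2, 4, 5)])
    vals[c("ir50_p", "ir50_c")] <- tvi[c("ir50_p", "ir50_c")] * exp(e[3])
    ipred <- simulate_values(vals, pop, s$doses, tt)
    v <- ipred^2 * pop$sigma_prop^2 + pop$sigma_add^2
    rows[[i]] <- data.frame(id = s$id, time = tt, dv = s$observations$anc,
                            pred = pred, ipred = ipred,
                            cwres = (s$observations$anc - ipred) / sqrt(v))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

days_since_dose <- function(t, doses) {
  dt <- doses$time[doses$drug %in% c("paclitaxel", "cisplatin")]
  vapply(t, function(ti) {
    before <- dt[dt <= ti]
    if (length(before)) ti - max(before) else ti
  }, numeric(1))
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets on the original design (same
#' subjects, covariates, dose events and observation times; fresh random
#' effects and residual errors), then compares observed 5/50/95 ANC
#' percentiles per time bin with the distribution of the same percentiles
#' across simulated replicates (95% CIs). Default binning is cycle-relative:
#' days since the most recent anticancer dose, in `bin_width`-day bins; bins
#' holding fewer than 5 observations are merged with their neighbour.
#'
#' @param dataset list of subject records (the observed data).
#' @param pop the [population_model()] to simulate from.
#' @param n_sim number of replicate datasets (>= 100 for stable CIs).
#' @param seed integer seed (required).
#' @param binning `"cycle"` (days since last anticancer dose) or
#'   `"absolute"` (study time).
#' @param bin_width bin width, days.
#' @param probs percentiles to track.
#' @param min_bin_n minimum observations per bin before merging.
#' @return An object of class `"kpd_vpc"`: `bands` (one row per bin with
#'   observed percentiles and simulated percentile medians and CIs),
#'   `n_sim`, `binning`. Has a `plot` method.
#' @export
vpc <- function(dataset, pop, n_sim = 200, seed, binning = c("cycle",
                "absolute"), bin_width = 3.5, probs = c(0.05, 0.5, 0.95),
                min_bin_n = 5L) {
  if (missing(seed) || is.null(seed))
    stop("vpc requires an explicit seed", call. = FALSE)
  binning <- match.arg(binning)
  set.seed(seed)
  covs <- dataset_covariates(dataset)

  obs_y <- unlist(lapply(dataset, function(s) s$observations$anc))
  tvar <- unlist(lapply(dataset, function(s) {
    if (binning == "cycle") days_since_dose(s$observations$time, s$doses)
    else s$observations$time
  }))
  n_obs_per <- vapply(dataset, function(s) nrow(s$observations), integer(1))

  # bins, merging sparse ones with the previous neighbour
  edges <- seq(0, max(tvar) + bin_width, by = bin_width)
  bin_of <- findInterval(tvar, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin_of, nbins = length(edges) - 1L)
  merged <- integer(0)
  map <- integer(length(counts))
  cur <- 0L
  acc <- 0L
  for (b in seq_along(counts)) {
    if (acc == 0L) cur <- cur + 1L
    map[b] <- cur
    acc <- acc + counts[b]
    if (acc >= min_bin_n) acc <- 0L
  }
  if (acc > 0L && cur > 1L) map[map == cur] <- cur - 1L  # tail merge
  bin_id <- map[bin_of]

  pct <- function(y, id) {
    do.call(rbind, lapply(sort(unique(id)), function(b)
      quantile(y[id == b], probs, names = FALSE)))
  }
  obs_p <- pct(obs_y, bin_id)

  sims <- array(NA_real_, c(n_sim, length(unique(bin_id)), length(probs)))
  for (r in seq_len(n_sim)) {
    ip <- sample_individual_params(pop, covs)
    y_r <- numeric(0)
    for (i in seq_along(dataset)) {
      s <- dataset[[i]]
      pr <- simulate_values(ip$values[i, ], pop, s$doses,
                            s$observations$time, rtol = 1e-6, atol = 1e-8)
      y_r <- c(y_r, apply_residual_error(pr, pop))
    }
    sims[r, , ] <- pct(y_r, bin_id)
  }

  ub <- sort(unique(bin_id))
  lo_edge <- vapply(ub, function(b) min(tvar[bin_id == b]), numeric(1))
  hi_edge <- vapply(ub, function(b) max(tvar[bin_id == b]), numeric(1))
  bands <- data.frame(bin = ub, t_lo = lo_edge, t_hi = hi_edge,
                      t_mid = (lo_edge + hi_edge) / 2,
                      n = as.integer(table(bin_id)))
  for (j in seq_along(probs)) {
    tag <- paste0("p", probs[j] * 100)
    bands[[paste0("obs_", tag)]] <- obs_p[, j]
    bands[[paste0("sim_", tag)]] <- apply(sims[, , j, drop = FALSE], 2,
                                          median)
    bands[[paste0("sim_", tag, "_lo")]] <-
      apply(sims[, , j, drop = FALSE], 2, quantile, probs = 0.025)
    bands[[paste0("sim_", tag, "_hi")]] <-
      apply(sims[, , j, drop = FALSE], 2, quantile, probs = 0.975)
  }
  structure(list(bands = bands, n_sim = n_sim, binning = binning,
                 probs = probs, seed = seed), class = "kpd_vpc")
}

#' @export
print.kpd_vpc <- function(x, ...) {
  cat("VPC:", x$n_sim, "replicates,", nrow(x$bands), "bins (", x$binning,
      "binning )\n")
  print(x$bands[, c("t_lo", "t_hi", "n", "obs_p50", "sim_p50",
                    "sim_p50_lo", "sim_p50_hi")], digits = 3,
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.kpd_vpc <- function(x, xlab = NULL, ylab = "ANC (1e9 cells/L)", ...) {
  b <- x$bands
  if (is.null(xlab))
    xlab <- if (x$binning == "cycle") "days since last dose" else "time (days)"
  yl <- range(b[, grepl("^(obs|sim)_", names(b))])
  plot(range(b$t_mid), yl, type = "n", xlab = xlab, ylab = ylab, ...)
  band <- function(tag, col) {
    polygon(c(b$t_mid, rev(b$t_mid)),
            c(b[[paste0("sim_", tag, "_lo")]],
              rev(b[[paste0("sim_", tag, "_hi")]])),
            col = adjustcolor(col, 0.3), border = NA)
    lines(b$t_mid, b[[paste0("sim_", tag)]], col = col, lty = 2)
    lines(b$t_mid, b[[paste0("obs_", tag)]], col = "red3",
          lty = if (tag == "p50") 1 else 2)
  }
  band("p5", "steelblue")
  band("p50", "grey30")
  band("p95", "steelblue")
  invisible(x)
}
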