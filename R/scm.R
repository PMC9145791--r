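#' Stepwise covariate modelling
#'
#' Greedy forward-inclusion / backward-deletion search over
#' parameter-covariate relations. At each forward step every remaining
#' candidate is added to the current model, the model is refit, and the
#' candidate with the largest OFV drop is included if the drop reaches the
#' forward threshold (6.635, the chi-square 1-df 1% point). Backward
#' deletion then removes, one at a time, any included relation whose removal
#' raises the OFV by less than the backward threshold (10.828, the 0.1%
#' point).
#'
#' @param dataset list of subject records.
#' @param base starting [population_model()] (without the candidate
#'   relations).
#' @param candidates data.frame with columns `param`, `covariate`, `form`
#'   (see [covariate_relation()]); continuous covariates are centred at
#'   their cohort median.
#' @param thresholds named vector `c(forward = 6.635, backward = 10.828)`.
#' @param fixed,options passed to the fitter.
#' @param fitter fitting function with the signature of [fit_population()];
#'   injectable for testing and for cheap surrogate models.
#' @return An object of class `"kpd_scm"`: `selected` (list of
#'   [covariate_relation()]s), `final` (fit of the final model), `trace`
#'   (data.frame of every tested step with delta-OFV and decision).
#' @export
scm <- function(dataset, base, candidates,
                thresholds = c(forward = 6.635, backward = 10.828),
                fixed = NULL, options = list(), fitter = fit_population) {
  stopifnot(is.data.frame(candidates),
            all(c("param", "covariate", "form") %in% names(candidates)))
  covs <- dataset_covariates(dataset)
  for (cv in unique(candidates$covariate)) {
    if (is.null(covs[[cv]]))
      stop("candidate covariate '", cv, "' missing from subjects",
           call. = FALSE)
  }
  make_rel <- function(i) {
    cv <- candidates$covariate[i]
    x <- covs[[cv]]
    binary <- all(x %in% c(0, 1))
    covariate_relation(candidates$param[i], cv,
                       form = candidates$form[i], theta = 0,
                       ref = if (binary) 0 else median(x))
  }
  rels <- lapply(seq_len(nrow(candidates)), make_rel)
  labels <- vapply(rels, relation_label, "")

  with_rels <- function(pop, rel_list) {
    pop$relations <- rel_list
    pop
  }
  fit1 <- function(pop) {
    tryCatch(fitter(dataset, init = pop, fixed = fixed, options = options),
             error = function(e) NULL)
  }

  trace <- data.frame(step = integer(), phase = character(),
                      relation = character(), ofv = numeric(),
                      delta = numeric(), decision = character(),
                      stringsAsFactors = FALSE)
  note <- function(step, phase, relation, ofv, delta, decision) {
    trace[nrow(trace) + 1L, ] <<- list(step, phase, relation, ofv, delta,
                                       decision)
  }

  included <- list()
  base_fit <- fit1(with_rels(base, included))
  if (is.null(base_fit)) stop("base model fit failed", call. = FALSE)
  cur_ofv <- base_fit$ofv
  remaining <- seq_along(rels)
  step <- 0L

  repeat {                                  # forward inclusion
    step <- step + 1L
    best <- NULL
    best_delta <- -Inf
    for (i in remaining) {
      f <- fit1(with_rels(base, c(included, rels[i])))
      if (is.null(f)) {
        note(step, "forward", labels[i], NA_real_, NA_real_, "fit failed")
        next
      }
      delta <- cur_ofv - f$ofv
      note(step, "forward", labels[i], f$ofv, delta, "tested")
      if (delta > best_delta) {
        best_delta <- delta
        best <- list(i = i, fit = f)
      }
    }
    if (is.null(best) || best_delta < thresholds[["forward"]]) break
    included <- c(included, list(best$fit$pop$relations[[length(included) + 1L]]))
    remaining <- setdiff(remaining, best$i)
    cur_ofv <- best$fit$ofv
    final_fit <- best$fit
    note(step, "forward", labels[best$i], best$fit$ofv, best_delta,
         "included")
    if (!length(remaining)) break
  }
  if (!length(included)) final_fit <- base_fit

  repeat {                                  # backward deletion
    if (!length(included)) break
    step <- step + 1L
    worst <- NULL
    worst_delta <- Inf
    for (k in seq_along(included)) {
      f <- fit1(with_rels(base, included[-k]))
      if (is.null(f)) {
        note(step, "backward", relation_label(included[[k]]), NA_real_,
             NA_real_, "fit failed")
        next
      }
      delta <- f$ofv - cur_ofv
      note(step, "backward", relation_label(included[[k]]), f$ofv, delta,
           "tested")
      if (delta < worst_delta) {
        worst_delta <- delta
        worst <- list(k = k, fit = f)
      }
    }
    if (is.null(worst) || worst_delta >= thresholds[["backward"]]) break
    note(step, "backward", relation_label(included[[worst$k]]),
         worst$fit$ofv, worst_delta, "removed")
    included <- included[-worst$k]
    cur_ofv <- worst$fit$ofv
    final_fit <- worst$fit
  }

  structure(list(selected = included,
                 labels = vapply(included, relation_label, ""),
                 final = final_fit, base_ofv = base_fit$ofv,
                 thresholds = thresholds, trace = trace),
            class = "kpd_scm")
}

#' @export
print.kpd_scm <- function(x, ...) {
  cat("Stepwise covariate modelling (forward >=",
      x$thresholds[["forward"]], ", backward >=",
      x$thresholds[["backward"]], ")\n")
  if (length(x$labels))
    cat("selected:", paste(x$labels, collapse = ", "), "\n")
  else cat("selected: none\n")
  cat("base OFV", format(x$base_ofv, digits = 8), "-> final OFV",
      format(x$final$ofv, digits = 8), "\n")
  invisible(x)
}
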