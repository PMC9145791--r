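#' Chemotherapy regimen specification
#'
#' Describes the study protocol: 28-day cycles (up to 6), paclitaxel
#' 175 mg/m2 on day 1 and cisplatin 75 mg/m2 on day 2 of each cycle, doses
#' scaled by body surface area, 25% dose reduction after grade-4 neutropenia,
#' and the grade-4 ANC threshold.
#'
#' @param bsa body surface area, m2.
#' @param n_cycles number of treatment cycles, 1-6.
#' @param cycle_length cycle length, days.
#' @param paclitaxel_per_bsa,cisplatin_per_bsa dose rates, mg/m2.
#' @param reduction_fraction fractional dose reduction applied after a
#'   grade-4 event (0.25 = 25% reduction).
#' @param grade4_threshold ANC below which an observation counts as grade-4
#'   neutropenia, 1e9 cells/L (CTCAE convention 0.5).
#' @param persistent_reduction logical; once triggered, keep the reduction
#'   for all later cycles (default) rather than the next cycle only.
#' @return An object of class `"kpd_regimen_spec"`.
#' @examples
#' regimen_spec(bsa = 1.70)
#' @export
regimen_spec <- function(bsa, n_cycles = 6, cycle_length = 28,
                         paclitaxel_per_bsa = 175, cisplatin_per_bsa = 75,
                         reduction_fraction = 0.25, grade4_threshold = 0.5,
                         persistent_reduction = TRUE) {
  n_cycles <- as.integer(n_cycles)
  if (!is.numeric(bsa) || bsa <= 0) stop("bsa must be positive", call. = FALSE)
  if (n_cycles < 1L || n_cycles > 6L)
    stop("n_cycles must be between 1 and 6", call. = FALSE)
  if (reduction_fraction < 0 || reduction_fraction >= 1)
    stop("reduction_fraction must be in [0, 1)", call. = FALSE)
  if (grade4_threshold < 0)
    stop("grade4_threshold must be non-negative", call. = FALSE)
  structure(list(bsa = bsa, n_cycles = n_cycles, cycle_length = cycle_length,
                 paclitaxel_per_bsa = paclitaxel_per_bsa,
                 cisplatin_per_bsa = cisplatin_per_bsa,
                 reduction_fraction = reduction_fraction,
                 grade4_threshold = grade4_threshold,
                 persistent_reduction = isTRUE(persistent_reduction)),
            class = "kpd_regimen_spec")
}

#' Build the dose-event list for a regimen
#'
#' Per cycle `c`, a paclitaxel bolus at `t = (c-1)*cycle_length` and a
#' cisplatin bolus one day later, with amounts `rate * bsa`. Cycles listed in
#' `reduced_cycles` (and, with persistent reduction, all later cycles) have
#' both amounts scaled by `1 - reduction_fraction`. G-CSF administrations are
#' appended as marker events. Doses are instantaneous boluses at the start of
#' the infusion day; the 3-hour infusion duration is negligible against the
#' multi-day virtual elimination scales.
#'
#' @param spec a [regimen_spec()].
#' @param reduced_cycles integer cycle indices (1-based) at which the dose
#'   reduction applies.
#' @param gcsf_times times of G-CSF administrations, days.
#' @param gcsf_amount amount recorded on G-CSF events (marker; the constant
#'   G-CSF models use only the administration time).
#' @return A `data.frame` with columns `time` (days), `drug`
#'   (paclitaxel/cisplatin/gcsf), `amount` (mg), `cycle`, sorted by time;
#'   class `"kpd_regimen"`.
#' @examples
#' build_regimen(regimen_spec(bsa = 1.70, n_cycles = 2))
#' @export
build_regimen <- function(spec, reduced_cycles = integer(), gcsf_times = numeric(),
                          gcsf_amount = 1) {
  stopifnot(inherits(spec, "kpd_regimen_spec"))
  reduced_cycles <- as.integer(reduced_cycles)
  if (length(reduced_cycles) && (min(reduced_cycles) < 1L ||
                                 max(reduced_cycles) > spec$n_cycles))
    stop("reduced_cycles out of 1..n_cycles", call. = FALSE)
  if (any(gcsf_times < 0)) stop("gcsf_times must be >= 0", call. = FALSE)

  cyc <- seq_len(spec$n_cycles)
  red <- rep(FALSE, spec$n_cycles)
  if (length(reduced_cycles)) {
    if (spec$persistent_reduction) {
      red[cyc >= min(reduced_cycles)] <- TRUE
      red[cyc < min(reduced_cycles)] <- cyc[cyc < min(reduced_cycles)] %in%
        reduced_cycles
    } else red[reduced_cycles] <- TRUE
  }
  fac <- ifelse(red, 1 - spec$reduction_fraction, 1)

  ev <- data.frame(
    time = c((cyc - 1) * spec$cycle_length,
             (cyc - 1) * spec$cycle_length + 1),
    drug = rep(c("paclitaxel", "cisplatin"), each = spec$n_cycles),
    amount = c(spec$paclitaxel_per_bsa * spec$bsa * fac,
               spec$cisplatin_per_bsa * spec$bsa * fac),
    cycle = rep(cyc, 2),
    stringsAsFactors = FALSE)
  if (length(gcsf_times)) {
    ev <- rbind(ev, data.frame(
      time = gcsf_times, drug = "gcsf", amount = gcsf_amount,
      cycle = pmin(spec$n_cycles,
                   floor(gcsf_times / spec$cycle_length) + 1L)))
  }
  if (anyDuplicated(ev[, c("time", "drug")]))
    stop("duplicate dose events (same time and drug)", call. = FALSE)
  ev <- ev[order(ev$time, match(ev$drug, names(.kpd_drug_codes))), ]
  rownames(ev) <- NULL
  class(ev) <- c("kpd_regimen", "data.frame")
  ev
}

#' G-CSF indicator at a set of times
#'
#' The indicator is 1 at time `t` when some administration time `d`
#' satisfies `d <= t < d + window`; overlapping windows do not stack.
#'
#' @param t times to evaluate, days (vectorised).
#' @param gcsf_times administration times, days.
#' @param window indicator duration after each administration, days.
#' @return Integer vector of 0/1.
#' @examples
#' gcsf_indicator(c(30.5, 32), gcsf_times = 30, window = 1.5)
#' @export
gcsf_indicator <- function(t, gcsf_times, window = 1.5) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  if (!length(gcsf_times)) return(integer(length(t)))
  vapply(t, function(ti)
    as.integer(any(gcsf_times <= ti & ti < gcsf_times + window)),
    integer(1))
}

#' Apply the toxicity management rules to observed ANC values
#'
#' Implements the protocol response to grade-4 neutropenia: any observation
#' below the grade-4 threshold during cycle `c` (i) marks all later cycles
#' for the 25% dose reduction and (ii) triggers a G-CSF administration at the
#' observation time. The function is idempotent: re-applying it to the same
#' observations returns the same schedule.
#'
#' @param observations `data.frame` with columns `time` (days, sorted) and
#'   `anc` (1e9 cells/L).
#' @param spec a [regimen_spec()].
#' @return A list with `reduced_cycles` (integer vector) and `gcsf_times`
#'   (numeric vector).
#' @examples
#' obs <- data.frame(time = c(0, 39), anc = c(5.2, 0.4))
#' apply_toxicity_rules(obs, regimen_spec(bsa = 1.7))
#' @export
apply_toxicity_rules <- function(observations, spec) {
  stopifnot(inherits(spec, "kpd_regimen_spec"))
  if (is.unsorted(observations$time))
    stop("observations must be time-ordered", call. = FALSE)
  g4 <- observations$anc < spec$grade4_threshold
  if (!any(g4))
    return(list(reduced_cycles = integer(), gcsf_times = numeric()))
  t4 <- observations$time[g4]
  cycles4 <- pmin(spec$n_cycles, floor(t4 / spec$cycle_length) + 1L)
  reduced <- sort(unique(unlist(lapply(cycles4, function(cc)
    if (cc < spec$n_cycles) seq.int(cc + 1L, spec$n_cycles) else integer()))))
  list(reduced_cycles = as.integer(reduced), gcsf_times = t4)
}
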