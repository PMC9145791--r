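test_that("no-dose trajectories hold the baseline steady state", {
  for (r in 1:5) {
    set.seed(100 + r)
    p <- kpd_params(circ0 = runif(1, 2, 10), mtt = runif(1, 3, 7),
                    gamma = runif(1, 0, 0.4))
    anc <- simulate_individual(p, data.frame(time = numeric(),
                                             drug = character(),
                                             amount = numeric()),
                               times = seq(0, 168, by = 7))
    expect_lt(max(abs(anc - p$circ0)) / p$circ0, 1e-6)
  }
  # every compartment stays at baseline, not just circ
  st <- simulate_individual(kpd_params(),
                            data.frame(time = numeric(), drug = character(),
                                       amount = numeric()),
                            times = c(0, 84, 168), full_state = TRUE)
  expect_lt(max(abs(st - 5.34)) / 5.34, 1e-6)
})

test_that("adaptive solver matches the fixed-step RK4 oracle", {
  # worked single-bolus case at the published typical values
  p <- kpd_params()
  doses <- data.frame(time = 0, drug = "paclitaxel", amount = 297.5)
  tt <- c(1, 3, 7, 10, 14, 21, 28, 42)
  a <- simulate_individual(p, doses, tt)
  b <- oracle_simulate(oracle_pars(p), doses, tt, h = 0.001)
  expect_lt(max(abs(a - b) / b), 1e-4)
  # randomized parameter/dose draws (cached; shared with the acceptance run)
  expect_lt(oracle_equiv_result(), 1e-4)
})

test_that("solver agrees with deSolve::lsoda as a second oracle", {
  library(deSolve)
  p <- kpd_params()
  reg <- build_regimen(regimen_spec(bsa = 1.70, n_cycles = 1))
  tt <- seq(0, 28, by = 1)
  rhs_ds <- function(t, y, parms) list(unname(ode_rhs(t, y, p)))
  # paclitaxel bolus at t = 0 goes into the initial state; the cisplatin
  # bolus on day 2 of the cycle is a deSolve event
  y0 <- c(prol = 5.34, transit1 = 5.34, transit2 = 5.34, transit3 = 5.34,
          circ = 5.34, a_p = 297.5, a_c = 0)
  ev <- data.frame(var = "a_c", time = 1, value = 127.5, method = "add")
  ls <- lsoda(y0, times = sort(unique(c(tt, 1))), func = rhs_ds,
              parms = NULL, events = list(data = ev), rtol = 1e-10,
              atol = 1e-12)
  ours <- simulate_individual(p, reg, tt)
  theirs <- ls[match(tt, ls[, "time"]), "circ"]
  expect_lt(max(abs(ours - theirs) / theirs), 1e-5)
})

test_that("feedback exponent produces post-nadir rebound overshoot", {
  # a cisplatin bolus clears fast enough (virtual half-life ~3.7 days) for
  # the rebound to show within the window; paclitaxel keeps suppressing for
  # weeks and damps it
  doses <- data.frame(time = 0, drug = "cisplatin", amount = 400)
  tt <- seq(0, 90, by = 0.25)
  anc0 <- simulate_individual(kpd_params(gamma = 0), doses, tt)
  ancg <- simulate_individual(kpd_params(gamma = 0.188), doses, tt)
  nadir_idx <- which.min(ancg)
  expect_lte(max(anc0[which.min(anc0):length(tt)]), 5.34 * (1 + 1e-6))
  expect_gt(max(ancg[nadir_idx:length(tt)]), 5.34)   # overshoot
  expect_lt(abs(ancg[length(tt)] - 5.34), 5.34 * 0.02)  # back near baseline
  # the feedback also speeds recovery: shallower late trajectory minimum
  expect_gt(min(ancg), min(anc0))
})

test_that("nadir is monotone non-increasing in paclitaxel dose", {
  tt <- seq(0, 56, by = 0.25)
  nadirs <- vapply(seq(0, 600, by = 100), function(amt) {
    doses <- data.frame(time = 0, drug = "paclitaxel", amount = amt)
    min(simulate_individual(kpd_params(), doses, tt))
  }, numeric(1))
  expect_true(all(diff(nadirs) <= 1e-9))
  expect_equal(nadirs[1], 5.34, tolerance = 1e-6)
})

test_that("G-CSF rescue at the nadir raises ANC and the later minimum", {
  # Accelerating maturation flushes the transit chain, so rescue given long
  # BEFORE a nadir can deepen it (the chain empties early); at the clinical
  # trigger timing - on a grade-4 nadir observation - it always helps. The
  # properties asserted: ANC inside the stimulation window never drops below
  # the untreated trajectory, and nadir-timed rescue does not deepen the
  # concurrent-or-later minimum.
  reg0 <- build_regimen(regimen_spec(bsa = 1.7, n_cycles = 2))
  tt <- seq(0, 70, by = 0.25)
  a0 <- simulate_individual(kpd_params(), reg0, tt)
  nad1 <- tt[which.min(a0[tt <= 28])]
  nad2 <- tt[tt > 28][which.min(a0[tt > 28])]
  for (tg in c(nad1, nad2)) {
    regg <- build_regimen(regimen_spec(bsa = 1.7, n_cycles = 2),
                          gcsf_times = tg)
    ag <- simulate_individual(kpd_params(), regg, tt)
    after <- tt >= tg
    expect_gte(min(ag[after]), min(a0[after]) - 1e-9)
    inwin <- tt >= tg & tt <= tg + 1.5
    expect_gte(min((ag - a0)[inwin]), -1e-9)
  }
})

test_that("simulation input validation", {
  p <- kpd_params()
  expect_error(simulate_individual(p, data.frame(time = 1, drug = "x",
                                                 amount = 1), 0:5),
               "unknown drug")
  expect_error(simulate_individual(p, data.frame(time = -1,
                                                 drug = "paclitaxel",
                                                 amount = 1), 0:5), ">= 0")
  expect_error(simulate_individual(p, NULL, c(3, 1)), "sorted")
})
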