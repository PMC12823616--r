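test_that("the fractional predictor-corrector matches the Mittag-Leffler closed form", {
  pr <- ml_decay_problem(0.7, 0.1, I0 = 70, horizon = 6, tau = 2)
  tr <- abm_fdde(pr$params, pr$histories, h = 5e-3)
  exI <- pr$exact$I(tr$t)
  expect_lt(sup_rel_err(tr$I, exI, floor = 1e-8), 1e-5)
  ## recovered compartment follows the fractional-integral identity
  exR <- pr$exact$R(tr$t)
  expect_lt(max(abs(tr$R - exR)), 1e-3)
})

test_that("at integer order the two oracles agree", {
  sc <- sir_scenario("as_text", alpha = 1)
  r1 <- rk4_dde(sc$params, sc$histories, h = 5e-3)
  r2 <- abm_fdde(sc$params, sc$histories, h = 5e-3)
  expect_lt(max(abs(as.matrix(r1[, 2:4]) - as.matrix(r2[, 2:4]))), 1e-4)
})

test_that("all-zero rates give a constant trajectory from the history head", {
  p <- sir_params(0, 0, 0, 0.8, 1, 700, 4)
  hs <- history_set(c(620, -5), c(10, 2), c(70, 3), 1)
  tr <- abm_fdde(p, hs, h = 0.01)
  expect_lt(max(abs(tr$S - 620), abs(tr$I - 10), abs(tr$R - 70)), 1e-12)
  p1 <- sir_params(0, 0, 0, 1, 1, 700, 4)
  tr1 <- rk4_dde(p1, hs, h = 0.01)
  expect_lt(max(abs(tr1$I - 10)), 1e-12)
})

test_that("both oracles conserve the total population", {
  sc <- sir_scenario("as_text", alpha = 0.8)
  tr <- abm_fdde(sc$params, sc$histories, h = 5e-3)
  expect_lt(conservation_residual(tr, 700), 1e-8)
  sc1 <- sir_scenario("as_text", alpha = 1)
  tr1 <- rk4_dde(sc1$params, sc1$histories, h = 5e-3)
  expect_lt(conservation_residual(tr1, 700), 1e-9)
})

test_that("RK4 self-convergence is fourth order", {
  sc <- sir_scenario("as_text", alpha = 1)
  ref <- rk4_dde(sc$params, sc$histories, h = 1e-3)
  pick <- function(tr, step) tr$I[seq(1, nrow(tr), by = round(1 / step))]
  e1 <- max(abs(pick(rk4_dde(sc$params, sc$histories, h = 0.02), 0.02) -
                  pick(ref, 1e-3)))
  e2 <- max(abs(pick(rk4_dde(sc$params, sc$histories, h = 0.01), 0.01) -
                  pick(ref, 1e-3)))
  expect_gt(log2(e1 / e2), 3.5)
})

test_that("ABM self-convergence order is at least 1 + alpha", {
  a <- 0.6
  pr <- ml_decay_problem(a, 0.2, I0 = 50, horizon = 4, tau = 1)
  ## measured away from the origin, where the solution's t^alpha term
  ## otherwise drags the observed sup-norm order down
  err <- vapply(c(0.02, 0.01, 0.005), function(h) {
    tr <- abm_fdde(pr$params, pr$histories, h = h)
    sel <- tr$t >= 1
    max(abs(tr$I[sel] - pr$exact$I(tr$t[sel])))
  }, numeric(1))
  orders <- log2(err[-3] / err[-1])
  expect_gt(min(orders), 1 + a - 0.3)
})

test_that("RK4 agrees with an independent general-purpose DDE solver", {
  skip_if_not_installed("deSolve")
  sc <- sir_scenario("as_text", alpha = 1)
  p <- sc$params
  deriv <- function(t, y, parms) {
    Idel <- if (t - p$tau < 0) sc$histories$phi2(t - p$tau)
    else deSolve::lagvalue(t - p$tau, 2)
    r <- sir_rhs(y[1], y[2], y[3], Idel, p)
    list(c(r$dS, r$dI, r$dR))
  }
  y0 <- c(sc$histories$phi1(0), sc$histories$phi2(0), sc$histories$phi3(0))
  out <- deSolve::dede(y0, seq(0, 10, by = 0.5), deriv, parms = NULL,
                       control = list(mxhist = 1e5))
  mine <- rk4_dde(p, sc$histories, h = 2e-3)
  sub <- mine[seq(1, nrow(mine), by = 250), ]  # every 0.5 time units
  expect_lt(max(abs(as.matrix(sub[, 2:4]) - out[, 2:4])), 1e-4)
})

test_that("invalid oracle configurations are rejected", {
  sc <- sir_scenario("as_text")
  expect_error(abm_fdde(sc$params, sc$histories, h = 3), "delay")
  expect_error(rk4_dde(sc$params, sc$histories), "alpha = 1")
})
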