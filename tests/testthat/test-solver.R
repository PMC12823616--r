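test_that("assembly produces a square system of the documented size", {
  sc <- sir_scenario("as_text")
  pr <- sir_collocation(sc$params, sc$histories, solver_config(J = 6))
  expect_identical(pr$n_b, 65L)   # 2^J wavelets + 1 trend column
  expect_identical(pr$n_c, pr$n_b)
  expect_identical(dim(pr$Psi), c(pr$n_c, pr$n_b))
  expect_identical(dim(pr$P), c(pr$n_c, pr$n_b))
  expect_true(all(pr$nodes > 0 & pr$nodes < sc$params$horizon))
  ## without augmentation the count is exactly 2^J
  pr0 <- sir_collocation(sc$params, sc$histories,
                         solver_config(J = 6, augment = 0))
  expect_identical(pr0$n_b, 64L)
  expect_error(sir_collocation(sc$params, sc$histories,
                               solver_config(J = 2)),
               "2\\^J|n_b")
})

test_that("with all rates zero and constant histories the zero vector solves the system", {
  p <- sir_params(0, 0, 0, 0.7, 2, 700, 10)
  hs <- history_set(620, 70, 10, 2)
  pr <- sir_collocation(p, hs, solver_config(J = 5))
  expect_lt(max(abs(collocation_residual(pr, numeric(3 * pr$n_b)))), 1e-12)
  sol <- solve_collocation(pr)
  expect_lt(max(abs(sol$coefficients)), 1e-12)
  expect_lt(max(abs(sol$trajectory$S - 620)), 1e-12)
})

test_that("the analytic Jacobian matches finite differences", {
  sc <- sir_scenario("as_text", alpha = 0.8)
  pr <- sir_collocation(sc$params, sc$histories, solver_config(J = 3))
  set.seed(11)
  x <- rnorm(3 * pr$n_b, sd = 0.1)
  st <- wavefdde:::.colloc_states(pr, x)
  Ja <- wavefdde:::.colloc_jacobian(pr, st)
  Jf <- wavefdde:::.colloc_jacobian_fd(pr, x)
  expect_lt(max(abs(Ja - Jf)), 1e-6)
})

test_that("relaxation with beta = delta = 0 reproduces the Mittag-Leffler decay", {
  pr <- ml_decay_problem(0.7, 0.1, I0 = 70, horizon = 10, tau = 2)
  sol <- solve_sir(pr$params, pr$histories, solver_config(J = 6))
  tg <- sol$trajectory$t
  expect_lt(sup_rel_err(sol$trajectory$I, pr$exact$I(tg), floor = 1e-8),
            1e-3)
  ## spot value at t = 5 against the independent evaluator
  at5 <- evaluate_solution(sol, 5)
  expect_equal(at5$I, 70 * mittag_leffler(0.7, -0.1 * 5^0.7),
               tolerance = 1e-3)
})

test_that("the reported initial susceptible value is exact to four decimals", {
  sc <- sir_scenario("as_text")
  sol <- solve_sir(sc$params, sc$histories, solver_config(J = 5))
  expect_identical(sprintf("%.4f", sol$trajectory$S[1]), "620.0000")
  expect_identical(sol$trajectory$t[1], 0)
})

test_that("converged runs conserve the population to solver accuracy", {
  for (variant in c("as_text", "as_tables")) {
    sc <- sir_scenario(variant, alpha = 0.9)
    sol <- solve_sir(sc$params, sc$histories, solver_config(J = 5))
    expect_true(sol$converged)
    expect_lt(sol$conservation, 1e-6)
  }
})

test_that("identical configurations give bit-identical output", {
  sc <- sir_scenario("as_text", alpha = 0.85)
  s1 <- solve_sir(sc$params, sc$histories, solver_config(J = 5))
  s2 <- solve_sir(sc$params, sc$histories, solver_config(J = 5))
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("fixed-point iteration reaches the same solution as Newton", {
  sc <- sir_scenario("as_text", alpha = 0.9)
  sn <- solve_sir(sc$params, sc$histories, solver_config(J = 5))
  sf <- solve_sir(sc$params, sc$histories,
                  solver_config(J = 5, method = "fixed_point",
                                max_iter = 200, residual_tol = 1e-9))
  expect_lt(max(abs(sn$trajectory$I - sf$trajectory$I)), 1e-6)
})

test_that("degree-one manufactured solutions are recovered essentially exactly", {
  p <- sir_params(5e-4, 0.1, 0.05, 1, 2, 700, 10)
  mp <- manufactured_problem(p, coef_S = c(600, -4), coef_I = c(30, 2),
                             coef_R = c(70, 2))
  sol <- solve_sir(mp$params, mp$histories, solver_config(J = 5),
                   forcing = mp$forcing)
  tg <- sol$trajectory$t
  err <- max(abs(sol$trajectory$S - mp$exact$S(tg)),
             abs(sol$trajectory$I - mp$exact$I(tg)),
             abs(sol$trajectory$R - mp$exact$R(tg)))
  expect_lt(err, 1e-6)
})

test_that("fractional manufactured solutions are recovered to discretization accuracy", {
  ## D^alpha of a polynomial is a t^(p - alpha) power function, outside the
  ## basis span, so recovery is limited by the kink-at-zero interpolation
  p <- sir_params(5e-4, 0.1, 0.05, 0.8, 2, 700, 10)
  mp <- manufactured_problem(p)
  sol <- solve_sir(mp$params, mp$histories, solver_config(J = 6),
                   forcing = mp$forcing)
  tg <- sol$trajectory$t
  expect_lt(sup_rel_err(sol$trajectory$I, mp$exact$I(tg)), 1e-3)
})

test_that("refinement study shows monotone convergence with positive order", {
  pf <- ml_decay_problem(0.7, 0.1, I0 = 70, horizon = 10, tau = 2)
  cs <- convergence_study(pf, 4:6)
  expect_true(all(diff(cs$l2_error) < 0))
  expect_gt(attr(cs, "order"), 1)
})

test_that("parameter sweeps solve each value independently", {
  sc <- sir_scenario("as_text")
  sw <- sweep_parameter(sc$params, sc$histories, "alpha", c(0.7, 1),
                        solver_config(J = 5))
  expect_length(sw, 2)
  for (s in sw) expect_lt(s$conservation, 1e-6)
  ## a singleton sweep reproduces a direct solve
  s1 <- sweep_parameter(sc$params, sc$histories, "alpha", 0.9,
                        solver_config(J = 5))[[1]]
  s2 <- solve_sir(sc$params, sc$histories, solver_config(J = 5))
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("the infection peak grows with the transmission rate (RK4 cross-check)", {
  sc <- sir_scenario("as_text", alpha = 1)
  betas <- c(3e-4, 6e-4, 1.2e-3)
  sw <- sweep_parameter(sc$params, sc$histories, "beta", betas,
                        solver_config(J = 6))
  peaks <- vapply(sw, function(s) max(s$trajectory$I), numeric(1))
  expect_true(all(diff(peaks) > 0))
  peaks_rk <- vapply(betas, function(b) {
    p <- sc$params; p$beta <- b
    max(rk4_dde(p, sc$histories, h = 5e-3)$I)
  }, numeric(1))
  expect_true(all(diff(peaks_rk) > 0))
  expect_lt(max(abs(peaks - peaks_rk) / peaks_rk), 1e-2)
})
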