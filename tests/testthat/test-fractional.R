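test_that("fractional integral matches closed forms", {
  expect_equal(rl_integral(function(s) rep(1, length(s)), 0.5, 1),
               1 / gamma(1.5), tolerance = 1e-10)
  expect_equal(rl_integral(function(s) s, 1, 2), 2, tolerance = 1e-12)
  expect_equal(rl_integral(function(s) s, 0.5, 1),
               gamma(2) / gamma(2.5), tolerance = 1e-10)
  expect_error(rl_integral(function(s) s, -0.1, 1), "positive")
})

test_that("Caputo derivative matches closed forms and kills constants", {
  expect_lt(max(abs(caputo_derivative(function(s) rep(7, length(s)),
                                      0.5, c(0.5, 1, 2)))), 1e-12)
  expect_equal(caputo_derivative(function(s) s^2, 0.5, 1,
                                 deriv = function(s) 2 * s),
               2 / gamma(2.5), tolerance = 1e-8)
  expect_equal(caputo_derivative(function(s) s^2, 1, 3,
                                 deriv = function(s) 2 * s), 6)
  expect_error(caputo_derivative(function(s) s, 1.2, 1), "\\(0, 1\\]")
})

test_that("power-function law holds across orders and powers", {
  for (p in 1:3) {
    for (a in c(0.3, 0.5, 0.7, 0.9)) {
      tt <- c(0.5, 2, 10)
      got <- caputo_derivative(function(s) s^p, a, tt,
                               deriv = function(s) p * s^(p - 1), n = 2048)
      ref <- gamma(p + 1) / gamma(p + 1 - a) * tt^(p - a)
      expect_lt(max(abs(got - ref) / abs(ref)), 1e-5)
    }
  }
})

test_that("operators are linear", {
  set.seed(42)
  for (rep in 1:3) {
    a <- runif(1, 0.2, 1)
    w <- rnorm(2)
    f <- function(s) sin(s) * exp(-s / 3)
    g <- function(s) cos(2 * s)
    df <- function(s) cos(s) * exp(-s / 3) - sin(s) * exp(-s / 3) / 3
    dg <- function(s) -2 * sin(2 * s)
    tt <- c(0.7, 1.9)
    lhs <- caputo_derivative(function(s) w[1] * f(s) + w[2] * g(s), a, tt,
                             deriv = function(s) w[1] * df(s) + w[2] * dg(s))
    rhs <- w[1] * caputo_derivative(f, a, tt, deriv = df) +
      w[2] * caputo_derivative(g, a, tt, deriv = dg)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("halving the quadrature step shrinks the error by >= 3x", {
  ref <- gamma(3) / gamma(3.5) * 2^2.5
  e1 <- abs(rl_integral(function(s) s^2, 0.5, 2, n = 128) - ref)
  e2 <- abs(rl_integral(function(s) s^2, 0.5, 2, n = 256) - ref)
  expect_gt(e1 / e2, 3)
})

test_that("semigroup property I^a I^b = I^(a+b) holds numerically", {
  f <- function(s) sin(s)
  inner <- function(tt) rl_integral(f, 0.4, tt, n = 512)
  lhs <- rl_integral(inner, 0.35, 2, n = 512)
  rhs <- rl_integral(f, 0.75, 2, n = 2048)
  expect_lt(abs(lhs - rhs), 1e-5)
})

test_that("collocation operator reproduces closed forms on its span", {
  b <- cached_basis(order = 4, J = 5, augment = 2)
  nodes <- (seq_len(b$n_b) - 0.5) / b$n_b
  op <- caputo_operator(b, 0.5, nodes)
  c1 <- basis_project(b, function(t) rep(1, length(t)))
  ## I^alpha of 1 is t^alpha / Gamma(1 + alpha)
  expect_lt(max(abs(op$P_alpha %*% c1 - nodes^0.5 / gamma(1.5))), 1e-6)
  ## Caputo annihilates constants
  expect_lt(max(abs(op$D_alpha %*% c1)), 1e-6)
  ## and matches the Gamma-ratio law on t^2 (exactly in the augmented span)
  c2 <- basis_project(b, function(t) t^2)
  expect_lt(max(abs(op$D_alpha %*% c2 - 2 * nodes^1.5 / gamma(2.5))), 1e-6)
})

test_that("at alpha = 1 the operator is the classical derivative", {
  b <- cached_basis(order = 4, J = 5, augment = 1)
  nodes <- (seq_len(b$n_b) - 0.5) / b$n_b
  op <- caputo_operator(b, 1, nodes)
  ct <- basis_project(b, function(t) t)
  expect_lt(max(abs(op$D_alpha %*% ct - 1)), 1e-4)
  ## rows agree with finite differences of the basis itself, relative to
  ## the scale of the derivative matrix (the cascade table is only Hoelder
  ## smooth, so entrywise agreement is limited by the table regularity)
  eps <- 1e-7
  mid <- nodes[3:6]
  fd <- (evaluate_basis(b, mid + eps) - evaluate_basis(b, mid - eps)) /
    (2 * eps)
  num <- op$D_alpha[3:6, ]
  expect_lt(max(abs(num - fd)) / max(abs(fd)), 1e-2)
})

test_that("integration undoes differentiation up to the initial value", {
  ## I^alpha D^alpha t^2 = t^2 - t^2|_0; the Gamma-ratio closed form is the
  ## independent reference; the t^(2-alpha) interpolant carries a small
  ## kink-at-zero error
  b <- cached_basis(order = 4, J = 5, augment = 2)
  nodes <- (seq_len(b$n_b) - 0.5) / b$n_b
  op <- caputo_operator(b, 0.5, nodes)
  c2 <- basis_project(b, function(t) t^2)
  Psin <- evaluate_basis(b, nodes)
  cD <- solve(unclass(Psin), as.vector(op$D_alpha %*% c2))
  expect_lt(max(abs(op$P_alpha %*% cD - nodes^2)), 1e-3)
})

test_that("Galerkin matrix is consistent with the physical-space operator", {
  b <- cached_basis(order = 4, J = 4, augment = 2)
  nodes <- (seq_len(b$n_b) - 0.5) / b$n_b
  op <- caputo_operator(b, 0.6, nodes, gram = TRUE)
  ## <psi_i, D^0.6 t^2> computed against the closed-form derivative
  c2 <- basis_project(b, function(t) t^2)
  u <- op$fine_grid
  nq <- length(u) - 1
  wq <- rep(b$T / nq, nq + 1)
  wq[c(1, nq + 1)] <- wq[c(1, nq + 1)] / 2
  ref <- as.vector(crossprod(op$Psi_fine,
                             wq * (2 * u^1.4 / gamma(2.4))))
  got <- as.vector(op$gram_D_alpha %*% c2)
  expect_lt(max(abs(got - ref)), 1e-4)
})

test_that("a node at zero is rejected for fractional orders", {
  b <- cached_basis(order = 4, J = 5)
  expect_error(caputo_operator(b, 0.5, c(0, 0.5)), "midpoint")
  expect_silent(op <- caputo_operator(b, 1, c(0, 0.5)))
})
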