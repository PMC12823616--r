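test_that("integer-multiple delay under the cyclic convention is the printed permutation", {
  sh <- shift_matrix(seq(0, 1, by = 0.25), 0.5, interp_order = 1,
                     policy = "cyclic")
  expected <- matrix(c(0, 0, 1, 0, 0,
                       0, 0, 0, 1, 0,
                       0, 0, 0, 0, 1,
                       1, 0, 0, 0, 0,
                       0, 1, 0, 0, 0), 5, 5, byrow = TRUE)
  expect_identical(as.matrix(sh$weights), expected)
  expect_identical(sh$weights[1, 3], 1)
  ## permutation also at higher interpolation order
  sh3 <- shift_matrix(seq(0, 1, by = 0.25), 0.25, policy = "cyclic")
  expect_true(all(rowSums(as.matrix(sh3$weights)) == 1))
  expect_true(all(as.matrix(sh3$weights) %in% c(0, 1)))
})

test_that("a vanishing delay gives the identity", {
  nodes <- c(0, 0.1, 0.35, 0.5, 0.9)
  sh <- shift_matrix(nodes, 1e-13)
  expect_equal(as.matrix(sh$weights), diag(5), tolerance = 1e-12)
})

test_that("linear interpolation at a midpoint gives (1/2, 1/2) weights", {
  nodes <- seq(0, 2, by = 0.1)
  sh <- shift_matrix(nodes, 0.15, interp_order = 1)
  W <- as.matrix(sh$weights)
  l <- 10  # t = 0.9, shifted to 0.75, between nodes 0.7 and 0.8
  expect_equal(unname(W[l, 8:9]), c(0.5, 0.5))
})

test_that("rows are a partition of unity with a bounded stencil", {
  nodes <- seq(0, 5, length.out = 41)
  for (ord in c(1, 3)) {
    sh <- shift_matrix(nodes, 0.43, interp_order = ord)
    W <- as.matrix(sh$weights)
    live <- setdiff(seq_len(41), sh$prehistory_rows)
    expect_lt(max(abs(rowSums(W[live, , drop = FALSE]) - 1)), 1e-12)
    expect_true(all(rowSums(W != 0) <= ord + 1))
    expect_true(all(rowSums(W[sh$prehistory_rows, , drop = FALSE] != 0) == 0))
  }
})

test_that("delayed values combine interpolation and history exactly", {
  nodes <- seq(0, 10, length.out = 51)
  sh <- shift_matrix(nodes, 2, interp_order = 1)
  Ifun <- function(t) 10 + 2 * t
  got <- delayed_values(sh, Ifun(nodes), history = Ifun)
  ## linear interpolation is exact on a linear signal, both branches
  expect_lt(max(abs(got - Ifun(nodes - 2))), 1e-10)
  ## the node t = 1 reads the history at -1: phi2(-1) = 8
  expect_equal(got[nodes == 1], 8)
  ## constants are preserved by the row-stochastic weights
  sh2 <- shift_matrix(nodes, 1.73)
  const <- delayed_values(sh2, rep(3.5, 51), history = function(t) rep(3.5, length(t)))
  expect_lt(max(abs(const - 3.5)), 1e-12)
})

test_that("interpolation error decays at the expected order", {
  f <- function(t) sin(1.3 * t) * exp(t / 8)
  ## keep the fractional grid offset of tau/h constant across refinements,
  ## otherwise the error constant (not the order) changes between grids
  err_for <- function(n, ord) {
    h <- 4 / n
    tau <- (round(0.31 / h) + 0.3) * h
    nodes <- seq(0, 4, length.out = n + 1)
    sh <- shift_matrix(nodes, tau, interp_order = ord)
    got <- delayed_values(sh, f(nodes), history = function(s) f(s))
    live <- setdiff(seq_len(n + 1), sh$prehistory_rows)
    max(abs(got[live] - f(nodes[live] - tau)))
  }
  for (ord in c(1, 3)) {
    e1 <- err_for(100, ord)
    e2 <- err_for(200, ord)
    p <- log2(e1 / e2)
    expected_p <- if (ord == 1) 2 else 4
    expect_lt(abs(p - expected_p), 0.3)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(shift_matrix(numeric(0), 0.5), "non-empty")
  expect_error(shift_matrix(c(0, 0.5, 0.4), 0.1), "increasing")
  expect_error(shift_matrix(seq(0, 1, 0.25), 1.5, policy = "cyclic"),
               "span")
  nodes <- seq(0, 1, 0.1)
  sh <- shift_matrix(nodes, 0.25)
  expect_error(delayed_values(sh, nodes[-1]), "match")
  expect_error(delayed_values(sh, f <- nodes * 0 + 1), "history")
})

test_that("history sets validate and convert their inputs", {
  hs <- history_set(c(620, -5), function(t) 10 + 2 * t,
                    list(x = c(-2, 0), y = c(64, 70)), tau = 2)
  expect_equal(hs$phi1(-2), 630)
  expect_equal(hs$phi2(-1), 8)
  expect_equal(hs$phi3(-1), 67)
  expect_error(history_set(c(1), c(1), function(t) 1 / t, tau = 2),
               "finite")
  expect_error(history_set(1, 1, 1, tau = -1), "positive")
})
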