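test_that("the LPAA update map evaluates its four equations correctly", {
  p <- lpaa_medians()
  # extinction is a fixed point
  expect_identical(unname(lpaa_step(p, c(0, 0, 0, 0))), c(0, 0, 0, 0))
  # linear Leslie limit without cannibalism
  p0 <- lpaa_params(b = 5, mu_l = 0.5, mu_p = 0.2, mu_a = 0.1, c1 = 0, c2 = 0)
  expect_equal(unname(lpaa_step(p0, c(0, 0, 0, 1))), c(5, 0, 0, 0.9))
  # term-by-term hand evaluation at the fitted medians
  st <- c(100, 50, 20, 40)
  expect_equal(unname(lpaa_step(p, st)),
               c(6.4232 * 40 * exp(-0.0099 * 40),
                 (1 - 0.6053) * 100,
                 (1 - 2.64e-12) * 50,
                 20 * exp(-0.0028 * 40) + (1 - 0.0358) * 40))
  expect_equal(unname(lpaa_step(p, st)), c(172.91, 39.47, 50, 56.45),
               tolerance = 1e-3)
})

test_that("the LPA update map evaluates its three equations correctly", {
  expect_identical(unname(lpa_step(lpa_medians(), c(0, 0, 0))), c(0, 0, 0))
  p0 <- lpa_params(b = 7, mu_l = 0.5, mu_a = 0.1, c1 = 0, c2 = 0, c3 = 0)
  expect_equal(unname(lpa_step(p0, c(0, 0, 1))), c(7, 0, 0.9))
  p <- lpa_params(b = 20, mu_l = 0.6053, mu_a = 0.0842,
                  c1 = 0.0179, c2 = 0.0003, c3 = 0)
  out <- lpa_step(p, c(50, 30, 40))
  expect_equal(out[["L"]], 20 * 40 * exp(-0.0179 * 50 - 0.0003 * 40))
  expect_equal(out[["P"]], (1 - 0.6053) * 50)
  expect_equal(out[["A"]], 30 + (1 - 0.0842) * 40)
})

test_that("states are validated", {
  expect_error(lpaa_step(lpaa_medians(), c(-1, 0, 0, 0)), "nonnegative")
  expect_error(lpaa_step(lpaa_medians(), c(1, 2, 3)), "length 4")
  expect_error(lpa_step(lpa_medians(), c(1, NA, 3)), "nonnegative")
})

test_that("trajectories are deterministic, restartable and length-correct", {
  p <- lpaa_medians()
  expect_equal(nrow(project_population(p, c(1, 2, 3, 4), 0)), 1L)
  tr <- project_population(p, c(100, 50, 20, 40), 100)
  expect_equal(nrow(tr), 101L)
  # re-simulating from the midpoint reproduces the tail exactly
  mid <- as.numeric(tr[51, c("L", "P", "A1", "A2")])
  tr2 <- project_population(p, mid, 50)
  expect_identical(tr2[, c("L", "P", "A1", "A2")],
                   structure(tr[51:101, c("L", "P", "A1", "A2")],
                             row.names = 1:51))
  # LPA trajectory has columns t, L, P, A
  expect_named(project_population(lpa_medians(), c(10, 10, 10), 5),
               c("t", "L", "P", "A"))
})

test_that("divergent trajectories are reported with their step index", {
  p <- lpaa_params(b = 50, mu_l = 0.2, mu_p = 0, mu_a = 0.1, c1 = 0, c2 = 0)
  expect_error(project_population(p, c(10, 10, 10, 10), 500, overflow = 1e6),
               "diverged.*step [0-9]+")
})

test_that("the projection matrix reproduces the map and is nonnegative", {
  set.seed(41)
  for (i in 1:20) {
    p <- random_interior_lpaa()
    st <- runif(4, 0, 300)
    M <- projection_matrix(p, st)
    expect_true(all(M >= 0))
    expect_equal(unname(as.numeric(M %*% st)), unname(lpaa_step(p, st)))
  }
  # at the origin the exponentials vanish: inherent matrix = Jacobian at E0
  p <- lpaa_medians()
  expect_equal(projection_matrix(p, c(0, 0, 0, 0)),
               model_jacobian(p, c(0, 0, 0, 0)))
})

test_that("the Jacobian matches central finite differences of the map", {
  fd_jacobian <- function(step, state, h = 1e-5) {
    n <- length(state)
    J <- matrix(0, length(step(state)), n)
    for (k in seq_len(n)) {
      up <- state; up[k] <- up[k] + h
      dn <- state; dn[k] <- dn[k] - h
      J[, k] <- (step(up) - step(dn)) / (2 * h)
    }
    J
  }
  set.seed(42)
  for (i in 1:50) {
    p <- random_interior_lpaa()
    st <- runif(4, 1, 300)
    J <- model_jacobian(p, st)
    expect_equal(unname(J), fd_jacobian(function(s) lpaa_step(p, s), st),
                 tolerance = 1e-6)
  }
  for (i in 1:25) {
    p <- lpa_medians()
    st <- runif(3, 1, 300)
    expect_equal(unname(model_jacobian(p, st)),
                 fd_jacobian(function(s) lpa_step(p, s), st),
                 tolerance = 1e-6)
  }
})

test_that("the Jacobian at the positive steady state satisfies the fixed-point identities", {
  set.seed(43)
  for (i in 1:20) {
    p <- lpaa_with_r0(runif(1, 1.5, 40))
    ss <- steady_states(p)
    J <- model_jacobian(p, ss$E_star)
    L <- ss$E_star[["L"]]; A2 <- ss$E_star[["A2"]]
    expect_equal(J[1, 4], L * (1 / A2 - p$c1))
    expect_equal(J[4, 4], 1 - p$mu_a * (1 + p$c2 * A2))
  }
})

test_that("the net reproductive number is b(1-mu_l)(1-mu_p)/mu_a", {
  # boundary: mu_a chosen to make R0 exactly one
  p <- lpaa_params(b = 2, mu_l = 0.5, mu_p = 0.5, mu_a = 0.5, c1 = 0.01, c2 = 0.01)
  expect_identical(net_reproductive_number(p), 1)
  expect_equal(net_reproductive_number(lpaa_medians()), 70.8, tolerance = 3e-4)
  expect_equal(net_reproductive_number(lpa_medians()), 20 * (1 - 0.6053) / 0.0842)
})

test_that("steady states exist per the R0 threshold and are exact fixed points", {
  p_sub <- lpaa_with_r0(0.8, mu_l = 0.5, mu_p = 0.1, mu_a = 0.4,
                        c1 = 0.01, c2 = 0.01)
  ss <- steady_states(p_sub)
  expect_null(ss$E_star)
  expect_identical(unname(lpaa_step(p_sub, ss$E0)), c(0, 0, 0, 0))

  p <- lpaa_medians()
  ss <- steady_states(p)
  expect_equal(ss$E_star[["A2"]], log(70.81668) / 0.0127, tolerance = 1e-6)
  expect_lt(max(abs(lpaa_step(p, ss$E_star) - ss$E_star)), 1e-12)

  set.seed(44)
  for (i in 1:20) {
    p <- lpaa_with_r0(runif(1, 1.2, 60))
    ss <- steady_states(p)
    expect_lt(max(abs(lpaa_step(p, ss$E_star) - ss$E_star)),
              1e-12 * (1 + max(ss$E_star)))
  }
  # supercritical without cannibalism: no interior equilibrium
  p_lin <- lpaa_params(b = 10, mu_l = 0.5, mu_p = 0, mu_a = 0.5, c1 = 0, c2 = 0)
  expect_error(steady_states(p_lin), "no interior equilibrium")
})

test_that("the invariant-region envelope is computed and respected", {
  env <- state_bounds(lpaa_medians())
  expect_equal(env$L_hat, 6.4232 / (exp(1) * 0.0099))
  expect_equal(env$P_hat, (1 - 0.6053) * env$L_hat)
  expect_equal(env$A1_hat, (1 - 2.64e-12) * env$P_hat)
  expect_error(state_bounds(lpaa_params(b = 1, mu_l = 0.5, mu_p = 0,
                                        mu_a = 0.5, c1 = 0, c2 = 0.1)),
               "no finite larval bound")
  # positive invariance along simulated orbits started inside the region
  set.seed(45)
  for (i in 1:10) {
    p <- random_interior_lpaa()
    env <- state_bounds(p, A2_0 = 50)
    st <- c(runif(1, 0, env$L_hat), runif(1, 0, env$P_hat),
            runif(1, 0, env$A1_hat), 50)
    tr <- project_population(p, st, 1000)
    expect_true(all(tr$L[-1] <= env$L_hat * (1 + 1e-12)))
    expect_true(all(tr$P[-1] <= env$P_hat * (1 + 1e-12)))
    expect_true(all(tr$A1[-1] <= env$A1_hat * (1 + 1e-12)))
    expect_true(all(tr$A2 <= env$A2_bound * (1 + 1e-12)))
  }
})

test_that("primitivity is decided by boolean matrix powers", {
  expect_identical(primitivity_index(matrix(1, 4, 4)), 1L)
  expect_identical(primitivity_index(diag(4)), NA_integer_)
  expect_error(primitivity_index(matrix(c(1, -1, 0, 1), 2, 2)), "nonnegative")
  # a 2-cycle permutation is irreducible but imprimitive
  expect_identical(primitivity_index(matrix(c(0, 1, 1, 0), 2, 2)), NA_integer_)
  set.seed(46)
  for (i in 1:20)
    expect_identical(primitivity_index(projection_matrix(random_interior_lpaa())), 6L)
})
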