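test_that("extinction is classified by R0 and corroborated by simulation", {
  set.seed(51)
  p <- lpaa_with_r0(0.8)
  expect_identical(classify_extinction(p), "GAS")
  for (i in 1:5) {
    st <- runif(4, 0, 500)
    tr <- project_population(p, st, 2000)
    expect_lt(max(tr[2001, c("L", "P", "A1", "A2")]), 1e-6)
    # eventual monotone decay of the total population
    tot <- rowSums(tr[, c("L", "P", "A1", "A2")])
    expect_true(all(diff(tot[1500:2001]) <= 0))
  }
  expect_identical(
    classify_extinction(lpaa_params(2, 0.5, 0.5, 0.5, 0.01, 0.01)), "boundary")
  expect_identical(classify_extinction(lpaa_medians()), "unstable")
})

test_that("the proved local-stability bound follows the Jacobian conditions", {
  p <- lpaa_params(b = 3, mu_l = 0.5, mu_p = 0.1, mu_a = 0.5, c1 = 1, c2 = 1)
  expect_equal(local_stability_bound(p), exp(2))
  # the two conditions cap A2* by 1/c1 and (1-mu_a)/(mu_a c2) respectively
  p2 <- lpaa_params(b = 3, mu_l = 0.5, mu_p = 0.1, mu_a = 0.25, c1 = 0.5, c2 = 0.1)
  expect_equal(local_stability_bound(p2),
               min(exp(1 + 0.1 / 0.5), exp(0.75 / 0.25 * (1 + 0.5 / 0.1))))
  # a vanishing coefficient disables the corresponding condition
  p3 <- lpaa_params(b = 3, mu_l = 0.5, mu_p = 0.1, mu_a = 0.5, c1 = 0, c2 = 0.1)
  expect_equal(local_stability_bound(p3), exp((1 - 0.5) / 0.5 * 1))
  p4 <- lpaa_params(b = 3, mu_l = 0.5, mu_p = 0.1, mu_a = 0.5, c1 = 0.1, c2 = 0)
  expect_equal(local_stability_bound(p4), exp(1))
  expect_warning(
    bound <- local_stability_bound(lpaa_params(3, 0.5, 0.1, 0.5, 0, 0)),
    "vacuous")
  expect_identical(bound, Inf)
})

test_that("the global-stability bound reduces to e for small c2", {
  expect_equal(global_stability_bound(lpaa_params(3, 0.5, 0.1, 0.5, 0.1, 0)),
               exp(1))
  # both terms equal when c1(1-mu_a) = c2 mu_a
  p <- lpaa_params(b = 3, mu_l = 0.5, mu_p = 0.1, mu_a = 0.5, c1 = 0.2, c2 = 0.2)
  expect_equal(global_stability_bound(p), exp(1))
  expect_equal(global_stability_bound(lpaa_medians()), exp(1))  # second term ~95e
  p2 <- lpaa_params(b = 3, mu_l = 0.5, mu_p = 0.1, mu_a = 0.8, c1 = 0.01, c2 = 0.2)
  expect_equal(global_stability_bound(p2), exp(1) * 0.01 * 0.2 / (0.2 * 0.8))
})

test_that("stability assessment combines the thresholds", {
  sa <- stability_assessment(lpaa_with_r0(0.5, mu_a = 0.5))
  expect_identical(sa$extinction_status, "GAS")
  expect_identical(sa$interior_status, "absent")
  set.seed(52)
  sa2 <- stability_assessment(random_global_stable_lpaa())
  expect_identical(sa2$interior_status, "global_AS")
  sa3 <- stability_assessment(lpaa_medians())
  expect_identical(sa3$interior_status, "outside_proved_region")
})

test_that("state-to-history conversion matches the first four mature-adult values", {
  p <- lpaa_medians()
  # no recruits in the pipeline: pure geometric decay of adults
  a <- 120
  expect_equal(unname(delay_history(p, c(0, 0, 0, a))),
               a * (1 - p$mu_a)^(0:3))
  expect_identical(unname(delay_history(p, c(0, 0, 0, 0))), rep(0, 4))
  set.seed(53)
  for (i in 1:10) {
    p <- random_interior_lpaa()
    st <- runif(4, 0, 300)
    tr <- project_population(p, st, 3)
    expect_equal(unname(delay_history(p, st)), tr$A2, tolerance = 1e-12)
  }
})

test_that("the delay equation reproduces the full model's mature adults", {
  set.seed(54)
  for (i in 1:50) {
    p <- random_interior_lpaa()
    st <- runif(4, 0, 300)
    tr <- project_population(p, st, 203)
    x <- delay_simulate(p, delay_history(p, st), 200)
    # x(t) = A2(t+3): the vector covers A2(0) .. A2(203)
    expect_lt(max(abs(x - tr$A2)), 1e-10 * (1 + max(tr$A2)))
  }
})

test_that("the delay equation fixes x* = ln(beta/mu_a)/(c1+c2) = A2*", {
  set.seed(55)
  for (i in 1:10) {
    p <- lpaa_with_r0(runif(1, 1.5, 30))
    beta <- p$b * (1 - p$mu_l) * (1 - p$mu_p)
    xs <- log(beta / p$mu_a) / (p$c1 + p$c2)
    expect_equal(xs, steady_states(p)$E_star[["A2"]])
    # one application of the delay map leaves x* unmoved (the equilibrium
    # itself may be unstable, so long iteration would amplify rounding)
    x <- delay_simulate(p, rep(xs, 4), 1)
    expect_lt(abs(x[5] - xs), 1e-12 * (1 + xs))
  }
})

test_that("delay trajectories respect the asymptotic upper bound beta/(e c1 mu_a)", {
  set.seed(56)
  for (i in 1:20) {
    p <- random_interior_lpaa()
    beta <- p$b * (1 - p$mu_l) * (1 - p$mu_p)
    cap <- beta / (exp(1) * p$c1 * p$mu_a)
    x <- delay_simulate(p, runif(4, 0, 500), 2000)
    expect_true(all(x[1001:length(x)] <= cap * (1 + 1e-6)))
  }
})

test_that("parameters inside the global-stability region converge to E*", {
  set.seed(57)
  for (i in 1:20) {
    p <- random_global_stable_lpaa()
    ss <- steady_states(p)
    tr <- project_population(p, runif(4, 1, 300), 5000)
    expect_lt(abs(tr$A2[5001] - ss$E_star[["A2"]]), 1e-8)
  }
})

test_that("the stability-region grid labels cells consistently with the bounds", {
  g <- stability_region(mu_a_grid = c(0.2, 0.5, 0.8),
                        ln_b_grid = c(-2, 0.5, 4),
                        c1 = 0.0099, c2 = 0, mu_l = 0.6053, mu_p = 0,
                        sim_check = TRUE, n_sim = 5000)
  expect_setequal(setdiff(unique(g$label),
                          c("extinction", "global_AS",
                            "local_AS_hypothesized", "unresolved")),
                  character(0))
  expect_true(all(g$label[g$r0 < 1] == "extinction"))
  gas <- g$r0 > 1 & g$r0 < exp(1)
  expect_true(all(g$label[gas] == "global_AS"))
  # simulation refinement: cells proved globally stable converge...
  g2 <- stability_region(0.5, log(1.5 * 0.5 / (1 - 0.6053)),
                         c1 = 0.0099, c2 = 0, mu_l = 0.6053, mu_p = 0)
  expect_identical(g2$label, "global_AS")
  # ...while sustained oscillation exists outside the proved regions
  posc <- lpaa_params(b = exp(4), mu_l = 0.6053, mu_p = 0, mu_a = 0.6,
                      c1 = 0.0099, c2 = 0)
  tr <- project_population(posc, c(10, 10, 10, 10), 5000)
  tail_tot <- rowSums(tr[4902:5001, c("L", "P", "A1", "A2")])
  expect_gt(diff(range(tail_tot)), 0.01 * mean(tail_tot))
  gr <- stability_region(0.6, 4, c1 = 0.0099, c2 = 0, mu_l = 0.6053,
                         mu_p = 0, sim_check = TRUE)
  expect_identical(gr$sim_label, "cycling_or_other")
})
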