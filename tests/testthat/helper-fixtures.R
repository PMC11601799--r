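# Shared fixtures: parameter draws used across the suite. All draws are
# plain runif under the caller's RNG state; tests set their own seeds.

# interior truth for recovery experiments: fitted medians except that the
# pupal mortality is moved off the boundary so relative errors are defined
interior_truth <- function() {
  lpaa_params(b = 6.4232, mu_l = 0.6053, mu_p = 0.05, mu_a = 0.0358,
              c1 = 0.0099, c2 = 0.0028)
}

# founding census population: larvae-heavy with an adult cohort, the usual
# way laboratory flour-beetle cultures are initiated
founding_state <- function() c(L = 250, P = 5, A1 = 0, A2 = 100)

random_interior_lpaa <- function() {
  lpaa_params(b = runif(1, 1, 20),
              mu_l = runif(1, 0.2, 0.8),
              mu_p = runif(1, 0, 0.5),
              mu_a = runif(1, 0.1, 0.9),
              c1 = runif(1, 0.005, 0.1),
              c2 = runif(1, 0.001, 0.05))
}

# draw with prescribed net reproductive number (b solved from R0)
lpaa_with_r0 <- function(r0, mu_l = runif(1, 0.2, 0.8), mu_p = runif(1, 0, 0.5),
                         mu_a = runif(1, 0.2, 0.9), c1 = runif(1, 0.005, 0.1),
                         c2 = runif(1, 0.001, 0.05)) {
  b <- r0 * mu_a / ((1 - mu_l) * (1 - mu_p))
  lpaa_params(b = b, mu_l = mu_l, mu_p = mu_p, mu_a = mu_a, c1 = c1, c2 = c2)
}

# draw satisfying the global-stability condition 1 < R0 < min(e, e c1 (1-mu_a)/(c2 mu_a))
random_global_stable_lpaa <- function() {
  repeat {
    mu_l <- runif(1, 0.2, 0.8); mu_p <- runif(1, 0, 0.5)
    mu_a <- runif(1, 0.1, 0.9)
    c1 <- runif(1, 0.005, 0.1); c2 <- runif(1, 0.001, 0.05)
    ub <- min(exp(1), exp(1) * c1 * (1 - mu_a) / (c2 * mu_a))
    if (ub > 1.1) {
      r0 <- runif(1, 1.05, min(ub * 0.95, exp(1) * 0.98))
      return(lpaa_with_r0(r0, mu_l, mu_p, mu_a, c1, c2))
    }
  }
}

# draw satisfying the local-stability (nonnegative primitive Jacobian) bound
random_local_stable_lpaa <- function() {
  repeat {
    mu_l <- runif(1, 0.2, 0.8); mu_p <- runif(1, 0, 0.5)
    mu_a <- runif(1, 0.2, 0.8)
    c1 <- runif(1, 0.05, 1); c2 <- runif(1, 0.05, 1)
    ub <- min(exp(1 + c2 / c1),
              exp((1 - mu_a) / mu_a * (1 + c1 / c2)))
    if (ub > 1.2) {
      r0 <- runif(1, 1.05, min(ub * 0.9, 50))
      return(lpaa_with_r0(r0, mu_l, mu_p, mu_a, c1, c2))
    }
  }
}
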