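#' One step of the LPAA map
#'
#' Advances a four-stage state (L, P, A1, A2) by one two-week step:
#' \deqn{L' = b A_2 e^{-c_1 A_2},\quad P' = (1-\mu_l) L,\quad
#'       A_1' = (1-\mu_p) P,\quad A_2' = A_1 e^{-c_2 A_2} + (1-\mu_a) A_2.}
#'
#' @param params an [lpaa_params()] object.
#' @param state numeric vector of length 4 (order L, P, A1, A2), all
#'   components nonnegative. Names are optional.
#' @return Named numeric vector `c(L, P, A1, A2)`, the next state.
#' @examples
#' lpaa_step(lpaa_medians(), c(L = 100, P = 50, A1 = 20, A2 = 40))
#' @export
lpaa_step <- function(params, state) {
  check_state(state, 4L)
  L <- state[[1]]; P <- state[[2]]; A1 <- state[[3]]; A2 <- state[[4]]
  c(L  = params$b * A2 * exp(-params$c1 * A2),
    P  = (1 - params$mu_l) * L,
    A1 = (1 - params$mu_p) * P,
    A2 = A1 * exp(-params$c2 * A2) + (1 - params$mu_a) * A2)
}

#' One step of the LPA map
#'
#' \deqn{L' = b A e^{-c_1 L - c_2 A},\quad P' = (1-\mu_l) L,\quad
#'       A' = P e^{-c_3 A} + (1-\mu_a) A.}
#'
#' @param params an [lpa_params()] object.
#' @param state numeric vector of length 3 (order L, P, A), nonnegative.
#' @return Named numeric vector `c(L, P, A)`.
#' @export
lpa_step <- function(params, state) {
  check_state(state, 3L)
  L <- state[[1]]; P <- state[[2]]; A <- state[[3]]
  c(L = params$b * A * exp(-params$c1 * L - params$c2 * A),
    P = (1 - params$mu_l) * L,
    A = P * exp(-params$c3 * A) + (1 - params$mu_a) * A)
}

check_state <- function(state, n) {
  if (!is.numeric(state) || length(state) != n)
    stop("state must be a numeric vector of length ", n)
  if (anyNA(state) || any(state < 0))
    stop("state components must be nonnegative and non-missing")
  invisible(state)
}

state_names <- function(params) {
  if (inherits(params, "lpaa_params")) c("L", "P", "A1", "A2") else c("L", "P", "A")
}

#' Iterate a beetle model forward in time
#'
#' Simulates the deterministic map for `n_steps` steps (one step = two
#' weeks), recording every state. States are continuous abundances; the
#' deterministic skeleton is what is iterated, integer observation noise
#' belongs to [generate_census()].
#'
#' @param params an [lpaa_params()] or [lpa_params()] object.
#' @param state0 initial state (length 4 for LPAA, 3 for LPA), nonnegative.
#' @param n_steps number of steps (>= 0).
#' @param overflow divergence guard: if any component exceeds this value the
#'   simulation aborts with an error reporting the step index. The map with
#'   `c1 + c2 = 0` and net reproductive number above one grows without
#'   bound, so unbounded orbits are reported rather than silently returned.
#' @return A data frame of class `"beetle_trajectory"` with columns `t` and
#'   the stage abundances (`L, P, A1, A2` or `L, P, A`), `n_steps + 1` rows.
#' @examples
#' tr <- project_population(lpaa_medians(), c(100, 50, 20, 40), 10)
#' head(tr)
#' @export
project_population <- function(params, state0, n_steps, overflow = 1e12) {
  UseMethod("project_population")
}

#' @export
project_population.lpaa_params <- function(params, state0, n_steps, overflow = 1e12) {
  check_state(state0, 4L)
  stopifnot(n_steps >= 0)
  n_steps <- as.integer(n_steps)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 4L)
  out[1L, ] <- as.numeric(state0)
  b <- params$b; sl <- 1 - params$mu_l; sp <- 1 - params$mu_p
  sa <- 1 - params$mu_a; c1 <- params$c1; c2 <- params$c2
  L <- state0[[1]]; P <- state0[[2]]; A1 <- state0[[3]]; A2 <- state0[[4]]
  if (n_steps > 0) for (t in seq_len(n_steps)) {
    Ln <- b * A2 * exp(-c1 * A2)
    Pn <- sl * L
    A1n <- sp * P
    A2n <- A1 * exp(-c2 * A2) + sa * A2
    L <- Ln; P <- Pn; A1 <- A1n; A2 <- A2n
    if (L > overflow || A2 > overflow)
      stop("trajectory diverged (component > ", overflow, ") at step ", t)
    out[t + 1L, ] <- c(L, P, A1, A2)
  }
  tr <- data.frame(t = 0:n_steps, L = out[, 1], P = out[, 2],
                   A1 = out[, 3], A2 = out[, 4])
  structure(tr, class = c("beetle_trajectory", "data.frame"), params = params)
}

#' @export
project_population.lpa_params <- function(params, state0, n_steps, overflow = 1e12) {
  check_state(state0, 3L)
  stopifnot(n_steps >= 0)
  n_steps <- as.integer(n_steps)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 3L)
  out[1L, ] <- as.numeric(state0)
  b <- params$b; sl <- 1 - params$mu_l; sa <- 1 - params$mu_a
  c1 <- params$c1; c2 <- params$c2; c3 <- params$c3
  L <- state0[[1]]; P <- state0[[2]]; A <- state0[[3]]
  if (n_steps > 0) for (t in seq_len(n_steps)) {
    Ln <- b * A * exp(-c1 * L - c2 * A)
    Pn <- sl * L
    An <- P * exp(-c3 * A) + sa * A
    L <- Ln; P <- Pn; A <- An
    if (L > overflow || A > overflow)
      stop("trajectory diverged (component > ", overflow, ") at step ", t)
    out[t + 1L, ] <- c(L, P, A)
  }
  tr <- data.frame(t = 0:n_steps, L = out[, 1], P = out[, 2], A = out[, 3])
  structure(tr, class = c("beetle_trajectory", "data.frame"), params = params)
}

#' Write a trajectory to CSV
#'
#' Columns `t, L, P, A1, A2` (LPAA) or `t, L, P, A` (LPA).
#' @param trajectory a `"beetle_trajectory"` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.beetle_trajectory <- function(x, which = setdiff(names(x), "t"), ...) {
  ylim <- range(unlist(x[which]), 0)
  graphics::matplot(x$t, as.matrix(x[which]), type = "l", lty = 1,
                    xlab = "time step (2 weeks)", ylab = "abundance",
                    ylim = ylim, ...)
  graphics::legend("topright", legend = which, lty = 1,
                   col = seq_along(which), bty = "n")
  invisible(x)
}

#' Density-dependent projection matrix of the LPAA model
#'
#' Returns the 4x4 nonnegative matrix `P(x)` such that the LPAA map is
#' `x(t+1) = P(x(t)) x(t)`. At the origin this is the inherent projection
#' matrix governing small populations.
#'
#' @param params an [lpaa_params()] object.
#' @param state state vector (only the mature-adult component `A2` enters);
#'   either a length-4 state or a single `A2` value.
#' @return A 4x4 numeric matrix with dimnames `L, P, A1, A2`.
#' @examples
#' projection_matrix(lpaa_medians(), c(0, 0, 0, 0))  # inherent matrix
#' @export
projection_matrix <- function(params, state = c(0, 0, 0, 0)) {
  stopifnot(inherits(params, "lpaa_params"))
  A2 <- if (length(state) == 1L) state else state[[4]]
  if (!is.finite(A2) || A2 < 0) stop("A2 must be a nonnegative number")
  nm <- c("L", "P", "A1", "A2")
  M <- matrix(0, 4, 4, dimnames = list(nm, nm))
  M[1, 4] <- params$b * exp(-params$c1 * A2)
  M[2, 1] <- 1 - params$mu_l
  M[3, 2] <- 1 - params$mu_p
  M[4, 3] <- exp(-params$c2 * A2)
  M[4, 4] <- 1 - params$mu_a
  M
}

#' Jacobian of a beetle map at a state
#'
#' For the LPAA model the only nonzero entries are
#' (1,4) = `b (1 - c1 A2) exp(-c1 A2)`, (2,1) = `1 - mu_l`,
#' (3,2) = `1 - mu_p`, (4,3) = `exp(-c2 A2)` and
#' (4,4) = `-c2 A1 exp(-c2 A2) + 1 - mu_a`. At the origin the Jacobian
#' coincides with the inherent projection matrix.
#'
#' @param params an [lpaa_params()] or [lpa_params()] object.
#' @param state state vector at which to linearise.
#' @return The Jacobian matrix (4x4 for LPAA, 3x3 for LPA).
#' @export
model_jacobian <- function(params, state) UseMethod("model_jacobian")

#' @export
model_jacobian.lpaa_params <- function(params, state) {
  check_state(state, 4L)
  A1 <- state[[3]]; A2 <- state[[4]]
  nm <- c("L", "P", "A1", "A2")
  J <- matrix(0, 4, 4, dimnames = list(nm, nm))
  J[1, 4] <- params$b * (1 - params$c1 * A2) * exp(-params$c1 * A2)
  J[2, 1] <- 1 - params$mu_l
  J[3, 2] <- 1 - params$mu_p
  J[4, 3] <- exp(-params$c2 * A2)
  J[4, 4] <- -params$c2 * A1 * exp(-params$c2 * A2) + 1 - params$mu_a
  J
}

#' @export
model_jacobian.lpa_params <- function(params, state) {
  check_state(state, 3L)
  L <- state[[1]]; P <- state[[2]]; A <- state[[3]]
  nm <- c("L", "P", "A")
  J <- matrix(0, 3, 3, dimnames = list(nm, nm))
  rec <- exp(-params$c1 * L - params$c2 * A)
  J[1, 1] <- -params$c1 * params$b * A * rec
  J[1, 3] <- params$b * (1 - params$c2 * A) * rec
  J[2, 1] <- 1 - params$mu_l
  J[3, 2] <- exp(-params$c3 * A)
  J[3, 3] <- -params$c3 * P * exp(-params$c3 * A) + 1 - params$mu_a
  J
}

#' Net reproductive number
#'
#' For the LPAA model, `R0 = b (1 - mu_l)(1 - mu_p) / mu_a`: the average
#' number of offspring of a single adult that survive to adulthood. A
#' positive steady state exists precisely when `R0 > 1`. The LPA analogue is
#' `b (1 - mu_l) / mu_a`.
#'
#' @param params a parameter object.
#' @return A single number.
#' @examples
#' net_reproductive_number(lpaa_medians())  # about 70.8
#' @export
net_reproductive_number <- function(params) UseMethod("net_reproductive_number")

#' @export
net_reproductive_number.lpaa_params <- function(params) {
  if (params$mu_a == 0) stop("net reproductive number undefined for mu_a = 0")
  params$b * (1 - params$mu_l) * (1 - params$mu_p) / params$mu_a
}

#' @export
net_reproductive_number.lpa_params <- function(params) {
  if (params$mu_a == 0) stop("net reproductive number undefined for mu_a = 0")
  params$b * (1 - params$mu_l) / params$mu_a
}

#' Steady states of the LPAA model
#'
#' The extinction state `E0 = (0,0,0,0)` always exists. When `R0 > 1` and
#' `c1 + c2 > 0` there is a unique positive steady state with
#' \deqn{A_2^* = \frac{\ln R_0}{c_1 + c_2},\quad L^* = b A_2^* e^{-c_1 A_2^*},
#'       \quad P^* = (1-\mu_l) L^*,\quad A_1^* = (1-\mu_p) P^*.}
#'
#' @param params an [lpaa_params()] object.
#' @return A list with components `E0` (named numeric), `E_star` (named
#'   numeric or `NULL` when `R0 <= 1`) and `R0`.
#' @examples
#' steady_states(lpaa_medians())$E_star
#' @export
steady_states <- function(params) {
  stopifnot(inherits(params, "lpaa_params"))
  R0 <- net_reproductive_number(params)
  E0 <- c(L = 0, P = 0, A1 = 0, A2 = 0)
  if (R0 <= 1) return(list(E0 = E0, E_star = NULL, R0 = R0))
  if (params$c1 + params$c2 == 0)
    stop("no interior equilibrium (unbounded growth): R0 > 1 with c1 + c2 = 0")
  A2s <- log(R0) / (params$c1 + params$c2)
  Ls <- params$b * A2s * exp(-params$c1 * A2s)
  Ps <- (1 - params$mu_l) * Ls
  A1s <- (1 - params$mu_p) * Ps
  list(E0 = E0, E_star = c(L = Ls, P = Ps, A1 = A1s, A2 = A2s), R0 = R0)
}

#' Invariant-region envelope of the LPAA model
#'
#' The map is positively invariant for the box with larval bound
#' `L_hat = b / (e c1)` (the maximum of `b x exp(-c1 x)`), pupal bound
#' `P_hat = (1 - mu_l) L_hat`, new-adult bound `A1_hat = (1 - mu_p) P_hat`,
#' and mature-adult bound `A1_hat / mu_a + A2(0)`.
#'
#' @param params an [lpaa_params()] object with `c1 > 0`.
#' @param A2_0 initial mature-adult abundance (enters only the `A2` bound).
#' @return A list of class `"bound_envelope"` with `L_hat`, `P_hat`,
#'   `A1_hat`, `A2_bound`.
#' @export
state_bounds <- function(params, A2_0 = 0) {
  stopifnot(inherits(params, "lpaa_params"))
  if (params$c1 <= 0) stop("no finite larval bound: c1 must be positive")
  L_hat <- params$b / (exp(1) * params$c1)
  P_hat <- (1 - params$mu_l) * L_hat
  A1_hat <- (1 - params$mu_p) * P_hat
  structure(list(L_hat = L_hat, P_hat = P_hat, A1_hat = A1_hat,
                 A2_bound = A1_hat / params$mu_a + A2_0),
            class = "bound_envelope")
}

#' @export
print.bound_envelope <- function(x, ...) {
  cat(sprintf("LPAA invariant-region envelope:\n  L <= %g, P <= %g, A1 <= %g, A2 <= %g\n",
              x$L_hat, x$P_hat, x$A1_hat, x$A2_bound))
  invisible(x)
}

#' Primitivity index of a nonnegative matrix
#'
#' The smallest positive integer `m` such that `M^m` is entrywise strictly
#' positive, or `NA` if no such power exists up to `m_max` (the matrix is
#' then imprimitive or reducible). Only the zero pattern of `M` matters, so
#' powers are taken over the boolean semiring and cannot overflow. For the
#' inherent projection matrix of the LPAA model the index is 6, which via
#' Perron-Frobenius gives a simple, strictly dominant positive eigenvalue.
#'
#' @param M a square nonnegative numeric matrix.
#' @param m_max maximum power examined. Wielandt's bound `(n-1)^2 + 1`
#'   guarantees that a primitive `n x n` matrix is detected at `m_max >= 10`
#'   for `n = 4`; the default 50 is a safe cap for larger inputs.
#' @return An integer, or `NA_integer_` if no power up to `m_max` is
#'   positive.
#' @examples
#' primitivity_index(projection_matrix(lpaa_medians()))  # 6
#' @export
primitivity_index <- function(M, m_max = 50L) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be a square matrix")
  if (any(M < 0)) stop("M must be nonnegative")
  A <- M > 0
  B <- A
  for (m in seq_len(m_max)) {
    if (all(B)) return(as.integer(m))
    B <- (B %*% A) > 0
  }
  NA_integer_
}
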