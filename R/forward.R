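#' Feng arterial input function
#'
#' Parameters of the standard tri-exponential arterial input model
#' B(t) = (A1 t - A2 - A3) exp(-lambda1 t) + A2 exp(-lambda2 t)
#'      + A3 exp(-lambda3 t), which rises from B(0) = 0 to an early peak and
#' then decays.  Defaults are the values commonly used for FDG-like inputs.
#'
#' @param A1 linear-rise amplitude (activity min^-1).
#' @param A2,A3 exponential amplitudes (activity).
#' @param lambda1,lambda2,lambda3 decay constants (min^-1); expected
#'   `lambda1 > lambda2 > lambda3 > 0`.
#' @return A list of class `"feng_params"`.
#' @examples
#' feng_input(seq(0, 2, by = 0.25), feng_params())
#' @export
feng_params <- function(A1 = 22.24, A2 = 8.36, A3 = 0.10,
                        lambda1 = 21.28, lambda2 = 7.71, lambda3 = 0.37) {
  p <- list(A1 = A1, A2 = A2, A3 = A3,
            lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3)
  if (!all(vapply(p, is.finite, logical(1))))
    stop("feng_params must be finite")
  if (!(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 > 0))
    warning("expected lambda1 > lambda2 > lambda3 > 0")
  structure(p, class = "feng_params")
}

# exponential-polynomial representation of the Feng input
feng_ep <- function(params) {
  ep_terms(coef = c(params$A1, -params$A2 - params$A3, params$A2, params$A3),
           rate = c(-params$lambda1, -params$lambda1,
                    -params$lambda2, -params$lambda3),
           pow = c(1L, 0L, 0L, 0L))
}

#' @rdname feng_params
#' @param t time (min), vectorised; the input is zero for `t < 0`.
#' @param params a [feng_params()] object.
#' @return `feng_input()`: numeric vector of input activities.
#' @export
feng_input <- function(t, params = feng_params()) {
  ep_eval(feng_ep(params), t)
}

# tissue curve as an exponential-polynomial (errors if modes degenerate)
tissue_ep <- function(params, input = feng_params()) {
  m <- poly_to_modes(rates_to_poly(params))
  b <- feng_ep(input)
  ep_combine(ep_scale(ep_convolve_exp(m$s1, b), m$a1),
             ep_scale(ep_convolve_exp(m$s2, b), m$a2))
}

#' Closed-form tissue time-activity curve
#'
#' Evaluates the analytic solution of the two-tissue model driven by a Feng
#' input: C(t) = a1 (exp(s1 t) * B)(t) + a2 (exp(s2 t) * B)(t), where `*` is
#' causal convolution and (s_i, a_i) come from [poly_to_modes()].  The
#' convolution is carried out exactly in exponential-polynomial algebra;
#' near-confluent pole/input-rate pairs switch to the limiting t exp(st)
#' form.
#'
#' @param params a [rate_params()] object in the stable (distinct real
#'   negative poles) regime.
#' @param input a [feng_params()] object.
#' @param times evaluation times (min), `>= 0` (zero returned for t < 0).
#' @return Numeric vector of instantaneous tissue activities.
#' @examples
#' tac_closed_form(rate_params(0.4, 0.3, 0.2, 0.1), feng_params(), c(1, 5, 30))
#' @export
tac_closed_form <- function(params, input = feng_params(), times) {
  ep_eval(tissue_ep(params, input), times)
}

#' Numerically integrate the two-tissue state equations
#'
#' Reference forward model: integrates
#' dC1/dt = -(k2 + k3) C1 + k4 C2 + K1 B(t),  dC2/dt = k3 C1 - k4 C2 with
#' C1(0) = C2(0) = 0 using a stiff solver, and returns C = C1 + C2.  This is
#' the package's independent oracle for [tac_closed_form()] and the fallback
#' forward model when the analytic mode decomposition is degenerate.
#'
#' @param params a [rate_params()] object.
#' @param input_fn function of time (min) returning the blood input.
#' @param times output times (min), nonnegative increasing.
#' @param rtol,atol solver tolerances.
#' @return `data.frame` with columns `time`, `C1`, `C2`, `C`.
#' @export
solve_two_tissue_ode <- function(params, input_fn, times,
                                 rtol = 1e-9, atol = 1e-12) {
  p <- unclass(as_rate_params(params))
  times <- as.numeric(times)
  t0 <- sort(unique(c(0, times)))
  deriv <- function(t, y, parms) {
    B <- input_fn(t)
    list(c(-(p["k2"] + p["k3"]) * y[1] + p["k4"] * y[2] + p["K1"] * B,
           p["k3"] * y[1] - p["k4"] * y[2]))
  }
  sol <- deSolve::ode(y = c(0, 0), times = t0, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1], ")")
  sol <- as.data.frame(sol)
  idx <- match(times, sol$time)
  data.frame(time = times, C1 = sol[[2]][idx], C2 = sol[[3]][idx],
             C = sol[[2]][idx] + sol[[3]][idx])
}
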