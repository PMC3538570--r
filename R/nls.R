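#' Options for the nonlinear least-squares stage
#'
#' @param init initial [rate_params()] (required: the fitter is a local
#'   optimiser and its endpoint depends on the start).
#' @param weights per-frame nonnegative weights (default uniform; pass the
#'   reciprocal noise variances when the noise model is known).
#' @param max_iter iteration cap.
#' @param ftol,ptol relative function / parameter convergence tolerances.
#' @param lower,upper optional length-4 box bounds (default unbounded, so
#'   negative rate estimates are representable; set `lower = rep(0, 4)` for a
#'   nonnegativity-constrained fit).
#' @return A list of class `"fit_options"`.
#' @export
fit_options <- function(init, weights = NULL, max_iter = 200,
                        ftol = 1e-12, ptol = 1e-12,
                        lower = NULL, upper = NULL) {
  init <- as_rate_params(init)
  if (ftol <= 0 || ptol <= 0) stop("tolerances must be > 0")
  if (!is.null(weights)) {
    if (any(!is.finite(weights)) || any(weights < 0) || all(weights == 0))
      stop("weights must be nonnegative with at least one positive entry")
  }
  structure(list(init = init, weights = weights, max_iter = as.integer(max_iter),
                 ftol = ftol, ptol = ptol,
                 lower = if (is.null(lower)) rep(-Inf, 4) else lower,
                 upper = if (is.null(upper)) rep(Inf, 4) else upper),
            class = "fit_options")
}

#' Model-predicted tissue curve on a measurement schedule
#'
#' Noiseless frame-integrated tissue curve for candidate rates.  With a
#' [feng_params()] input the analytic closed form is used (exact
#' exponential-polynomial frame integrals); if the candidate's mode
#' decomposition is degenerate (repeated or complex poles, as can happen
#' mid-optimisation), the prediction falls back to numerical integration of
#' the state equations.
#'
#' @param params candidate [rate_params()] (any real values).
#' @param input a [feng_params()] object.
#' @param schedule a [sampling_schedule()].
#' @return A [tac()] of predicted frame-integrated tissue values.
#' @export
model_predict <- function(params, input = feng_params(),
                          schedule = default_schedule()) {
  params <- as_rate_params(params)
  vals <- tryCatch(
    ep_integrate(tissue_ep(params, input),
                 pmax(0, schedule$frame_ends_min - schedule$window_min),
                 schedule$frame_ends_min),
    error = function(e)
      ode_frame_integrals(params, function(t) feng_input(t, input), schedule))
  tac(schedule$frame_ends_min, vals, kind = "tissue")
}

# frame integrals of the ODE solution: augment the states with the running
# integral of C and difference it at the window edges
ode_frame_integrals <- function(params, input_fn, schedule) {
  p <- unclass(as_rate_params(params))
  hi <- schedule$frame_ends_min
  lo <- pmax(0, hi - schedule$window_min)
  tt <- sort(unique(c(0, lo, hi)))
  deriv <- function(t, y, parms) {
    B <- input_fn(t)
    list(c(-(p["k2"] + p["k3"]) * y[1] + p["k4"] * y[2] + p["K1"] * B,
           p["k3"] * y[1] - p["k4"] * y[2],
           y[1] + y[2]))
  }
  sol <- deSolve::ode(y = c(0, 0, 0), times = tt, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12)
  Fi <- stats::approx(sol[, 1], sol[, 4], xout = c(lo, hi))$y
  n <- length(hi)
  Fi[(n + 1):(2 * n)] - Fi[1:n]
}

# convolution of the bi-exponential impulse response with a measured input
# curve, linearly interpolated through (0,0); used when fitting file data
# where no parametric input model is available (frame averaging commutes
# with the system, so the frame-averaged input maps to the frame-averaged
# tissue curve under the same kernel)
conv_modes_linear <- function(modes, blood, times) {
  knots_t <- c(0, blood$times)
  knots_v <- c(0, blood$values)
  vals <- stats::approx(knots_t, knots_v, xout = times, rule = 2)$y
  one_mode <- function(s) {
    tt <- sort(unique(c(knots_t, times)))
    vv <- stats::approx(knots_t, knots_v, xout = tt, rule = 2)$y
    acc <- numeric(length(tt))
    for (i in seq_along(tt)[-1]) {
      h <- tt[i] - tt[i - 1]
      r <- (vv[i] - vv[i - 1]) / h
      if (abs(s) < 1e-12) {
        seg <- vv[i] * h - r * h^2 / 2
        acc[i] <- acc[i - 1] + seg
      } else {
        esh <- exp(s * h)
        seg <- vv[i] * (esh - 1) / s - r * (esh * (h / s - 1 / s^2) + 1 / s^2)
        acc[i] <- acc[i - 1] * esh + seg
      }
    }
    acc[match(times, tt)]
  }
  modes$a1 * one_mode(modes$s1) + modes$a2 * one_mode(modes$s2)
}

predict_values <- function(params, input, schedule, times) {
  if (inherits(input, "feng_params")) {
    params <- as_rate_params(params)
    tryCatch(
      ep_integrate(tissue_ep(params, input),
                   pmax(0, schedule$frame_ends_min - schedule$window_min),
                   schedule$frame_ends_min),
      error = function(e)
        ode_frame_integrals(params, function(t) feng_input(t, input),
                            schedule))
  } else if (inherits(input, "tac")) {
    modes <- poly_to_modes(rates_to_poly(params))
    conv_modes_linear(modes, input, times)
  } else stop("input must be feng_params or a blood tac")
}

#' Weighted least-squares objective
#'
#' F = sum_i w_i (C_measured(t_i) - C_model(t_i))^2, the discrepancy between
#' the measured tissue curve and the model prediction for candidate rates.
#'
#' @param params candidate [rate_params()].
#' @param measured measured tissue [tac()].
#' @param input a [feng_params()] object, or a blood [tac()] to drive the
#'   model with a measured input.
#' @param schedule a [sampling_schedule()] (used with a parametric input).
#' @param weights per-frame weights (default uniform).
#' @return Numeric scalar `F >= 0`.
#' @export
wls_objective <- function(params, measured, input = feng_params(),
                          schedule = default_schedule(), weights = NULL) {
  stopifnot(inherits(measured, "tac"))
  if (inherits(input, "feng_params") &&
      (length(measured) != length(schedule$frame_ends_min) ||
       max(abs(measured$times - schedule$frame_ends_min)) > 1e-9))
    stop("measured curve does not match the schedule")
  w <- if (is.null(weights)) rep(1, length(measured)) else weights
  if (length(w) != length(measured)) stop("weights length mismatch")
  pred <- predict_values(params, input, schedule, measured$times)
  sum(w * (measured$values - pred)^2)
}

#' Fit the two-tissue model by damped least squares
#'
#' Minimises the weighted least-squares objective over (K1, k2, k3, k4) with
#' a Levenberg-Marquardt optimiser from a user-supplied start.  Unbounded by
#' default (negative endpoints are possible and reported); box bounds are
#' honoured when given in `options`.  Deterministic.
#'
#' @param measured measured tissue [tac()].
#' @param input [feng_params()] or a blood [tac()].
#' @param schedule a [sampling_schedule()] (parametric input only).
#' @param options a [fit_options()] (the initial condition lives here).
#' @return List of class `"fit_result"`: `params`, `objective`, `converged`,
#'   `n_iter`, `init_used`, `message`.
#' @examples
#' ds <- generate_dataset(rate_params(0.4, 0.3, 0.2, 0.1), alpha = 0)
#' nls_fit(ds$tissue, options = fit_options(c(0.45, 0.35, 0.25, 0.15)))
#' @export
nls_fit <- function(measured, input = feng_params(),
                    schedule = default_schedule(), options) {
  stopifnot(inherits(measured, "tac"), inherits(options, "fit_options"))
  w <- if (is.null(options$weights)) rep(1, length(measured)) else options$weights
  sw <- sqrt(w)
  # unstable candidates explored mid-iteration can overflow the forward
  # model; a large finite residual steers the optimiser back without
  # aborting the fit
  resid_fn <- function(theta) {
    pred <- tryCatch(
      predict_values(as_rate_params(theta), input, schedule,
                     measured$times),
      error = function(e) rep(NA_real_, length(measured$times)))
    r <- sw * (measured$values - pred)
    r[!is.finite(r)] <- 1e12
    r
  }
  pred0 <- predict_values(options$init, input, schedule, measured$times)
  if (any(!is.finite(sw * (measured$values - pred0))))
    stop("non-finite objective at the initial condition; check init/weights")
  fit <- minpack.lm::nls.lm(
    par = unclass(options$init), fn = resid_fn,
    lower = options$lower, upper = options$upper,
    control = minpack.lm::nls.lm.control(
      maxiter = options$max_iter, ftol = options$ftol, ptol = options$ptol,
      maxfev = 100 * (options$max_iter + 1)))
  structure(list(params = as_rate_params(fit$par),
                 objective = fit$deviance,
                 converged = fit$info %in% 1:4,
                 n_iter = fit$niter,
                 init_used = options$init,
                 message = fit$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted NLS fit: F = %.4g, %s in %d iterations\n",
              x$objective, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  print(round(unclass(x$params), digits))
  invisible(x)
}

#' Combined closed-form + iterative estimate
#'
#' Two-stage estimator: the closed-form frequency-domain estimate
#' ([fourier_estimate()]) supplies the initial condition, which
#' [nls_fit()] then refines.  This removes the need for a user-chosen start
#' while retaining the low bias of time-domain curve fitting.
#'
#' @param blood,tissue measured [tac()] curves on a shared schedule.
#' @param input [feng_params()] (simulation-style fits) or `NULL` to drive
#'   the model with the measured blood curve.
#' @param schedule a [sampling_schedule()] (parametric input only).
#' @param config an [est_config()] for stage 1.
#' @param weights,max_iter passed to [fit_options()].
#' @return A `"fit_result"`; the stage-1 estimate is in `$init_used` and as
#'   attribute `stage1`.
#' @examples
#' ds <- generate_dataset(rate_params(0.4, 0.3, 0.2, 0.1), alpha = 0)
#' combined_estimate(ds$blood, ds$tissue)
#' @export
combined_estimate <- function(blood, tissue, input = feng_params(),
                              schedule = default_schedule(),
                              config = est_config(), weights = NULL,
                              max_iter = 200) {
  stage1 <- fourier_estimate(blood, tissue, config)
  if (is.null(input)) input <- blood
  res <- nls_fit(tissue, input, schedule,
                 fit_options(stage1, weights = weights, max_iter = max_iter))
  attr(res, "stage1") <- stage1
  res
}
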