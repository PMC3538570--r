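test_that("model prediction reproduces the forward simulator", {
  pred <- model_predict(truth_rates)
  expect_equal(pred$values, ds_noiseless$tissue$values, tolerance = 1e-8)
  zero <- model_predict(rate_params(0, 0.3, 0.2, 0.1))
  expect_equal(zero$values, rep(0, 83))
})

test_that("degenerate candidates fall back to the ODE forward model", {
  # repeated pole: k3 = 0, k2 = k4 makes the discriminant vanish
  deg <- rate_params(0.4, 0.2, 0, 0.2)
  expect_error(poly_to_modes(rates_to_poly(deg)), "degenerate")
  pred <- model_predict(deg)
  sch <- default_schedule()
  direct <- vapply(seq_along(sch$frame_ends_min), function(i) {
    hi <- sch$frame_ends_min[i]; lo <- max(0, hi - 1)
    stats::integrate(function(u) vapply(u, function(ui)
      solve_two_tissue_ode(deg, function(t) feng_input(t), ui)$C,
      numeric(1)), lo, hi, rel.tol = 1e-8)$value
  }, numeric(1))[c(1, 20, 50, 83)]
  expect_equal(pred$values[c(1, 20, 50, 83)], direct, tolerance = 1e-5)
})

test_that("objective is zero at truth, linear in weights, and checkable by hand", {
  expect_lt(wls_objective(truth_rates, ds_noiseless$tissue), 1e-20)
  off <- rate_params(0.5, 0.3, 0.2, 0.1)
  F1 <- wls_objective(off, ds_noiseless$tissue)
  F2 <- wls_objective(off, ds_noiseless$tissue, weights = rep(2, 83))
  expect_equal(F2, 2 * F1)
  # 4-frame toy case, hand arithmetic
  sch <- sampling_schedule(c(60, 120, 180, 240))
  pred <- model_predict(truth_rates, schedule = sch)
  meas <- tac(pred$times, pred$values + c(0.1, -0.2, 0.05, 0))
  w <- c(1, 2, 3, 4)
  expect_equal(wls_objective(truth_rates, meas, schedule = sch, weights = w),
               1 * 0.1^2 + 2 * 0.2^2 + 3 * 0.05^2 + 4 * 0)
  expect_error(wls_objective(truth_rates, meas), "schedule")
})

test_that("fitting from the truth stays at the truth", {
  res <- nls_fit(ds_noiseless$tissue, options = fit_options(truth_rates))
  expect_true(res$converged)
  expect_equal(unclass(res$params), truth_vec, tolerance = 1e-8)
  expect_lt(res$objective, 1e-20)
})

test_that("a good start converges to the truth; objective never increases", {
  opt <- fit_options(c(0.45, 0.35, 0.25, 0.15))
  res <- nls_fit(ds_noiseless$tissue, options = opt)
  expect_true(res$converged)
  expect_equal(unclass(res$params), truth_vec, tolerance = 1e-5)
  expect_lte(res$objective,
             wls_objective(opt$init, ds_noiseless$tissue))
  expect_equal(unclass(res$init_used), unclass(opt$init))
})

test_that("the endpoint depends on the start: a pathological start fails", {
  # a sufficiently bad start leaves the fit at a non-truth point with a
  # positive residual even on noiseless data -- the initial-condition
  # dependence that motivates a closed-form stage 1.  (Which starts fail is
  # optimiser-specific; this damped LM escapes several starts that defeat
  # simpler fitters.)
  res <- suppressWarnings(
    nls_fit(ds_noiseless$tissue,
            options = fit_options(c(0.01, 2, 2, 0.01))))
  expect_gt(res$objective, 1e-6)                      # not the global minimum
  expect_gt(max(abs(unclass(res$params) - truth_vec)), 0.05)
  expect_lte(res$objective,
             wls_objective(rate_params(0.01, 2, 2, 0.01),
                           ds_noiseless$tissue))      # still monotone
})

test_that("box bounds are honoured", {
  res <- nls_fit(ds_noiseless$tissue,
                 options = fit_options(c(0.7, 0.7, 0.7, 0.7),
                                       lower = rep(0, 4)))
  expect_true(all(unclass(res$params) >= 0))
})

test_that("non-finite objective at the start fails fast", {
  # a start whose forward model overflows is rejected before iterating
  expect_error(nls_fit(ds_noiseless$tissue,
                       options = fit_options(c(0.4, -50, 0.2, 0.1))),
               "non-finite objective")
  expect_error(fit_options(c(NaN, 1, 1, 1)), "finite")
})

test_that("combined estimator refines the closed form to the truth", {
  res <- combined_estimate(ds_noiseless$blood, ds_noiseless$tissue)
  expect_lt(max(abs(unclass(res$params) - truth_vec)), 0.005)
  # the Fourier stage supplied the start
  expect_equal(unclass(res$init_used), unclass(attr(res, "stage1")))
  # idempotence: a second refinement stays put
  res2 <- nls_fit(ds_noiseless$tissue, options = fit_options(res$params))
  expect_lt(max(abs(unclass(res2$params) - unclass(res$params))), 1e-6)
})

test_that("empirical-input fitting drives the model with the measured blood curve", {
  res <- nls_fit(ds_noiseless$tissue, input = ds_noiseless$blood,
                 options = fit_options(c(0.45, 0.35, 0.25, 0.15)))
  expect_true(res$converged)
  expect_lt(max(abs(unclass(res$params) - truth_vec)), 0.01)
})

test_that("noisy-data recovery from a good start is accurate on average", {
  clean <- ds_noiseless$tissue
  errs <- vapply(1:20, function(s) {
    noisy <- add_noise(clean, 0.1, seed = s)
    r <- nls_fit(noisy, options = fit_options(c(0.45, 0.35, 0.25, 0.15)))
    abs(unclass(r$params) - truth_vec)
  }, numeric(4))
  expect_true(all(rowMeans(errs) < 0.05))
})
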