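test_that("tail anchor is the mean of the last frames", {
  x <- tac(1:5, c(9, 9, 2, 3, 4))
  expect_equal(tail_anchor(x, 3), 3)
  expect_equal(tail_anchor(x, 1), 4)
  expect_error(tail_anchor(x, 0), "between")
  expect_error(tail_anchor(x, 6), "between")
  ds <- ds_noiseless
  expect_equal(tail_anchor(ds$tissue, 3), mean(ds$tissue$values[81:83]))
})

test_that("tail extrapolation follows the exponential-mixture decay", {
  ds <- ds_noiseless
  cfg <- est_config()
  ext <- extrapolate_tail(ds$tissue, cfg)
  n_meas <- length(ds$tissue)
  expect_identical(ext$values[1:n_meas], ds$tissue$values)  # measured unchanged
  anchor <- tail_anchor(ds$tissue, 3)
  t_end <- max(ds$tissue$times)
  # continuity: first appended point one resampling step past t_end
  first <- ext$values[n_meas + 1]
  expect_equal(first, anchor * mean(exp(-cfg$tail_rates * 5 / 60)),
               tolerance = 1e-12)
  expect_lt(first, anchor)
  # direct series evaluation at a 30-minute lag
  i30 <- which(abs(ext$times - (t_end + 30)) < 1e-9)
  expect_equal(ext$values[i30], anchor * mean(exp(-cfg$tail_rates * 30)),
               tolerance = 1e-12)
  # tail strictly decreasing
  expect_true(all(diff(ext$values[(n_meas + 1):length(ext$times)]) < 0))
  expect_warning(extrapolate_tail(ds$tissue, est_config(horizon_s = 3000)),
                 "horizon")
})

test_that("uniform resampling interpolates linearly on the target grid", {
  cfg <- est_config()
  u <- resample_uniform(extrapolate_tail(ds_noiseless$tissue, cfg), cfg)
  expect_equal(u$n, 1441)
  expect_identical(u$values[1], 0)
  # fixed points: a curve already on the grid is returned unchanged
  grid <- seq(5, 7200, by = 5) / 60
  vals <- exp(-grid)
  u2 <- resample_uniform(tac(grid, vals), cfg)
  expect_equal(u2$values, c(0, vals), tolerance = 1e-12)
  # midpoint of two samples is their mean
  x <- tac(c(1, 2), c(2, 6))
  cfg2 <- est_config(resample_s = 90, horizon_s = 180)
  expect_equal(resample_uniform(x, cfg2)$values, c(0, 4, 0))
})

test_that("low-frequency spectra match naive summation and the DC gain", {
  cfg <- est_config()
  ds <- ds_noiseless
  bu <- resample_uniform(extrapolate_tail(ds$blood, cfg), cfg)
  cu <- resample_uniform(extrapolate_tail(ds$tissue, cfg), cfg)
  sp <- spectral_transform(bu, cu, cfg)
  # k = 0 derived terms vanish exactly
  expect_identical(sp$g[1], 0 + 0i)
  expect_identical(sp$d[1], 0 + 0i)
  expect_identical(sp$e[1], 0 + 0i)
  expect_identical(sp$f[1], 0 + 0i)
  # enforced DC gain is close to the true VD = 4
  expect_equal(sp$c0 / sp$b0, 4.0, tolerance = 0.1 / 4)
  # naive-DFT oracle at k = 1
  Tm <- bu$interval; N <- bu$n
  n <- 0:(N - 1)
  naive <- sum(bu$values * exp(-1i * 2 * pi * n / N)) * Tm
  expect_equal(sp$b[2], naive, tolerance = 1e-10)
  expect_equal(sp$fundamental, 2 * pi / (N * Tm))
})

test_that("normal equations form a symmetric PSD system; k = 0 is inert", {
  cfg <- est_config()
  ds <- ds_noiseless
  sp <- spectral_transform(resample_uniform(extrapolate_tail(ds$blood, cfg), cfg),
                           resample_uniform(extrapolate_tail(ds$tissue, cfg), cfg),
                           cfg)
  ne <- build_normal_equations(sp)
  expect_lt(max(abs(ne$A - t(ne$A))), 1e-12 * max(abs(ne$A)))
  expect_gt(min(eigen(ne$A, symmetric = TRUE)$values), -1e-10)
  # dropping the k = 0 terms changes nothing
  sp0 <- sp
  for (f in c("b", "c", "d", "e", "f", "g", "omega"))
    sp0[[f]] <- sp0[[f]][-1]
  ne0 <- build_normal_equations(sp0)
  expect_equal(ne$A, ne0$A)
  expect_equal(ne$P, ne0$P)
})

test_that("coefficient solve is stable and guarded", {
  ne <- structure(list(A = diag(3), P = c(1, 2, 3)),
                  class = "normal_equations")
  expect_equal(solve_coefficients(ne), c(1, 2, 3))
  cfg <- est_config()
  ds <- ds_noiseless
  sp <- spectral_transform(resample_uniform(extrapolate_tail(ds$blood, cfg), cfg),
                           resample_uniform(extrapolate_tail(ds$tissue, cfg), cfg),
                           cfg)
  ne2 <- build_normal_equations(sp)
  x <- solve_coefficients(ne2)
  expect_lt(sqrt(sum((ne2$A %*% x - ne2$P)^2)), 1e-10 * sqrt(sum(ne2$P^2)))
  bad <- structure(list(A = diag(c(1, 1e-15, 1)), P = c(1, 1, 1)),
                   class = "normal_equations")
  expect_error(solve_coefficients(bad), "condition number")
})

test_that("rate recovery inverts the coefficient map under the DC constraint", {
  r <- recover_rates(c(0.4, 0.12, -0.6), b0 = 1, c0 = 4)
  expect_equal(unclass(r), truth_vec, tolerance = 1e-12)
  # one-compartment collapse: x2 = 0 forces k4 = 0
  r0 <- recover_rates(c(0.4, 0, -0.6), b0 = 1, c0 = 4)
  expect_equal(unname(r0["k4"]), 0)
  expect_equal(unname(r0["k2"]), 0.6)
  expect_equal(unname(r0["k3"]), 0)
  expect_error(recover_rates(c(0, 0.1, -0.6), 1, 4), "x1")
})

test_that("full pipeline is deterministic, scale invariant, and near-unbiased", {
  ds <- ds_noiseless
  e1 <- fourier_estimate(ds$blood, ds$tissue)
  e2 <- fourier_estimate(ds$blood, ds$tissue)
  expect_identical(unclass(e1), unclass(e2))
  # common rescaling of both curves leaves the estimate unchanged
  scale7 <- function(x) tac(x$times, 7 * x$values, x$kind)
  e7 <- fourier_estimate(scale7(ds$blood), scale7(ds$tissue))
  expect_equal(unclass(e7), unclass(e1), tolerance = 1e-12)
  # noiseless default protocol lands near the truth
  expect_lt(max(abs(unclass(e1) - truth_vec)), 0.02)
  # DC fidelity: VD of the estimate equals the enforced gain exactly
  expect_equal(unname(macro_params(e1)["vd"]), attr(e1, "vd"),
               tolerance = 1e-12)
  expect_error(fourier_estimate(ds$blood, tac(1:5, 1:5)), "schedule")
})

test_that("estimates converge to truth as sampling and resampling refine", {
  errs <- vapply(c(5, 2, 1), function(Ts) {
    tt <- seq(Ts, 36000, by = Ts) / 60
    bt <- tac(tt, feng_input(tt), "blood")
    ct <- tac(tt, tac_closed_form(truth_rates, times = tt), "tissue")
    e <- suppressWarnings(fourier_estimate(
      bt, ct, est_config(resample_s = Ts, horizon_s = 36000)))
    max(abs(unclass(e) - truth_vec))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))    # monotone shrinking error
  expect_lt(errs[3], 0.01)            # dense-limit recovery
})

test_that("window integration commutes with the estimator", {
  sch <- sampling_schedule(seq(1, 3650, by = 1), window_s = 60)
  ds <- generate_dataset(truth_rates, schedule = sch, alpha = 0)
  cfg <- est_config(resample_s = 1)
  e_int <- fourier_estimate(ds$blood, ds$tissue, cfg)
  tt <- sch$frame_ends_min
  e_inst <- fourier_estimate(tac(tt, feng_input(tt), "blood"),
                             tac(tt, tac_closed_form(truth_rates, times = tt),
                                 "tissue"), cfg)
  expect_lt(max(abs(unclass(e_int) - unclass(e_inst))), 0.01)
})
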