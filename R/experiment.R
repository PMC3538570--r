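#' Monte-Carlo experiment specification
#'
#' Describes a grid of simulation experiments: for every combination of
#' noise level and cutoff index, `n_realizations` noisy datasets are
#' generated (seeds `base_seed + realization index`) and the chosen
#' estimator is run on each.
#'
#' @param truth ground-truth [rate_params()].
#' @param alphas noise scales to sweep.
#' @param n_realizations realizations per cell (1 suffices when `alpha = 0`:
#'   the data are then deterministic).
#' @param cutoffs cutoff indices k_c to sweep.
#' @param base_seed integer; realization i uses seed `base_seed + i - 1`.
#' @param estimator `"fourier"`, `"nls"` or `"combined"`.
#' @param nls_init initial [rate_params()] for the pure-NLS arm.
#' @param input a [feng_params()] object.
#' @param schedule a [sampling_schedule()].
#' @param config an [est_config()] (its cutoff is overridden by `cutoffs`).
#' @param half_life isotope half-life (min) for the noise model.
#' @return A list of class `"experiment_spec"`.
#' @export
experiment_spec <- function(truth, alphas = 0, n_realizations = 250,
                            cutoffs = 10, base_seed = 1,
                            estimator = c("fourier", "nls", "combined"),
                            nls_init = NULL, input = feng_params(),
                            schedule = default_schedule(),
                            config = est_config(), half_life = 110) {
  estimator <- match.arg(estimator)
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  if (estimator == "nls" && is.null(nls_init))
    stop("the pure-NLS arm needs an explicit nls_init")
  structure(list(truth = as_rate_params(truth), alphas = alphas,
                 n_realizations = as.integer(n_realizations),
                 cutoffs = as.integer(cutoffs),
                 base_seed = as.integer(base_seed), estimator = estimator,
                 nls_init = if (is.null(nls_init)) NULL
                            else as_rate_params(nls_init),
                 input = input, schedule = schedule, config = config,
                 half_life = half_life),
            class = "experiment_spec")
}

single_estimate <- function(est, blood, tissue, spec, config) {
  switch(est,
         fourier = as_rate_params(fourier_estimate(blood, tissue, config)),
         nls = nls_fit(tissue, spec$input, spec$schedule,
                       fit_options(spec$nls_init))$params,
         combined = combined_estimate(blood, tissue, spec$input,
                                      spec$schedule, config)$params)
}

#' Run a Monte-Carlo estimator experiment
#'
#' Generates the noiseless curves once, then for every (alpha, cutoff) cell
#' draws seeded noise realizations, runs the estimator, and aggregates the
#' mean and SD of each rate constant and macro-parameter.  Realizations
#' where the estimator fails (or where a macro-parameter is undefined) are
#' excluded from the moments and counted in `n_fail`; a warning reports the
#' exclusions, and a cell where every realization fails is marked invalid
#' (`NA` moments).  Rerunning with the same `base_seed` is bit-reproducible.
#'
#' @param spec an [experiment_spec()].
#' @return A `data.frame` (one row per cell, plus a leading `"true"` row
#'   carrying the ground-truth values) with per-parameter `_mean` and `_sd`
#'   columns; the raw per-realization estimates are in attribute `"raw"`.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  noiseless <- generate_dataset(spec$truth, spec$input, spec$schedule,
                                alpha = 0)
  pars <- c("K1", "k2", "k3", "k4")
  macros <- c("vd", "bp", "k3k4_ratio")
  truth_macro <- macro_params(spec$truth)
  rows <- list(); raw <- list()
  mk_row <- function(case, alpha, cutoff, mat, n_fail) {
    out <- data.frame(case = case, alpha = alpha, cutoff = cutoff,
                      n_ok = nrow(mat), n_fail = n_fail)
    for (p in colnames(mat)) {
      out[[paste0(p, "_mean")]] <- if (nrow(mat)) mean(mat[, p]) else NA_real_
      out[[paste0(p, "_sd")]] <- if (nrow(mat) > 1) stats::sd(mat[, p]) else NA_real_
    }
    out
  }
  truth_mat <- matrix(c(unclass(spec$truth), truth_macro[macros]), nrow = 1,
                      dimnames = list(NULL, c(pars, macros)))
  rows[[1]] <- mk_row("true", NA_real_, NA_integer_, truth_mat, 0L)
  rows[[1]][paste0(c(pars, macros), "_sd")] <- NA_real_
  for (alpha in spec$alphas) for (kc in spec$cutoffs) {
    config <- spec$config
    config$cutoff <- as.integer(kc)
    n <- if (alpha == 0) 1L else spec$n_realizations
    ests <- vector("list", n)
    n_fail <- 0L
    for (i in seq_len(n)) {
      tissue_i <- if (alpha == 0) noiseless$tissue else
        add_noise(noiseless$tissue, alpha, half_life = spec$half_life,
                  window_s = spec$schedule$window_s,
                  seed = spec$base_seed + i - 1L)
      est <- tryCatch({
        r <- single_estimate(spec$estimator, noiseless$blood, tissue_i,
                             spec, config)
        m <- macro_params(r)
        c(unclass(r), m[macros])
      }, error = function(e) NULL)
      if (is.null(est)) n_fail <- n_fail + 1L else ests[[i]] <- est
    }
    mat <- do.call(rbind, ests[!vapply(ests, is.null, logical(1))])
    if (is.null(mat))
      mat <- matrix(numeric(0), 0, 7, dimnames = list(NULL, c(pars, macros)))
    colnames(mat) <- c(pars, macros)
    if (n_fail > 0)
      warning(sprintf("alpha=%g kc=%d: %d of %d realizations failed and were excluded",
                      alpha, kc, n_fail, n))
    key <- sprintf("a%g_k%d", alpha, kc)
    raw[[key]] <- mat
    rows[[length(rows) + 1]] <- mk_row(spec$estimator, alpha, kc, mat, n_fail)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "raw") <- raw
  out
}

#' Round a summary table for display
#'
#' Two-decimal presentation of a [run_experiment()] table (the returned
#' full-precision table is unchanged).
#'
#' @param summary a [run_experiment()] result.
#' @return A `data.frame` with numeric columns rounded to 2 decimals.
#' @export
format_summary <- function(summary) {
  num <- vapply(summary, is.numeric, logical(1))
  summary[num] <- lapply(summary[num], round, digits = 2)
  summary
}
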