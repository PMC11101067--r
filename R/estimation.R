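#' The uncertain-parameter space of the chain model
#'
#' Ten chain parameters cannot be measured directly: impactor stiffness,
#' impactor tip (contact) stiffness and damping, the hard-stop transition
#' depth, both friction coefficients, the two normal-force coefficients,
#' the stem stiffness and the tissue damping. Sensitivity screening rated
#' the transition depth, the normal-force constant and the tissue damping
#' as weakly influential, so they carry broadly estimated fixed values
#' (50 um, 5 N, 10\% of the tissue spring stiffness) and the remaining
#' seven are free for optimization.
#'
#' Ranges are centred on the fitted reference values and span a factor of
#' four in each direction for the scale-type parameters (stiffnesses,
#' damping, quadratic normal-force factor) and a physically plausible
#' interval for the friction coefficients.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`, `default`,
#'   `free` (logical: optimized rather than fixed) and `log_scale`
#'   (logical: optimized on a log axis).
#' @examples
#' parameter_space()
#' @export
parameter_space <- function() {
  tibble::tibble(
    parameter = c("impactor_stiffness", "contact_stiffness",
                  "contact_damping", "contact_transition",
                  "mu_static", "mu_kinetic",
                  "normal_force_const", "normal_force_quad",
                  "stem_stiffness", "tissue_damping"),
    default = c(85e6, 13e6, 240e3, 50e-6, 0.79, 0.49, 5, 140e9, 130e6, 400),
    lower = c(85e6 / 4, 13e6 / 4, 240e3 / 4, 12.5e-6, 0.30, 0.10,
              1.25, 35e9, 130e6 / 4, 100),
    upper = c(85e6 * 4, 13e6 * 4, 240e3 * 4, 200e-6, 1.20, 0.90,
              20, 560e9, 130e6 * 4, 1600),
    free = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    log_scale = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE,
                  TRUE)
  )
}

sample_space <- function(space, n) {
  draws <- purrr::map(seq_len(nrow(space)), function(i) {
    stats::runif(n, space$lower[i], space$upper[i])
  })
  names(draws) <- space$parameter
  df <- tibble::as_tibble(draws)
  # physical constraint: kinetic friction never exceeds static friction
  if (all(c("mu_static", "mu_kinetic") %in% names(df))) {
    df$mu_kinetic <- pmin(df$mu_kinetic, df$mu_static)
  }
  df
}

space_overrides <- function(values) {
  values[intersect(names(values), names(chain_defaults()))]
}

#' Rank parameters by absolute Spearman correlation with responses
#'
#' The correlation backbone of [sensitivity_mc()], exposed so that ranking
#' behaviour can be examined on arbitrary sample/response tables.
#'
#' @param samples Data frame of sampled parameter values (one column per
#'   parameter).
#' @param responses Data frame of scalar responses (one column per
#'   response), same number of rows.
#' @return A tibble with `parameter`, one `|rho|` column per response,
#'   `max_abs_rho`, sorted by decreasing `max_abs_rho`.
#' @export
spearman_ranking <- function(samples, responses) {
  stopifnot(nrow(samples) == nrow(responses))
  rho <- abs(stats::cor(samples, responses, method = "spearman"))
  out <- tibble::as_tibble(rho, rownames = "parameter")
  out$max_abs_rho <- apply(rho, 1, max)
  dplyr::arrange(out, dplyr::desc(.data$max_abs_rho))
}

#' Monte-Carlo sensitivity screening of the chain parameters
#'
#' Samples parameter vectors uniformly over their declared ranges, simulates
#' each, reduces every run to scalar responses (normalized impactor and stem
#' peaks, and windowed RMSE of each PoM trace against the nominal run) and
#' ranks the parameters by the largest absolute Spearman rank correlation
#' across responses. Failed simulations are dropped; more than 20\% failures
#' abort the analysis.
#'
#' @param space A [parameter_space()]-shaped tibble; parameters whose name
#'   is not a chain parameter are sampled but do not enter the dynamics
#'   (useful as null references).
#' @param chain Baseline [chain_config()].
#' @param pulse Mallet [force_pulse()] driving every run.
#' @param n_samples Number of Monte-Carlo samples (>= 50).
#' @param seed Integer seed; fixed seed gives an identical ranking.
#' @return The [spearman_ranking()] tibble, with attributes `n_failed` and
#'   `samples` (the sampled design with its responses).
#' @export
sensitivity_mc <- function(space = parameter_space(), chain = chain_config(),
                           pulse = pulse_half_sine(), n_samples = 200,
                           seed = 1) {
  if (n_samples < 50) {
    stop("sensitivity screening needs at least 50 samples", call. = FALSE)
  }
  peak <- pulse_attr(pulse, "peak_force")
  nominal <- simulate_chain(chain, pulse)
  nom_imp <- nominal$data$force_impactor / peak
  nom_stem <- nominal$data$force_stem / peak

  samples <- withr::with_seed(seed, sample_space(space, n_samples))
  one_run <- function(values) {
    cfg <- chain_config(utils::modifyList(unclass(chain),
                                          space_overrides(values)))
    sim <- simulate_chain(cfg, pulse)
    c(peak_impactor = max(sim$data$force_impactor) / peak,
      peak_stem = max(sim$data$force_stem) / peak,
      rmse_impactor = rmse_window(sim$data$force_impactor / peak, nom_imp),
      rmse_stem = rmse_window(sim$data$force_stem / peak, nom_stem))
  }
  res <- purrr::map(seq_len(n_samples), function(i) {
    tryCatch(one_run(as.list(samples[i, ])), error = function(e) NULL)
  })
  ok <- !purrr::map_lgl(res, is.null)
  if (mean(!ok) > 0.2) {
    stop("more than 20% of sensitivity samples failed to simulate",
         call. = FALSE)
  }
  if (any(!ok)) {
    message(sum(!ok), " sensitivity sample(s) failed and were dropped")
  }
  responses <- dplyr::bind_rows(purrr::map(res[ok], as.list))
  ranking <- spearman_ranking(samples[ok, ], responses)
  attr(ranking, "n_failed") <- sum(!ok)
  attr(ranking, "samples") <- dplyr::bind_cols(samples[ok, ], responses)
  ranking
}

#' Generate pseudo-measured force datasets from known parameters
#'
#' Stand-in for in vitro recordings: simulates the chain with known
#' parameter values, adds white Gaussian sensor noise (scaled to the mallet
#' peak), applies the per-PoM zero-phase low-pass filters (10 kHz impactor,
#' 15 kHz stem) and normalizes to the mallet peak.
#'
#' @param chain Baseline [chain_config()].
#' @param true_params Named list of chain-parameter overrides acting as the
#'   generating truth.
#' @param pulses List of mallet [force_pulse()]s, one per dataset.
#' @param noise_sd Noise standard deviation as a fraction of the mallet
#'   peak (>= 0).
#' @param seed Optional integer seed for the noise.
#' @param cutoff_impactor,cutoff_stem Filter cut-offs in Hz.
#' @return A tibble with one row per dataset: `id`, list-columns `pulse`,
#'   `impactor` and `stem` (normalized filtered traces on the simulation
#'   grid).
#' @export
make_pseudo_measurements <- function(chain = chain_config(),
                                     true_params = list(),
                                     pulses = list(pulse_half_sine()),
                                     noise_sd = 0, seed = NULL,
                                     cutoff_impactor = 10e3,
                                     cutoff_stem = 15e3) {
  stopifnot(noise_sd >= 0)
  cfg <- chain_config(utils::modifyList(unclass(chain),
                                        space_overrides(true_params)))
  gen <- function() {
    purrr::imap(pulses, function(pulse, i) {
      sim <- simulate_chain(cfg, pulse)
      fs <- sim$sample_rate
      peak <- pulse_attr(pulse, "peak_force")
      n <- nrow(sim$data)
      imp <- sim$data$force_impactor + stats::rnorm(n, 0, noise_sd * peak)
      stm <- sim$data$force_stem + stats::rnorm(n, 0, noise_sd * peak)
      tibble::tibble(
        id = i,
        pulse = list(pulse),
        impactor = list(lowpass_zerophase(imp, fs, cutoff_impactor) / peak),
        stem = list(lowpass_zerophase(stm, fs, cutoff_stem) / peak)
      )
    }) |> dplyr::bind_rows()
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Fit the free chain parameters to measured force traces
#'
#' Minimizes the summed squared error between simulated and measured
#' normalized forces at both PoMs over all datasets, evaluated on the RMSE
#' window of each measured trace (zero crossing before the first to zero
#' crossing after the second positive peak). Simulated traces are passed
#' through the same per-PoM zero-phase filters as the measurements before
#' comparison. Optimization uses bounded Levenberg-Marquardt least squares
#' on the windowed residual vector (log axes for scale-type parameters),
#' restarted from `n_starts` points; the best run is returned.
#'
#' @param datasets A tibble as returned by [make_pseudo_measurements()]
#'   (list-columns `pulse`, `impactor`, `stem`).
#' @param space A [parameter_space()] tibble; rows with `free = TRUE` are
#'   optimized, the rest stay at the baseline chain's values.
#' @param chain Baseline [chain_config()] supplying every non-optimized
#'   parameter.
#' @param n_starts Number of optimizer starts (first start: `space`
#'   defaults; later starts drawn uniformly in range).
#' @param seed Seed for the extra starts.
#' @param maxiter Maximum Levenberg-Marquardt iterations per pass.
#' @param refine Names of weakly identified parameters given an extra 1-D
#'   profile-refinement pass (grid search over their range at the incumbent
#'   solution, then re-polish); defaults to the hard-stop pair, whose
#'   sensitivity is small because the printed tip damping keeps the contact
#'   force damping-dominated.
#' @param cutoff_impactor,cutoff_stem Filter cut-offs in Hz applied to the
#'   simulated traces (match the measurement conditioning).
#' @return An object of class `impact_fit`; see [tidy.impact_fit()] and
#'   [glance.impact_fit()].
#' @export
fit_parameters <- function(datasets, space = parameter_space(),
                           chain = chain_config(), n_starts = 3, seed = 1,
                           maxiter = 50,
                           refine = c("contact_stiffness",
                                      "contact_damping"),
                           cutoff_impactor = 10e3, cutoff_stem = 15e3) {
  stopifnot(nrow(datasets) >= 1)
  free <- space[space$free, ]
  sample_rate <- 1 / diff(datasets$pulse[[1]]$time[1:2])

  prep <- purrr::map(seq_len(nrow(datasets)), function(i) {
    list(
      pulse = datasets$pulse[[i]],
      peak = pulse_attr(datasets$pulse[[i]], "peak_force"),
      imp = datasets$impactor[[i]],
      stem = datasets$stem[[i]],
      w_imp = rmse_window_indices(datasets$impactor[[i]]),
      w_stem = rmse_window_indices(datasets$stem[[i]])
    )
  })
  duration <- (length(prep[[1]]$imp) - 1) / sample_rate

  to_opt <- function(v) ifelse(free$log_scale, log(v), v)
  from_opt <- function(th) ifelse(free$log_scale, exp(th), th)

  sim_traces <- function(values) {
    cfg <- chain_config(utils::modifyList(unclass(chain),
                                          space_overrides(values)))
    purrr::map(prep, function(d) {
      sim <- simulate_chain(cfg, d$pulse, duration = duration,
                            sample_rate = sample_rate)
      list(imp = lowpass_zerophase(sim$data$force_impactor, sample_rate,
                                   cutoff_impactor) / d$peak,
           stem = lowpass_zerophase(sim$data$force_stem, sample_rate,
                                    cutoff_stem) / d$peak)
    })
  }

  residual_fn <- function(th) {
    values <- as.list(stats::setNames(from_opt(th), free$parameter))
    if (!is.null(values$mu_kinetic) && !is.null(values$mu_static)) {
      values$mu_kinetic <- min(values$mu_kinetic, values$mu_static)
    }
    tr <- tryCatch(sim_traces(values), error = function(e) NULL)
    if (is.null(tr)) {
      return(rep(1e3, sum(purrr::map_int(
        prep, ~ length(.x$w_imp) + length(.x$w_stem)))))
    }
    unlist(purrr::map2(tr, prep, function(s, d) {
      c(s$imp[d$w_imp] - d$imp[d$w_imp], s$stem[d$w_stem] - d$stem[d$w_stem])
    }))
  }

  lm_pass <- function(th0) {
    minpack.lm::nls.lm(
      par = th0, lower = to_opt(free$lower), upper = to_opt(free$upper),
      fn = residual_fn,
      # the trust region starts small (factor) because the weakly
      # identified directions otherwise overshoot to their bounds, and the
      # forward-difference step (epsfcn) must clear the ODE-solver noise
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-15,
                                           ptol = 1e-13, epsfcn = 1e-8,
                                           factor = 0.1)
    )
  }
  weak <- which(free$parameter %in% refine)
  strong <- setdiff(seq_len(nrow(free)), weak)
  lm_subset <- function(th0, idx) {
    # LM restricted to a parameter subset; used to pin the well-identified
    # directions while the near-flat, noise-corrupted Jacobian columns of
    # the weak ones stay frozen (they otherwise drag the whole fit into
    # compensated basins)
    r <- minpack.lm::nls.lm(
      par = th0[idx], lower = to_opt(free$lower)[idx],
      upper = to_opt(free$upper)[idx],
      fn = function(ths) {
        th <- th0
        th[idx] <- ths
        residual_fn(th)
      },
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-15,
                                           ptol = 1e-13, epsfcn = 1e-8,
                                           factor = 0.1)
    )
    th0[idx] <- r$par
    th0
  }
  profile_weak <- function(th) {
    # two-level 1-D grid profile of each weak parameter over its range
    for (j in weak) {
      grid <- seq(to_opt(free$lower)[j], to_opt(free$upper)[j],
                  length.out = 11)
      sse <- purrr::map_dbl(grid, function(v) {
        t2 <- th
        t2[j] <- v
        sum(residual_fn(t2)^2)
      })
      best <- grid[which.min(sse)]
      step <- grid[2] - grid[1]
      fine <- seq(max(to_opt(free$lower)[j], best - step),
                  min(to_opt(free$upper)[j], best + step), length.out = 9)
      sse2 <- purrr::map_dbl(fine, function(v) {
        t2 <- th
        t2[j] <- v
        sum(residual_fn(t2)^2)
      })
      th[j] <- fine[which.min(sse2)]
    }
    th
  }
  one_start <- function(th0) {
    th <- th0
    if (length(weak) && length(strong)) {
      # alternate well-conditioned sub-problems before the joint polish
      for (cycle in 1:3) {
        th <- lm_subset(th, strong)
        th <- profile_weak(th)
      }
    }
    lm_pass(th) # joint polish over all free parameters
  }

  th_default <- to_opt(free$default)
  starts <- c(list(th_default),
              withr::with_seed(seed, purrr::map(
                seq_len(max(0, n_starts - 1)),
                # jittered restarts (~10% on the working axes): the rugged,
                # near-degenerate objective makes the descent path chaotic,
                # so the best of several perturbed descents is kept
                ~ pmin(pmax(th_default + stats::rnorm(nrow(free), 0, 0.1),
                            to_opt(free$lower)), to_opt(free$upper)))))
  runs <- purrr::map(starts, one_start)
  dev <- purrr::map_dbl(runs, "deviance")
  best <- runs[[which.min(dev)]]
  if (best$info == 0 || best$info == 9) {
    warning("optimizer did not converge (info = ", best$info,
            "); returning best-so-far parameters", call. = FALSE)
  }
  est <- from_opt(best$par)

  # diagnostics at the fitted point
  values <- as.list(stats::setNames(est, free$parameter))
  tr <- sim_traces(values)
  diag <- purrr::imap(tr, function(s, i) {
    d <- prep[[i]]
    off <- function(sim, meas) {
      (find_positive_peaks(sim)[1] - find_positive_peaks(meas)[1]) /
        sample_rate
    }
    tibble::tibble(
      dataset = i, pom = c("impactor", "stem"),
      rmse = c(rmse_window(s$imp, d$imp), rmse_window(s$stem, d$stem)),
      peak_time_offset = c(off(s$imp, d$imp), off(s$stem, d$stem))
    )
  }) |> dplyr::bind_rows()

  structure(list(
    par = tibble::tibble(
      parameter = free$parameter, estimate = est,
      start = from_opt(starts[[which.min(dev)]]),
      lower = free$lower, upper = free$upper, log_scale = free$log_scale
    ),
    chain = chain_config(utils::modifyList(unclass(chain),
                                           space_overrides(values))),
    diagnostics = diag,
    sse = best$deviance,
    sse_trace = purrr::map(runs, "rsstrace"),
    niter = best$niter,
    info = best$info,
    n_datasets = nrow(datasets)
  ), class = "impact_fit")
}

#' @export
print.impact_fit <- function(x, ...) {
  cat("<impact_fit> ", nrow(x$par), " free parameters, ",
      x$n_datasets, " dataset(s), SSE = ", format(x$sse, digits = 5),
      "\n", sep = "")
  print(tidy(x), n = nrow(x$par))
  invisible(x)
}

#' Tidy the fitted parameters
#' @param x An `impact_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fitted parameter (`parameter`,
#'   `estimate`, `start`, `lower`, `upper`, `log_scale`).
#' @export
tidy.impact_fit <- function(x, ...) x$par

#' One-row fit summary
#' @param x An `impact_fit`.
#' @param ... Unused.
#' @return Tibble with the SSE, the median per-PoM RMSEs (percent of mallet
#'   peak), iteration count and convergence code.
#' @export
glance.impact_fit <- function(x, ...) {
  med <- function(pom) {
    stats::median(x$diagnostics$rmse[x$diagnostics$pom == pom])
  }
  tibble::tibble(
    sse = x$sse,
    median_rmse_impactor = med("impactor"),
    median_rmse_stem = med("stem"),
    n_datasets = x$n_datasets,
    niter = x$niter,
    converged = !(x$info %in% c(0, 9))
  )
}

#' Write a fit report
#'
#' Serializes an [fit_parameters()] result as a human-readable text report
#' plus a CSV of per-dataset RMSEs and peak-time offsets.
#'
#' @param fit An `impact_fit`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fit_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(fit$diagnostics, file.path(dir, "fit_rmse.csv"))
  con <- file(file.path(dir, "fit_report.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    "impactchain parameter fit",
    sprintf("datasets: %d    SSE: %.6g    iterations: %d", fit$n_datasets,
            fit$sse, fit$niter),
    "",
    utils::capture.output(as.data.frame(fit$par)),
    "",
    utils::capture.output(as.data.frame(fit$diagnostics))
  ), con)
  invisible(dir)
}

#' Screen out datasets with atypical oscillatory behaviour
#'
#' Optional outlier screen mirroring the exclusion of recordings with
#' distinctly different oscillation: a dataset is dropped when the dominant
#' frequency of its impactor trace deviates by more than `threshold`
#' (relative) from the group median.
#'
#' @param datasets A dataset tibble (see [make_pseudo_measurements()]).
#' @param sample_rate Sampling frequency in Hz.
#' @param threshold Relative deviation limit (default 25\%).
#' @return The retained rows, with attribute `excluded` holding the dropped
#'   `id`s.
#' @export
screen_datasets <- function(datasets, sample_rate = 800e3,
                            threshold = 0.25) {
  f <- purrr::map_dbl(datasets$impactor, dominant_frequency,
                      sample_rate = sample_rate)
  keep <- abs(f - stats::median(f)) <= threshold * stats::median(f)
  out <- datasets[keep, ]
  attr(out, "excluded") <- datasets$id[!keep]
  out
}
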