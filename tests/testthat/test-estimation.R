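test_that("the uncertain-parameter space matches the screening outcome", {
  sp <- parameter_space()
  expect_equal(nrow(sp), 10)
  expect_true(all(sp$upper > sp$lower))
  expect_true(all(sp$default >= sp$lower & sp$default <= sp$upper))
  expect_equal(sum(sp$free), 7)
  expect_setequal(sp$parameter[!sp$free],
                  c("contact_transition", "normal_force_const",
                    "tissue_damping"))
})

test_that("rank correlation separates informative from null parameters", {
  n <- 500
  smp <- withr::with_seed(1, data.frame(
    strong = runif(n, 1, 2),
    dummy = runif(n, 1, 2)
  ))
  resp <- withr::with_seed(2, data.frame(
    # monotone (affine) map of one parameter, plus an independent response
    y = 3 * smp$strong - 1,
    z = rnorm(n)
  ))
  rk <- spearman_ranking(smp, resp)
  expect_equal(rk$parameter[1], "strong")
  expect_gt(rk$y[rk$parameter == "strong"], 0.95)
  expect_lt(rk$y[rk$parameter == "dummy"], 0.1)
  expect_lt(rk$z[rk$parameter == "dummy"], 0.1)
  # ranking is invariant under monotone rescaling of a response
  resp2 <- resp
  resp2$y <- exp(resp2$y / 2)
  expect_equal(spearman_ranking(smp, resp2)$y, rk$y)
})

test_that("Monte-Carlo screening is deterministic and physically plausible", {
  rk1 <- sensitivity_mc(n_samples = 60, seed = 7)
  rk2 <- sensitivity_mc(n_samples = 60, seed = 7)
  expect_equal(as.data.frame(rk1), as.data.frame(rk2))
  expect_equal(attr(rk1, "n_failed"), 0)
  # the impactor spring dominates the error of the impactor PoM trace
  expect_equal(rk1$parameter[which.max(rk1$rmse_impactor)],
               "impactor_stiffness")
  expect_error(sensitivity_mc(n_samples = 10), "at least 50")
})

test_that("pseudo-measurements reproduce the conditioning pipeline", {
  pulses <- list(pulse_half_sine())
  clean <- make_pseudo_measurements(pulses = pulses, noise_sd = 0)
  sim <- reference_sim()
  expect_equal(clean$impactor[[1]],
               lowpass_zerophase(sim$data$force_impactor, 800e3, 10e3) /
                 9247)
  expect_equal(clean$stem[[1]],
               lowpass_zerophase(sim$data$force_stem, 800e3, 15e3) / 9247)
  # determinism under a seed
  n1 <- make_pseudo_measurements(pulses = pulses, noise_sd = 0.02, seed = 4)
  n2 <- make_pseudo_measurements(pulses = pulses, noise_sd = 0.02, seed = 4)
  expect_equal(n1$impactor[[1]], n2$impactor[[1]])
  # residual noise level: white noise loses variance to the filter band
  resid <- n1$impactor[[1]] - clean$impactor[[1]]
  oracle <- withr::with_seed(99, {
    mean(replicate(10, stats::sd(lowpass_zerophase(rnorm(641), 800e3,
                                                   10e3))))
  })
  expect_lt(abs(stats::sd(resid) - 0.02 * oracle) / (0.02 * oracle), 0.2)
})

test_that("datasets with atypical oscillation frequency are screened out", {
  fs <- 800e3
  t <- seq(0, 0.8e-3, by = 1 / fs)
  mk <- function(f0) 0.3 * sin(2 * pi * f0 * t)
  ds <- tibble::tibble(
    id = 1:5,
    pulse = replicate(5, pulse_half_sine(), simplify = FALSE),
    impactor = list(mk(3.5e3), mk(3.4e3), mk(3.6e3), mk(7e3), mk(3.5e3)),
    stem = replicate(5, mk(3e3), simplify = FALSE)
  )
  kept <- screen_datasets(ds)
  expect_equal(attr(kept, "excluded"), 4)
  expect_equal(kept$id, c(1, 2, 3, 5))
})

test_that("least-squares fitting recovers strongly identified stiffnesses", {
  truth <- list(impactor_stiffness = 100e6, stem_stiffness = 110e6)
  ds <- make_pseudo_measurements(true_params = truth,
                                 pulses = list(pulse_half_sine()),
                                 noise_sd = 0)
  sp <- parameter_space()
  sp$free <- sp$parameter %in% names(truth)
  fit <- fit_parameters(ds, space = sp, n_starts = 1, refine = NULL,
                        maxiter = 25)
  est <- stats::setNames(fit$par$estimate, fit$par$parameter)
  expect_lt(abs(est[["impactor_stiffness"]] - 100e6) / 100e6, 0.01)
  expect_lt(abs(est[["stem_stiffness"]] - 110e6) / 110e6, 0.01)
  g <- glance(fit)
  expect_true(g$converged)
  expect_lt(g$median_rmse_impactor, 0.5)
  expect_equal(nrow(tidy(fit)), 2)
  # report writing round-trips the diagnostics table
  dir <- withr::local_tempdir()
  write_fit_report(fit, dir)
  expect_true(file.exists(file.path(dir, "fit_report.txt")))
  back <- readr::read_csv(file.path(dir, "fit_rmse.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), 2)
})
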