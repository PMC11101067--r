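test_that("output grid honours the acquisition contract", {
  sim <- reference_sim()
  d <- sim$data
  expect_equal(nrow(d), 0.8e-3 * 800e3 + 1) # 641 samples including t = 0
  expect_equal(unique(round(diff(d$time), 12)), 1.25e-6)
  # initial state: at rest, PoM forces at their preload (deviation zero)
  expect_equal(d$force_impactor[1], 0, tolerance = 1e-8)
  expect_equal(d$force_stem[1], 0, tolerance = 1e-8)
  expect_true(all(abs(d[1, paste0("v_", c("impactor", "loadcell", "tip",
                                          "head", "stem", "tissue"))]) == 0))
})

test_that("a zero pulse leaves the preloaded chain in static equilibrium", {
  sim <- simulate_chain(chain_config(), zero_pulse())
  thresh <- 1e-6 * total_chain_mass() * 9.81
  expect_lt(max(abs(sim$data$force_impactor)), thresh)
  expect_lt(max(abs(sim$data$force_stem)), thresh)
  expect_lt(max(abs(unlist(sim$data[paste0("v_", "tissue")]))), 1e-9)
})

test_that("contact and friction respect their physical bounds along the blow", {
  d <- reference_sim()$data
  # no adhesion: the one-sided stop never pulls
  expect_true(all(d$force_contact >= 0))
  # transmitted junction force never exceeds the static cone
  active <- d$normal_force > 0
  expect_true(all(abs(d$force_friction[active]) <=
                    0.79 * d$normal_force[active] * (1 + 1e-9)))
  # insertion depth is non-negative by construction
  expect_true(all(d$insertion_depth >= 0))
})

test_that("the rigid single-oscillator limit reproduces the closed-form period", {
  # upper assembly detached (frictionless, no contact), stem spring rigid:
  # stem + tissue ride the tissue spring as one mass
  k <- 1e7
  m <- 0.043 + 0.52
  cfg <- chain_config(mu_static = 0, mu_kinetic = 0, contact_stiffness = 0,
                      contact_damping = 0, gravity = 0,
                      stem_stiffness = 1e10, tissue_stiffness = k,
                      tissue_damping = 0)
  sim <- simulate_chain(cfg, zero_pulse(4e-3), duration = 4e-3,
                        state0 = c(0, 0, 0, 0, 1e-4, 1e-4, rep(0, 6)))
  x <- sim$data$x_tissue
  pk <- impactchain:::find_positive_peaks(x - min(x))
  period <- mean(diff(sim$data$time[pk]))
  expect_lt(abs(period - 2 * pi * sqrt(m / k)) / (2 * pi * sqrt(m / k)),
            0.005)
})

test_that("the conservative limit conserves mechanical energy after the pulse", {
  cfg <- chain_config(mu_static = 0, mu_kinetic = 0,
                      contact_bilateral = TRUE, contact_damping = 0,
                      gravity = 0, tissue_damping = 0)
  sim <- simulate_chain(cfg, pulse_half_sine())
  d <- sim$data
  ke <- 0.5 * (0.508 * d$v_impactor^2 + 0.137 * d$v_loadcell^2 +
                 0.084 * d$v_tip^2 + 0.062 * d$v_head^2 +
                 0.043 * d$v_stem^2 + 0.52 * d$v_tissue^2)
  pe <- 0.5 * (85e6 * (d$x_impactor - d$x_loadcell)^2 +
                 2.3e9 * (d$x_loadcell - d$x_tip)^2 +
                 13e6 * (d$x_tip - d$x_head)^2 +
                 130e6 * (d$x_stem - d$x_tissue)^2 +
                 4000 * d$x_tissue^2)
  E <- ke + pe
  after <- d$time > 0.145e-3 # the pulse has ended
  expect_lt((max(E[after]) - min(E[after])) / max(E[after]), 0.01)
})

test_that("pulses on a foreign grid are resampled with a warning", {
  coarse <- pulse_half_sine(sample_rate = 400e3)
  expect_warning(sim <- simulate_chain(chain_config(), coarse), "resampled")
  fine <- simulate_chain(chain_config(), pulse_half_sine())
  expect_equal(max(sim$data$force_impactor), max(fine$data$force_impactor),
               tolerance = 1e-3)
})

test_that("tidy, glance and autoplot expose the simulation tabularly", {
  sim <- reference_sim()
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$signal), c("force_impactor", "force_stem"))
  expect_equal(nrow(td), 2 * 641)
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_equal(g$normalized_peak_impactor,
               max(sim$data$force_impactor) / 9247)
  expect_s3_class(autoplot(sim), "ggplot")
})
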