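test_that("junction normal force follows the quadratic insertion law", {
  cfg <- chain_config()
  expect_equal(normal_force(cfg, 0), 5.0)
  expect_equal(normal_force(cfg, 10e-6), 5.0 + 140e9 * (1e-5)^2) # 19 N
  expect_equal(normal_force(chain_config(normal_force_quad = 0),
                            c(0, 1e-4, 5e-3)), rep(5, 3))
  expect_error(normal_force(cfg, -1e-6), "non-negative")
})

test_that("hard stop ramps, never pulls, and closes at the right depth", {
  cfg <- chain_config()
  expect_equal(hardstop_force(cfg, -10e-6, 5), 0)
  expect_equal(hardstop_force(cfg, 50e-6, 0), 13e6 * 50e-6)        # 650 N
  expect_equal(hardstop_force(cfg, 25e-6, 0), 13e6 * 25e-6 * 0.5)  # 162.5 N
  # beyond the transition depth the ramp factor saturates at one
  expect_equal(hardstop_force(cfg, 100e-6, 0), 13e6 * 100e-6)
  # elastic part continuous and non-decreasing in penetration
  pen <- seq(-10e-6, 120e-6, by = 1e-6)
  f <- hardstop_force(cfg, pen, 0)
  expect_true(all(diff(f) >= 0))
  # strong separation velocity cannot make the contact tensile
  expect_equal(hardstop_force(cfg, 10e-6, -100), 0)
  expect_true(all(hardstop_force(cfg, pen, rnorm(length(pen), 0, 10)) >= 0))
  # bilateral variant is a plain spring-damper
  cfgb <- chain_config(contact_bilateral = TRUE)
  expect_equal(hardstop_force(cfgb, -10e-6, 0), 13e6 * -10e-6)
})

test_that("taper friction sticks below the static cone and slides at the kinetic force", {
  cfg <- chain_config()
  # stick: demand 3 N under limit 0.79 * 5 = 3.95 N
  expect_equal(taper_friction_force(cfg, 3, 0, 0), 3)
  # slip at 10 um insertion: 0.49 * 19 = 9.31 N opposing the motion
  expect_equal(taper_friction_force(cfg, 0, 0.1, 10e-6), 9.31)
  expect_equal(taper_friction_force(cfg, 0, -0.1, 10e-6), -9.31)
  # breakaway: demand above the cone at rest slides in the demand direction
  expect_equal(taper_friction_force(cfg, 100, 0, 0), 0.49 * 5)
  expect_equal(taper_friction_force(cfg, -100, 0, 0), -0.49 * 5)
  # frictionless limit
  cfg0 <- chain_config(mu_static = 0, mu_kinetic = 0)
  expect_equal(taper_friction_force(cfg0, 50, 0.3, 1e-5), 0)
  expect_error(taper_friction_force(cfg, 1, 0, -1e-6), "non-negative")
})

test_that("steady-state preload reproduces hand statics", {
  pre <- steady_state_preload(chain_config())
  w_total <- total_chain_mass() * 9.81
  expect_equal(pre$spring_compression[["tissue_spring"]], w_total / 4000,
               tolerance = 1e-12)                         # ~3.32 mm
  w_stop <- (0.508 + 0.137 + 0.084) * 9.81
  expect_equal(pre$contact_penetration, sqrt(w_stop * 50e-6 / 13e6),
               tolerance = 1e-9)                          # ~5.24 um
  w_junction <- (0.508 + 0.137 + 0.084 + 0.062) * 9.81
  d0 <- sqrt((w_junction / 0.79 - 5) / 140e9)
  expect_equal(pre$insertion_depth, d0, tolerance = 1e-6) # ~5.87 um
  expect_equal(unname(pre$static_pom_force),
               c((0.508 + 0.137) * 9.81, (1.354 - 0.52) * 9.81))
})

test_that("preload handles degenerate limits", {
  pre0 <- steady_state_preload(chain_config(gravity = 0))
  expect_true(all(pre0$spring_compression == 0))
  expect_equal(pre0$contact_penetration, 0)
  expect_equal(pre0$insertion_depth, 0)
  # seating force alone can carry a light enough column
  light <- chain_config(impactor_mass = 1e-3, loadcell_mass = 1e-3,
                        tip_mass = 1e-3, head_mass = 1e-3)
  expect_equal(steady_state_preload(light)$insertion_depth, 0)
  # unsatisfiable equilibria are reported
  expect_error(steady_state_preload(chain_config(tissue_stiffness = 0)),
               "zero-stiffness")
  expect_error(steady_state_preload(
    chain_config(mu_static = 0, mu_kinetic = 0)), "static friction")
})
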