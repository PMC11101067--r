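#' Taper-junction normal force
#'
#' The clamping (normal) force between head and stem tapers grows with the
#' contact area and hence with the insertion depth `d`; it is modelled as a
#' quadratic polynomial in `d` without a linear term,
#' `N(d) = N0 + beta * d^2`.
#'
#' @param chain A [chain_config()] (supplies `normal_force_const` and
#'   `normal_force_quad`).
#' @param d Insertion depth in metres, `>= 0` (vectorized).
#' @return Normal force in newtons.
#' @examples
#' normal_force(chain_config(), 0)      # 5 N seating force
#' normal_force(chain_config(), 10e-6)  # 19 N
#' @export
normal_force <- function(chain, d) {
  stopifnot(inherits(chain, "chain_config"))
  if (any(d < 0)) stop("insertion depth must be non-negative", call. = FALSE)
  chain$normal_force_const + chain$normal_force_quad * d^2
}

#' One-sided hard-stop contact force
#'
#' The loose contact between the polymer impactor tip and the metal head is a
#' one-sided hard stop whose stiffness (and damping) ramp linearly from zero
#' to their full values over the transition depth `delta`: for penetration
#' `x > 0` the force is `k * min(x/delta, 1) * x + c * min(x/delta, 1) * v`,
#' clamped to be non-tensile; an open gap (`x <= 0`) transmits nothing.
#'
#' @param chain A [chain_config()].
#' @param penetration Penetration depth in metres; negative values mean an
#'   open gap (vectorized).
#' @param relative_velocity Relative approach velocity in m/s (vectorized,
#'   recycled against `penetration`).
#' @return Contact force in newtons (always `>= 0`).
#' @examples
#' hardstop_force(chain_config(), 50e-6, 0) # 650 N at full ramp
#' hardstop_force(chain_config(), -10e-6, 1) # open gap: 0
#' @export
hardstop_force <- function(chain, penetration, relative_velocity = 0) {
  stopifnot(inherits(chain, "chain_config"))
  n <- max(length(penetration), length(relative_velocity))
  x <- rep_len(penetration, n)
  v <- rep_len(relative_velocity, n)
  if (chain$contact_bilateral) {
    return(chain$contact_stiffness * x + chain$contact_damping * v)
  }
  r <- pmin(pmax(x / chain$contact_transition, 0), 1)
  f <- chain$contact_stiffness * r * x + chain$contact_damping * r * v
  f[x <= 0] <- 0
  pmax(f, 0)
}

#' Stick-slip friction force transmitted across the taper junction
#'
#' Karnopp-regularized Coulomb friction: while the head-stem relative
#' velocity is below the stick threshold and the demanded shear does not
#' exceed `mu_static * N(d)`, the junction transmits the demand unchanged
#' (stick); otherwise it transmits `mu_kinetic * N(d)` opposing the relative
#' sliding (or the demand, at breakaway). A junction pulled apart (`d < 0`)
#' transmits nothing.
#'
#' @param chain A [chain_config()].
#' @param shear_demand Axial force in newtons the junction is asked to carry.
#' @param relative_velocity Head-stem relative velocity in m/s.
#' @param d Insertion depth in metres (`>= 0`).
#' @return Transmitted axial force in newtons.
#' @examples
#' taper_friction_force(chain_config(), 3, 0, 0)       # sticks: 3 N
#' taper_friction_force(chain_config(), 0, 0.1, 10e-6) # slides: 9.31 N
#' @export
taper_friction_force <- function(chain, shear_demand, relative_velocity, d) {
  stopifnot(inherits(chain, "chain_config"))
  if (any(d < 0)) stop("insertion depth must be non-negative", call. = FALSE)
  n <- max(length(shear_demand), length(relative_velocity), length(d))
  fd <- rep_len(shear_demand, n)
  v <- rep_len(relative_velocity, n)
  d <- rep_len(d, n)
  N <- normal_force(chain, d)
  slip_mag <- chain$mu_kinetic * N
  out <- numeric(n)
  sticking <- abs(v) < chain$stick_velocity_tol
  held <- sticking & abs(fd) <= chain$mu_static * N
  out[held] <- fd[held]
  brk <- sticking & !held
  out[brk] <- slip_mag[brk] * sign(fd[brk])
  sl <- !sticking
  out[sl] <- slip_mag[sl] * sign(v[sl])
  out
}

#' Gravitational steady-state preload of the chain
#'
#' Solves the static equilibrium the simulation starts from: every spring is
#' compressed by the weight it supports, the hard stop is closed far enough
#' to carry the weight of the impactor assembly above it, and the insertion
#' depth is seated at the smallest `d >= 0` at which static friction
#' (`mu_static * N(d)`) can hold the weight above the taper junction. All
#' velocities are zero, so the net force on every node vanishes.
#'
#' @param chain A [chain_config()].
#' @return A list of class `chain_preload` with components
#'   `spring_compression` (named, metres), `contact_penetration` (m),
#'   `insertion_depth` (m) and `static_pom_force` (named, newtons: the
#'   element forces at the two measurement positions before the blow).
#' @examples
#' steady_state_preload(chain_config())
#' @export
steady_state_preload <- function(chain) {
  stopifnot(inherits(chain, "chain_config"))
  g <- chain$gravity
  m <- unlist(chain[chain_mass_names])
  w_above <- cumsum(m) * g # weight carried below node i

  comp <- c(
    impactor_spring = w_above[[1]] / chain$impactor_stiffness,
    loadcell_spring = w_above[[2]] / chain$loadcell_stiffness,
    stem_spring     = w_above[[5]] / chain$stem_stiffness,
    tissue_spring   = w_above[[6]] / chain$tissue_stiffness
  )
  comp[!is.finite(comp)] <- 0 # rigid (infinite-stiffness) reading of k = Inf
  if (any(unlist(chain[c("impactor_stiffness", "loadcell_stiffness",
                         "stem_stiffness", "tissue_stiffness")]) == 0 &
          g > 0)) {
    stop("a zero-stiffness spring cannot carry a gravitational preload",
         call. = FALSE)
  }

  # hard stop carries the impactor + load cell + tip weight
  w_stop <- w_above[[3]]
  k <- chain$contact_stiffness
  delta <- chain$contact_transition
  if (w_stop == 0) {
    p0 <- 0
  } else if (chain$contact_bilateral) {
    p0 <- w_stop / k
  } else {
    if (k <= 0) {
      stop("hard stop cannot carry the static weight with zero stiffness",
           call. = FALSE)
    }
    p0 <- if (w_stop <= k * delta) sqrt(w_stop * delta / k) else w_stop / k
  }

  # junction seats at the smallest d with mu_static * N(d) >= supported weight
  w_junction <- w_above[[4]]
  mu_s <- chain$mu_static
  if (w_junction == 0) {
    d0 <- 0
  } else if (mu_s * chain$normal_force_const >= w_junction) {
    d0 <- 0
  } else if (mu_s <= 0 || chain$normal_force_quad <= 0) {
    stop("static friction cannot hold the weight above the taper junction",
         call. = FALSE)
  } else {
    d0 <- sqrt((w_junction / mu_s - chain$normal_force_const) /
                 chain$normal_force_quad)
    d0 <- d0 * (1 + 1e-9) # seat marginally inside the friction cone
  }

  structure(list(
    spring_compression = comp,
    contact_penetration = p0,
    insertion_depth = d0,
    static_pom_force = c(impactor = w_above[[2]], stem = w_above[[5]])
  ), class = "chain_preload")
}

#' @export
print.chain_preload <- function(x, ...) {
  cat("<chain_preload> static equilibrium before the blow\n")
  cat("  spring compressions [m]:\n")
  print(signif(x$spring_compression, 4))
  cat("  contact penetration [m]:", signif(x$contact_penetration, 4), "\n")
  cat("  insertion depth     [m]:", signif(x$insertion_depth, 4), "\n")
  cat("  static PoM forces   [N]:\n")
  print(signif(x$static_pom_force, 4))
  invisible(x)
}
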