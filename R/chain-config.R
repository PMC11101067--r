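#' Build the impaction transmission chain configuration
#'
#' Constructs the serial six-mass chain used throughout the package:
#' mallet pulse -> impactor -- load cell -- impactor tip =(one-sided hard
#' stop)= femoral head =(taper friction)= stem -- responding tissue -- ground.
#' Defaults reproduce the fitted reference configuration of the transmission
#' chain (tissue spring 4.0 N/mm, tissue mass 0.52 kg).
#'
#' All values are SI (kg, N/m, Ns/m, m). Note that the instrument-catalogue
#' dialect quotes stiffness in N/mm and damping in Ns/mm; [read_chain_config()]
#' and [write_chain_config()] translate between the two.
#'
#' @param ... Named overrides of individual parameters, e.g.
#'   `chain_config(tissue_mass = 0.89)` for the added-weight assembly.
#'   Unknown names are an error.
#'
#' @section Parameters:
#' \describe{
#'   \item{impactor_mass, loadcell_mass, tip_mass, head_mass, stem_mass,
#'     tissue_mass}{node masses in kg (all strictly positive); the tissue mass
#'     includes its load cell}
#'   \item{impactor_stiffness, impactor_damping}{spring-damper between
#'     impactor and load-cell node}
#'   \item{loadcell_stiffness, loadcell_damping}{spring-damper between the
#'     load-cell node and the polymer tip; its force is the impactor
#'     position-of-measurement (PoM) signal}
#'   \item{contact_stiffness, contact_damping, contact_transition}{one-sided
#'     hard stop between tip and head; stiffness and damping ramp linearly
#'     from zero over the transition depth (50 um by default)}
#'   \item{contact_bilateral}{if `TRUE` the hard stop is replaced by a plain
#'     bilateral spring-damper (used for conservative-limit checks)}
#'   \item{mu_static, mu_kinetic, normal_force_const, normal_force_quad}{taper
#'     junction friction: Coulomb coefficients and the normal-force law
#'     `N(d) = N0 + beta * d^2` in the insertion depth d}
#'   \item{stem_stiffness, stem_damping}{spring-damper between stem and
#'     tissue node; its force is the stem PoM signal}
#'   \item{tissue_stiffness, tissue_damping}{tissue spring-damper to ground;
#'     damping defaults to 10\% of the stiffness value (`NULL` keeps that
#'     rule active under stiffness overrides)}
#'   \item{gravity}{acceleration along the impaction axis, m/s^2}
#'   \item{stick_velocity_tol}{Karnopp stick-slip regularization threshold
#'     on the head-stem relative velocity, m/s}
#' }
#'
#' @return An object of class `chain_config`: a named list of validated
#'   parameters.
#' @examples
#' chain_config()
#' chain_config(tissue_mass = 0.89) # added-weight assembly
#' @export
chain_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  defaults <- chain_defaults()
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown chain parameter(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
           call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  cfg <- defaults
  if (is.null(cfg$tissue_damping)) {
    cfg$tissue_damping <- 0.1 * cfg$tissue_stiffness
  }
  validate_chain(cfg)
}

chain_defaults <- function() {
  list(
    impactor_mass      = 0.508,
    loadcell_mass      = 0.137,
    tip_mass           = 0.084,
    head_mass          = 0.062,
    stem_mass          = 0.043,
    tissue_mass        = 0.52,
    impactor_stiffness = 85e6,    # 85 x 10^3 N/mm
    impactor_damping   = 0,
    loadcell_stiffness = 2.3e9,   # 2.3 x 10^6 N/mm
    loadcell_damping   = 0,
    contact_stiffness  = 13e6,    # 13 x 10^3 N/mm
    contact_damping    = 240e3,   # 240 Ns/mm
    contact_transition = 50e-6,
    contact_bilateral  = FALSE,
    mu_static          = 0.79,
    mu_kinetic         = 0.49,
    normal_force_const = 5.0,
    normal_force_quad  = 140e9,
    stem_stiffness     = 130e6,   # 130 x 10^3 N/mm
    stem_damping       = 0,
    tissue_stiffness   = 4000,    # 4.0 N/mm reference
    tissue_damping     = NULL,    # -> 10% of tissue stiffness
    gravity            = 9.81,
    stick_velocity_tol = 1e-4
  )
}

chain_mass_names <- c("impactor_mass", "loadcell_mass", "tip_mass",
                      "head_mass", "stem_mass", "tissue_mass")

validate_chain <- function(cfg) {
  num <- setdiff(names(cfg), "contact_bilateral")
  for (nm in num) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("chain parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  cfg$contact_bilateral <- isTRUE(cfg$contact_bilateral)
  masses <- unlist(cfg[chain_mass_names])
  if (any(masses <= 0)) {
    stop("all masses must be strictly positive", call. = FALSE)
  }
  nonneg <- c("impactor_stiffness", "impactor_damping", "loadcell_stiffness",
              "loadcell_damping", "contact_stiffness", "contact_damping",
              "stem_stiffness", "stem_damping", "tissue_stiffness",
              "tissue_damping", "normal_force_const", "normal_force_quad",
              "mu_static", "mu_kinetic", "gravity", "contact_transition",
              "stick_velocity_tol")
  bad <- nonneg[vapply(nonneg, function(nm) cfg[[nm]] < 0, logical(1))]
  if (length(bad)) {
    stop("chain parameter(s) must be non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$mu_kinetic > cfg$mu_static) {
    stop("mu_kinetic must not exceed mu_static", call. = FALSE)
  }
  if (!cfg$contact_bilateral && cfg$contact_stiffness > 0 &&
      cfg$contact_transition <= 0) {
    stop("contact_transition must be positive for the one-sided hard stop",
         call. = FALSE)
  }
  structure(cfg, class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat("<chain_config> serial impaction chain (SI units)\n")
  df <- tibble::tibble(
    parameter = names(x),
    value = vapply(x, function(v) format(v, digits = 6), character(1))
  )
  print(df, n = nrow(df))
  invisible(x)
}

#' Tissue-surrogate presets of the consecutive-assembly experiment
#'
#' The five distinct soft-tissue surrogate configurations used in the
#' in vitro assembly series: the reference (4.0 N/mm spring, 0.52 kg below
#' the stem taper), three stiffness variants (1.9, 5.0 and 0.6 N/mm spanning
#' roughly 15\%-125\% of the reference) and one added-weight variant
#' (0.89 kg).
#'
#' @return A tibble with columns `label`, `tissue_mass` (kg) and
#'   `tissue_stiffness` (N/m).
#' @examples
#' tissue_presets()
#' @export
tissue_presets <- function() {
  tibble::tibble(
    label = c("reference", "stiffness 1.9 N/mm", "stiffness 5.0 N/mm",
              "stiffness 0.6 N/mm", "additional weight"),
    tissue_mass = c(0.52, 0.52, 0.52, 0.52, 0.89),
    tissue_stiffness = c(4.0, 1.9, 5.0, 0.6, 4.0) * 1e3
  )
}

# key -> (chain parameter, scale from file units to SI)
config_file_dialect <- function() {
  tibble::tibble(
    key = c("impactor_mass_kg", "loadcell_mass_kg", "tip_mass_kg",
            "head_mass_kg", "stem_mass_kg", "tissue_mass_kg",
            "impactor_stiffness_N_mm", "impactor_damping_Ns_mm",
            "loadcell_stiffness_N_mm", "loadcell_damping_Ns_mm",
            "contact_stiffness_N_mm", "contact_damping_Ns_mm",
            "contact_transition_m",
            "mu_static", "mu_kinetic",
            "normal_force_const_N", "normal_force_quad_N_m2",
            "stem_stiffness_N_mm", "stem_damping_Ns_mm",
            "tissue_stiffness_N_mm", "tissue_damping_Ns_mm",
            "gravity_m_s2", "stick_velocity_tol_m_s"),
    parameter = c(chain_mass_names,
                  "impactor_stiffness", "impactor_damping",
                  "loadcell_stiffness", "loadcell_damping",
                  "contact_stiffness", "contact_damping",
                  "contact_transition",
                  "mu_static", "mu_kinetic",
                  "normal_force_const", "normal_force_quad",
                  "stem_stiffness", "stem_damping",
                  "tissue_stiffness", "tissue_damping",
                  "gravity", "stick_velocity_tol"),
    scale = c(rep(1, 6), rep(1e3, 6), 1, 1, 1, 1, 1,
              1e3, 1e3, 1e3, 1e3, 1, 1)
  )
}

#' Read or write a chain configuration file
#'
#' Chain configurations are stored as flat `key: value` YAML with stiffness
#' in N/mm and damping in Ns/mm (the instrument-catalogue dialect); values
#' are converted to SI on load. `write_chain_config()` followed by
#' `read_chain_config()` round-trips exactly.
#'
#' @param path File path.
#' @param chain A [chain_config()] object.
#' @return `read_chain_config()` returns a `chain_config`;
#'   `write_chain_config()` returns `path` invisibly.
#' @export
read_chain_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dial <- config_file_dialect()
  bad <- setdiff(names(raw), c(dial$key, "contact_bilateral"))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  overrides <- list()
  for (i in seq_len(nrow(dial))) {
    k <- dial$key[i]
    if (!is.null(raw[[k]])) {
      overrides[[dial$parameter[i]]] <- as.numeric(raw[[k]]) * dial$scale[i]
    }
  }
  if (!is.null(raw$contact_bilateral)) {
    overrides$contact_bilateral <- isTRUE(raw$contact_bilateral)
  }
  chain_config(overrides)
}

#' @rdname read_chain_config
#' @export
write_chain_config <- function(chain, path) {
  stopifnot(inherits(chain, "chain_config"))
  dial <- config_file_dialect()
  out <- list()
  for (i in seq_len(nrow(dial))) {
    out[[dial$key[i]]] <- chain[[dial$parameter[i]]] / dial$scale[i]
  }
  out$contact_bilateral <- chain$contact_bilateral
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
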