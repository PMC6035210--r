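# Blast loading: peak side-on overpressure from charge mass and standoff via
# the scaled-distance (cube-root) law, Friedlander time profiles, and the
# two study scenario presets.

TNT_EQUIVALENCE <- c(C4 = 1.2, Octol = 1.14, TNT = 1.0)

P_AMBIENT <- 101325  # Pa, standard atmosphere

# Kinney & Graham (1985) free-air burst fit for chemical explosives:
# ratio of peak side-on overpressure to ambient pressure as a function of
# scaled distance Z (m/kg^(1/3), TNT equivalent).
KG_Z_RANGE <- c(0.05, 500)

kinney_graham_ratio <- function(Z) {
  808 * (1 + (Z / 4.5)^2) /
    sqrt((1 + (Z / 0.048)^2) * (1 + (Z / 0.32)^2) * (1 + (Z / 1.35)^2))
}

#' Blast scenario descriptor
#'
#' @param charge_mass explosive charge mass (kg).
#' @param explosive `"C4"`, `"Octol"`, `"TNT"` or `"custom"`.
#' @param standoff distance from charge to target (m).
#' @param tnt_equivalence TNT mass-equivalence factor; defaults per
#'   explosive (C-4 1.2, Octol 1.14, TNT 1.0); required for `"custom"`.
#' @return object of class `blast_scenario`.
#' @examples
#' blast_scenario(2.3, "C4", 2.3)
#' @export
blast_scenario <- function(charge_mass, explosive = c("C4", "Octol", "TNT", "custom"),
                           standoff, tnt_equivalence = NULL) {
  explosive <- match.arg(explosive)
  if (is.null(tnt_equivalence)) {
    if (explosive == "custom")
      stop("'tnt_equivalence' is required for a custom explosive",
           call. = FALSE)
    tnt_equivalence <- unname(TNT_EQUIVALENCE[explosive])
  }
  vals <- c(charge_mass = charge_mass, standoff = standoff,
            tnt_equivalence = tnt_equivalence)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("charge mass, standoff and TNT equivalence must be positive",
         call. = FALSE)
  structure(list(charge_mass = charge_mass, explosive = explosive,
                 standoff = standoff, tnt_equivalence = tnt_equivalence),
            class = "blast_scenario")
}

#' @export
print.blast_scenario <- function(x, ...) {
  cat(sprintf("<blast_scenario> %.3g kg %s (TNT eq. %.3g) at %.3g m standoff\n",
              x$charge_mass, x$explosive, x$tnt_equivalence, x$standoff))
  cat(sprintf("  scaled distance Z = %.4g m/kg^(1/3), peak overpressure ~ %.4g kPa\n",
              scaled_distance(x), peak_overpressure(x) / 1e3))
  invisible(x)
}

#' Scaled (Hopkinson-Cranz) distance of a scenario
#'
#' @param scenario a [blast_scenario()].
#' @return Z = standoff / (TNT-equivalent mass)^(1/3), in m/kg^(1/3).
#' @export
scaled_distance <- function(scenario) {
  stopifnot(inherits(scenario, "blast_scenario"))
  scenario$standoff /
    (scenario$tnt_equivalence * scenario$charge_mass)^(1 / 3)
}

#' Peak side-on blast overpressure
#'
#' Evaluates the packaged Kinney-Graham free-air (spherical burst)
#' scaled-distance fit for chemical explosives at the scenario's scaled
#' distance. The fit is continuous and strictly decreasing in Z over its
#' validity range.
#'
#' @param scenario a [blast_scenario()].
#' @return peak overpressure (Pa).
#' @examples
#' peak_overpressure(blast_scenario(2.3, "C4", 2.3)) / 1e3  # ~ 330 kPa
#' @export
peak_overpressure <- function(scenario) {
  Z <- scaled_distance(scenario)
  if (Z < KG_Z_RANGE[1] || Z > KG_Z_RANGE[2])
    stop(sprintf(
      "scaled distance Z = %.4g m/kg^(1/3) outside the fit validity range [%g, %g]",
      Z, KG_Z_RANGE[1], KG_Z_RANGE[2]), call. = FALSE)
  P_AMBIENT * kinney_graham_ratio(Z)
}

#' Friedlander overpressure waveform
#'
#' \deqn{P(t) = P_0 (1 - t/t_d)\, e^{-b t / t_d}} for \eqn{0 \le t \le t_d},
#' zero afterwards (negative phase truncated).
#'
#' @param P0 peak overpressure (Pa).
#' @param td positive phase duration (s).
#' @param b decay shape parameter (dimensionless).
#' @param t time(s) since arrival (s), vectorised, `t >= 0`.
#' @return overpressure (Pa), same length as `t`.
#' @examples
#' friedlander(360e3, 2e-3, 1, c(0, 1e-3, 2e-3))
#' @export
friedlander <- function(P0, td, b, t) {
  if (any(c(P0, td, b) <= 0) || any(!is.finite(c(P0, td, b))))
    stop("'P0', 'td' and 'b' must be positive", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  ifelse(t <= td, P0 * (1 - t / td) * exp(-b * t / td), 0)
}

#' Positive-phase impulse of a Friedlander waveform
#'
#' Closed form of \eqn{\int_0^{t_d} P(t)\,dt}.
#'
#' @inheritParams friedlander
#' @return impulse (Pa s).
#' @export
friedlander_impulse <- function(P0, td, b) {
  if (any(c(P0, td, b) <= 0)) stop("parameters must be positive", call. = FALSE)
  P0 * td * (1 / b - (1 - exp(-b)) / b^2)
}

#' Blast overpressure profile
#'
#' A Friedlander waveform with sampled time series, usable as the traction
#' load of [solve_column()].
#'
#' @param P0 peak overpressure (Pa).
#' @param td positive phase duration (s). Default 2 ms, a representative
#'   free-field positive phase for kilogram-scale charges at metre-scale
#'   standoffs.
#' @param b decay shape (default 1).
#' @param dt sample spacing of the stored time series (s).
#' @return object of class `blast_profile` with fields `P0`, `td`, `b` and
#'   `samples` (data frame `t_s`, `overpressure_Pa`), plus a `pressure(t)`
#'   function.
#' @export
blast_profile <- function(P0, td = 2e-3, b = 1, dt = td / 200) {
  tt <- seq(0, td, by = dt)
  structure(list(
    P0 = P0, td = td, b = b,
    samples = data.frame(t_s = tt,
                         overpressure_Pa = friedlander(P0, td, b, tt)),
    pressure = function(t) friedlander(P0, td, b, pmax(t, 0))
  ), class = "blast_profile")
}

#' @export
print.blast_profile <- function(x, ...) {
  cat(sprintf("<blast_profile> P0 = %.4g kPa, td = %.4g ms, b = %g, impulse = %.4g Pa s\n",
              x$P0 / 1e3, x$td * 1e3, x$b,
              friedlander_impulse(x$P0, x$td, x$b)))
  invisible(x)
}

#' Study blast scenario presets
#'
#' Two scenario/profile pairs used throughout the package:
#' \describe{
#'   \item{`c4_low`}{2.3 kg C-4 at 2.3 m standoff; peak pinned to the
#'     reported 360 kPa magnitude.}
#'   \item{`octol_high`}{3 kg Octol at 2 m standoff; peak pinned to the
#'     reported 1.3 MPa magnitude.}
#' }
#' Peaks are pinned constants (the magnitudes as reported), not re-derived
#' from the scaled-distance fit; `td = 2` ms and `b = 1` are package
#' defaults.
#'
#' @param name preset name, or `NULL` to list all presets.
#' @return for a single name, a list with `scenario` ([blast_scenario()])
#'   and `profile` ([blast_profile()]); for `NULL`, a named list of all
#'   presets.
#' @examples
#' scenario_presets("c4_low")$profile$P0  # 360 kPa
#' @export
scenario_presets <- function(name = NULL) {
  presets <- list(
    c4_low = list(scenario = blast_scenario(2.3, "C4", 2.3),
                  profile = blast_profile(360e3)),
    octol_high = list(scenario = blast_scenario(3, "Octol", 2.0),
                      profile = blast_profile(1.3e6))
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  presets[[name]]
}
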