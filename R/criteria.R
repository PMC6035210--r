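# Candidate mechanistic injury criteria evaluated on material-point
# deformation/stress histories. All criteria are peak-value based; the
# power (energy-rate) criteria take the maximum of the positive part of the
# instantaneous stress power, since elastic unloading produces negative
# power that cannot plausibly injure.

CRITERION_NAMES <- c("pressure", "von_mises", "equivalent_strain",
                     "volumetric_energy_rate", "shear_energy_rate",
                     "axonal_stretch", "axonal_stretch_energy_rate")

AXONAL_CRITERIA <- c("axonal_stretch", "axonal_stretch_energy_rate")

#' Injury criterion specification
#'
#' @param name one of `"pressure"`, `"von_mises"`, `"equivalent_strain"`,
#'   `"volumetric_energy_rate"`, `"shear_energy_rate"`, `"axonal_stretch"`,
#'   `"axonal_stretch_energy_rate"`.
#' @param threshold damage threshold in the SI units of the criterion
#'   (Pa, dimensionless, or W/m^3); must be positive, `Inf` disables the
#'   exceedance flag.
#' @param tissue tissue the criterion applies to: `"grey"`, `"white"` or
#'   `"both"`; the axonal criteria are only valid for white matter.
#' @return object of class `criterion_spec`.
#' @examples
#' criterion_spec("shear_energy_rate", 1e8, "grey")
#' @export
criterion_spec <- function(name, threshold, tissue = c("both", "grey", "white")) {
  name <- match.arg(name, CRITERION_NAMES)
  tissue <- match.arg(tissue)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0)
    stop("'threshold' must be a positive scalar", call. = FALSE)
  if (name %in% AXONAL_CRITERIA && tissue != "white")
    stop("axonal criteria are only valid for tissue = 'white'", call. = FALSE)
  structure(list(name = name, threshold = threshold, tissue = tissue),
            class = "criterion_spec")
}

#' Default injury criteria
#'
#' The calibrated damage thresholds are 100 MJ/m^3/s (1e8 W/m^3) for the
#' shear energy rate in grey matter and 1.5 MJ/m^3/s (1.5e6 W/m^3) for the
#' axonal stretch energy rate in white matter. The remaining criteria have
#' no calibrated threshold and default to `Inf` (peak reported, never
#' flagged) until the user supplies one.
#'
#' @param tissue `"grey"`, `"white"` or `"both"` (default); axonal criteria
#'   are included only when white matter is requested.
#' @return list of [criterion_spec()] objects.
#' @examples
#' vapply(default_criteria("grey"), `[[`, "", "name")
#' @export
default_criteria <- function(tissue = c("both", "grey", "white")) {
  tissue <- match.arg(tissue)
  specs <- list(
    criterion_spec("pressure", Inf, "both"),
    criterion_spec("von_mises", Inf, "both"),
    criterion_spec("equivalent_strain", Inf, "both"),
    criterion_spec("volumetric_energy_rate", Inf, "both"),
    criterion_spec("shear_energy_rate", 1e8, "grey"),
    criterion_spec("axonal_stretch", Inf, "white"),
    criterion_spec("axonal_stretch_energy_rate", 1.5e6, "white")
  )
  keep <- vapply(specs, function(s)
    tissue == "both" || s$tissue == "both" || s$tissue == tissue, TRUE)
  specs[keep]
}

check_alignment <- function(history, stress_hist) {
  if (length(history$t) != length(stress_hist$t) ||
      max(abs(history$t - stress_hist$t)) > 1e-12 * max(1, max(history$t)))
    stop("deformation and stress histories are not time-aligned",
         call. = FALSE)
}

positive_peak <- function(t, x) {
  xp <- pmax(x, 0)
  i <- which.max(xp)
  list(peak = xp[i], t_peak = t[i])
}

#' Peak pressure and von Mises stress of a stress history
#'
#' @param stress_hist a [stress_history()].
#' @return list with `pressure` (peak `|P|` over time, Pa), `von_mises`
#'   (peak \eqn{\sqrt{3/2\,\sigma_{iso}:\sigma_{iso}}}, Pa) and the times of
#'   the peaks. Both compressive and tensile pressure excursions count
#'   (cavitation-relevant tension is not ignored).
#' @export
stress_invariant_criteria <- function(stress_hist) {
  stopifnot(inherits(stress_hist, "stress_history"))
  n <- length(stress_hist$t)
  if (n == 0L) stop("empty stress history", call. = FALSE)
  vm <- vapply(seq_len(n), function(i)
    sqrt(1.5 * ddot3(stress_hist$sigma_iso[, , i],
                     stress_hist$sigma_iso[, , i])), 0)
  ip <- which.max(abs(stress_hist$P))
  iv <- which.max(vm)
  list(pressure = abs(stress_hist$P[ip]), t_pressure = stress_hist$t[ip],
       von_mises = vm[iv], t_von_mises = stress_hist$t[iv])
}

#' Peak equivalent (von Mises) strain of a deformation history
#'
#' Uses the Hencky (logarithmic) strain of each state:
#' \eqn{\epsilon_{eq} = \sqrt{2/3\;\epsilon_{dev}:\epsilon_{dev}}}.
#'
#' @param history a [deformation_history()].
#' @return list with `peak` (dimensionless) and `t_peak` (s).
#' @export
equivalent_strain <- function(history) {
  stopifnot(inherits(history, "deformation_history"))
  eq <- vapply(seq_along(history$t), function(i) {
    ed <- dev3(hencky_strain(history$F[, , i]))
    sqrt(2 / 3 * ddot3(ed, ed))
  }, 0)
  i <- which.max(eq)
  list(peak = eq[i], t_peak = history$t[i])
}

energy_rate_signals <- function(history, stress_hist) {
  check_alignment(history, stress_hist)
  n <- length(history$t)
  vol <- numeric(n)
  shear <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    D <- rate_of_deformation(history, i)
    vol[i] <- -stress_hist$P[i] * sum(diag(D))
    shear[i] <- ddot3(stress_hist$sigma_iso[, , i], dev3(D))
  }
  list(t = history$t, volumetric = vol, shear = shear)
}

#' Peak volumetric and shear energy rates (stress powers)
#'
#' Instantaneous volumetric power \eqn{-P\,\mathrm{tr}(D)} and shear
#' (deviatoric) power \eqn{\sigma_{iso} : D_{dev}}, in W/m^3
#' (1 MJ/m^3/s = 1e6 W/m^3). The two signals partition the total stress
#' power \eqn{\sigma : D} exactly. Peaks are maxima over time of the
#' positive part of each signal.
#'
#' @param history a [deformation_history()].
#' @param stress_hist a time-aligned [stress_history()].
#' @return list with `volumetric`, `shear` (peak powers, W/m^3) and the
#'   times of the peaks.
#' @export
energy_rate_criteria <- function(history, stress_hist) {
  stopifnot(inherits(history, "deformation_history"),
            inherits(stress_hist, "stress_history"))
  sig <- energy_rate_signals(history, stress_hist)
  pv <- positive_peak(sig$t, sig$volumetric)
  ps <- positive_peak(sig$t, sig$shear)
  list(volumetric = pv$peak, t_volumetric = pv$t_peak,
       shear = ps$peak, t_shear = ps$t_peak)
}

#' Peak axonal stretch and axonal stretch energy rate
#'
#' Axonal stretch \eqn{\lambda_a(t) = \|F(t) a_0\|} along the reference
#' fibre direction; the axonal power is
#' \eqn{\sigma_a \dot\lambda_a / \lambda_a} with \eqn{\sigma_a = a_t \cdot
#' \sigma\, a_t} the normal Cauchy stress along the current fibre direction
#' (rate by backward difference; peak of the positive part).
#'
#' @param history a [deformation_history()].
#' @param stress_hist a time-aligned [stress_history()].
#' @param a0 unit reference fibre direction.
#' @return list with `stretch` (peak, dimensionless), `power` (peak, W/m^3)
#'   and the times of the peaks.
#' @export
axonal_criteria <- function(history, stress_hist, a0) {
  stopifnot(inherits(history, "deformation_history"),
            inherits(stress_hist, "stress_history"))
  check_alignment(history, stress_hist)
  a0 <- unit_vector(a0, "a0")
  n <- length(history$t)
  lam <- vapply(seq_len(n), function(i)
    sqrt(sum((history$F[, , i] %*% a0)^2)), 0)
  pow <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    dt <- history$t[i] - history$t[i - 1L]
    lamdot <- (lam[i] - lam[i - 1L]) / dt
    at <- as.numeric(history$F[, , i] %*% a0) / lam[i]
    sig_a <- as.numeric(at %*% stress_hist$sigma[, , i] %*% at)
    pow[i] <- sig_a * lamdot / lam[i]
  }
  il <- which.max(lam)
  pp <- positive_peak(history$t, pow)
  list(stretch = lam[il], t_stretch = history$t[il],
       power = pp$peak, t_power = pp$t_peak)
}

#' Evaluate injury criteria at one material point
#'
#' Computes the peak value of each requested criterion over the histories
#' and flags exceedance against the criterion threshold (closed comparison:
#' `peak >= threshold`).
#'
#' @param history a [deformation_history()].
#' @param stress_hist a time-aligned [stress_history()].
#' @param a0 unit reference fibre direction, or `NULL`; required when any
#'   axonal criterion is requested.
#' @param criteria list of [criterion_spec()]s; defaults to
#'   [default_criteria()] for the appropriate tissue.
#' @return a `point_injury_result`: data frame with columns `criterion`,
#'   `peak`, `t_peak` (s), `threshold`, `exceeded`.
#' @examples
#' h <- make_deformation_history("simple_shear", rate = 10, amplitude = 0.01,
#'                               duration = 1e-3, dt = 5e-5)
#' evaluate_point(h, grey_stress(h), criteria = default_criteria("grey"))
#' @export
evaluate_point <- function(history, stress_hist, a0 = NULL,
                           criteria = default_criteria(
                             if (is.null(a0)) "grey" else "white")) {
  stopifnot(inherits(history, "deformation_history"),
            inherits(stress_hist, "stress_history"))
  if (inherits(criteria, "criterion_spec")) criteria <- list(criteria)
  names_req <- vapply(criteria, `[[`, "", "name")
  if (any(names_req %in% AXONAL_CRITERIA) && is.null(a0))
    stop("axonal criteria require a fibre direction 'a0'", call. = FALSE)
  inv <- stress_invariant_criteria(stress_hist)
  eqs <- equivalent_strain(history)
  er <- energy_rate_criteria(history, stress_hist)
  ax <- if (!is.null(a0)) axonal_criteria(history, stress_hist, a0)
  peak_of <- function(nm) switch(nm,
    pressure = c(inv$pressure, inv$t_pressure),
    von_mises = c(inv$von_mises, inv$t_von_mises),
    equivalent_strain = c(eqs$peak, eqs$t_peak),
    volumetric_energy_rate = c(er$volumetric, er$t_volumetric),
    shear_energy_rate = c(er$shear, er$t_shear),
    axonal_stretch = c(ax$stretch, ax$t_stretch),
    axonal_stretch_energy_rate = c(ax$power, ax$t_power))
  rows <- lapply(criteria, function(spec) {
    pk <- peak_of(spec$name)
    data.frame(criterion = spec$name, peak = pk[1], t_peak = pk[2],
               threshold = spec$threshold,
               exceeded = pk[1] >= spec$threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("point_injury_result", class(out))
  out
}
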