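# Grey- and white-matter constitutive laws: Cauchy stress histories from
# deformation-gradient histories. The stress is decomposed as
# sigma = -P I + sigma_iso with P the pressure, positive in compression —
# this sign convention is used everywhere in the package.

#' Pressure/deviatoric split of a Cauchy stress tensor
#'
#' @param sigma symmetric numeric 3x3 Cauchy stress (Pa).
#' @return list with `P` (pressure, Pa, positive in compression) and
#'   `sigma_iso` (traceless deviatoric stress, Pa); the input reconstructs
#'   exactly as `-P * diag(3) + sigma_iso`.
#' @examples
#' split_stress(diag(c(3e6, 0, 0)))
#' @export
split_stress <- function(sigma) {
  sigma <- check_symmetric(sigma, "sigma")
  P <- -sum(diag(sigma)) / 3
  list(P = P, sigma_iso = sigma + P * I3)
}

#' Cauchy stress history container
#'
#' @param t numeric time vector (s), strictly increasing.
#' @param sigma 3x3xN array or list of symmetric Cauchy stress tensors (Pa).
#' @return object of class `stress_history` with elements `t`, `sigma`
#'   (3x3xN), `P` (length-N pressure vector, positive in compression) and
#'   `sigma_iso` (3x3xN deviatoric stresses).
#' @export
stress_history <- function(t, sigma) {
  if (is.list(sigma))
    sigma <- vapply(sigma, function(s) check_symmetric(s, "sigma"),
                    matrix(0, 3, 3))
  if (!is.array(sigma) || length(dim(sigma)) != 3L ||
      !all(dim(sigma)[1:2] == 3L))
    stop("'sigma' must be a 3x3xN array or list of 3x3 matrices",
         call. = FALSE)
  n <- dim(sigma)[3]
  if (!is.numeric(t) || length(t) != n)
    stop("'t' must match the number of stress states", call. = FALSE)
  if (n > 1 && any(diff(t) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  P <- numeric(n)
  iso <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    s <- split_stress(sigma[, , i])
    P[i] <- s$P
    iso[, , i] <- s$sigma_iso
  }
  structure(list(t = as.numeric(t), sigma = sigma, P = P, sigma_iso = iso),
            class = "stress_history")
}

#' @export
print.stress_history <- function(x, ...) {
  n <- length(x$t)
  vm <- vapply(seq_len(n), function(i)
    sqrt(1.5 * ddot3(x$sigma_iso[, , i], x$sigma_iso[, , i])), 0)
  cat(sprintf("<stress_history> %d states, t in [%g, %g] s\n", n, x$t[1], x$t[n]))
  cat(sprintf("  peak |P| = %.4g Pa, peak von Mises = %.4g Pa\n",
              max(abs(x$P)), max(vm)))
  invisible(x)
}

#' @export
length.stress_history <- function(x) length(x$t)

# One exponential-map update of the Maxwell deviatoric overstress:
#   ds/dt = 2 mu_v D_dev - s / tau
# integrated exactly over dt with D_dev held constant. Unconditionally
# stable for stiff tau at blast time steps.
maxwell_update <- function(s, D_dev, mu_v, tau, dt) {
  e <- exp(-dt / tau)
  e * s + 2 * mu_v * tau * (1 - e) * D_dev
}

# Shared isotropic viscoelastic backbone of the grey and white models.
# Returns list(t, sigma array) of the base (isotropic) Cauchy stress.
iso_stress_states <- function(history, params) {
  n <- length(history$t)
  sigma <- array(0, c(3, 3, n))
  s_v <- matrix(0, 3, 3)  # viscous deviatoric overstress
  for (i in seq_len(n)) {
    Fi <- history$F[, , i]
    dec <- decompose_deformation(Fi)
    J <- dec$J
    Bstar <- dec$Fstar %*% t(dec$Fstar)
    P <- params$K * (1 - J)                     # positive in compression
    sig_eq <- params$mu_eq / J * dev3(Bstar)    # neo-Hookean equilibrium
    if (i > 1L) {
      dt <- history$t[i] - history$t[i - 1L]
      D_dev <- dev3(rate_of_deformation(history, i))
      s_v <- maxwell_update(s_v, D_dev, params$mu_v, params$tau, dt)
    }
    s <- -P * I3 + sig_eq + s_v
    if (any(!is.finite(s)))
      stop(sprintf("numerical failure in stress update at step %d", i),
           call. = FALSE)
    sigma[, , i] <- sym3(s)
  }
  sigma
}

#' Grey-matter Cauchy stress history
#'
#' Integrates the isotropic grey-matter model along a deformation history:
#' volumetric law \eqn{P = K(1 - J)}, neo-Hookean equilibrium deviatoric
#' stress \eqn{\mu_{eq} \mathrm{dev}(B^*)/J}, and one Maxwell viscous branch
#' (modulus `mu_v`, relaxation time `tau`) integrated with an exponential-map
#' update — the branch captures the stiffened response of brain tissue at
#' blast strain rates and relaxes to the equilibrium response for slow
#' loading.
#'
#' @param history a [deformation_history()].
#' @param params a [grey_matter_params()].
#' @return a [stress_history()].
#' @examples
#' h <- make_deformation_history("simple_shear", rate = 1, amplitude = 1e-4,
#'                               duration = 1e-4, dt = 1e-5)
#' grey_stress(h, grey_matter_params())
#' @export
grey_stress <- function(history, params = grey_matter_params()) {
  stopifnot(inherits(history, "deformation_history"))
  if (!inherits(params, "grey_matter_params"))
    stop("'params' must be grey_matter_params", call. = FALSE)
  stress_history(history$t, iso_stress_states(history, params))
}

#' White-matter Cauchy stress history
#'
#' The isotropic grey backbone (same `K`, `mu_eq`, `mu_v`, `tau`) plus an
#' FA-weighted fibre reinforcement along the axonal tract direction:
#' \deqn{\sigma_f = \frac{2\,FA\,k_f}{J}\,(I_4 - 1)\; a_t \otimes a_t,}
#' with \eqn{I_4 = a_0 \cdot C a_0}, \eqn{C = F^T F}, and
#' \eqn{a_t = F a_0 / \|F a_0\|} the current fibre direction. The term is
#' active only in fibre tension (\eqn{I_4 > 1}); at `FA = 0` the grey
#' response is recovered exactly.
#'
#' @param history a [deformation_history()].
#' @param params a [white_matter_params()].
#' @return a [stress_history()].
#' @export
white_stress <- function(history, params = white_matter_params()) {
  stopifnot(inherits(history, "deformation_history"))
  if (!inherits(params, "white_matter_params"))
    stop("'params' must be white_matter_params", call. = FALSE)
  a0 <- unit_vector(params$a0, "a0")
  sigma <- iso_stress_states(history, params)
  n <- dim(sigma)[3]
  for (i in seq_len(n)) {
    Fi <- history$F[, , i]
    Fa <- as.numeric(Fi %*% a0)
    I4 <- sum(Fa^2)  # a0 . C a0
    if (I4 > 1) {
      J <- det(Fi)
      at <- Fa / sqrt(I4)
      sigma[, , i] <- sigma[, , i] +
        (2 * params$FA * params$k_f / J) * (I4 - 1) * tcrossprod(at)
    }
  }
  stress_history(history$t, sigma)
}
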