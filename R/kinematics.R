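# Finite-strain kinematics: deformation histories, the volumetric/deviatoric
# split of the deformation gradient, and rate-of-deformation tensors.

#' Deformation history at a material point
#'
#' A time-ordered sequence of 3x3 deformation gradients \eqn{F(t)} describing
#' the loading path of one material point. This is the kinematic input to the
#' constitutive models and all injury criteria.
#'
#' @param t numeric vector of strictly increasing, finite, non-negative
#'   times (s).
#' @param F either a 3x3xN numeric array or a list of N 3x3 matrices, one
#'   deformation gradient per time; every gradient must have positive
#'   determinant.
#' @return an object of class `deformation_history` with elements `t`
#'   (numeric vector) and `F` (3x3xN array).
#' @examples
#' h <- deformation_history(c(0, 1e-3), list(diag(3), diag(c(1.1, 1, 1))))
#' h
#' @seealso [make_deformation_history()] for analytic test load paths.
#' @export
deformation_history <- function(t, F) {
  if (is.list(F)) {
    F <- vapply(F, function(Fi) check_matrix3(Fi, "F"), matrix(0, 3, 3))
  }
  if (!is.array(F) || length(dim(F)) != 3L || !all(dim(F)[1:2] == 3L))
    stop("'F' must be a 3x3xN array or a list of 3x3 matrices", call. = FALSE)
  n <- dim(F)[3]
  if (!is.numeric(t) || length(t) != n)
    stop("'t' must be numeric with one entry per deformation state",
         call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (n > 1 && any(diff(t) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  dets <- apply(F, 3, det)
  if (any(dets <= 0))
    stop(sprintf("invalid deformation: det(F) <= 0 at state %d",
                 which(dets <= 0)[1]), call. = FALSE)
  structure(list(t = as.numeric(t), F = F), class = "deformation_history")
}

#' @export
print.deformation_history <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<deformation_history> %d states, t in [%g, %g] s\n",
              n, x$t[1], x$t[n]))
  J <- apply(x$F, 3, det)
  cat(sprintf("  J (volume ratio) range: [%.6g, %.6g]\n", min(J), max(J)))
  invisible(x)
}

#' @export
length.deformation_history <- function(x) length(x$t)

#' Volumetric/deviatoric split of a deformation gradient
#'
#' Multiplicatively decomposes \eqn{F = J^{1/3} F^*} into the volume ratio
#' \eqn{J = \det F} and the distortional (isochoric) part \eqn{F^*} with
#' \eqn{\det F^* = 1}.
#'
#' @param F numeric 3x3 deformation gradient, `det(F) > 0`.
#' @return list with elements `J` (scalar) and `Fstar` (3x3 matrix).
#' @examples
#' decompose_deformation(2 * diag(3))  # J = 8, Fstar = I
#' @export
decompose_deformation <- function(F) {
  check_matrix3(F, "F")
  J <- det(F)
  if (J <= 0)
    stop("invalid deformation: det(F) must be positive", call. = FALSE)
  list(J = J, Fstar = J^(-1 / 3) * F)
}

#' Rate-of-deformation tensor from a discrete history
#'
#' Backward-difference estimate of the rate of deformation
#' \eqn{D = \mathrm{sym}(\dot F F^{-1})} at state `index` of a history, using
#' the increment from state `index - 1`.
#'
#' @param history a [deformation_history()].
#' @param index integer state index, `2 <= index <= length(history)`.
#' @return symmetric 3x3 rate-of-deformation tensor (1/s).
#' @examples
#' h <- make_deformation_history("simple_shear", rate = 50, amplitude = 0.05,
#'                               duration = 1e-3, dt = 1e-4)
#' rate_of_deformation(h, 5)[1, 2]  # = 25/s
#' @export
rate_of_deformation <- function(history, index) {
  stopifnot(inherits(history, "deformation_history"))
  n <- length(history$t)
  index <- as.integer(index)
  if (is.na(index) || index < 2L || index > n)
    stop(sprintf("'index' must be in [2, %d]", n), call. = FALSE)
  dt <- history$t[index] - history$t[index - 1L]
  if (dt <= 0) stop("non-positive time increment", call. = FALSE)
  Fn <- history$F[, , index]
  dF <- Fn - history$F[, , index - 1L]
  sym3(dF %*% solve(Fn) / dt)
}

#' Rate-of-deformation tensors along a whole history
#'
#' @param history a [deformation_history()].
#' @return 3x3xN array of rate tensors; state 1 (no predecessor) is zero.
#' @export
rate_of_deformation_history <- function(history) {
  stopifnot(inherits(history, "deformation_history"))
  n <- length(history$t)
  D <- array(0, c(3, 3, n))
  if (n >= 2L)
    for (i in 2:n) D[, , i] <- rate_of_deformation(history, i)
  D
}
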