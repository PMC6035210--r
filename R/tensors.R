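# Small dense 3x3 tensor helpers shared across the package. All tensors are
# plain numeric 3x3 matrices in SI units; histories stack them along the
# third dimension of a 3x3xN array.

I3 <- diag(3)

#' @noRd
check_matrix3 <- function(A, name = "A") {
  if (!is.matrix(A) || !all(dim(A) == c(3L, 3L)) || !is.numeric(A))
    stop(sprintf("'%s' must be a numeric 3x3 matrix", name), call. = FALSE)
  if (any(!is.finite(A)))
    stop(sprintf("'%s' contains non-finite entries", name), call. = FALSE)
  invisible(A)
}

#' @noRd
check_symmetric <- function(A, name = "A", tol = 1e-8) {
  check_matrix3(A, name)
  scale <- max(abs(A), 1)
  if (max(abs(A - t(A))) > tol * scale)
    stop(sprintf("'%s' is not symmetric within tolerance", name), call. = FALSE)
  invisible((A + t(A)) / 2)
}

#' @noRd
sym3 <- function(A) (A + t(A)) / 2

#' @noRd
dev3 <- function(A) A - sum(diag(A)) / 3 * I3

#' Double contraction A:B of two 3x3 tensors
#' @noRd
ddot3 <- function(A, B) sum(A * B)

#' Hencky (logarithmic) strain of a deformation gradient
#'
#' Computes the spatial logarithmic strain \eqn{\epsilon = \frac{1}{2}\log(B)}
#' with \eqn{B = F F^T} the left Cauchy-Green tensor, via the symmetric
#' eigendecomposition of \eqn{B}.
#'
#' @param F numeric 3x3 deformation gradient with positive determinant.
#' @return symmetric 3x3 Hencky strain tensor (dimensionless).
#' @examples
#' hencky_strain(diag(c(1.2, 1/sqrt(1.2), 1/sqrt(1.2))))
#' @export
hencky_strain <- function(F) {
  check_matrix3(F, "F")
  if (det(F) <= 0)
    stop("invalid deformation: det(F) must be positive", call. = FALSE)
  B <- F %*% t(F)
  e <- eigen(sym3(B), symmetric = TRUE)
  e$vectors %*% diag(0.5 * log(e$values)) %*% t(e$vectors)
}

#' @noRd
unit_vector <- function(a, name = "a0", tol = 1e-8) {
  if (!is.numeric(a) || length(a) != 3L)
    stop(sprintf("'%s' must be a numeric 3-vector", name), call. = FALSE)
  n <- sqrt(sum(a^2))
  if (abs(n - 1) > tol)
    stop(sprintf("'%s' must be a unit vector (norm %.6g)", name, n),
         call. = FALSE)
  a / n
}
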