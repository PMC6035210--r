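# Voxelwise fibre orientation and fractional anisotropy from diffusion
# tensors, and nearest-voxel mapping of a tensor field onto material points —
# the same per-node extraction a finite-element head model performs on DTI
# data.

check_diffusion_tensor <- function(D) {
  D <- check_symmetric(D, "D", tol = 1e-6)
  D
}

#' Principal fibre direction of a diffusion tensor
#'
#' Unit eigenvector of the largest eigenvalue — the preferred axon
#' orientation of the voxel. The sign is fixed so that the first non-zero
#' component is positive; for degenerate (isotropic) tensors the tie-break
#' deterministically returns the x axis.
#'
#' @param D symmetric 3x3 diffusion tensor (mm^2/s).
#' @return unit 3-vector.
#' @examples
#' principal_direction(diag(c(3, 1, 1)) * 1e-3)
#' @export
principal_direction <- function(D) {
  D <- check_diffusion_tensor(D)
  if (all(abs(D) == 0))
    stop("undefined direction: all-zero diffusion tensor", call. = FALSE)
  e <- eigen(D, symmetric = TRUE)
  # isotropic / degenerate leading eigenvalue: documented tie-break (x axis)
  if (abs(e$values[1] - e$values[2]) <= 1e-12 * max(abs(e$values), 1e-300))
    return(c(1, 0, 0))
  v <- e$vectors[, 1]
  nz <- which(abs(v) > 1e-12)[1]
  if (!is.na(nz) && v[nz] < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Fractional anisotropy of a diffusion tensor
#'
#' \deqn{FA = \sqrt{3/2}\;\frac{\|\lambda - \bar\lambda\|}{\|\lambda\|}}
#' over the eigenvalues \eqn{\lambda}. Negative eigenvalues (noise) are
#' clipped to zero first and the result is clamped to `[0, 1]`; the all-zero
#' tensor has FA defined as 0.
#'
#' @param D symmetric 3x3 diffusion tensor (mm^2/s).
#' @return scalar in `[0, 1]`.
#' @examples
#' fractional_anisotropy(diag(c(1.7, 0.3, 0.2)) * 1e-3)
#' @export
fractional_anisotropy <- function(D) {
  D <- check_diffusion_tensor(D)
  lam <- pmax(eigen(D, symmetric = TRUE, only.values = TRUE)$values, 0)
  nrm <- sqrt(sum(lam^2))
  if (nrm == 0) return(0)
  fa <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / nrm
  min(max(fa, 0), 1)
}

#' Voxel tensor field container
#'
#' A regular voxel grid of diffusion tensors. Voxel indices are 0-based and
#' the world coordinate of a voxel centre is `origin + (index + 0.5) *
#' spacing`.
#'
#' @param dims integer 3-vector of voxel counts per axis.
#' @param tensors either a `prod(dims) x 6` matrix of unique tensor
#'   components (columns Dxx, Dyy, Dzz, Dxy, Dxz, Dyz; voxel order x
#'   fastest) or a 3x3x`prod(dims)` array.
#' @param origin world coordinates of the grid corner (length 3).
#' @param spacing voxel edge lengths (length 3, positive).
#' @return object of class `fiber_field`.
#' @export
fiber_field <- function(dims, tensors, origin = c(0, 0, 0),
                        spacing = c(1, 1, 1)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("'dims' must be three positive voxel counts", call. = FALSE)
  nvox <- prod(dims)
  if (is.array(tensors) && length(dim(tensors)) == 3L) {
    if (dim(tensors)[3] != nvox)
      stop("tensor count does not match grid dimensions", call. = FALSE)
    comp <- t(apply(tensors, 3, function(M)
      c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])))
  } else {
    comp <- as.matrix(tensors)
    if (nrow(comp) != nvox || ncol(comp) != 6L)
      stop(sprintf("'tensors' must be a %d x 6 matrix for a %dx%dx%d grid",
                   nvox, dims[1], dims[2], dims[3]), call. = FALSE)
  }
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive lengths", call. = FALSE)
  structure(list(dims = dims, components = comp,
                 origin = as.numeric(origin), spacing = as.numeric(spacing)),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("<fiber_field> %dx%dx%d voxels, spacing (%g, %g, %g)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @noRd
field_tensor <- function(field, linear_index) {
  v <- field$components[linear_index, ]
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Map a voxel tensor field onto material points
#'
#' Each point receives the diffusion tensor of its nearest voxel centre
#' (no interpolation, matching per-node voxelwise extraction), then the
#' principal direction and FA of that tensor. A point exactly on the
#' midplane between voxels is assigned to the lower-index voxel.
#'
#' @param field a [fiber_field()].
#' @param points numeric `n x 3` matrix of world coordinates.
#' @param outside how to treat points outside the grid bounding box:
#'   `"error"` (default) or `"nearest"` (clamp to the nearest edge voxel).
#' @return data frame with columns `point` (row index), `a0x`, `a0y`, `a0z`
#'   (unit fibre direction) and `FA`.
#' @export
map_field_to_points <- function(field, points, outside = c("error", "nearest")) {
  stopifnot(inherits(field, "fiber_field"))
  outside <- match.arg(outside)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("'points' must be an n x 3 coordinate matrix", call. = FALSE)
  if (nrow(points) == 0L)
    return(data.frame(point = integer(), a0x = numeric(), a0y = numeric(),
                      a0z = numeric(), FA = numeric()))
  lo <- field$origin
  hi <- field$origin + field$dims * field$spacing
  out <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    if (any(p < lo) || any(p > hi)) {
      if (outside == "error")
        stop(sprintf("point %d lies outside the voxel grid bounding box", i),
             call. = FALSE)
      p <- pmin(pmax(p, lo), hi)
    }
    # nearest voxel centre; midplane ties go to the lower index
    # (round-half-down of the fractional index (p - lo)/spacing - 0.5)
    idx <- ceiling((p - lo) / field$spacing - 1)
    idx <- pmin(pmax(idx, 0), field$dims - 1L)
    lin <- 1L + idx[1] + field$dims[1] * (idx[2] + field$dims[2] * idx[3])
    D <- field_tensor(field, lin)
    a0 <- principal_direction(D)
    out[[i]] <- data.frame(point = i, a0x = a0[1], a0y = a0[2], a0z = a0[3],
                           FA = fractional_anisotropy(D))
  }
  do.call(rbind, out)
}

#' Read / write a voxel tensor field as CSV
#'
#' Columns: `i`, `j`, `k` (0-based voxel indices), `Dxx`, `Dyy`, `Dzz`,
#' `Dxy`, `Dxz`, `Dyz`. Grid geometry is given as arguments (CSV carries
#' only indices and components); every voxel of the grid must be present.
#'
#' @param path CSV file path.
#' @param dims,origin,spacing grid geometry as in [fiber_field()].
#' @return a [fiber_field()].
#' @export
read_fiber_field <- function(path, dims, origin = c(0, 0, 0),
                             spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("i", "j", "k", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed fiber field CSV, missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  dims <- as.integer(dims)
  lin <- 1L + df$i + dims[1] * (df$j + dims[2] * df$k)
  if (anyDuplicated(lin) || length(lin) != prod(dims) ||
      any(lin < 1L) || any(lin > prod(dims)))
    stop(sprintf("fiber field CSV does not cover the %dx%dx%d grid exactly (first bad row: %d)",
                 dims[1], dims[2], dims[3],
                 which(duplicated(lin) | lin < 1L | lin > prod(dims))[1]),
         call. = FALSE)
  comp <- matrix(0, prod(dims), 6)
  comp[lin, ] <- as.matrix(df[, c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")])
  fiber_field(dims, comp, origin, spacing)
}

#' @rdname read_fiber_field
#' @param field a [fiber_field()] to write.
#' @export
write_fiber_field <- function(field, path) {
  stopifnot(inherits(field, "fiber_field"))
  d <- field$dims
  idx <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  df <- cbind(idx, as.data.frame(field$components))
  names(df)[4:9] <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
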