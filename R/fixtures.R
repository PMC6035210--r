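# Synthetic input generators: analytic material-point load paths, random
# voxel tensor fields standing in for DTI acquisitions, and preset layered
# head columns.

#' Analytic deformation-gradient test loads
#'
#' Generates a [deformation_history()] for a canonical loading mode sampled
#' at constant time step:
#' \describe{
#'   \item{uniaxial}{isochoric uniaxial stretch: `F = diag(l, 1/sqrt(l),
#'     1/sqrt(l))` with `l = 1 + rate * t` up to `1 + amplitude`
#'     (`det F = 1` at every sample).}
#'   \item{simple_shear}{`F[1,2] = gamma = rate * t` up to `amplitude`.}
#'   \item{dilatation}{`F = J^(1/3) I` with `J = 1 + rate * t` ramped to
#'     `amplitude` (the target `J`; `amplitude = 1` gives a constant
#'     identity history).}
#'   \item{fiber_stretch}{uniaxial (non-isochoric) stretch along `a0`:
#'     `F = I + (l - 1) a0 a0^T`.}
#' }
#' After the ramp reaches `amplitude` the deformation is held constant
#' until `duration` (permitting relaxation studies).
#'
#' @param mode one of `"uniaxial"`, `"simple_shear"`, `"dilatation"`,
#'   `"fiber_stretch"`.
#' @param rate loading rate (1/s), positive.
#' @param amplitude target stretch/shear/volume ratio (mode-dependent).
#' @param duration total history duration (s).
#' @param dt sample spacing (s), `dt < duration`.
#' @param a0 unit stretch direction for `fiber_stretch`.
#' @return a [deformation_history()].
#' @examples
#' make_deformation_history("simple_shear", rate = 1000, amplitude = 1,
#'                          duration = 1e-3, dt = 1e-5)
#' @export
make_deformation_history <- function(mode = c("uniaxial", "simple_shear",
                                              "dilatation", "fiber_stretch"),
                                     rate, amplitude, duration, dt,
                                     a0 = c(1, 0, 0)) {
  mode <- match.arg(mode)
  if (!is.numeric(rate) || rate <= 0) stop("'rate' must be positive",
                                           call. = FALSE)
  if (dt >= duration) stop("'dt' must be smaller than 'duration'",
                           call. = FALSE)
  tt <- seq(0, duration, by = dt)
  ramp_target <- switch(mode,
    uniaxial = ,
    fiber_stretch = amplitude,            # extra stretch beyond 1
    simple_shear = amplitude,             # target shear strain
    dilatation = amplitude - 1)           # extra volume ratio beyond 1
  prog <- pmin(rate * tt, abs(ramp_target)) * sign(ramp_target)
  if (mode == "fiber_stretch") a0 <- unit_vector(a0, "a0")
  Fs <- array(0, c(3, 3, length(tt)))
  for (i in seq_along(tt)) {
    g <- prog[i]
    Fs[, , i] <- switch(mode,
      uniaxial = diag(c(1 + g, 1 / sqrt(1 + g), 1 / sqrt(1 + g))),
      simple_shear = {
        Fm <- diag(3); Fm[1, 2] <- g; Fm
      },
      dilatation = (1 + g)^(1 / 3) * diag(3),
      fiber_stretch = diag(3) + g * tcrossprod(a0))
  }
  deformation_history(tt, Fs)
}

#' Synthetic voxel diffusion-tensor field
#'
#' Generates a reproducible `n x n x n` voxel field of prolate diffusion
#' tensors with prescribed fractional anisotropy, standing in for a DTI
#' acquisition. Each voxel gets a random unit fibre direction and a tensor
#' `lam1 a a^T + lam2 (I - a a^T)` whose eigenvalue pair realises the FA
#' drawn from the spec.
#'
#' @param n voxels per axis (`n >= 1`).
#' @param fa_spec either a single FA value in `[0, 1)` applied to every
#'   voxel, or `list(mean =, sd =)` for truncated-normal draws (FA = 1 uses
#'   rank-one tensors).
#' @param seed integer seed; the same seed yields a bit-identical field.
#' @param mean_diffusivity trace/3 of each tensor (mm^2/s).
#' @param spacing voxel edge length (grid is cubic, origin at 0).
#' @return a [fiber_field()].
#' @examples
#' f <- make_fiber_field(4, fa_spec = 0.6, seed = 1)
#' @export
make_fiber_field <- function(n, fa_spec = 0.5, seed = 1L,
                             mean_diffusivity = 0.7e-3, spacing = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1", call. = FALSE)
  nvox <- n^3
  set.seed(as.integer(seed))
  if (is.numeric(fa_spec) && length(fa_spec) == 1L) {
    if (fa_spec < 0 || fa_spec > 1) stop("FA must lie in [0, 1]",
                                         call. = FALSE)
    fa <- rep(fa_spec, nvox)
  } else if (is.list(fa_spec) && !is.null(fa_spec$mean)) {
    fa <- stats::rnorm(nvox, fa_spec$mean, fa_spec$sd %||% 0.1)
    fa <- pmin(pmax(fa, 0), 0.999)
  } else stop("invalid 'fa_spec'", call. = FALSE)
  # random unit directions
  dirs <- matrix(stats::rnorm(3 * nvox), nvox, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  comp <- matrix(0, nvox, 6)
  for (v in seq_len(nvox)) {
    # prolate (lam1, lam2, lam2) with FA = (lam1-lam2)/sqrt(lam1^2+2*lam2^2)
    # * sqrt(... ) solved via the axial ratio
    f <- fa[v]
    if (f >= 1) {
      lam1 <- 3 * mean_diffusivity; lam2 <- 0
    } else {
      # solve r = lam2/lam1 from FA of (1, r, r)
      # FA^2 = (2/3)*( (1-r)^2 * 2 ... ) use closed form:
      # FA = (1 - r) / sqrt(1 + 2 r^2) * 1 ... derive numerically
      g <- function(r) fractional_anisotropy(diag(c(1, r, r))) - f
      r <- if (f == 0) 1 else stats::uniroot(g, c(0, 1), tol = 1e-12)$root
      lam1 <- 3 * mean_diffusivity / (1 + 2 * r)
      lam2 <- r * lam1
    }
    a <- dirs[v, ]
    D <- lam1 * tcrossprod(a) + lam2 * (diag(3) - tcrossprod(a))
    comp[v, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }
  fiber_field(c(n, n, n), comp, origin = c(0, 0, 0),
              spacing = rep(spacing, 3))
}

#' Preset layered head columns
#'
#' Layer stacks for the 1-D wave solver, ordered outside-in. Thicknesses are
#' package defaults chosen at anatomical scale:
#' \describe{
#'   \item{rat_like}{skin/fat 1 mm, skull 0.7 mm, CSF 0.3 mm, grey brain
#'     8 mm (planar by default).}
#'   \item{human_like}{skin 5 mm, skull 7 mm, CSF 3 mm, homogenised
#'     (grey-model) brain 60 mm, fluid ventricle core 15 mm; spherical with
#'     the column reaching the centre.}
#'   \item{shielded_human}{`human_like` with a 10 mm polycarbonate shield
#'     prepended; the shield's two-region layout (central region diameter
#'     1/3 of the shield diameter) is handled by [shield_sweep()].}
#' }
#'
#' @param preset `"rat_like"`, `"human_like"` or `"shielded_human"`.
#' @param materials material library as from [default_materials()].
#' @param refine multiplier on the default per-layer element counts.
#' @param shield_material material block for the shield layer
#'   (`shielded_human` only); defaults to polycarbonate.
#' @return a [column_geometry()].
#' @examples
#' make_toy_head("human_like")
#' @export
make_toy_head <- function(preset = c("human_like", "rat_like",
                                     "shielded_human"),
                          materials = default_materials(), refine = 1,
                          shield_material = NULL) {
  preset <- match.arg(preset)
  ne <- function(k) max(2L, as.integer(round(k * refine)))
  if (preset == "rat_like") {
    lys <- list(
      layer("skin", 1e-3, materials$skin, ne(8)),
      layer("skull", 0.7e-3, materials$skull, ne(6)),
      layer("csf", 0.3e-3, materials$csf, ne(4)),
      layer("brain", 8e-3, materials$grey, ne(60)))
    return(column_geometry(lys, symmetry = "planar", inner_bc = "free"))
  }
  head_layers <- list(
    layer("skin", 5e-3, materials$skin, ne(12)),
    layer("skull", 7e-3, materials$skull, ne(16)),
    layer("csf", 3e-3, materials$csf, ne(8)),
    layer("brain", 60e-3, materials$grey, ne(150)),
    layer("ventricle", 15e-3, materials$ventricle, ne(20)))
  if (preset == "human_like")
    return(column_geometry(head_layers, symmetry = "spherical",
                           inner_bc = "fixed_center"))
  if (is.null(shield_material)) shield_material <- materials$polycarbonate
  column_geometry(c(list(layer("shield", 10e-3, shield_material, ne(20))),
                    head_layers),
                  symmetry = "spherical", inner_bc = "fixed_center")
}
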