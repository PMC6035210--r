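# Material parameter containers for brain tissue and the passive head/shield
# layers, plus YAML-backed material libraries. SI units throughout.

#' Grey-matter constitutive parameters
#'
#' Parameters of the isotropic grey-matter model: a volumetric law
#' \eqn{P = K(1 - J)} (pressure positive in compression), a neo-Hookean
#' equilibrium shear response on the distortional deformation, and a single
#' Maxwell viscous branch giving the rate stiffening observed in brain
#' tissue between low- and high-rate loading.
#'
#' Defaults are documented placeholder values for near-incompressible brain
#' tissue; all of them can be overridden, e.g. from a YAML material file via
#' [read_materials()].
#'
#' @param rho density (kg/m^3).
#' @param K bulk modulus (Pa); orders of magnitude above the shear moduli
#'   (near-incompressibility).
#' @param mu_eq equilibrium (long-time) shear modulus (Pa).
#' @param mu_v viscous-branch shear modulus (Pa); controls rate stiffening.
#' @param tau relaxation time of the viscous branch (s).
#' @return object of class `grey_matter_params`.
#' @examples
#' grey_matter_params()
#' @export
grey_matter_params <- function(rho = 1040, K = 2.19e9, mu_eq = 1e3,
                               mu_v = 5e3, tau = 1e-4) {
  p <- list(rho = rho, K = K, mu_eq = mu_eq, mu_v = mu_v, tau = tau)
  bad <- names(p)[vapply(p, function(x)
    !is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0, TRUE)]
  if (length(bad))
    stop("material parameters must be positive scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (K <= 10 * mu_eq)
    stop("'K' must greatly exceed 'mu_eq' (near-incompressibility)",
         call. = FALSE)
  structure(p, class = "grey_matter_params")
}

#' White-matter constitutive parameters
#'
#' Extends [grey_matter_params()] with a transversely isotropic fibre
#' reinforcement along the local axonal tract direction, weighted by the
#' fractional anisotropy (FA) extracted from diffusion-tensor imaging. The
#' fibre term acts only in fibre tension (axons carry no compressive
#' reinforcement).
#'
#' @inheritParams grey_matter_params
#' @param a0 unit reference fibre (axon) direction, numeric 3-vector.
#' @param FA fractional anisotropy in `[0, 1]`; `FA = 0` recovers the grey
#'   (isotropic) response exactly.
#' @param k_f fibre reinforcement modulus (Pa), `>= 0`.
#' @return object of class `white_matter_params` (also inherits
#'   `grey_matter_params`).
#' @examples
#' white_matter_params(a0 = c(0, 0, 1), FA = 0.7)
#' @export
white_matter_params <- function(rho = 1040, K = 2.19e9, mu_eq = 1e3,
                                mu_v = 5e3, tau = 1e-4,
                                a0 = c(1, 0, 0), FA = 0.5, k_f = 2e3) {
  base <- grey_matter_params(rho, K, mu_eq, mu_v, tau)
  a0 <- unit_vector(a0, "a0")
  if (!is.numeric(FA) || length(FA) != 1L || is.na(FA) || FA < 0 || FA > 1)
    stop("'FA' must be a scalar in [0, 1]", call. = FALSE)
  if (!is.numeric(k_f) || length(k_f) != 1L || is.na(k_f) || k_f < 0)
    stop("'k_f' must be a non-negative scalar", call. = FALSE)
  structure(c(unclass(base), list(a0 = a0, FA = FA, k_f = k_f)),
            class = c("white_matter_params", "grey_matter_params"))
}

#' @export
print.grey_matter_params <- function(x, ...) {
  kind <- if (inherits(x, "white_matter_params")) "white" else "grey"
  cat(sprintf("<%s_matter_params> rho=%g kg/m^3, K=%g Pa, mu_eq=%g Pa, mu_v=%g Pa, tau=%g s\n",
              kind, x$rho, x$K, x$mu_eq, x$mu_v, x$tau))
  if (kind == "white")
    cat(sprintf("  a0=(%g, %g, %g), FA=%g, k_f=%g Pa\n",
                x$a0[1], x$a0[2], x$a0[3], x$FA, x$k_f))
  invisible(x)
}

#' Built-in material library
#'
#' Named material blocks for the layered head and shield models: brain grey
#' and white matter, skull, skin/fat, CSF (acoustic fluid) and polycarbonate
#' (the blast-visor reference material of the shield study). Values are
#' conventional handbook-scale defaults in SI units, intended as starting
#' points and overridable via [read_materials()].
#'
#' @return named list of material blocks. Brain blocks are parameter objects;
#'   passive layers are lists with `type` (`"elastic"` or `"fluid"`) and the
#'   moduli/density used by the wave solver.
#' @examples
#' names(default_materials())
#' @export
default_materials <- function() {
  list(
    grey  = grey_matter_params(),
    white = white_matter_params(),
    skull = list(type = "elastic", E = 6.5e9, rho = 1700),
    skin  = list(type = "elastic", E = 2.0e7, rho = 1100),
    csf   = list(type = "fluid", K = 2.19e9, rho = 1000),
    ventricle = list(type = "fluid", K = 2.19e9, rho = 1000),
    polycarbonate = list(type = "elastic", E = 2.4e9, rho = 1200)
  )
}

#' Read a material library from YAML
#'
#' The file holds named material blocks in SI units. Blocks named `grey` /
#' `white` are converted to [grey_matter_params()] /
#' [white_matter_params()]; other blocks must carry a `type` field
#' (`elastic` with `E`, `rho`; `fluid` with `K`, `rho`). Missing brain
#' parameters fall back to the package defaults.
#'
#' @param path path to a YAML file.
#' @return named list as in [default_materials()].
#' @export
read_materials <- function(path) {
  if (!file.exists(path))
    stop("material file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)))
    stop("material file must contain named material blocks: ", path,
         call. = FALSE)
  out <- default_materials()
  for (nm in names(raw)) {
    blk <- raw[[nm]]
    if (nm == "grey") {
      out$grey <- do.call(grey_matter_params,
                          blk[intersect(names(blk),
                                        c("rho", "K", "mu_eq", "mu_v", "tau"))])
    } else if (nm == "white") {
      keep <- intersect(names(blk),
                        c("rho", "K", "mu_eq", "mu_v", "tau", "a0", "FA", "k_f"))
      blk$a0 <- if (!is.null(blk$a0)) as.numeric(blk$a0)
      out$white <- do.call(white_matter_params, blk[keep])
    } else {
      if (is.null(blk$type))
        stop(sprintf("material block '%s' lacks a 'type' field", nm),
             call. = FALSE)
      for (fld in intersect(names(blk), c("E", "rho", "K")))
        blk[[fld]] <- as.numeric(blk[[fld]])
      out[[nm]] <- blk
    }
  }
  out
}
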