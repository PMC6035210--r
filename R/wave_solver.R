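# Explicit 1-D Lagrangian wave solver for layered shield/skull/CSF/brain
# columns, in planar or spherically symmetric mode — the desk-scale
# surrogate for a concentric-sphere head model. Central-difference time
# stepping with lumped masses and standard linear+quadratic artificial
# viscosity for shock capture.

#' Acoustic impedance and wave speed of a linear material
#'
#' @param E stiffness modulus (Pa); for the 1-D solver this is the
#'   longitudinal modulus governing plane-wave propagation.
#' @param rho density (kg/m^3).
#' @return list with `impedance` = sqrt(E rho) (Pa s/m) and `wave_speed` =
#'   sqrt(E/rho) (m/s).
#' @examples
#' acoustic_properties(2.4e9, 1200)  # polycarbonate
#' @export
acoustic_properties <- function(E, rho) {
  if (any(!is.finite(c(E, rho))) || E <= 0 || rho <= 0)
    stop("'E' and 'rho' must be positive", call. = FALSE)
  list(impedance = sqrt(E * rho), wave_speed = sqrt(E / rho))
}

#' Stress transmission coefficient across an interface
#'
#' For a normally incident stress wave crossing from medium 1 into medium 2:
#' \eqn{T = 2 Z_2 / (Z_1 + Z_2)}.
#'
#' @param Z1,Z2 acoustic impedances (Pa s/m) of the incident and
#'   transmitting media.
#' @return dimensionless stress-transmission factor.
#' @examples
#' transmission_coefficient(1e6, 3e6)  # 1.5
#' @export
transmission_coefficient <- function(Z1, Z2) {
  if (any(!is.finite(c(Z1, Z2))) || Z1 <= 0 || Z2 <= 0)
    stop("impedances must be positive", call. = FALSE)
  2 * Z2 / (Z1 + Z2)
}

#' Column layer
#'
#' One layer of a 1-D head/shield column, listed outside-in.
#'
#' @param name layer name (e.g. `"skull"`, `"brain"`).
#' @param thickness layer thickness (m), positive.
#' @param material a material block: `list(type = "elastic", E, rho)`,
#'   `list(type = "fluid", K, rho)` (zero shear), a [grey_matter_params()]
#'   or a [white_matter_params()] (fibres taken along the propagation
#'   direction).
#' @param elements number of elements across the layer.
#' @return object of class `column_layer`.
#' @export
layer <- function(name, thickness, material, elements = 20L) {
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single string", call. = FALSE)
  if (!is.numeric(thickness) || thickness <= 0 || !is.finite(thickness))
    stop("'thickness' must be positive", call. = FALSE)
  elements <- as.integer(elements)
  if (is.na(elements) || elements < 1L)
    stop("'elements' must be a positive integer", call. = FALSE)
  mat <- normalise_material(material)
  structure(list(name = name, thickness = thickness, material = mat,
                 elements = elements), class = "column_layer")
}

normalise_material <- function(material) {
  if (inherits(material, "white_matter_params"))
    return(list(type = "white", params = material))
  if (inherits(material, "grey_matter_params"))
    return(list(type = "grey", params = material))
  if (!is.list(material) || is.null(material$type))
    stop("material must carry a 'type' or be brain matter params",
         call. = FALSE)
  if (material$type %in% c("grey", "white")) {
    if (is.null(material$params))
      material$params <- if (material$type == "grey") grey_matter_params()
                         else white_matter_params()
    return(material[c("type", "params")])
  }
  if (material$type == "elastic") {
    if (is.null(material$E) || is.null(material$rho) ||
        material$E <= 0 || material$rho <= 0)
      stop("elastic material needs positive 'E' and 'rho'", call. = FALSE)
    return(material[c("type", "E", "rho")])
  }
  if (material$type == "fluid") {
    if (is.null(material$K) || is.null(material$rho) ||
        material$K <= 0 || material$rho <= 0)
      stop("fluid material needs positive 'K' and 'rho'", call. = FALSE)
    return(material[c("type", "K", "rho")])
  }
  stop("unknown material type: ", material$type, call. = FALSE)
}

#' Layered column geometry
#'
#' @param layers list of [layer()]s ordered outside-in (the blast-facing
#'   layer first).
#' @param symmetry `"planar"` or `"spherical"`. In spherical mode the
#'   outermost surface sits at `outer_radius` and the column extends inward;
#'   if the layers reach the centre the central node is held fixed by
#'   symmetry.
#' @param inner_bc boundary condition at the inner end: `"fixed_center"`,
#'   `"free"` or (planar only) `"non_reflecting"`.
#' @param outer_radius outer radius (m) for spherical mode; defaults to the
#'   total layer thickness (column reaching the centre).
#' @return object of class `column_geometry`.
#' @export
column_geometry <- function(layers, symmetry = c("planar", "spherical"),
                            inner_bc = c("fixed_center", "free",
                                         "non_reflecting"),
                            outer_radius = NULL) {
  symmetry <- match.arg(symmetry)
  inner_bc <- match.arg(inner_bc)
  if (inherits(layers, "column_layer")) layers <- list(layers)
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "column_layer")))
    stop("'layers' must be a non-empty list of column layers", call. = FALSE)
  total <- sum(vapply(layers, `[[`, 0, "thickness"))
  if (symmetry == "spherical") {
    if (is.null(outer_radius)) outer_radius <- total
    if (outer_radius <= 0 || outer_radius < total - 1e-12)
      stop("'outer_radius' must be positive and at least the total thickness",
           call. = FALSE)
    if (inner_bc == "non_reflecting")
      stop("non-reflecting inner boundary is a planar-mode option",
           call. = FALSE)
  }
  structure(list(layers = layers, symmetry = symmetry, inner_bc = inner_bc,
                 outer_radius = outer_radius, total_thickness = total),
            class = "column_geometry")
}

#' @export
print.column_geometry <- function(x, ...) {
  cat(sprintf("<column_geometry> %s, %d layers, total thickness %.4g m\n",
              x$symmetry, length(x$layers), x$total_thickness))
  for (ly in x$layers)
    cat(sprintf("  %-14s %8.4g m  %-8s %d elements\n",
                ly$name, ly$thickness, ly$material$type, ly$elements))
  invisible(x)
}

#' Explicit solver configuration
#'
#' @param total_time simulated time (s).
#' @param cfl Courant safety factor in `(0, 1]` (default 0.9).
#' @param av_linear,av_quadratic linear and quadratic artificial-viscosity
#'   coefficients (defaults 0.06, 1.5).
#' @param output_stride record every `output_stride`-th step (default 1).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(total_time, cfl = 0.9, av_linear = 0.06,
                          av_quadratic = 1.5, output_stride = 1L) {
  if (!is.numeric(total_time) || total_time <= 0)
    stop("'total_time' must be positive", call. = FALSE)
  if (!is.numeric(cfl) || cfl <= 0 || cfl > 1)
    stop("'cfl' must lie in (0, 1]", call. = FALSE)
  structure(list(total_time = total_time, cfl = cfl, av_linear = av_linear,
                 av_quadratic = av_quadratic,
                 output_stride = max(1L, as.integer(output_stride))),
            class = "solver_config")
}

# Flatten geometry into per-element property vectors.
discretise_column <- function(geometry) {
  nel <- sum(vapply(geometry$layers, `[[`, 0L, "elements"))
  type <- integer(nel)   # 1 elastic, 2 fluid, 3 grey, 4 white
  E <- K <- rho <- mu_eq <- mu_v <- tau <- FAkf <- numeric(nel)
  lname <- character(nel)
  pos <- 1L
  for (ly in geometry$layers) {
    m <- ly$material
    idx <- pos:(pos + ly$elements - 1L)
    lname[idx] <- ly$name
    tcode <- switch(m$type, elastic = 1L, fluid = 2L, grey = 3L, white = 4L)
    type[idx] <- tcode
    if (tcode == 1L) { E[idx] <- m$E; rho[idx] <- m$rho }
    if (tcode == 2L) { K[idx] <- m$K; rho[idx] <- m$rho }
    if (tcode >= 3L) {
      p <- m$params
      K[idx] <- p$K; rho[idx] <- p$rho
      mu_eq[idx] <- p$mu_eq; mu_v[idx] <- p$mu_v; tau[idx] <- p$tau
      FAkf[idx] <- if (tcode == 4L) p$FA * p$k_f else 0
    }
    pos <- pos + ly$elements
  }
  # node depths
  depth <- numeric(nel + 1L)
  pos <- 1L
  x0 <- 0
  for (ly in geometry$layers) {
    dx <- ly$thickness / ly$elements
    depth[(pos + 1L):(pos + ly$elements)] <- x0 + dx * seq_len(ly$elements)
    x0 <- x0 + ly$thickness
    pos <- pos + ly$elements
  }
  c_wave <- ifelse(type == 1L, sqrt(E / rho),
            ifelse(type == 2L, sqrt(K / rho),
                   sqrt((K + 4 / 3 * (mu_eq + mu_v)) / rho)))
  list(n = nel, type = type, E = E, K = K, rho = rho, mu_eq = mu_eq,
       mu_v = mu_v, tau = tau, FAkf = FAkf, layer = lname,
       depth = depth, c_wave = c_wave)
}

# Vectorised constitutive update for all elements. Diagonal kinematics:
# F = diag(lam_r, lam_t, lam_t). Returns axial/hoop Cauchy stress and the
# updated Maxwell overstress state.
column_stress <- function(mesh, lam_r, lam_t, D_r, D_t, sv_r, sv_t, dt) {
  J <- lam_r * lam_t^2
  sig_r <- numeric(mesh$n)
  sig_t <- numeric(mesh$n)
  el <- mesh$type == 1L
  if (any(el)) {
    sig_r[el] <- mesh$E[el] * log(lam_r[el])
    sig_t[el] <- mesh$E[el] * log(lam_t[el])
  }
  fl <- mesh$type == 2L
  if (any(fl)) {
    P <- mesh$K[fl] * (1 - J[fl])
    sig_r[fl] <- -P
    sig_t[fl] <- -P
  }
  br <- mesh$type >= 3L
  if (any(br)) {
    Jb <- J[br]
    Jm23 <- Jb^(-2 / 3)
    bsr <- lam_r[br]^2 * Jm23
    bst <- lam_t[br]^2 * Jm23
    trb <- bsr + 2 * bst
    P <- mesh$K[br] * (1 - Jb)
    seq_r <- mesh$mu_eq[br] / Jb * (bsr - trb / 3)
    seq_t <- mesh$mu_eq[br] / Jb * (bst - trb / 3)
    # Maxwell branch, exponential update on the deviatoric rate
    ddiff <- D_r[br] - D_t[br]
    Ddev_r <- 2 / 3 * ddiff
    Ddev_t <- -1 / 3 * ddiff
    ex <- exp(-dt / mesh$tau[br])
    g <- 2 * mesh$mu_v[br] * mesh$tau[br] * (1 - ex)
    sv_r[br] <- ex * sv_r[br] + g * Ddev_r
    sv_t[br] <- ex * sv_t[br] + g * Ddev_t
    sig_r[br] <- -P + seq_r + sv_r[br]
    sig_t[br] <- -P + seq_t + sv_t[br]
    wh <- mesh$type == 4L
    if (any(wh)) {
      I4 <- lam_r[wh]^2
      fib <- ifelse(I4 > 1, 2 * mesh$FAkf[wh] / J[wh] * (I4 - 1), 0)
      sig_r[wh] <- sig_r[wh] + fib
    }
  }
  list(sig_r = sig_r, sig_t = sig_t, sv_r = sv_r, sv_t = sv_t)
}

#' Solve a layered 1-D column under blast loading
#'
#' Explicit central-difference Lagrangian time stepping. The blast
#' overpressure is applied as a compressive traction at the outer surface;
#' fluid layers carry zero shear; spherical mode includes the geometric
#' focusing of a converging wave. The stable step is
#' `dt = cfl * min(dx / c)` over elements; a runtime CFL violation or a
#' non-finite field aborts with the step number.
#'
#' @param geometry a [column_geometry()].
#' @param load a [blast_profile()], a function of time returning the applied
#'   overpressure (Pa), or a constant (Pa).
#' @param config a [solver_config()].
#' @return object of class `field_history`: element-wise time series of
#'   axial/hoop stretch (`lam_r`, `lam_t`) and Cauchy stress (`sig_r`,
#'   `sig_t`, Pa), the output time base `t`, element reference positions,
#'   layer names, node position history and an `energy` data frame of
#'   conservation diagnostics (external work, kinetic, internal,
#'   artificial-viscosity dissipation, energy absorbed at a non-reflecting
#'   boundary; all per unit reference area — or per steradian in spherical
#'   mode).
#' @examples
#' col <- column_geometry(list(
#'   layer("bar", 0.1, list(type = "elastic", E = 1e9, rho = 1000), 50)),
#'   symmetry = "planar", inner_bc = "free")
#' fh <- solve_column(col, blast_profile(1e5, td = 2e-5, b = 1),
#'                    solver_config(5e-5))
#' fh
#' @export
solve_column <- function(geometry, load, config) {
  stopifnot(inherits(geometry, "column_geometry"),
            inherits(config, "solver_config"))
  pfun <- if (inherits(load, "blast_profile")) load$pressure
          else if (is.function(load)) load
          else function(t) rep(as.numeric(load), length(t))
  mesh <- discretise_column(geometry)
  n <- mesh$n
  spherical <- geometry$symmetry == "spherical"

  # reference coordinates: node depths; spherical nodes at radius R - depth
  if (spherical) {
    r0 <- geometry$outer_radius - mesh$depth
    if (min(r0) < -1e-12 * geometry$outer_radius)
      stop("layers extend past the centre", call. = FALSE)
    r0 <- pmax(r0, 0)
  }
  L0 <- diff(mesh$depth)
  vol0 <- if (spherical) (r0[-(n + 1L)]^3 - r0[-1L]^3) / 3 else L0
  m_el <- mesh$rho * vol0
  m_nd <- c(m_el / 2, 0) + c(0, m_el / 2)
  if (spherical && r0[n + 1L] == 0) m_nd[n + 1L] <- m_el[n] / 2  # centre node

  dt <- config$cfl * min(L0 / mesh$c_wave)
  nsteps <- max(1L, ceiling(config$total_time / dt))
  stride <- config$output_stride
  nout <- length(seq(0L, nsteps, by = stride))

  # state
  x <- mesh$depth            # planar: current depth; spherical: r0 - u
  if (spherical) rr <- r0    # current radii
  v <- numeric(n + 1L)       # planar: depth velocity; spherical: radial
  sv_r <- sv_t <- numeric(n)
  sig_r <- sig_t <- numeric(n)

  out_t <- numeric(nout)
  out_lr <- matrix(1, nout, n)
  out_lt <- matrix(1, nout, n)
  out_sr <- matrix(0, nout, n)
  out_st <- matrix(0, nout, n)
  out_x <- matrix(0, nout, n + 1L)
  energy <- matrix(0, nout, 6L,
                   dimnames = list(NULL, c("t", "W_ext", "KE", "E_int",
                                           "E_av", "E_bc")))
  W_ext <- E_int <- E_av <- E_bc <- 0
  row <- 1L
  record <- function(step, tnow, vprev) {
    out_t[row] <<- tnow
    if (spherical) {
      lam_r <- (rr[-(n + 1L)] - rr[-1L]) / L0
      rbar0 <- (r0[-(n + 1L)] + r0[-1L]) / 2
      lam_t <- ((rr[-(n + 1L)] + rr[-1L]) / 2) / rbar0
      out_x[row, ] <<- rr
    } else {
      lam_r <- diff(x) / L0
      lam_t <- rep(1, n)
      out_x[row, ] <<- x
    }
    out_lr[row, ] <<- lam_r
    out_lt[row, ] <<- lam_t
    out_sr[row, ] <<- sig_r
    out_st[row, ] <<- sig_t
    KE <- 0.5 * sum(m_nd * vprev * v)
    energy[row, ] <<- c(tnow, W_ext, KE, E_int, E_av, E_bc)
    row <<- row + 1L
  }
  record(0L, 0, v)

  av1 <- config$av_linear
  av2 <- config$av_quadratic
  inner_free <- geometry$inner_bc == "free"
  inner_fixed <- geometry$inner_bc == "fixed_center" ||
    (spherical && r0[n + 1L] == 0)
  inner_nr <- geometry$inner_bc == "non_reflecting"
  Z_end <- mesh$rho[n] * mesh$c_wave[n]

  tnow <- 0
  for (step in seq_len(nsteps)) {
    # kinematic rates from current (half-step) velocities
    if (spherical) {
      dL <- rr[-(n + 1L)] - rr[-1L]
      dv <- v[-(n + 1L)] - v[-1L]          # lengthening rate of element
      rbar <- (rr[-(n + 1L)] + rr[-1L]) / 2
      vbar <- (v[-(n + 1L)] + v[-1L]) / 2
      lam_r <- dL / L0
      rbar0 <- (r0[-(n + 1L)] + r0[-1L]) / 2
      lam_t <- rbar / rbar0
      D_r <- dv / dL
      D_t <- vbar / rbar
    } else {
      dL <- diff(x)
      dv <- diff(v)
      lam_r <- dL / L0
      lam_t <- rep(1, n)
      D_r <- dv / dL
      D_t <- numeric(n)
    }
    if (any(dL <= 0))
      stop(sprintf("element inverted at step %d", step), call. = FALSE)
    if (any(dL / mesh$c_wave < dt * 0.999))
      stop(sprintf("CFL violation detected at step %d", step), call. = FALSE)

    upd <- column_stress(mesh, lam_r, lam_t, D_r, D_t, sv_r, sv_t, dt)
    sig_r <- upd$sig_r; sig_t <- upd$sig_t
    sv_r <- upd$sv_r; sv_t <- upd$sv_t
    if (any(!is.finite(sig_r)))
      stop(sprintf("numerical failure (non-finite stress) at step %d", step),
           call. = FALSE)

    # artificial viscosity on axial compression (dv is the element
    # lengthening rate in both modes; negative when compressing)
    q <- ifelse(dv < 0,
                mesh$rho * (av1 * mesh$c_wave * abs(dv) + av2 * dv^2), 0)
    sig_tot <- sig_r - q

    tmid <- tnow + dt / 2
    p_appl <- pfun(tmid)

    if (spherical) {
      vol <- (rr[-(n + 1L)]^3 - rr[-1L]^3) / 3
      alpha <- sig_tot * vol / dL
      beta <- sig_t * vol / rbar
      f <- numeric(n + 1L)
      f[-(n + 1L)] <- f[-(n + 1L)] - alpha - beta
      f[-1L] <- f[-1L] + alpha - beta
      f[1L] <- f[1L] - p_appl * rr[1L]^2        # blast pushes inward (-r)
    } else {
      # node force = stress(inner side) - stress(outer side)
      f <- c(sig_tot, 0) - c(-p_appl, sig_tot)
      if (inner_free) f[n + 1L] <- 0 - sig_tot[n]
      if (inner_nr) f[n + 1L] <- -sig_tot[n]   # damper applied implicitly
    }

    vold <- v
    a <- f / m_nd
    v <- v + dt * a
    # implicit update of the non-reflecting impedance damper -Z v
    if (inner_nr)
      v[n + 1L] <- v[n + 1L] / (1 + dt * Z_end / m_nd[n + 1L])
    if (inner_fixed) v[n + 1L] <- 0

    # Energy bookkeeping: each force component of this step is paired with
    # the average of the old and new half-step velocities, the discrete
    # work conjugate of central-difference time stepping.
    vb <- (vold + v) / 2
    if (spherical) {
      W_ext <- W_ext - p_appl * rr[1L]^2 * vb[1L] * dt
      dvb <- vb[-(n + 1L)] - vb[-1L]
      vbarb <- (vb[-(n + 1L)] + vb[-1L]) / 2
      E_int <- E_int + sum(sig_r * vol / dL * dvb +
                           2 * sig_t * vol / rbar * vbarb) * dt
      E_av <- E_av + sum(-q * vol / dL * dvb) * dt
      rr <- rr + dt * v
      if (any(rr[-1L] >= rr[-(n + 1L)]))
        stop(sprintf("element inverted at step %d", step), call. = FALSE)
    } else {
      W_ext <- W_ext + p_appl * vb[1L] * dt
      dvb <- diff(vb)
      E_int <- E_int + sum(sig_r * dvb) * dt
      E_av <- E_av + sum(-q * dvb) * dt
      # energy absorbed by the non-reflecting boundary (leaves the domain)
      if (inner_nr) E_bc <- E_bc + Z_end * v[n + 1L] * vb[n + 1L] * dt
      x <- x + dt * v
    }
    tnow <- step * dt

    if (step %% stride == 0L) record(step, tnow, vold)
  }

  elem_mid <- (mesh$depth[-(n + 1L)] + mesh$depth[-1L]) / 2
  structure(list(
    t = out_t[seq_len(row - 1L)],
    lam_r = out_lr[seq_len(row - 1L), , drop = FALSE],
    lam_t = out_lt[seq_len(row - 1L), , drop = FALSE],
    sig_r = out_sr[seq_len(row - 1L), , drop = FALSE],
    sig_t = out_st[seq_len(row - 1L), , drop = FALSE],
    node_pos = out_x[seq_len(row - 1L), , drop = FALSE],
    elem_depth = elem_mid,
    elem_radius = if (spherical) geometry$outer_radius - elem_mid,
    layer = mesh$layer,
    dt = dt, symmetry = geometry$symmetry,
    geometry = geometry, config = config,
    energy = as.data.frame(energy[seq_len(row - 1L), , drop = FALSE])
  ), class = "field_history")
}

#' @export
print.field_history <- function(x, ...) {
  cat(sprintf("<field_history> %s column, %d elements, %d frames, dt = %.3g s\n",
              x$symmetry, length(x$layer), length(x$t), x$dt))
  cat(sprintf("  peak |axial stress| = %.4g Pa\n", max(abs(x$sig_r))))
  e <- x$energy[nrow(x$energy), ]
  bal <- abs(e$W_ext - (e$KE + e$E_int + e$E_av + e$E_bc)) /
    max(abs(e$W_ext), 1e-300)
  cat(sprintf("  energy closure at end: %.3g%% of external work\n", 100 * bal))
  invisible(x)
}

#' Extract material-point histories from a solved field
#'
#' Builds [deformation_history()] / [stress_history()] pairs at sampled
#' elements, embedding the 1-D state into 3x3 tensors: planar mode is
#' uniaxial strain (`F = diag(lam_r, 1, 1)`), spherical mode carries the
#' hoop stretch `r_current / r_reference` on both transverse axes.
#'
#' @param field a [field_history()] from [solve_column()].
#' @param samples either an integer vector of element indices, or a list
#'   `list(layer = "brain", n = 100)` sampling `n` elements uniformly across
#'   the named layer.
#' @return list of samples; each has `element`, `layer`, `depth` (m),
#'   `deformation` and `stress`.
#' @export
extract_point_histories <- function(field, samples) {
  stopifnot(inherits(field, "field_history"))
  nel <- length(field$layer)
  if (is.list(samples) && !is.null(samples$layer)) {
    idx_layer <- which(field$layer == samples$layer)
    if (!length(idx_layer))
      stop("no elements in layer '", samples$layer, "'", call. = FALSE)
    nsamp <- min(samples$n %||% 100L, length(idx_layer))
    samples <- idx_layer[unique(round(seq(1, length(idx_layer),
                                          length.out = nsamp)))]
  }
  samples <- as.integer(samples)
  if (any(is.na(samples)) || any(samples < 1L) || any(samples > nel))
    stop("sample element indices out of domain", call. = FALSE)
  lapply(samples, function(e) {
    Fm <- array(0, c(3, 3, length(field$t)))
    Sm <- array(0, c(3, 3, length(field$t)))
    for (i in seq_along(field$t)) {
      Fm[, , i] <- diag(c(field$lam_r[i, e], field$lam_t[i, e],
                          field$lam_t[i, e]))
      Sm[, , i] <- diag(c(field$sig_r[i, e], field$sig_t[i, e],
                          field$sig_t[i, e]))
    }
    list(element = e, layer = field$layer[e], depth = field$elem_depth[e],
         deformation = deformation_history(field$t, Fm),
         stress = stress_history(field$t, Sm))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
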