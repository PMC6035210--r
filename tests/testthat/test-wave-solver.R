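# Solver oracle fixtures: an elastic bar with E = 1 GPa, rho = 1000 kg/m^3
# (c = 1000 m/s), step and smooth-pulse loads.
E1 <- 1e9; RHO1 <- 1000; C1 <- 1e3; S0 <- 1e5

bar <- function(L = 0.1, nel = 100, E = E1, rho = RHO1,
                bc = "non_reflecting")
  column_geometry(list(layer("bar", L, list(type = "elastic", E = E,
                                            rho = rho), nel)),
                  symmetry = "planar", inner_bc = bc)

two_layer <- function(E2, rho2, nel = 50)
  column_geometry(list(
    layer("a", 0.05, list(type = "elastic", E = E1, rho = RHO1), nel),
    layer("b", 0.05, list(type = "elastic", E = E2, rho = rho2), nel)),
    symmetry = "planar", inner_bc = "non_reflecting")

# raised-cosine pulse: smooth rise and fall over 20 us
smooth_pulse <- function(t) S0 * sin(pmin(pmax(t, 0) / 2e-5, 1) * pi)^2 *
  (t < 2e-5)

energy_closure <- function(fh) {
  e <- fh$energy[nrow(fh$energy), ]
  abs(e$W_ext - (e$KE + e$E_int + e$E_av + e$E_bc)) / abs(e$W_ext)
}

test_that("acoustic properties and transmission coefficients are exact", {
  expect_equal(acoustic_properties(1, 1), list(impedance = 1, wave_speed = 1))
  a1 <- acoustic_properties(E1, RHO1)
  a4 <- acoustic_properties(4 * E1, RHO1)
  expect_equal(a4$impedance / a1$impedance, 2)
  expect_equal(a4$wave_speed / a1$wave_speed, 2)
  pc <- acoustic_properties(2.4e9, 1200)
  expect_equal(pc$impedance, sqrt(2.4e9 * 1200), tolerance = 1e-12)
  expect_equal(pc$impedance, 1.697e6, tolerance = 1e-3)
  expect_equal(pc$wave_speed, 1414, tolerance = 1e-3)

  expect_equal(transmission_coefficient(5, 5), 1)
  expect_lt(transmission_coefficient(1, 1e-9), 1e-8)
  expect_equal(transmission_coefficient(1, 3), 1.5)
  expect_error(transmission_coefficient(-1, 1), "positive")
})

test_that("step load on a homogeneous bar: plateau amplitude and front speed", {
  fh <- solve_column(bar(), function(t) rep(S0, length(t)),
                     solver_config(8e-5))
  # plateau behind the front within 2 percent of -S0
  ei <- which.min(abs(fh$elem_depth - 0.03))
  expect_equal(fh$sig_r[nrow(fh$sig_r), ei], -S0, tolerance = 0.02)
  # front (half-amplitude crossing) arrives at depth/c within one element
  d <- 0.05
  ei <- which.min(abs(fh$elem_depth - d))
  arrival <- fh$t[which(abs(fh$sig_r[, ei]) > 0.5 * S0)[1]]
  expect_lt(abs(arrival - fh$elem_depth[ei] / C1), (0.1 / 100) / C1)
})

test_that("transmitted amplitude across a two-layer interface matches 2 Z2/(Z1+Z2)", {
  E2 <- 9e9; rho2 <- RHO1            # Z2 = 3 Z1, c2 = 3000 m/s
  fh <- solve_column(two_layer(E2, rho2),
                     function(t) rep(S0, length(t)), solver_config(7.5e-5))
  Tc <- transmission_coefficient(sqrt(E1 * RHO1), sqrt(E2 * rho2))
  ei <- which.min(abs(fh$elem_depth - 0.055))
  arr <- 0.05 / C1 + 0.005 / 3000
  win <- fh$t > arr + 5e-6 & fh$t < 7.4e-5
  expect_equal(mean(fh$sig_r[win, ei]), -S0 * Tc, tolerance = 0.03)
})

test_that("zero-amplitude load leaves the fields identically zero", {
  fh <- solve_column(bar(nel = 30), 0, solver_config(5e-5))
  expect_true(all(fh$sig_r == 0))
  expect_true(all(fh$lam_r == 1))
  expect_true(all(fh$energy$KE == 0))
})

test_that("energy is conserved within 2 percent for smooth loads", {
  # planar, fixed end (reflection included)
  fh <- solve_column(bar(bc = "fixed_center"), blast_profile(S0, td = 5e-5),
                     solver_config(1.5e-4))
  expect_lt(energy_closure(fh), 0.02)
  # planar, absorbing end
  fh2 <- solve_column(bar(), smooth_pulse, solver_config(2e-4))
  expect_lt(energy_closure(fh2), 0.02)
  # spherical shell
  sph <- column_geometry(list(layer("shell", 0.05,
                                    list(type = "elastic", E = E1,
                                         rho = RHO1), 100)),
                         symmetry = "spherical", inner_bc = "free",
                         outer_radius = 0.1)
  fh3 <- solve_column(sph, blast_profile(S0, td = 3e-5), solver_config(8e-5))
  expect_lt(energy_closure(fh3), 0.02)
})

test_that("impedance-matched interface does not reflect", {
  # layer b with matched impedance but 4x wave speed
  fm <- solve_column(two_layer(4e9, RHO1 / 4), smooth_pulse,
                     solver_config(6e-5))
  fh <- solve_column(bar(), smooth_pulse, solver_config(6e-5))
  ei <- which.min(abs(fh$elem_depth - 0.045))
  sm <- stats::approx(fm$t, fm$sig_r[, ei], xout = fh$t, rule = 2)$y
  expect_lt(max(abs(sm - fh$sig_r[, ei])) / max(abs(fh$sig_r[, ei])), 0.05)
})

test_that("peak transmitted stress is grid-converged", {
  peak_at <- function(nel) {
    fh <- solve_column(two_layer(9e9, RHO1, nel = nel), smooth_pulse,
                       solver_config(8e-5, av_linear = 0))
    ei <- which.min(abs(fh$elem_depth - 0.06))
    max(abs(fh$sig_r[, ei]))
  }
  p50 <- peak_at(50); p100 <- peak_at(100)
  expect_lt(abs(p100 - p50) / p100, 0.02)
})

test_that("spherical solver recovers the planar solution at large radius", {
  thin <- list(layer("sh", 0.02, list(type = "elastic", E = E1, rho = RHO1),
                     80))
  fp <- solve_column(column_geometry(thin, "planar", "free"),
                     blast_profile(S0, td = 1e-5), solver_config(1.8e-5))
  fs <- solve_column(column_geometry(thin, "spherical", "free",
                                     outer_radius = 20),
                     blast_profile(S0, td = 1e-5), solver_config(1.8e-5))
  ei <- 40
  expect_lt(max(abs(fs$sig_r[, ei] - fp$sig_r[, ei])) /
              max(abs(fp$sig_r[, ei])), 0.03)
})

test_that("extracted point histories embed the 1-D state consistently", {
  # static: identity deformation everywhere
  fh <- solve_column(bar(nel = 20), 0, solver_config(2e-5))
  ph <- extract_point_histories(fh, c(5, 15))
  expect_equal(ph[[1]]$deformation$F[, , 3], diag(3))
  expect_true(all(ph[[2]]$stress$sigma == 0))

  # planar: only the axial component of F varies
  fh2 <- solve_column(bar(), smooth_pulse, solver_config(4e-5))
  ph2 <- extract_point_histories(fh2, list(layer = "bar", n = 3))
  Fme <- ph2[[1]]$deformation$F   # outermost sample, inside the swept zone
  expect_true(any(Fme[1, 1, ] != 1))
  expect_true(all(Fme[2, 2, ] == 1) && all(Fme[3, 3, ] == 1))
  expect_true(all(Fme[1, 2, ] == 0))

  # spherical: hoop stretch equals r_current / r_reference
  sph <- column_geometry(list(layer("sh", 0.05,
                                    list(type = "elastic", E = E1,
                                         rho = RHO1), 50)),
                         symmetry = "spherical", inner_bc = "free",
                         outer_radius = 0.1)
  fs <- solve_column(sph, blast_profile(S0, td = 2e-5), solver_config(4e-5))
  e <- 25
  r_ref <- (fs$node_pos[1, e] + fs$node_pos[1, e + 1]) / 2
  for (i in c(2, length(fs$t) %/% 2, length(fs$t))) {
    r_cur <- (fs$node_pos[i, e] + fs$node_pos[i, e + 1]) / 2
    expect_equal(fs$lam_t[i, e], r_cur / r_ref, tolerance = 1e-6)
  }

  expect_error(extract_point_histories(fh, 10000), "out of domain")
})

test_that("fluid layers carry no shear", {
  col <- column_geometry(list(
    layer("skull", 0.007, list(type = "elastic", E = 6.5e9, rho = 1700), 10),
    layer("csf", 0.02, list(type = "fluid", K = 2.19e9, rho = 1000), 30)),
    symmetry = "planar", inner_bc = "fixed_center")
  fh <- solve_column(col, blast_profile(S0, td = 1e-5), solver_config(3e-5))
  fl <- which(fh$layer == "csf")
  expect_lt(max(abs(fh$sig_r[, fl] - fh$sig_t[, fl])), 1e-9 * S0)
})
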