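const_stress_history <- function(t, sigma) {
  stress_history(t, array(rep(sigma, length(t)), c(3, 3, length(t))))
}

test_that("stress-invariant criteria match closed forms", {
  tt <- c(0, 1e-4, 2e-4)
  # hydrostatic compression
  inv <- stress_invariant_criteria(const_stress_history(tt, -1e6 * diag(3)))
  expect_equal(inv$pressure, 1e6)
  expect_equal(inv$von_mises, 0)
  # uniaxial: von Mises equals the axial stress
  inv <- stress_invariant_criteria(const_stress_history(tt, diag(c(3e6, 0, 0))))
  expect_equal(inv$von_mises, 3e6, tolerance = 1e-12)
  # pure shear: von Mises = sqrt(3) tau
  tau <- matrix(0, 3, 3); tau[1, 2] <- tau[2, 1] <- 1e6
  inv <- stress_invariant_criteria(const_stress_history(tt, tau))
  expect_equal(inv$von_mises, sqrt(3) * 1e6, tolerance = 1e-12)
})

test_that("equivalent strain uses the Hencky deviator", {
  idh <- deformation_history(c(0, 1), list(diag(3), diag(3)))
  expect_equal(equivalent_strain(idh)$peak, 0)

  dil <- deformation_history(c(0, 1), list(diag(3), 1.1 * diag(3)))
  expect_lt(equivalent_strain(dil)$peak, 1e-12)

  lam <- 1.2
  uni <- deformation_history(c(0, 1),
    list(diag(3), diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))))
  expect_equal(equivalent_strain(uni)$peak, log(lam), tolerance = 1e-10)
})

test_that("volumetric and shear powers vanish on complementary load paths", {
  # isochoric shear: zero volumetric power
  h <- make_deformation_history("simple_shear", rate = 100, amplitude = 0.05,
                                duration = 5e-4, dt = 2.5e-5)
  sh <- grey_stress(h)
  er <- energy_rate_criteria(h, sh)
  expect_lt(er$volumetric, 1e-8 * max(er$shear, 1))
  # pure dilatation: zero shear power
  hd <- make_deformation_history("dilatation", rate = 10, amplitude = 0.99,
                                 duration = 1e-3, dt = 5e-5)
  sd <- grey_stress(hd)
  erd <- energy_rate_criteria(hd, sd)
  expect_lt(erd$shear, 1e-8 * max(erd$volumetric, 1))
})

test_that("steady shear at 10 kPa and D12 = 5000/s sits exactly at the grey threshold", {
  gdot <- 1e4                          # engineering shear rate; D12 = 5000/s
  tau <- 1e4                           # 10 kPa shear stress
  tt <- seq(0, 1e-4, by = 1e-5)
  Fs <- array(rep(diag(3), length(tt)), c(3, 3, length(tt)))
  Fs[1, 2, ] <- gdot * tt
  h <- deformation_history(tt, Fs)
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- tau
  sh <- const_stress_history(tt, S)
  er <- energy_rate_criteria(h, sh)
  expect_equal(er$shear, 1e8, tolerance = 1e-12)   # 2 * tau * D12
  expect_equal(er$volumetric, 0)

  res <- evaluate_point(h, sh, criteria = default_criteria("grey"))
  row <- res[res$criterion == "shear_energy_rate", ]
  expect_equal(row$peak, 1e8, tolerance = 1e-12)
  expect_gte(row$peak, row$threshold)
  expect_true(row$exceeded)            # closed threshold: >= trips the flag
})

test_that("axonal stretch and power behave kinematically", {
  a0 <- c(1, 0, 0)
  tt <- c(0, 1)
  idh <- deformation_history(tt, list(diag(3), diag(3)))
  ax <- axonal_criteria(idh, const_stress_history(tt, matrix(0, 3, 3)), a0)
  expect_equal(ax$stretch, 1)
  expect_equal(ax$power, 0)

  h <- deformation_history(tt, list(diag(3), diag(c(1.05, 1, 1))))
  ax <- axonal_criteria(h, const_stress_history(tt, diag(c(1e5, 0, 0))), a0)
  expect_equal(ax$stretch, 1.05)
  expect_gt(ax$power, 0)

  # isochoric stretch orthogonal to the fibre: lambda_a < 1, peak stays 1
  lam <- 1.2
  hq <- deformation_history(tt,
    list(diag(3), diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))))
  ax <- axonal_criteria(hq, const_stress_history(tt, matrix(0, 3, 3)),
                        c(0, 0, 1))
  expect_equal(ax$stretch, 1)

  expect_error(axonal_criteria(hq, const_stress_history(tt, diag(3)),
                               c(1, 1, 0)), "unit")
})

test_that("stress power partitions exactly into volumetric plus shear power", {
  h <- random_history(seed = 9, n = 25)
  sh <- white_stress(h, white_matter_params(a0 = c(0, 1, 0), FA = 0.4))
  sig <- btbimech:::energy_rate_signals(h, sh)
  for (i in 2:length(h)) {
    D <- rate_of_deformation(h, i)
    total <- sum(sh$sigma[, , i] * D)
    expect_equal(sig$volumetric[i] + sig$shear[i], total,
                 tolerance = 1e-10 * max(abs(total), 1))
  }
})

test_that("criterion peaks are invariant under rigid rotation of the whole history", {
  h <- random_history(seed = 13)
  R <- random_rotation(seed = 2)
  hr <- rotate_history(h, R)
  s <- grey_stress(h)
  sr <- grey_stress(hr)
  er <- energy_rate_criteria(h, s)
  err <- energy_rate_criteria(hr, sr)
  expect_equal(err$shear, er$shear, tolerance = 1e-7)
  expect_equal(err$volumetric, er$volumetric, tolerance = 1e-7)
  expect_equal(equivalent_strain(hr)$peak, equivalent_strain(h)$peak,
               tolerance = 1e-8)
  inv <- stress_invariant_criteria(s); invr <- stress_invariant_criteria(sr)
  expect_equal(invr$von_mises, inv$von_mises, tolerance = 1e-7)
  expect_equal(invr$pressure, inv$pressure, tolerance = 1e-7)
})

test_that("peaks are monotone under history extension", {
  h <- random_history(seed = 21, n = 30)
  sh <- grey_stress(h)
  sub <- function(k) {
    hh <- deformation_history(h$t[1:k], h$F[, , 1:k])
    ss <- stress_history(sh$t[1:k], sh$sigma[, , 1:k])
    er <- energy_rate_criteria(hh, ss)
    c(er$shear, er$volumetric, stress_invariant_criteria(ss)$von_mises)
  }
  prev <- sub(5)
  for (k in c(10, 20, 30)) {
    cur <- sub(k)
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("doubling the rate of an elastic isochoric path doubles peak shear power", {
  p_el <- grey_matter_params(mu_v = 1e-9, tau = 1e-4)  # effectively elastic
  mk <- function(rate) make_deformation_history("simple_shear", rate = rate,
                                                amplitude = 0.1,
                                                duration = 0.1 / rate,
                                                dt = 0.1 / rate / 40)
  pow <- function(rate) {
    h <- mk(rate)
    energy_rate_criteria(h, grey_stress(h, p_el))$shear
  }
  expect_equal(pow(200) / pow(100), 2, tolerance = 1e-6)
})

test_that("evaluate_point wires peaks, thresholds and flags together", {
  tt <- c(0, 1e-4, 2e-4)
  idh <- deformation_history(tt, replicate(3, diag(3), simplify = FALSE))
  zs <- stress_history(tt, array(0, c(3, 3, 3)))
  res <- evaluate_point(idh, zs, a0 = c(1, 0, 0),
                        criteria = default_criteria("white"))
  expect_false(any(res$exceeded))

  # infinite thresholds flag nothing, whatever the loading
  h <- make_deformation_history("simple_shear", rate = 1000, amplitude = 0.5,
                                duration = 5e-4, dt = 1e-5)
  crits <- lapply(c("pressure", "von_mises", "shear_energy_rate"),
                  criterion_spec, threshold = Inf, tissue = "both")
  res <- evaluate_point(h, grey_stress(h), criteria = crits)
  expect_false(any(res$exceeded))
  expect_true(all(res$peak >= 0))

  expect_error(evaluate_point(h, grey_stress(h), a0 = NULL,
                              criteria = default_criteria("white")),
               "a0")
  expect_error(criterion_spec("axonal_stretch", 1, "grey"), "white")
  expect_error(criterion_spec("pressure", -1), "positive")
})
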