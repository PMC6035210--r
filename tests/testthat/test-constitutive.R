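grey <- grey_matter_params()

test_that("undeformed body carries zero stress", {
  h <- deformation_history(c(0, 1e-4, 2e-4),
                           replicate(3, diag(3), simplify = FALSE))
  sh <- grey_stress(h, grey)
  expect_true(all(abs(sh$sigma) == 0))
  expect_true(all(sh$P == 0))
})

test_that("static dilatation follows the volumetric law P = K(1 - J)", {
  J <- 0.99
  Fd <- J^(1 / 3) * diag(3)
  h <- deformation_history(c(0, 1), list(Fd, Fd))
  sh <- grey_stress(h, grey)
  expect_equal(sh$P[1], 0.01 * grey$K, tolerance = 1e-9)
  expect_lt(max(abs(sh$sigma_iso[, , 1])), 1e-9 * grey$K)
})

test_that("slow small-strain shear recovers the equilibrium shear modulus", {
  gam <- 1e-4
  h <- make_deformation_history("simple_shear", rate = gam / 2,
                                amplitude = gam, duration = 2, dt = 0.02)
  sh <- grey_stress(h, grey)
  n <- length(h)
  expect_equal(sh$sigma[1, 2, n], grey$mu_eq * gam,
               tolerance = 0.01)
})

test_that("viscous branch stiffens the response at high rate and relaxes after a step", {
  gam <- 0.1
  slow <- make_deformation_history("simple_shear", rate = 1, amplitude = gam,
                                   duration = gam / 1, dt = gam / 1 / 50)
  fast <- make_deformation_history("simple_shear", rate = 1000,
                                   amplitude = gam, duration = gam / 1000,
                                   dt = gam / 1000 / 50)
  peak12 <- function(sh) max(sh$sigma[1, 2, ])
  expect_gt(peak12(grey_stress(fast, grey)), peak12(grey_stress(slow, grey)))

  # step strain held for 10 tau: within 1% of the equilibrium response
  gam <- 0.05
  tt <- c(0, 1e-6, seq(1e-5, 10 * grey$tau, length.out = 60))
  Fs <- array(rep(diag(3), length(tt)), c(3, 3, length(tt)))
  for (i in 2:length(tt)) Fs[1, 2, i] <- gam
  sh <- grey_stress(deformation_history(tt, Fs), grey)
  expect_equal(sh$sigma[1, 2, length(tt)], grey$mu_eq * gam,
               tolerance = 0.01)
})

test_that("grey and white responses are frame indifferent", {
  h <- random_history(seed = 7)
  R <- random_rotation(seed = 3)
  wp <- white_matter_params(a0 = c(0, 0, 1), FA = 0.6)
  for (model in list(function(hh) grey_stress(hh, grey),
                     function(hh) white_stress(hh, wp))) {
    s <- model(h)
    sR <- model(rotate_history(h, R))
    for (i in c(2, 15, 30)) {
      expected <- R %*% s$sigma[, , i] %*% t(R)
      expect_lt(max(abs(sR$sigma[, , i] - expected)),
                1e-8 * max(abs(expected), 1))
    }
  }
})

test_that("grey model is isotropic under coordinate permutation", {
  h <- random_history(seed = 11)
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1  # cyclic permutation
  hp <- h
  for (i in seq_len(length(h))) hp$F[, , i] <- P %*% h$F[, , i] %*% t(P)
  s <- grey_stress(h, grey)
  sp <- grey_stress(hp, grey)
  for (i in c(5, 20)) {
    expect_equal(sp$sigma[, , i], P %*% s$sigma[, , i] %*% t(P),
                 tolerance = 1e-10)
  }
})

test_that("white model is transversely isotropic about the fibre axis", {
  a0 <- c(0, 0, 1)
  wp <- white_matter_params(a0 = a0, FA = 0.8)
  h <- random_history(seed = 5)
  Q <- rotation_about(a0, 1.1)       # material rotation about the fibre
  hq <- h
  for (i in seq_len(length(h))) hq$F[, , i] <- h$F[, , i] %*% Q
  s <- white_stress(h, wp)
  sq <- white_stress(hq, wp)
  expect_lt(max(abs(s$sigma - sq$sigma)), 1e-8 * max(abs(s$sigma)))
})

test_that("white response reduces to grey linearly as FA -> 0", {
  h <- make_deformation_history("fiber_stretch", rate = 100,
                                amplitude = 0.02, duration = 2e-4,
                                dt = 1e-5, a0 = c(1, 0, 0))
  sg <- grey_stress(h, grey)
  sup_diff <- function(FA) {
    wp <- white_matter_params(a0 = c(1, 0, 0), FA = FA)
    max(abs(white_stress(h, wp)$sigma - sg$sigma))
  }
  expect_equal(sup_diff(0), 0)
  d2 <- sup_diff(0.2); d1 <- sup_diff(0.1); d05 <- sup_diff(0.05)
  expect_equal(d2 / d1, 2, tolerance = 1e-8)   # linear in FA
  expect_equal(d1 / d05, 2, tolerance = 1e-8)
})

test_that("fibre reinforcement has the closed form in uniaxial stretch and is tension-only", {
  lam <- 1.01
  a0 <- c(1, 0, 0)
  wp <- white_matter_params(a0 = a0, FA = 1, k_f = 2e3)
  F1 <- diag(c(lam, 1, 1))
  h <- deformation_history(c(0, 1), list(diag(3), F1))
  sg <- grey_stress(h, grey)
  sw <- white_stress(h, wp)
  fib <- sw$sigma[1, 1, 2] - sg$sigma[1, 1, 2]
  expect_equal(fib, 2 * wp$k_f * (lam^2 - 1) / lam, tolerance = 0.01)

  # stretch perpendicular to the fibre leaves I4 = 1: no fibre stress
  wp_z <- white_matter_params(a0 = c(0, 0, 1), FA = 1)
  sw2 <- white_stress(h, wp_z)
  expect_equal(sw2$sigma, sg$sigma, tolerance = 1e-12)

  # fibre compression (I4 < 1) contributes nothing
  hc <- deformation_history(c(0, 1), list(diag(3), diag(c(0.99, 1, 1))))
  expect_equal(white_stress(hc, wp)$sigma, grey_stress(hc, grey)$sigma,
               tolerance = 1e-12)
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(grey_matter_params(K = -1), "positive")
  expect_error(grey_matter_params(K = 5e3, mu_eq = 1e3), "incompressibility")
  expect_error(white_matter_params(a0 = c(1, 1, 0)), "unit")
  expect_error(white_matter_params(FA = 1.5), "FA")
})
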