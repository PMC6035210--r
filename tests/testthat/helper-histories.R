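# Shared helpers: random rotations and smooth random deformation paths
# (fixed-seed) for property-style tests.

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# smooth random deformation path: identity plus a few low-amplitude modes
random_history <- function(seed = 1, n = 30, amp = 0.02, duration = 1e-3) {
  set.seed(seed)
  tt <- seq(0, duration, length.out = n)
  A <- matrix(rnorm(9), 3, 3)
  B <- matrix(rnorm(9), 3, 3)
  Fs <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    s <- tt[i] / duration
    Fs[, , i] <- diag(3) + amp * (sin(pi * s) * A + (1 - cos(2 * pi * s)) * B)
    stopifnot(det(Fs[, , i]) > 0)
  }
  deformation_history(tt, Fs)
}

rotate_history <- function(history, R) {
  Fs <- history$F
  for (i in seq_len(dim(Fs)[3])) Fs[, , i] <- R %*% Fs[, , i]
  deformation_history(history$t, Fs)
}
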