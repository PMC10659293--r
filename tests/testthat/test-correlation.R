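test_that("standard FSC: identity, independence, and brute-force agreement", {
  set.seed(31)
  g <- white_noise_grid(c(8, 8))
  self <- fsc(g, g)
  expect_true(all(abs(self$values[!is.na(self$values)] - 1) < 1e-12))

  ## independent white noise: per-shell mean ~ 0 over 100 seeds
  acc <- 0
  for (s in 1:100) {
    acc <- acc + fsc(white_noise_grid(c(16, 16), seed = 900 + s),
                     white_noise_grid(c(16, 16), seed = 2900 + s))$values
  }
  mu <- acc / 100
  b <- build_shells(c(16, 16), 1)
  tol <- 3 / sqrt(b$counts * 100)
  expect_true(all(abs(mu[-1]) < pmax(tol[-1], 0.05)))

  ## fixed integer images vs brute-force shell loop
  set.seed(32)
  m1 <- matrix(sample(-5:5, 64, replace = TRUE), 8, 8)
  m2 <- matrix(sample(-5:5, 64, replace = TRUE), 8, 8)
  curve <- fsc(real_grid(m1), real_grid(m2))
  c1 <- brute_dft2_unitary(m1)
  c2 <- brute_dft2_unitary(m2)
  ref <- brute_shell_members(c(8L, 8L))
  for (r in 0:(length(curve$values) - 1L)) {
    mem <- which(ref$label == r)
    z1 <- sapply(mem, function(i) c1[ref$index[i, 1], ref$index[i, 2]])
    z2 <- sapply(mem, function(i) c2[ref$index[i, 1], ref$index[i, 2]])
    manual <- sum(Re(Conj(z1) * z2)) / sqrt(sum(Mod(z1)^2) * sum(Mod(z2)^2))
    expect_equal(curve$values[r + 1L], manual, tolerance = 1e-10)
  }
  expect_error(fsc(g, white_noise_grid(c(8, 10))), "shapes")
})

test_that("closed-form EFSC/ESFSC and the variance correction are consistent", {
  ## ESFSC trivial substitutions
  n_par <- 16L
  lam2 <- c(2, 2, 2, 2, 2, rep(0, 4))  # parent shells 0..8
  sig2 <- rep(1, 9)
  cf <- esfsc_closed_form(lam2, sig2, parent_length = n_par)
  ## at k where lam2[k] = 2*sig2 and the partner lam2 = 0: value 1/2
  expect_equal(cf$values[2], (2 - 0 + 1 - 1) / (2 + 0 + 1 + 1))
  expect_equal(esfsc_closed_form(rep(0, 9), sig2, n_par)$values,
               rep(0, 5))

  ## EFSC: lam2 = sig2 -> 1/2; sig2 = 0 -> 1
  expect_equal(efsc_closed_form(rep(3, 5), rep(3, 5))$values, rep(0.5, 5))
  expect_equal(efsc_closed_form(rep(3, 5), rep(0, 5))$values, rep(1, 5))

  ## variance correction examples and fixed points
  b <- build_shells(8L, 1)
  mk <- function(v) correlation_curve(v, b, provenance = "sfsc_mean")
  expect_equal(variance_correction(mk(c(1/3, 1, 0, 0.5, 0.2)))$values[1:3],
               c(0.5, 1, 0))
  expect_error(variance_correction(variance_correction(mk(rep(0.5, 5)))),
               "twice")
  expect_true(is.na(variance_correction(mk(c(-1, 0.5, 0.5, 0.5, 0.5)))$values[1]))

  ## algebraic identity: correction of the white-noise/rapid-decay ESFSC
  ## equals the EFSC, on random profiles
  set.seed(33)
  for (i in 1:20) {
    lam2 <- runif(9, 0, 5)
    sig2 <- rep(runif(1, 0.1, 2), 9)
    half_form <- lam2 / (lam2 + 2 * sig2)        # rapid-decay ESFSC
    curve <- correlation_curve(half_form[1:5], build_shells(8L, 1),
                               provenance = "sfsc_mean")
    expect_equal(variance_correction(curve)$values,
                 (lam2 / (lam2 + sig2))[1:5], tolerance = 1e-12)
  }
})

test_that("self FSC is ~1 for noiseless signals and ~0 for pure noise", {
  sp <- synthetic_spec(c(32, 32), b_signal = 150, snr = 1e9, seed = 5)
  sg <- sample_signal(sp)
  v <- sfsc(sg$grid)$values
  expect_true(all(v[2:8] > 0.98))

  ## pure white noise: mean ~ 0 per shell (200 seeds)
  acc <- acc2 <- 0
  for (s in 1:200) {
    v <- sfsc(white_noise_grid(c(32, 32), seed = 5000 + s))$values
    acc <- acc + v; acc2 <- acc2 + v^2
  }
  mu <- acc / 200
  se <- sqrt(pmax(acc2 / 200 - mu^2, 0) / 200)
  ri <- 3:length(mu)
  expect_true(all(abs(mu[ri]) < pmax(4 * se[ri], 0.02)))
})

test_that("Monte-Carlo mean SFSC matches the expectation oracle", {
  N <- 32
  sp0 <- synthetic_spec(c(N, N), b_signal = 60, b_noise = 20, snr = 3, seed = 1)
  acc <- acc2 <- NULL
  nseeds <- 200
  for (s in 1:nseeds) {
    sp <- synthetic_spec(c(N, N), b_signal = 60, b_noise = 20, snr = 3, seed = s)
    m <- sample_measurement(sp)
    v <- sfsc(m$y)$values
    if (is.null(acc)) { acc <- v * 0; acc2 <- v * 0 }
    acc <- acc + v; acc2 <- acc2 + v^2
    truth <- m$truth
  }
  mu <- acc / nseeds
  se <- sqrt(pmax(acc2 / nseeds - mu^2, 0) / nseeds)
  oracle <- esfsc_expected_grid(truth$lam2_full, truth$sig2_full, c(N, N),
                                sp0$voxel_size)
  ri <- 4:length(mu)
  z <- abs(mu[ri] - oracle$values[ri]) / pmax(se[ri], 1e-6)
  expect_true(mean(z < 3) >= 0.9)
  expect_lt(max(z), 4.5)
})

test_that("upsampled SFSC handles flat spectra and removes its noise bias", {
  N <- 32
  ## whitened flat-signal measurement: plain corrected SFSC collapses while
  ## the upsampled estimator recovers the expected FSC level
  acc_up <- acc_pl <- 0
  nseeds <- 60
  for (s in 1:nseeds) {
    sp <- synthetic_spec(c(N, N), b_signal = 0, b_noise = 0, snr = 10, seed = s)
    m <- sample_measurement(sp)
    nm <- known_noise_model(m$truth$sig2, m$truth$shells)
    gw <- whiten(m$y, nm)
    acc_up <- acc_up + sfsc_upsampled(gw)$values[2:(N / 2)]
    acc_pl <- acc_pl + variance_correction(sfsc(gw))$values[2:(N / 4)]
  }
  truth_level <- 10 / 11  # flat EFSC at snr 10
  mu_up <- acc_up / nseeds
  expect_lt(max(abs(mu_up[-1] - truth_level)), 0.05)
  expect_lt(max(acc_pl / nseeds), 0.2)  # flat spectrum: plain SFSC near 0

  ## pure whitened noise: gamma = 1/4 gives ~0; gamma = 0 gives ~1, because
  ## the decimated interpolants of band-limited noise are identical copies
  acc0 <- accg <- 0
  for (s in 1:60) {
    g <- white_noise_grid(c(N, N), seed = 7000 + s)
    acc0 <- acc0 + sfsc_upsampled(g)$values
    accg <- accg + sfsc_upsampled(g, gamma = 0)$values
  }
  ri <- 4:(N / 2)
  ## residual negative bias of the ratio decays like 2/n_r per shell
  expect_lt(max(abs(acc0[ri] / 60)), 0.2)
  expect_lt(max(abs(acc0[9:(N / 2)] / 60)), 0.08)
  expect_gt(min(accg[ri] / 60), 0.95)
})

test_that("every estimator respects the Cauchy-Schwarz bound", {
  set.seed(34)
  for (s in 1:5) {
    g <- white_noise_grid(c(16, 16), seed = 60 + s)
    h <- white_noise_grid(c(16, 16), seed = 160 + s)
    for (v in list(fsc(g, h)$values, sfsc(g)$values,
                   sfsc(g, scheme = "checkerboard")$values,
                   sfsc_upsampled(g)$values)) {
      expect_true(all(abs(v[!is.na(v)]) <= 1 + 1e-9))
    }
  }
})
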