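## Shared study protocols used by the acceptance-level checks and mirrored
## by scripts/acceptance.R.

## Mean SFSC curve over seeds for the reference condition (B_signal = 100,
## white noise, snr 1) and the fitted noise-inflation constant c in
## mean-SFSC(r) ~ lam2(r) / (lam2(r) + c * sig2(r)), fitted on interior
## shells where the rapid-decay condition holds.
fit_noise_inflation <- function(scheme, n = 64L, nseeds = 500L, seed0 = 0L) {
  acc <- NULL
  truth <- NULL
  for (s in seq_len(nseeds)) {
    sp <- synthetic_spec(c(n, n), b_signal = 100, b_noise = 0, snr = 1,
                         seed = seed0 + s)
    m <- sample_measurement(sp)
    v <- sfsc(m$y, scheme = scheme)$values
    if (is.null(acc)) acc <- v * 0
    acc <- acc + v
    truth <- m$truth
  }
  mean_curve <- acc / nseeds
  lam2 <- truth$lam2
  sig2 <- truth$sig2
  R <- length(mean_curve) - 1L
  r <- 2:(floor(0.75 * R) + 1L)
  obj <- function(cc) sum((mean_curve[r] - lam2[r] / (lam2[r] + cc * sig2[r]))^2)
  stats::optimize(obj, c(0.2, 10))$minimum
}

## Smooth random spectral profile family over all parent shell labels: a
## B-factor decay plus a flat floor, the model class of the generative study.
random_profile_pair <- function(n, voxel_size, rng_seed) {
  set.seed(rng_seed)
  nlab <- as.integer(round(sqrt(2) * (n / 2))) + 1L
  s <- (0:(nlab - 1L)) / (n * voxel_size)
  list(
    signal_amp = exp(-stats::runif(1, 20, 150) * s^2 / 4) +
      stats::runif(1, 0, 0.15),
    noise_amp = exp(-stats::runif(1, 0, 60) * s^2 / 4),
    snr = exp(stats::runif(1, log(0.5), log(15)))
  )
}

## Per-shell mean and MC standard error of an estimator over seeds.
mc_curve <- function(nseeds, draw) {
  acc <- acc2 <- NULL
  extra <- NULL
  for (s in seq_len(nseeds)) {
    out <- draw(s)
    v <- out$values
    if (is.null(acc)) { acc <- v * 0; acc2 <- v * 0 }
    acc <- acc + v
    acc2 <- acc2 + v^2
    extra <- out$extra
  }
  mu <- acc / nseeds
  list(mean = mu,
       se = sqrt(pmax(acc2 / nseeds - mu^2, 0) / nseeds),
       extra = extra)
}

## Mean per-shell difference between a single-measurement estimate and the
## two-measurement FSC reference under one generative condition.
condition_delta <- function(n, b_signal, b_noise, snr, nseeds, seed0 = 0L,
                            preprocess = c("none", "whiten",
                                           "whiten_upsample")) {
  preprocess <- match.arg(preprocess)
  eacc <- racc <- NULL
  for (s in seq_len(nseeds)) {
    sp <- synthetic_spec(c(n, n), b_signal = b_signal, b_noise = b_noise,
                         snr = snr, seed = seed0 + s)
    pr <- sample_measurement_pair(sp)
    ref <- fsc(pr$y1, pr$y2)
    y <- pr$y1
    if (preprocess != "none") {
      y <- whiten(y, known_noise_model(pr$truth$sig2, pr$truth$shells))
    }
    est <- if (preprocess == "whiten_upsample") sfsc_upsampled(y)
           else variance_correction(sfsc(y))
    if (is.null(eacc)) { eacc <- est$values * 0; racc <- est$values * 0 }
    nsh <- length(eacc)
    eacc <- eacc + est$values[seq_len(nsh)]
    racc <- racc + ref$values[seq_len(nsh)]
  }
  (eacc - racc) / nseeds
}
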