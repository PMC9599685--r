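test_that("analytic signal of a cosine has unit modulus and correct frequency", {
  fs <- 1000
  tt <- seq_len(3000) / fs
  ep <- make_epochs(list(rbind(cos(2 * pi * 10 * tt),
                               cos(2 * pi * 10 * tt - pi / 3))),
                    sampling_rate = fs, band = "alpha")
  an <- analytic_signal(ep, trim_fraction = 0.10)
  expect_equal(dim(an)[3], 2400)
  z <- an[1, 1, ]
  expect_lt(max(abs(Mod(z) - 1)), 0.02)
  inst_f <- diff(signal::unwrap(Arg(z))) * fs / (2 * pi)
  expect_lt(max(abs(inst_f - 10)), 0.2)
  # matches the textbook FFT Hilbert recipe exactly
  oracle <- hilbert_oracle(cos(2 * pi * 10 * tt))[301:2700]
  expect_lt(max(Mod(z - oracle)), 1e-10)
})

test_that("edge trimming arithmetic follows floor(n (1 - 2 f))", {
  ep <- make_epochs(list(matrix(rnorm(2 * 1001), 2)), band = "beta")
  expect_equal(dim(analytic_signal(ep, 0.10))[3], floor(1001 * 0.8))
  expect_equal(dim(analytic_signal(ep, 0))[3], 1001)
  expect_error(analytic_signal(ep, 0.5))
  ep_nb <- make_epochs(list(matrix(rnorm(200), 2)), band = NULL)
  expect_warning(analytic_signal(ep_nb), "band")
})

test_that("wpli matches a literal transcription of its definition", {
  set.seed(10)
  for (rep in 1:25) {
    ep <- make_epochs(lapply(1:3, function(i) matrix(rnorm(2 * 200), 2)),
                      band = "beta")
    an <- analytic_signal(ep, 0.1)
    for (mode in c("pooled", "within_trial")) {
      w <- wpli(an, average = mode)
      expect_equal(w[1, 2], wpli_pair_oracle(an[, 1, ], an[, 2, ],
                                             average = mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("constant lag gives 1, zero lag gives 0, and values stay in range", {
  fs <- 1000
  tt <- seq_len(1000) / fs
  lagged <- make_epochs(lapply(1:5, function(i) {
    ph <- runif(1, 0, 2 * pi)
    rbind(sin(2 * pi * 10 * tt + ph), sin(2 * pi * 10 * tt + ph - pi / 4))
  }), band = "alpha")
  expect_equal(wpli(analytic_signal(lagged))[1, 2], 1, tolerance = 1e-12)

  same <- matrix(rnorm(1000), 1)
  zero_lag <- make_epochs(list(rbind(same, same)), band = "beta")
  expect_equal(wpli(analytic_signal(zero_lag))[1, 2], 0)

  set.seed(11)
  for (rep in 1:10) {
    ep <- make_epochs(lapply(1:2, function(i) matrix(rnorm(3 * 150), 3)),
                      band = "beta")
    w <- wpli(analytic_signal(ep, 0.1))
    expect_true(all(w >= 0 & w <= 1))
    expect_identical(unname(diag(w)), rep(0, 3))
    expect_equal(unclass(w), t(unclass(w)))
  }
})

test_that("zero-lag common components do not move WPLI of a lagged pair", {
  set.seed(12)
  fs <- 250
  n <- 750
  # identical signal and noise components in both runs; only the zero-lag
  # common term is added in the second, so any change is its doing
  comps <- lapply(1:40, function(i) list(
    s = fft_bandpass(rnorm(n), 16, 24, fs),
    n1 = fft_bandpass(rnorm(n), 13, 30, fs),
    n2 = fft_bandpass(rnorm(n), 13, 30, fs),
    z = fft_bandpass(rnorm(n), 13, 30, fs)))
  mk <- function(gain) lapply(comps, function(cc) {
    x <- 4 * cc$s + cc$n1 + gain * cc$z
    y <- 4 * c(cc$s[(n - 4):n], cc$s[1:(n - 5)]) + cc$n2 + 0.5 * gain * cc$z
    rbind(x, y)
  })
  w_plain <- wpli(analytic_signal(make_epochs(mk(0), sampling_rate = fs)))
  w_comm <- wpli(analytic_signal(make_epochs(mk(1), sampling_rate = fs)))
  expect_lt(abs(w_plain[1, 2] - w_comm[1, 2]), 0.08)
  expect_gt(w_plain[1, 2], 0.8)
  # the common term alone creates no spurious coupling
  alone <- lapply(comps, function(cc)
    rbind(cc$n1 + 2 * cc$z, cc$n2 + cc$z))
  w_alone <- wpli(analytic_signal(make_epochs(alone, sampling_rate = fs)))
  expect_lt(w_alone[1, 2], 0.1)
})

test_that("matrix summaries average the right entries", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[upper.tri(m)] <- c(0.1, 0.2, 0.3)
  m <- m + t(m)
  expect_equal(mean_wpli(m), 0.2)
  u <- matrix(0.4, 4, 4); diag(u) <- 0
  expect_equal(mean_wpli(u), 0.4)
  expect_equal(unname(channel_mean_wpli(u)), rep(0.4, 4))

  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- m2[2, 1] <- 0.6
  m2[1, 3] <- m2[3, 1] <- 0.2
  m2[2, 3] <- m2[3, 2] <- 0.4
  expect_equal(unname(channel_mean_wpli(m2)), c(0.4, 0.5, 0.3))
  expect_equal(unname(channel_mean_wpli(matrix(0, 3, 3))), rep(0, 3))
  expect_equal(mean_wpli(matrix(0, 3, 3)), 0)
})

test_that("erwpli implements the baseline change rate with a guarded floor", {
  w <- matrix(0.4, 4, 4); diag(w) <- 0
  r <- w
  z <- erwpli(w, r)
  expect_true(all(z == 0))

  z2 <- erwpli(2 * w, w)
  expect_true(all(z2[upper.tri(z2)] == 1))
  expect_identical(unname(diag(z2)), rep(0, 4))

  r0 <- w; r0[1, 2] <- r0[2, 1] <- 0
  z3 <- erwpli(w, r0, floor = 1e-6)
  expect_equal(z3[1, 2], 0.4 / 1e-6)
  expect_equal(nrow(attr(z3, "floored")), 1)
  expect_error(erwpli(w, matrix(0.1, 3, 3)), "shapes")

  # sign logic: positive iff aiming exceeds baseline
  set.seed(14)
  wa <- matrix(runif(16, 0.2, 0.8), 4); wa <- (wa + t(wa)) / 2; diag(wa) <- 0
  wb <- matrix(runif(16, 0.2, 0.8), 4); wb <- (wb + t(wb)) / 2; diag(wb) <- 0
  zz <- erwpli(wa, wb)
  off <- upper.tri(zz)
  expect_identical(unname(zz[off] > 0), unname(wa[off] > wb[off]))
  expect_true(all(zz >= -1))
})

test_that("connectivity CSV round-trips with channel labels", {
  dir <- withr::local_tempdir()
  m <- matrix(runif(16), 4); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(c("C3", "C4", "O1", "O2"), c("C3", "C4", "O1", "O2"))
  f <- file.path(dir, "m.csv")
  write_conn_csv(m, f)
  m2 <- read_conn_csv(f)
  expect_equal(m2, m, tolerance = 1e-12)
})
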