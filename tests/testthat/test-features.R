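test_that("Slepian tapers are orthonormal, concentrated, and match scipy", {
  tp <- dpss_tapers(256, nw = 2, k = 3)
  expect_equal(crossprod(tp), diag(3), tolerance = 1e-10)
  # spectral concentration of the leading taper inside |f| <= W
  n <- 256; W <- 2 / n
  pad <- 16L * n
  spec <- Mod(fft(c(tp[, 1], numeric(pad - n))))^2
  f <- (0:(pad - 1)) / pad
  inband <- f <= W | f >= 1 - W
  expect_gt(sum(spec[inband]) / sum(spec), 0.999)

  script <- paste(
    "import sys, numpy as np",
    "from scipy.signal.windows import dpss",
    "t = dpss(256, 2, 3)",
    "np.savetxt(sys.stdout, t.T, fmt='%.12e')", sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  ref <- matrix(scan(text = out, quiet = TRUE), ncol = 3, byrow = TRUE)
  for (j in 1:3)   # sign convention may differ per taper
    expect_lt(min(max(abs(tp[, j] - ref[, j])),
                  max(abs(tp[, j] + ref[, j]))), 1e-8)
})

test_that("band power scales with amplitude and vanishes for silence", {
  fs <- 128; t <- (0:255) / fs
  p1 <- band_power(3 * cos(2 * pi * 20 * t), fs, c(13, 30))
  p2 <- band_power(6 * cos(2 * pi * 20 * t), fs, c(13, 30))
  expect_equal(p2 / p1, 4, tolerance = 0.01)
  expect_equal(band_power(numeric(256), fs, c(13, 30)), 0)
  expect_gt(p1, 0)
  expect_error(band_power(numeric(0), fs, c(13, 30)), "zero-length")
  expect_error(band_power(t, fs, c(13, 100)), "Nyquist")
})

test_that("multitaper band power agrees with a periodogram oracle on noise", {
  fs <- 128
  set.seed(21)
  # both estimate a flat PSD; compare band averages over many epochs
  mt <- replicate(200, band_power(rnorm(256), fs, c(13, 30)))
  pg <- replicate(200, {
    x <- rnorm(256)
    p <- Mod(fft(x))^2 / (fs * 256) * 2
    f <- (0:255) * fs / 256
    mean(p[f >= 13 & f <= 30])
  })
  expect_equal(mean(mt), mean(pg), tolerance = 0.2)
})

test_that("asymmetry index has its closed form and symmetries", {
  expect_equal(asymmetry_index(5, 5), 0)
  expect_equal(asymmetry_index(2, 1), log(2))
  expect_equal(asymmetry_index(1, 2), -log(2))
  expect_equal(asymmetry_index(3, 7), -asymmetry_index(7, 3))
  expect_equal(asymmetry_index(10 * 3, 10 * 7), asymmetry_index(3, 7))
  expect_error(asymmetry_index(0, 1), "positive")
  expect_error(asymmetry_index(1, -2), "positive")
})

test_that("instantaneous phase tracks the analytic-signal identities", {
  fs <- 128; t <- (0:511) / fs
  ph <- instantaneous_phase(cos(2 * pi * 20 * t))
  v <- attr(ph, "valid")
  expect_true(all(ph > -pi & ph <= pi))
  # unwrapped phase advances at 2*pi*20 rad/s
  d <- diff(ph[v]); d[d < -pi] <- d[d < -pi] + 2 * pi
  rate <- mean(d) * fs
  expect_equal(rate, 2 * pi * 20, tolerance = 0.01 * 2 * pi * 20)
  # sin lags cos by pi/2
  ph_s <- instantaneous_phase(sin(2 * pi * 20 * t))
  off <- Arg(mean(exp(1i * (ph_s[v] - ph[v]))))
  expect_equal(off, -pi / 2, tolerance = 0.01)
  # amplitude modulation leaves the phase ramp unchanged
  am <- (1 + 0.5 * cos(2 * pi * 1 * t)) * cos(2 * pi * 20 * t)
  ph_am <- instantaneous_phase(am)
  expect_lt(max(abs(ph_am[v] - ph[v])), 0.05)
  expect_error(instantaneous_phase(rep(1, 256)), "constant")
})

test_that("PLV analytic identities hold", {
  th <- runif(256, -pi, pi)
  expect_equal(plv(th, th), 1)
  expect_equal(plv(th, th - 1.2), 1)
  for (M in c(2, 3, 4, 8)) {   # symmetric phase sets cancel exactly
    d <- rep(seq(0, 2 * pi, length.out = M + 1)[-(M + 1)], 240 / M)
    expect_lt(plv(d, numeric(240)), 1e-12)
  }
  expect_error(plv(th, th[-1]), "length")
})

test_that("PLV of independent phases is small and shrinks with length", {
  set.seed(5)
  p256 <- replicate(200, plv(runif(256, -pi, pi), runif(256, -pi, pi)))
  p1024 <- replicate(200, plv(runif(1024, -pi, pi), runif(1024, -pi, pi)))
  expect_true(all(p256 >= 0 & p256 <= 1))
  expect_lt(mean(p256), 0.2)
  expect_lt(mean(p1024), mean(p256))
})

test_that("feature tables have canonical shape and reuse the scalar ops", {
  m <- pair_montage()
  catp <- feature_catalog(m)
  fs <- 128
  set.seed(9)
  ep1 <- eeg_epochs("A", m, array(rnorm(5 * 2 * 256), c(5, 2, 256)), fs,
                    band = c(13, 30))
  ep2 <- eeg_epochs("B", m, array(rnorm(4 * 2 * 256), c(4, 2, 256)), fs,
                    band = c(13, 30))
  tab <- build_feature_table(list(ep1, ep2), catp)
  expect_equal(dim(tab$values), c(9L, 4L))
  expect_equal(tab$subject, c(rep("A", 5), rep("B", 4)))

  # row 1 must equal the scalar operations applied to the same epoch
  x1 <- ep1$epochs[1, 1, ]; x2 <- ep1$epochs[1, 2, ]
  ps1 <- band_power(x1, fs, c(13, 30))
  ps2 <- band_power(x2, fs, c(13, 30))
  expect_equal(unname(tab$values[1, "PS:C3"]), ps1, tolerance = 1e-12)
  expect_equal(unname(tab$values[1, "PS:C4"]), ps2, tolerance = 1e-12)
  expect_equal(unname(tab$values[1, "AI:C3/C4"]), asymmetry_index(ps1, ps2),
               tolerance = 1e-12)
  expect_equal(unname(tab$values[1, "PLV:C3-C4"]),
               plv(instantaneous_phase(x1), instantaneous_phase(x2)),
               tolerance = 1e-12)

  # determinism and montage mismatch
  tab2 <- build_feature_table(list(ep1, ep2), catp)
  expect_identical(tab$values, tab2$values)
  expect_error(build_feature_table(list(ep1), feature_catalog(tiny_montage())),
               "montage mismatch")
})

test_that("feature tables round-trip through CSV", {
  tab <- quick_table(2, n_subjects = 2, duration_s = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path, tab$catalog, band = tab$band, fs = tab$fs)
  expect_equal(back$values, tab$values, tolerance = 1e-11)
  expect_equal(back$subject, tab$subject)
})
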