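# Carrier-based signal splitting.

test_that("carrier-zero sampling counts and isolates components", {
  geom <- scan_geometry()
  # 80 cm scan, D = 16 cm: phi positions every 8 cm -> 11 of them
  S <- scan_signal(matrix(1, 200, 6), geom$scan_positions)
  zp <- sample_at_carrier_zeros(S, geom, gamma = 0, component = "phi")
  expect_length(zp$positions, 11)
  expect_equal(diff(zp$positions), rep(0.08, 10), tolerance = 1e-12)
  # a pure psi signal samples to zero at all phi positions
  hom <- make_phantom("homogeneous")
  sig <- signal_from_currents(basis_currents(hom, geom), geom)
  zp2 <- sample_at_carrier_zeros(sig$psi, geom, 0, "phi")
  expect_lt(max(abs(zp2$samples)), 1e-4 * max(abs(sig$psi$values)))
  # scans shorter than one period are rejected
  gshort <- scan_geometry(scan = list(min = -0.05, max = 0.05, n = 40))
  Ss <- scan_signal(matrix(1, 40, 6), gshort$scan_positions)
  expect_error(sample_at_carrier_zeros(Ss, gshort), "period")
})

test_that("a one-component signal is recovered exactly", {
  # when the carrier zeros fall on the scan sample grid (201 samples over
  # 80 cm put them exactly on grid points) the recovery is exact to
  # round-off; on the default 200-sample grid it is exact to the envelope
  # interpolation accuracy
  ga <- scan_geometry(scan = list(min = -0.40, max = 0.40, n = 201))
  siga <- signal_from_currents(basis_currents(make_phantom("homogeneous"),
                                              ga), ga)
  spa <- split_signal(siga$psi, ga)
  sca <- max(abs(siga$psi$values))
  expect_lt(max(abs(spa$phi$values)), 1e-12 * sca)
  expect_lt(max(abs(spa$psi$values - siga$psi$values)), 1e-12 * sca)

  geom <- scan_geometry()
  sig <- signal_from_currents(basis_currents(make_phantom("homogeneous"),
                                             geom), geom)
  scale <- max(abs(sig$psi$values))
  sp <- split_signal(sig$psi, geom)
  expect_lt(max(abs(sp$phi$values)), 1e-4 * scale)
  expect_lt(max(abs(sp$psi$values - sig$psi$values)), 1e-4 * scale)
  sp2 <- split_signal(sig$phi, geom)
  expect_lt(max(abs(sp2$psi$values)), 1e-4 * scale)
  expect_lt(max(abs(sp2$phi$values - sig$phi$values)), 1e-4 * scale)
})

test_that("the two split components always sum to the input exactly", {
  geom <- scan_geometry()
  for (seed in c(1, 8)) {
    d <- differential_signals(random_phantom(seed), geom)
    sp <- split_signal(d$total, geom)
    expect_lt(max(abs(sp$phi$values + sp$psi$values - d$total$values)),
              1e-12 * max(abs(d$total$values)))
  }
  # degenerate all-zero input gives zero components
  z <- scan_signal(matrix(0, 200, 6), geom$scan_positions)
  spz <- split_signal(z, geom)
  expect_true(all(spz$phi$values == 0) && all(spz$psi$values == 0))
})

test_that("splitting is homogeneous of degree one at fixed gamma", {
  geom <- scan_geometry()
  d <- differential_signals(random_phantom(4), geom)
  sp1 <- split_signal(d$total, geom, gamma = 0.01)
  S3 <- scan_signal(3 * d$total$values, d$total$x_s, "differential")
  sp3 <- split_signal(S3, geom, gamma = 0.01)
  expect_equal(sp3$phi$values, 3 * sp1$phi$values, tolerance = 1e-10)
  expect_equal(sp3$psi$values, 3 * sp1$psi$values, tolerance = 1e-10)
})

test_that("band-limited envelopes split losslessly with sinc interpolation", {
  geom <- scan_geometry()
  xs <- geom$scan_positions
  # synthetic components with envelopes band-limited below 1/D (half the
  # carrier-zero sampling rate 2/D), tapered to zero at the scan edges
  taper <- exp(-(xs / 0.25)^6)
  P <- (0.8 + 0.4 * cos(2 * pi * xs / 0.45)) * taper
  Q <- (0.3 * sin(2 * pi * xs / 0.5) + 0.1) * taper
  th <- 2 * pi * xs / geom$D
  S <- scan_signal(matrix(P * cos(th) + Q * sin(th), ncol = 1), xs)
  sp <- split_signal(S, geom, interp = "sinc", gamma = 0)
  expect_lt(max(abs(sp$phi$values[, 1] - P * cos(th))), 0.02 * max(abs(P)))
  expect_lt(max(abs(sp$psi$values[, 1] - Q * sin(th))), 0.02 * max(abs(P)))
})

test_that("recovered components correlate with the truth on random phantoms", {
  geom <- scan_geometry()
  cors <- c()
  for (seed in 1:20) {
    d <- differential_signals(random_phantom(seed, n_perturbations = 2),
                              geom)
    sp <- split_signal(d$total, geom)
    cors <- c(cors,
              stats::cor(as.vector(sp$phi$values), as.vector(d$phi)),
              stats::cor(as.vector(sp$psi$values), as.vector(d$psi)))
  }
  expect_gte(stats::median(cors), 0.90)
})

test_that("scan signal CSV round-trips with component labels", {
  geom <- scan_geometry()
  sig <- signal_from_currents(basis_currents(make_phantom("two_contrast"),
                                             geom), geom)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal(sig, path)
  back <- read_signal(path)
  expect_setequal(names(back), c("phi", "psi", "total"))
  expect_equal(back$total$values, sig$total$values, tolerance = 1e-12)
})
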