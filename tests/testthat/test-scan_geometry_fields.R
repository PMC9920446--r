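# Geometry validation and the fixed excitation / receiver field maps.

test_that("geometry invariants are enforced", {
  expect_error(scan_geometry(cell_size = 0.03), "divide")
  expect_error(scan_geometry(z_exciter = 0), "z_exciter")
  expect_error(scan_geometry(z_receiver = -0.01), "z_receiver")
  expect_error(scan_geometry(gamma = 0.05), "gamma")
  g <- scan_geometry(z_receiver = 0)   # contacting diagnostic mode allowed
  expect_identical(g$z_receiver, 0)
  g <- scan_geometry()
  expect_identical(c(g$nx, g$ny), c(20L, 20L))
  expect_true(all(diff(g$scan_positions) > 0))
  expect_lt(diff(range(diff(g$scan_positions))), 1e-12)
})

test_that("geometry round-trips through YAML and JSON configs", {
  g <- scan_geometry(D = 0.2, z_receiver = 0.05,
                     scan = list(min = -0.3, max = 0.3, n = 128))
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_geometry(g, path)
    g2 <- read_geometry(path)
    expect_equal(g2$D, g$D)
    expect_equal(g2$scan_positions, g$scan_positions)
    expect_equal(g2$receivers$y, g$receivers$y)
  }
})

test_that("ideal undulator potential is periodic and decays exponentially", {
  g <- scan_geometry()
  x <- seq(-0.4, 0.4, length.out = 41)
  A1 <- undulator_potential(g, list(x = x, y = x * 0))
  A2 <- undulator_potential(g, list(x = x + g$D, y = x * 0))
  expect_equal(A1$Ay, A2$Ay, tolerance = 1e-12)
  expect_true(all(A1$Ax == 0))
  # doubling the distance multiplies the amplitude by exp(-2 pi z1 / D)
  gz <- scan_geometry(z_exciter = 0.2)
  A3 <- undulator_potential(gz, list(x = x, y = x * 0))
  expect_equal(A3$Ay / A1$Ay, rep(exp(-2 * pi * 0.1 / g$D), length(x)),
               tolerance = 1e-10)
  expect_error(undulator_potential(g, list(x = 0, y = 0, z = -0.2)),
               "below the undulator")
})

test_that("finite stripe array converges to the ideal periodic sheet", {
  g <- scan_geometry()
  x <- seq(-0.2, 0.2, length.out = 81)
  ideal <- undulator_potential(g, list(x = x, y = x * 0))$Ay
  stripes <- undulator_potential(g, list(x = x, y = x * 0),
                                 mode = "stripes", n_stripes = 41)$Ay
  expect_lt(max(abs(stripes - ideal) / max(abs(ideal))), 0.02)
})

test_that("shifting the scan by D/2 flips every ideal-mode EMF", {
  g <- scan_geometry()
  net <- build_network(make_phantom("homogeneous"))
  u0 <- induced_emfs(net, g, x_s = 0.013)
  u2 <- induced_emfs(net, g, x_s = 0.013 + g$D / 2)
  expect_equal(u2, -u0, tolerance = 1e-12)
  # only y-directed edges are driven by the y-oriented excitation
  expect_true(all(u0[net$edges$type == "x"] == 0))
})

test_that("segment B matches a numeric Biot-Savart line integral", {
  # receiver segment of length L along y; field point on the perpendicular
  # bisector at several distances, compared against quadrature of
  # mu0/4pi * dl x r / r^3
  L <- 0.10
  g <- scan_geometry(receivers = data.frame(x = 0, y = 0, length = L,
                                            orient = "y"),
                     z_receiver = 0)
  for (rho in c(0.05, 0.2, 1.0)) {
    oracle_bz <- stats::integrate(function(yp) {
      r3 <- (rho^2 + yp^2)^(3 / 2)
      1e-7 * rho / r3          # (dl x r)_z for dl = dy yhat, r = (rho,-yp,0)
    }, -L / 2, L / 2, rel.tol = 1e-12)$value
    Bz <- receiver_fields(g, list(x = rho, y = 0), what = "Bz")[1, 1]
    expect_equal(abs(Bz), abs(oracle_bz), tolerance = 1e-10)
    # far field approaches wire limit scaled by L / sqrt(L^2/4 + rho^2)
    if (rho >= 1.0) {
      expect_equal(abs(Bz),
                   2e-7 / rho * L / (2 * sqrt(L^2 / 4 + rho^2)),
                   tolerance = 1e-10)
    }
  }
})

test_that("closed-form B_R equals the finite-difference curl of A_R", {
  g <- scan_geometry()
  pc <- pixel_centers(g)
  pts <- list(x = pc$xc, y = pc$yc)
  Bz <- receiver_fields(g, pts, what = "Bz")
  h <- 1e-3
  Ap <- receiver_fields(g, list(x = pts$x + h / 2, y = pts$y), what = "A")
  Am <- receiver_fields(g, list(x = pts$x - h / 2, y = pts$y), what = "A")
  Bfd <- (Ap - Am) / h
  expect_lt(max(abs(Bfd - Bz)) / max(abs(Bz)), 1e-3)
})

test_that("receiver fields decay and narrow with distance", {
  pc <- pixel_centers(scan_geometry())
  peak <- sapply(c(0.05, 0.15), function(z) {
    g <- scan_geometry(z_receiver = z)
    max(abs(receiver_fields(g, list(x = pc$xc, y = pc$yc), what = "Bz")))
  })
  expect_lt(peak[2], peak[1])
  # spatial low-pass: the x-spectrum of B_R at the sheet concentrates at
  # lower frequencies as the receiver distance grows
  x <- seq(-0.4, 0.4, length.out = 256)
  rolloff <- sapply(c(0.05, 0.10, 0.15), function(z) {
    g <- scan_geometry(z_receiver = z)
    b <- receiver_fields(g, list(x = x, y = rep(0.02, 256)), what = "Bz")[, 3]
    p <- Mod(stats::fft(b))^2
    p <- p[1:128]
    min(which(cumsum(p) >= 0.95 * sum(p)))   # 95% energy bandwidth index
  })
  expect_true(all(diff(rolloff) <= 0))
})
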