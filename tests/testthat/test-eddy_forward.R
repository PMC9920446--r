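# Resistor-network forward model: graph counts, nodal solve, basis
# superposition, reciprocity signals in both formulations.

test_that("network counts follow the loop-count law", {
  net <- build_network(conductivity_grid(matrix(0.5, 3, 3)))
  expect_identical(net$n_nodes, 16L)
  expect_identical(nrow(net$edges), 24L)
  expect_identical(nrow(net$edges) - net$n_nodes + 1L, 9L)
  net20 <- build_network(conductivity_grid(matrix(0.5, 20, 20)))
  expect_identical(net20$n_nodes, 441L)
  expect_identical(nrow(net20$edges), 840L)
  expect_identical(nrow(net20$edges) - net20$n_nodes + 1L, 400L)
  for (c in 2:30) {
    net <- build_network(conductivity_grid(matrix(1, c, c), cell_size = 0.02))
    expect_identical(nrow(net$edges) - net$n_nodes + 1L, as.integer(c^2))
  }
  # cycle-space rank of the incidence matrix confirms the loop count
  net <- build_network(conductivity_grid(matrix(1, 4, 4)))
  k <- nrow(net$edges)
  B <- matrix(0, k, net$n_nodes)
  B[cbind(seq_len(k), net$edges$from)] <- 1
  B[cbind(seq_len(k), net$edges$to)] <- -1
  expect_identical(k - qr(B)$rank, 16L)
})

test_that("homogeneous grids give equal interior conductances", {
  net <- build_network(conductivity_grid(matrix(0.7, 5, 5), thickness = 0.01))
  e <- net$edges
  interior <- (e$type == "x" & e$i >= 1 & e$i <= 4) |
    (e$type == "y" & e$j >= 1 & e$j <= 4)
  expect_equal(unique(e$g[interior]), 0.7 * 0.01, tolerance = 1e-15)
})

test_that("nodal solve matches an independent mesh-current oracle", {
  set.seed(42)
  grid <- conductivity_grid(matrix(0.5, 3, 3))
  net <- build_network(grid)
  emfs <- rnorm(nrow(net$edges)) * 1e-6
  J <- solve_eddy_currents(net, emfs)

  # mesh (loop) analysis oracle: one CCW loop current per pixel
  e <- net$edges
  loop_sign <- matrix(0, nrow(e), 9)   # edge x loop incidence
  for (i in 1:3) for (j in 1:3) {
    l <- (j - 1) * 3 + i
    bot <- which(e$type == "x" & e$i == i - 1 & e$j == j)
    top <- which(e$type == "x" & e$i == i & e$j == j)
    lef <- which(e$type == "y" & e$j == j - 1 & e$i == i)
    rig <- which(e$type == "y" & e$j == j & e$i == i)
    loop_sign[bot, l] <- 1; loop_sign[rig, l] <- 1
    loop_sign[top, l] <- -1; loop_sign[lef, l] <- -1
  }
  R <- 1 / e$g
  A <- t(loop_sign) %*% (R * loop_sign)   # KVL system
  b <- as.vector(t(loop_sign) %*% emfs)
  lambda <- solve(A, b)
  I_mesh <- as.vector(loop_sign %*% lambda)
  expect_lt(max(abs(I_mesh - J$I)) / max(abs(J$I)), 1e-8)
})

test_that("zero EMFs and zero conductivity both give zero currents", {
  net <- build_network(conductivity_grid(matrix(0.5, 4, 4)))
  J <- solve_eddy_currents(net, numeric(nrow(net$edges)))
  expect_true(all(J$I == 0))
  net0 <- build_network(conductivity_grid(matrix(0, 4, 4)))
  J0 <- solve_eddy_currents(net0, rnorm(nrow(net0$edges)))
  expect_true(all(J0$I == 0))
})

test_that("disconnected conducting islands are solved per component", {
  v <- matrix(0, 6, 6)
  v[1:2, 1:2] <- 0.5
  v[5:6, 5:6] <- 0.8
  net <- build_network(conductivity_grid(v))
  set.seed(3)
  J <- solve_eddy_currents(net, rnorm(nrow(net$edges)) * 1e-6)
  res <- max(abs(mitchain:::node_residuals(J$I, J$edges, net$n_nodes)))
  expect_lte(res, 1e-10 * max(abs(J$I)))
  # currents confined to the conducting support
  expect_true(all(J$I[net$edges$g == 0] == 0))
})

test_that("homogeneous sheet at the symmetric position is mirror symmetric", {
  geom <- scan_geometry()
  J <- basis_currents(make_phantom("homogeneous"), geom)$phi
  e <- J$edges
  # mirror x -> -x: y-edges at vline v map to vline nx - v with equal
  # current; x-edges at column j map to column nx + 1 - j with flipped sign
  isy <- e$type == "y"
  Iy <- J$I[isy]
  key <- paste(e$i[isy], e$j[isy])
  mirr <- paste(e$i[isy], J$nx - e$j[isy])
  expect_lt(max(abs(Iy - Iy[match(mirr, key)])) / max(abs(Iy)), 1e-8)
  Ix <- J$I[!isy]
  keyx <- paste(e$i[!isy], e$j[!isy])
  mirrx <- paste(e$i[!isy], J$nx + 1 - e$j[!isy])
  expect_lt(max(abs(Ix + Ix[match(mirrx, keyx)])) / max(abs(J$I)), 1e-8)
})

test_that("two basis fields reproduce direct solves at any scan position", {
  geom <- scan_geometry()
  grid <- make_phantom("two_contrast")
  net <- build_network(grid)
  J <- basis_currents(grid, geom)
  set.seed(7)
  for (xs in runif(8, -0.4, 0.4)) {
    th <- 2 * pi * xs / geom$D
    direct <- solve_eddy_currents(net, induced_emfs(net, geom, x_s = xs))
    combo <- cos(th) * J$phi$I + sin(th) * J$psi$I
    expect_lt(max(abs(direct$I - combo)) / max(abs(direct$I)), 1e-8)
  }
  # at x_s = 0 the sine weight vanishes: J(0) = J_phi
  direct0 <- solve_eddy_currents(net, induced_emfs(net, geom, x_s = 0))
  expect_equal(direct0$I, J$phi$I, tolerance = 1e-12)
  # at x_s = D/8 both weights equal cos(pi/4)
  th8 <- 2 * pi * (geom$D / 8) / geom$D
  expect_equal(cos(th8), sin(th8), tolerance = 1e-15)
})

test_that("signals are linear in the currents and in the moments", {
  geom <- scan_geometry()
  J <- basis_currents(make_phantom("two_contrast"), geom)
  S1 <- signal_from_currents(J, geom)
  J2 <- list(phi = current_field(2 * J$phi$I, J$phi$edges, 20, 20, 0.02,
                                 J$phi$origin, "phi"),
             psi = current_field(2 * J$psi$I, J$psi$edges, 20, 20, 0.02,
                                 J$psi$origin, "psi"))
  S2 <- signal_from_currents(J2, geom)
  expect_equal(S2$total$values, 2 * S1$total$values, tolerance = 1e-12)
  Jz <- list(phi = current_field(0 * J$phi$I, J$phi$edges, 20, 20, 0.02,
                                 J$phi$origin, "phi"),
             psi = current_field(0 * J$psi$I, J$psi$edges, 20, 20, 0.02,
                                 J$psi$origin, "psi"))
  expect_true(all(signal_from_currents(Jz, geom)$total$values == 0))
})

test_that("current and moment formulations give identical signals", {
  geom <- scan_geometry()
  for (seed in c(2, 5)) {
    ph <- random_phantom(seed, n_perturbations = 2)
    J <- basis_currents(ph, geom)
    m <- list(phi = currents_to_moments(J$phi),
              psi = currents_to_moments(J$psi))
    Sc <- signal_from_currents(J, geom)
    Sm <- signal_from_moments(m, geom)
    expect_lt(max(abs(Sc$total$values - Sm$total$values)) /
                max(abs(Sc$total$values)), 1e-6)
  }
  # identity also holds for arbitrary (non-solved) moment arrays
  set.seed(9)
  for (rep in 1:20) {
    mv <- matrix(rnorm(400), 20, 20)
    m <- moment_field(mv)
    Jm <- moments_to_currents(m)
    ec <- as.vector(signal_from_currents(Jm, geom)$values)
    em <- as.vector(signal_from_moments(m, geom)$values)
    expect_lt(max(abs(ec - em)) / max(abs(em)), 1e-6)
  }
})

test_that("single unit moment signal traces the receiver flux density", {
  geom <- scan_geometry()
  m <- matrix(0, 20, 20)
  m[10, 10] <- 1                       # pixel centred at (-0.01, -0.01)
  env <- signal_from_moments(moment_field(m), geom)
  pc <- pixel_centers(geom)
  x0 <- pc$x[10]; y0 <- pc$y[10]
  for (r in c(1, 4)) {
    ref <- sapply(geom$scan_positions, function(xs)
      mitchain:::recv_Bzgrid_matrix(geom, x0 + xs, y0, geom$cell_size)[1, r])
    expect_equal(env$values[, r], ref, tolerance = 1e-12)
  }
})

test_that("moment <-> current conversion round-trips exactly", {
  set.seed(11)
  for (rep in 1:50) {
    mv <- matrix(rnorm(100), 10, 10)
    m <- moment_field(mv)
    J <- moments_to_currents(m)
    m2 <- currents_to_moments(J)
    expect_lt(max(abs(m2$values - mv)), 1e-12)
  }
  # path independence: bottom vs left sweep
  mv <- matrix(rnorm(100), 10, 10)
  J <- moments_to_currents(moment_field(mv))
  mb <- currents_to_moments(J, from = "bottom")
  ml <- currents_to_moments(J, from = "left")
  expect_lt(max(abs(mb$values - ml$values)), 1e-12)
  # node-rule-violating input is rejected
  J$I[3] <- J$I[3] + 1
  expect_error(currents_to_moments(J), "node rule")
})

test_that("solved current fields convert to exactly c^2 moments", {
  geom <- scan_geometry()
  J <- basis_currents(make_phantom("two_contrast"), geom)
  m <- currents_to_moments(J$phi)
  expect_identical(dim(m$values), c(20L, 20L))
  J2 <- moments_to_currents(m)
  expect_lt(max(abs(J2$I - J$phi$I)) / max(abs(J$phi$I)), 1e-12)
})

test_that("current field CSV round-trips", {
  geom <- scan_geometry()
  J <- basis_currents(make_phantom("two_contrast"), geom)$phi
  path <- withr::local_tempfile(fileext = ".csv")
  write_currents(J, path)
  J2 <- read_currents(path)
  expect_equal(J2$I, J$I, tolerance = 1e-12)
  expect_identical(J2$basis, "phi")
})
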