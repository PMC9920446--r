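# Excitation and receiver field maps.
#
# All fields are magnetostatic closed forms under the weak-coupling
# assumption: neither the excitation vector potential A_E nor the receiver
# adjoint fields A_R / B_R are ever modified by the solved eddy currents.
# SI units; mu0/(4*pi) = 1e-7.  The undulator amplitude is normalised so the
# ideal mode has unit amplitude at the undulator plane.

MU0_4PI <- 1e-7

#' Undulator excitation vector potential
#'
#' Evaluates the excitation vector potential A_E of the spatially periodic
#' undulator at sample points in the body frame.  In `"ideal"` mode the
#' undulator is an infinite sinusoidal current sheet: the only nonzero
#' component is along the stripes (y) and equals
#' `cos(2*pi*x_lab/D) * exp(-2*pi*z/D)` where `x_lab = x + x_s`.  In
#' `"stripes"` mode the field is the Biot-Savart superposition of
#' `n_stripes` parallel straight wires with alternating current direction at
#' spacing `D/2`, normalised so its fundamental Fourier harmonic matches the
#' ideal mode.
#'
#' @param geometry A [scan_geometry()].
#' @param points Data frame or list with numeric `x`, `y` (body frame, m).
#'   An optional `z` column gives the distance below the sheet plane at
#'   which to evaluate; default 0 (the sheet plane, i.e. a total distance
#'   `z_exciter` from the undulator).
#' @param mode `"ideal"` or `"stripes"`.
#' @param x_s Scan position (m); the body frame is shifted by `x_s`.
#' @param n_stripes Odd number of stripes for `"stripes"` mode.
#' @return A data frame with columns `x`, `y`, `Ax`, `Ay` (class
#'   `field_map`).
#' @export
undulator_potential <- function(geometry, points, mode = c("ideal", "stripes"),
                                x_s = 0, n_stripes = 11) {
  mode <- match.arg(mode)
  x <- points$x
  y <- points$y
  z <- if (!is.null(points$z)) points$z else rep(0, length(x))
  zdist <- geometry$z_exciter + z   # distance from the undulator plane
  if (any(zdist <= 0))
    stop("undulator field requested at or below the undulator plane ",
         "(z distance must be > 0 in ideal mode)")
  xl <- x + x_s
  D <- geometry$D
  if (mode == "ideal") {
    Ay <- cos(2 * pi * xl / D) * exp(-2 * pi * zdist / D)
  } else {
    if (n_stripes %% 2 != 1) stop("n_stripes must be odd")
    kmax <- (n_stripes - 1) / 2
    # alternating straight wires along y at lab x = k*D/2; wire at x = 0
    # carries +I so the pattern peaks at x = 0 like the ideal cosine.
    # The outermost stripes carry half weight (zero net current), and the
    # gauge constant plus slowly varying truncation background - which
    # drive no eddy currents - are removed by the half-difference of
    # positions half a period apart: the array has only odd spatial
    # harmonics, which that difference preserves exactly.
    stripe_sum <- function(xq) {
      s <- numeric(length(xq))
      for (k in seq(-kmax, kmax)) {
        w <- if (abs(k) == kmax) 0.5 else 1
        rho <- sqrt((xq - k * D / 2)^2 + zdist^2)
        s <- s + w * (-1)^k * (-2 * MU0_4PI) * log(rho)
      }
      s
    }
    Ay <- (stripe_sum(xl) - stripe_sum(xl + D / 2)) / 2
    Ay <- Ay / (4e-7)   # fundamental harmonic of the array is mu0*I/pi
  }
  structure(data.frame(x = x, y = y, z = z, Ax = 0, Ay = Ay),
            class = c("field_map", "data.frame"))
}

# Stable ln((u2+R2)/(u1+R1)) for the finite-segment vector potential:
# for negative u the direct form cancels catastrophically; use
# u + R = rho2 / (R - u).
segment_log_term <- function(u, rho2) {
  R <- sqrt(u^2 + rho2)
  ifelse(u >= 0, u + R, rho2 / (R - u))
}

# Vector potential (component along the wire) of a finite straight segment
# carrying unit current.  u1, u2: signed coordinates of the segment ends
# along the wire measured from the field point's foot; rho2: squared
# perpendicular distance.
segment_A <- function(u1, u2, rho2) {
  MU0_4PI * log(segment_log_term(u2, rho2) / segment_log_term(u1, rho2))
}

# Biot-Savart factor (u2/R2 - u1/R1)/rho^2 for the same segment; the field
# components follow as B_perp = MU0_4PI * f * (perpendicular offsets).
segment_Bfac <- function(u1, u2, rho2) {
  (u2 / sqrt(u2^2 + rho2) - u1 / sqrt(u1^2 + rho2)) / rho2
}

# Per-receiver evaluation helpers.  Inputs are *lab frame* coordinates of
# the field points at the sheet plane (z = 0); the receiver segment sits at
# z = z_receiver.  Outputs are matrices [n_points x n_receivers].

recv_A_matrix <- function(geometry, xlab, ylab) {
  rec <- geometry$receivers
  zr <- geometry$z_receiver
  n <- length(xlab)
  A <- matrix(0, n, nrow(rec))
  for (r in seq_len(nrow(rec))) {
    L <- rec$length[r]
    if (rec$orient[r] == "y") {
      rho2 <- (xlab - rec$x[r])^2 + zr^2
      u1 <- (rec$y[r] - L / 2) - ylab
      u2 <- (rec$y[r] + L / 2) - ylab
    } else {
      rho2 <- (ylab - rec$y[r])^2 + zr^2
      u1 <- (rec$x[r] - L / 2) - xlab
      u2 <- (rec$x[r] + L / 2) - xlab
    }
    if (any(rho2 == 0))
      stop("field point coincides with a receiver segment axis (singular)")
    A[, r] <- segment_A(u1, u2, rho2)
  }
  A
}

# Closed-form z-component of B_R at the sheet plane.
recv_Bz_matrix <- function(geometry, xlab, ylab) {
  rec <- geometry$receivers
  zr <- geometry$z_receiver
  n <- length(xlab)
  B <- matrix(0, n, nrow(rec))
  for (r in seq_len(nrow(rec))) {
    L <- rec$length[r]
    if (rec$orient[r] == "y") {
      dx <- xlab - rec$x[r]
      rho2 <- dx^2 + zr^2
      u1 <- (rec$y[r] - L / 2) - ylab
      u2 <- (rec$y[r] + L / 2) - ylab
      f <- segment_Bfac(u1, u2, rho2)
      B[, r] <- -MU0_4PI * dx * f      # Bz = d(Ay)/dx
    } else {
      dy <- ylab - rec$y[r]
      rho2 <- dy^2 + zr^2
      u1 <- (rec$x[r] - L / 2) - xlab
      u2 <- (rec$x[r] + L / 2) - xlab
      f <- segment_Bfac(u1, u2, rho2)
      B[, r] <- MU0_4PI * dy * f       # Bz = -d(Ax)/dy
    }
  }
  B
}

# Grid-consistent flux density: the discrete curl of A_R at the pixel pitch
# h (central differences of the segment vector potential).  This is the
# B that makes the moment-formulation signal algebraically identical to the
# current-formulation signal on the discrete lattice.
recv_Bzgrid_matrix <- function(geometry, xlab, ylab, h) {
  rec <- geometry$receivers
  is_y <- rec$orient == "y"
  B <- matrix(0, length(xlab), nrow(rec))
  if (any(is_y)) {
    Ap <- recv_A_matrix(geometry, xlab + h / 2, ylab)
    Am <- recv_A_matrix(geometry, xlab - h / 2, ylab)
    B[, is_y] <- (Ap[, is_y, drop = FALSE] - Am[, is_y, drop = FALSE]) / h
  }
  if (any(!is_y)) {
    Ap <- recv_A_matrix(geometry, xlab, ylab + h / 2)
    Am <- recv_A_matrix(geometry, xlab, ylab - h / 2)
    B[, !is_y] <- -(Ap[, !is_y, drop = FALSE] - Am[, !is_y, drop = FALSE]) / h
  }
  B
}

#' Receiver adjoint vector potential and flux density
#'
#' Each receiver is modelled as a finite straight conductor segment carrying
#' unit current at height `z_receiver` above the sheet.  `A_R` follows the
#' closed-form segment vector potential, `B_R` the closed-form segment
#' Biot-Savart law; both are reciprocity weights for signal synthesis, never
#' altered by the eddy currents.
#'
#' @param geometry A [scan_geometry()].
#' @param points Data frame or list with `x`, `y` (body frame, m) at the
#'   sheet plane.
#' @param x_s Scan position (m): fields are evaluated at
#'   `(x + x_s, y + y0)` in the lab frame.
#' @param what `"A"` for the vector potential component matrix (along each
#'   receiver's own orientation), `"Bz"` for the closed-form z flux density,
#'   `"Bz_grid"` for the discrete-curl flux density at the pixel pitch.
#' @return A matrix `[n_points x n_receivers]`.
#' @export
receiver_fields <- function(geometry, points, x_s = 0,
                            what = c("A", "Bz", "Bz_grid")) {
  what <- match.arg(what)
  xl <- points$x + x_s
  yl <- points$y + geometry$y0
  switch(what,
         A = recv_A_matrix(geometry, xl, yl),
         Bz = recv_Bz_matrix(geometry, xl, yl),
         Bz_grid = recv_Bzgrid_matrix(geometry, xl, yl, geometry$cell_size))
}

#' Export a field map to CSV
#'
#' @param fm A `field_map` data frame (from [undulator_potential()]) or a
#'   plain matrix of per-receiver values with point coordinates supplied via
#'   `points`.
#' @param path Output CSV path.
#' @param points Optional coordinates when `fm` is a matrix.
#' @export
write_field_map <- function(fm, path, points = NULL) {
  if (is.matrix(fm)) {
    stopifnot(!is.null(points))
    df <- data.frame(x = points$x, y = points$y)
    colnames(fm) <- paste0("receiver_", seq_len(ncol(fm)))
    df <- cbind(df, fm)
  } else {
    df <- as.data.frame(fm)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
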