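# Shared small fixtures, built in code.

# Default full-size geometry (20 x 20 sheet, receivers at 10 cm).
default_geom <- function(...) scan_geometry(...)

# Reduced geometry for expensive linear-algebra tests: 10 x 10 sheet,
# 100 scan positions.
reduced_geom <- function(...) {
  scan_geometry(sheet_size = 0.2, scan = list(min = -0.3, max = 0.3, n = 100),
                ...)
}

# Forward-simulated differential signal of a phantom against the
# homogeneous reference, with the true carrier components retained.
differential_signals <- function(phantom, geom,
                                 reference = NULL) {
  if (is.null(reference))
    reference <- conductivity_grid(
      matrix(0.5, geom$ny, geom$nx), geom$cell_size, geom$origin,
      phantom$thickness)
  Sh <- signal_from_currents(basis_currents(reference, geom), geom)
  Sp <- signal_from_currents(basis_currents(phantom, geom), geom)
  list(phi = Sp$phi$values - Sh$phi$values,
       psi = Sp$psi$values - Sh$psi$values,
       total = scan_signal(Sp$total$values - Sh$total$values,
                           geom$scan_positions, "differential"))
}

# Differential basis current fields of a phantom vs the homogeneous body.
differential_currents <- function(phantom, geom) {
  ref <- conductivity_grid(matrix(0.5, geom$ny, geom$nx),
                           geom$cell_size, geom$origin, phantom$thickness)
  Jh <- basis_currents(ref, geom)
  Jp <- basis_currents(phantom, geom)
  list(phi = current_field(Jp$phi$I - Jh$phi$I, Jh$phi$edges, geom$nx,
                           geom$ny, geom$cell_size, geom$origin, "phi"),
       psi = current_field(Jp$psi$I - Jh$psi$I, Jh$psi$edges, geom$nx,
                           geom$ny, geom$cell_size, geom$origin, "psi"))
}

# Centre of mass (row, col) of the positive (sign = +1) or negative
# (sign = -1) part of a conductivity map relative to its background.
perturbation_com <- function(sigma_values, sign = 1, background = 0.5) {
  d <- (sigma_values - background) * sign
  d[d < 0] <- 0
  w <- d / sum(d)
  c(sum(row(sigma_values) * w), sum(col(sigma_values) * w))
}
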