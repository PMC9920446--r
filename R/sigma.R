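# Stage 4: nonlinear iterative reconstruction of the conductivity grid from
# the measured phi/psi current fields.  Signs of the current elements are
# dropped; per-pixel current amounts of the two basis positions are
# combined in quadrature, and the ratio of measured to estimated amounts
# multiplies the conductivity estimate (clamped to [0, sigma_cap]).

# Split an edge-current vector into its |I| lattices:
#   list(x = (ny+1) x nx matrix [line, col], y = ny x (nx+1) [row, vline]).
edge_abs_lattices <- function(J) {
  nx <- J$nx; ny <- J$ny
  kx <- nx * (ny + 1L)
  Ix <- t(matrix(abs(J$I[seq_len(kx)]), nrow = nx))        # [line l+1, col]
  Iy <- matrix(abs(J$I[(kx + 1L):length(J$I)]), nrow = ny) # [row, vline v+1]
  list(x = Ix, y = Iy)
}

# Per-pixel current amount of a single field: mean (or RMS) of the absolute
# currents on the pixel's 4 bordering edges.
pixel_amount <- function(J, condense = c("mean", "rms")) {
  condense <- match.arg(condense)
  a <- edge_abs_lattices(J)
  nx <- J$nx; ny <- J$ny
  bot <- a$x[1:ny, , drop = FALSE]
  top <- a$x[2:(ny + 1), , drop = FALSE]
  lef <- a$y[, 1:nx, drop = FALSE]
  rig <- a$y[, 2:(nx + 1), drop = FALSE]
  if (condense == "mean") {
    (bot + top + lef + rig) / 4
  } else {
    sqrt((bot^2 + top^2 + lef^2 + rig^2) / 4)
  }
}

#' Per-pixel current intensity of a basis current pair
#'
#' Condenses the absolute edge currents of each basis field to one amount
#' per pixel (mean of the 4 bordering edges by default) and combines the
#' two positions in quadrature:
#' `I = sqrt(I_phi^2 + I_psi^2)`.
#'
#' @param J_phi,J_psi [current_field()]s on the same grid.
#' @param condense `"mean"` or `"rms"` edge-to-pixel condensation.
#' @return Object of class `intensity_map`: `ny x nx` matrix of
#'   non-negative amounts (A) with the grid metric attached.
#' @export
pixel_intensity <- function(J_phi, J_psi, condense = c("mean", "rms")) {
  stopifnot(J_phi$nx == J_psi$nx, J_phi$ny == J_psi$ny)
  v <- sqrt(pixel_amount(J_phi, condense)^2 +
              pixel_amount(J_psi, condense)^2)
  structure(list(values = v, cell_size = J_phi$cell_size,
                 origin = J_phi$origin),
            class = "intensity_map")
}

#' Multiplicative conductivity correction array
#'
#' `K = I_M / I_E` elementwise; pixels whose estimated intensity falls
#' below `eps_rel * max(I_E)` carry no correction information and get
#' `K = 1`.  A measured amount above the estimate raises the local
#' conductivity, and vice versa.
#'
#' @param I_M,I_E [pixel_intensity()] maps (measured / estimated).
#' @param eps_rel Relative guard threshold in (0, 1).
#' @return `ny x nx` matrix of non-negative correction factors.
#' @export
correction_array <- function(I_M, I_E, eps_rel = 1e-3) {
  stopifnot(eps_rel > 0, eps_rel < 1)
  m <- I_M$values; e <- I_E$values
  guard <- eps_rel * max(e)
  K <- matrix(1, nrow(m), ncol(m))
  ok <- e >= guard & guard > 0
  K[ok] <- m[ok] / e[ok]
  K
}

#' Iterative nonlinear conductivity reconstruction
#'
#' From an initial estimate, alternates forward eddy-current solves with
#' multiplicative intensity corrections: forward-solve the basis currents
#' of the current estimate, form the measured and estimated pixel
#' intensities, correct `sigma <- clip(sigma * K, 0, sigma_cap)`, and stop
#' after `max_iter` repetitions or when `max|K - 1| < tol`.  The true
#' conductivity is a fixed point when the measured currents are exact.
#'
#' @param sigma_init Initial [conductivity_grid()] (e.g. homogeneous).
#' @param J_meas Measured basis pair (list `phi`, `psi` of
#'   [current_field()]s).
#' @param geometry A [scan_geometry()].
#' @param max_iter Maximum corrections (default 10).
#' @param sigma_cap Upper conductivity clamp (S/m); 1 covers the
#'   biomedical range.
#' @param tol Stationarity threshold on `max|K - 1|`.
#' @param eps_rel Intensity guard, see [correction_array()].
#' @param condense Edge-to-pixel condensation rule.
#' @param mode,n_stripes Undulator options for the forward solves.
#' @return List with `sigma` (final [conductivity_grid()]) and `history`
#'   (per-iteration `max_K_dev`, per-pixel `map_change`, map-stationarity
#'   `map_change_maxnorm`, and sigma snapshots).
#' @export
iterate_conductivity <- function(sigma_init, J_meas, geometry,
                                 max_iter = 10, sigma_cap = 1,
                                 tol = 0.01, eps_rel = 1e-3,
                                 condense = "mean",
                                 mode = "ideal", n_stripes = 11) {
  stopifnot(all(sigma_init$values >= 0))
  I_M <- pixel_intensity(J_meas$phi, J_meas$psi, condense)
  sigma <- sigma_init
  hist <- list(max_K_dev = numeric(0), map_change = numeric(0),
               map_change_maxnorm = numeric(0), sigma = list())
  prev_dev <- Inf
  for (it in seq_len(max_iter)) {
    J_E <- basis_currents(sigma, geometry, mode = mode, n_stripes = n_stripes)
    I_E <- pixel_intensity(J_E$phi, J_E$psi, condense)
    K <- correction_array(I_M, I_E, eps_rel)
    new_vals <- pmin(pmax(sigma$values * K, 0), sigma_cap)
    dev <- max(abs(K - 1))
    denom <- pmax(sigma$values, 1e-12)
    change <- max(abs(new_vals - sigma$values) / denom)
    # map-stationarity measure: max-norm change relative to the map scale
    change_mn <- max(abs(new_vals - sigma$values)) / max(sigma$values, 1e-12)
    sigma <- conductivity_grid(new_vals, sigma$cell_size, sigma$origin,
                               sigma$thickness)
    hist$max_K_dev <- c(hist$max_K_dev, dev)
    hist$map_change <- c(hist$map_change, change)
    hist$map_change_maxnorm <- c(hist$map_change_maxnorm, change_mn)
    hist$sigma[[it]] <- sigma
    if (dev > prev_dev * (1 + 1e-9))
      warning(sprintf("max|K-1| increased at iteration %d (%.3g -> %.3g)",
                      it, prev_dev, dev))
    prev_dev <- dev
    if (dev < tol) break
  }
  list(sigma = sigma, history = hist)
}
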