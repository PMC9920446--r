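# Stage 3: lossless conversion from moment arrays to eddy-current fields by
# the discrete curl.  With moments restricted to the z-direction the 2D
# specialisation reads, for square cells of pitch h:
#   I_x(line l, col j) = (m[l+1, j] - m[l, j]) / h^2
#   I_y(row i, vline v) = (m[i, v] - m[i, v+1]) / h^2
# with m = 0 outside the grid.  Every elementary moment is a localised
# four-edge circulation; superposing them yields the interconnected eddy
# field, and the node rule holds exactly by construction.

#' Eddy currents from a moment field (discrete curl)
#'
#' @param m A [moment_field()] (or plain matrix plus `cell_size`/`origin`).
#' @param cell_size,origin Used only when `m` is a plain matrix.
#' @return A [current_field()] satisfying the node rule to round-off.
#' @export
#' @examples
#' m <- moment_field(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
#' J <- moments_to_currents(m)
#' max(abs(J$I)) * J$cell_size   # elementary vortex: |I| * dl = 1 / dl
moments_to_currents <- function(m, cell_size = 0.02, origin = NULL) {
  if (!inherits(m, "moment_field"))
    m <- moment_field(m, cell_size, origin)
  v <- m$values
  ny <- nrow(v); nx <- ncol(v)
  h2 <- m$cell_size^2
  P <- rbind(0, v, 0)
  Ix <- (P[2:(ny + 2), , drop = FALSE] - P[1:(ny + 1), , drop = FALSE]) / h2
  Q <- cbind(0, v, 0)
  Iy <- (Q[, 1:(nx + 1), drop = FALSE] - Q[, 2:(nx + 2), drop = FALSE]) / h2
  I <- c(as.vector(t(Ix)), as.vector(Iy))
  e <- grid_edge_table(nx, ny, m$cell_size, m$origin)
  current_field(I, e, nx, ny, m$cell_size, m$origin, m$basis)
}

#' Total current fields from differential and estimated fields
#'
#' Differential MIT reconstructs only the current difference relative to a
#' known reference body; adding the reference's absolute basis currents
#' yields the "measured" total current fields consumed by the conductivity
#' stage.
#'
#' @param dJ Differential basis pair (list `phi`, `psi` of
#'   [current_field()]s).
#' @param J_est Reference/estimated basis pair on the same grid.
#' @return Basis pair of summed current fields.
#' @export
reconstructed_total_currents <- function(dJ, J_est) {
  stopifnot(all(c("phi", "psi") %in% names(dJ)),
            all(c("phi", "psi") %in% names(J_est)))
  out <- lapply(c("phi", "psi"), function(cc) {
    a <- dJ[[cc]]; b <- J_est[[cc]]
    if (a$nx != b$nx || a$ny != b$ny ||
        abs(a$cell_size - b$cell_size) > 1e-12 ||
        any(abs(a$origin - b$origin) > 1e-12))
      stop("mismatched grids in reconstructed_total_currents")
    current_field(a$I + b$I, a$edges, a$nx, a$ny, a$cell_size, a$origin, cc)
  })
  names(out) <- c("phi", "psi")
  out
}
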