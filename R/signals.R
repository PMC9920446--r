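# Receiver signal synthesis via reciprocity, in both formulations:
# currents dotted with the receiver vector potential, and moments dotted
# with the (grid-consistent) receiver flux density.  On the discrete
# lattice the two paths are algebraically identical.

#' Per-receiver scan signal traces
#'
#' @param values Numeric matrix `[n_scan x n_receivers]`.
#' @param x_s Scan position vector (m).
#' @param component Label: `"total"`, `"phi"`, `"psi"`, `"differential"`, ...
#' @return Object of class `scan_signal`.
#' @export
scan_signal <- function(values, x_s, component = "total") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(x_s))
  structure(list(values = values, x_s = x_s, component = component),
            class = "scan_signal")
}

#' @export
print.scan_signal <- function(x, ...) {
  cat(sprintf("Scan signal (%s): %d positions x %d receivers, max |S| = %.3g\n",
              x$component, nrow(x$values), ncol(x$values),
              max(abs(x$values))))
  invisible(x)
}

# Stack a scan-signal matrix receiver-block-wise (receiver-major blocks of
# n_scan samples), matching the transfer-matrix row ordering.
stack_signal <- function(S) as.vector(S$values)

unstack_signal <- function(v, x_s, n_recv, component = "total") {
  scan_signal(matrix(v, nrow = length(x_s), ncol = n_recv), x_s, component)
}

# Envelope of the reciprocity sum for a single current field:
# E[s, r] = sum_e I_e * dl * (dir_e . A_R_r) at body points shifted by x_s.
current_signal_envelope <- function(J, geometry) {
  e <- J$edges
  xs <- geometry$scan_positions
  nr <- nrow(geometry$receivers)
  # per-receiver direction mask: a receiver's A_R points along its own axis
  dmask <- outer(e$diry, as.integer(geometry$receivers$orient == "y")) +
    outer(e$dirx, as.integer(geometry$receivers$orient == "x"))
  W <- dmask * (J$I * e$dl)
  keep <- rowSums(abs(W)) > 0
  W <- W[keep, , drop = FALSE]
  mx <- e$mx[keep]; my <- e$my[keep]
  env <- matrix(0, length(xs), nr)
  for (s in seq_along(xs)) {
    A <- recv_A_matrix(geometry, mx + xs[s], my + geometry$y0)
    env[s, ] <- colSums(A * W)
  }
  env
}

# Envelope of the moment formulation: E[s, r] = sum_p m_p * Bz_grid_r.
moment_signal_envelope <- function(m, geometry) {
  pc <- pixel_centers(geometry)
  xs <- geometry$scan_positions
  mv <- as.vector(m$values)   # column-major: y index fastest, matches pc
  nz <- mv != 0
  env <- matrix(0, length(xs), nrow(geometry$receivers))
  if (!any(nz)) return(env)
  xc <- pc$xc[nz]; yc <- pc$yc[nz]; w <- mv[nz]
  for (s in seq_along(xs)) {
    B <- recv_Bzgrid_matrix(geometry, xc + xs[s] ,
                            yc + geometry$y0, geometry$cell_size)
    env[s, ] <- colSums(B * w)
  }
  env
}

carrier <- function(geometry, component = c("phi", "psi"), x_s = NULL) {
  component <- match.arg(component)
  if (is.null(x_s)) x_s <- geometry$scan_positions
  th <- 2 * pi * x_s / geometry$D
  if (component == "phi") cos(th) else sin(th)
}

#' Receiver signals from the basis eddy currents
#'
#' Reciprocity synthesis: for each scan position the basis current field is
#' weighted by the receiver vector potential evaluated in the shifted body
#' frame, and modulated by its sinusoidal carrier.  The total signal is the
#' sum of the two components.
#'
#' @param J Basis pair from [basis_currents()] (list with `phi`, `psi`),
#'   or a single [current_field()] (then no carrier is applied and a single
#'   `scan_signal` is returned).
#' @param geometry A [scan_geometry()].
#' @return For a basis pair: list with `phi`, `psi`, `total` scan signals
#'   (the components carry their carrier).  For a single field: one
#'   `scan_signal` of the un-modulated reciprocity trace.
#' @export
signal_from_currents <- function(J, geometry) {
  if (inherits(J, "current_field")) {
    env <- current_signal_envelope(J, geometry)
    return(scan_signal(env, geometry$scan_positions, "envelope"))
  }
  stopifnot(all(c("phi", "psi") %in% names(J)))
  xs <- geometry$scan_positions
  Sphi <- carrier(geometry, "phi") * current_signal_envelope(J$phi, geometry)
  Spsi <- carrier(geometry, "psi") * current_signal_envelope(J$psi, geometry)
  list(phi = scan_signal(Sphi, xs, "phi"),
       psi = scan_signal(Spsi, xs, "psi"),
       total = scan_signal(Sphi + Spsi, xs, "total"))
}

#' Receiver signals from magnetic dipole moments
#'
#' The dual formulation: per-pixel z-moments weighted by the z-component of
#' the receiver flux density.  Uses the grid-consistent discrete-curl flux
#' density so that the result is algebraically identical to
#' [signal_from_currents()] applied to the curl of the moments.
#'
#' @param m Basis pair (list with `phi`, `psi` [moment_field()]s) or a
#'   single `moment_field`.
#' @param geometry A [scan_geometry()].
#' @param modulate Apply the sinusoidal carriers (default `TRUE`; ignored
#'   for a single field, which returns the raw envelope).
#' @return As [signal_from_currents()].
#' @export
signal_from_moments <- function(m, geometry, modulate = TRUE) {
  if (inherits(m, "moment_field")) {
    env <- moment_signal_envelope(m, geometry)
    return(scan_signal(env, geometry$scan_positions, "envelope"))
  }
  stopifnot(all(c("phi", "psi") %in% names(m)))
  xs <- geometry$scan_positions
  ephi <- moment_signal_envelope(m$phi, geometry)
  epsi <- moment_signal_envelope(m$psi, geometry)
  if (modulate) {
    ephi <- carrier(geometry, "phi") * ephi
    epsi <- carrier(geometry, "psi") * epsi
  }
  list(phi = scan_signal(ephi, xs, "phi"),
       psi = scan_signal(epsi, xs, "psi"),
       total = scan_signal(ephi + epsi, xs, "total"))
}

#' Moments from a node-rule-consistent current field
#'
#' Discrete line-integral inversion of the lattice curl: anchored at zero
#' outside the body, the per-pixel z-moment is accumulated from the
#' boundary inward (`m` is the discrete vector potential of the edge
#' currents).  Exact right/left inverse of [moments_to_currents()].
#'
#' @param J A [current_field()] satisfying the node rule.
#' @param from Sweep direction, `"bottom"` (x-edges) or `"left"` (y-edges);
#'   both give identical results for node-rule-consistent input.
#' @param tol Relative node-rule tolerance for rejecting inconsistent input.
#' @return A [moment_field()].
#' @export
currents_to_moments <- function(J, from = c("bottom", "left"), tol = 1e-8) {
  from <- match.arg(from)
  nx <- J$nx; ny <- J$ny
  n_nodes <- (nx + 1L) * (ny + 1L)
  mi <- max(abs(J$I))
  if (mi > 0) {
    res <- max(abs(node_residuals(J$I, J$edges, n_nodes)))
    if (res > tol * mi)
      stop(sprintf(
        "current field violates the node rule (residual %.3g > %.3g): no consistent moment field exists",
        res, tol * mi))
  }
  h2 <- J$cell_size^2
  kx <- nx * (ny + 1L)
  if (from == "bottom") {
    Ix <- matrix(J$I[seq_len(kx)], nrow = nx)          # [j, line l+1]
    C <- apply(Ix, 1, cumsum)                          # [(l+1), j]
    m <- C[seq_len(ny), , drop = FALSE] * h2           # rows = pixel rows
  } else {
    Iy <- matrix(J$I[(kx + 1L):length(J$I)], nrow = ny)  # [i, vline v+1]
    C <- apply(Iy, 1, cumsum)                            # [(v+1), i]
    m <- -t(C[seq_len(nx), , drop = FALSE]) * h2
  }
  moment_field(m, J$cell_size, J$origin, J$basis)
}

#' Write / read a scan signal as CSV
#'
#' Long format with columns `receiver_id`, `x_s`, `value`, `component`.
#'
#' @param S A [scan_signal()] or list of them (e.g. the `phi`/`psi`/`total`
#'   set from [signal_from_currents()]).
#' @param path CSV path.
#' @export
write_signal <- function(S, path) {
  if (inherits(S, "scan_signal")) S <- list(S)
  df <- do.call(rbind, lapply(S, function(s) {
    data.frame(receiver_id = rep(seq_len(ncol(s$values)), each = nrow(s$values)),
               x_s = rep(s$x_s, times = ncol(s$values)),
               value = as.vector(s$values),
               component = s$component)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$component), function(d) {
    xs <- sort(unique(d$x_s))
    nr <- max(d$receiver_id)
    v <- matrix(NA_real_, length(xs), nr)
    v[cbind(match(d$x_s, xs), d$receiver_id)] <- d$value
    scan_signal(v, xs, d$component[1])
  })
  if (length(out) == 1) out[[1]] else out
}
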