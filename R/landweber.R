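# Stage 2: moment reconstruction from split signals by Landweber iteration
# over a precomputed transfer matrix.  The matrix maps per-pixel unit
# z-moments to stacked receiver signal traces; it is computed once and is
# valid for both carrier components (carriers enter as diagonal row
# scalings).  Regularisation is by early stopping only.

#' Transfer matrix from pixel moments to stacked signals
#'
#' Row `(receiver rho, scan position s)`, column `(pixel p)` holds the
#' grid-consistent z flux density of receiver `rho` at pixel `p`'s centre
#' shifted by `x_s` - the un-modulated signal a unit moment at that pixel
#' would produce.  Rows are stacked receiver-major (receiver blocks of
#' `n_scan` samples); columns follow the column-major pixel order of the
#' `ny x nx` moment matrix.
#'
#' @param geometry A [scan_geometry()].
#' @return Object of class `transfer_matrix`: list with the dense matrix
#'   `M` (`n_recv*n_scan` x `nx*ny`), `geometry` metadata, and dimensions.
#' @export
build_transfer_matrix <- function(geometry) {
  pc <- pixel_centers(geometry)
  xs <- geometry$scan_positions
  ns <- length(xs)
  nr <- nrow(geometry$receivers)
  np <- geometry$nx * geometry$ny
  M <- matrix(0, nr * ns, np)
  for (s in seq_len(ns)) {
    B <- recv_Bzgrid_matrix(geometry, pc$xc + xs[s], pc$yc + geometry$y0,
                            geometry$cell_size)           # [np x nr]
    M[s + (seq_len(nr) - 1L) * ns, ] <- t(B)
  }
  structure(list(M = M, n_scan = ns, n_recv = nr,
                 nx = geometry$nx, ny = geometry$ny,
                 x_s = xs, D = geometry$D,
                 cell_size = geometry$cell_size, origin = geometry$origin),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("Transfer matrix: %d signal samples (%d receivers x %d positions) x %d moments\n",
              nrow(x$M), x$n_recv, x$n_scan, ncol(x$M)))
  invisible(x)
}

#' Effective number of independent signal entries
#'
#' Counts singular values at or above `rel_threshold` times the largest -
#' the number of signal-space directions above the useful dynamic range.
#' The bandwidth limitation of distant receivers makes this far smaller
#' than the nominal row count, and it shrinks as the receiver distance
#' grows.
#'
#' @param Tm A [build_transfer_matrix()] result or plain matrix.
#' @param rel_threshold Relative singular-value threshold in (0, 1).
#' @return Integer count.
#' @export
effective_rank <- function(Tm, rel_threshold = 1e-3) {
  stopifnot(rel_threshold > 0, rel_threshold < 1)
  M <- if (inherits(Tm, "transfer_matrix")) Tm$M else Tm
  d <- svd(M, nu = 0, nv = 0)$d
  sum(d >= rel_threshold * d[1])
}

# Largest singular value by power iteration on M'M (deterministic start).
spectral_norm <- function(M, iters = 100) {
  v <- rep(1, ncol(M))
  v <- v / sqrt(sum(v^2))
  s <- 0
  for (i in seq_len(iters)) {
    w <- crossprod(M, M %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- as.vector(w) / nw
    s <- nw
  }
  sqrt(s)
}

#' Landweber iteration for the linear moment reconstruction
#'
#' Gradient-descent iteration `m_{k+1} = m_k + tau * M'(s - M m_k)` from a
#' zero start; with `tau` inside `(0, 2/sigma_max^2)` the data residual is
#' non-increasing, and early stopping (a fixed iteration count) acts as the
#' only regularisation.
#'
#' @param Tm Transfer matrix (object or plain matrix), possibly
#'   carrier-scaled.
#' @param s Stacked signal vector (length `nrow(M)`).
#' @param n_iter Number of iterations (default 1000).
#' @param tau Relaxation factor; default `1/sigma_max^2`.
#' @param m_ref Optional reference moment vector; if given, the error norm
#'   `||m_k - m_ref||` is recorded per iteration (semi-convergence
#'   diagnostics).
#' @return List with `m` (solution vector), `residuals` (data residual
#'   norm per iteration), `errors` (if `m_ref` given), `tau`, `sigma_max`.
#' @export
landweber <- function(Tm, s, n_iter = 1000, tau = NULL, m_ref = NULL) {
  M <- if (inherits(Tm, "transfer_matrix")) Tm$M else Tm
  stopifnot(length(s) == nrow(M))
  smax <- spectral_norm(M)
  if (is.null(tau)) {
    tau <- if (smax > 0) 1 / smax^2 else 1
  } else if (smax > 0 && (tau <= 0 || tau >= 2 / smax^2 * (1 + 1e-9))) {
    stop(sprintf("relaxation tau = %.3g outside the convergence interval (0, %.3g)",
                 tau, 2 / smax^2))
  }
  m <- numeric(ncol(M))
  residuals <- numeric(n_iter)
  errors <- if (!is.null(m_ref)) numeric(n_iter) else NULL
  for (k in seq_len(n_iter)) {
    r <- s - as.vector(M %*% m)
    residuals[k] <- sqrt(sum(r^2))
    m <- m + tau * as.vector(crossprod(M, r))
    if (!is.null(m_ref)) errors[k] <- sqrt(sum((m - m_ref)^2))
  }
  list(m = m, residuals = residuals, errors = errors,
       tau = tau, sigma_max = smax)
}

# Carrier weights for one component: the carrier value, zeroed where its
# magnitude is below `null_guard` (samples at carrier nulls carry no
# information for that component and would only amplify noise).
carrier_weights <- function(Tm, component, null_guard = 0.05) {
  th <- 2 * pi * Tm$x_s / Tm$D
  c0 <- if (component == "phi") cos(th) else sin(th)
  c0[abs(c0) < null_guard] <- 0
  rep(c0, times = Tm$n_recv)
}

#' Reconstruct both moment components from split signals
#'
#' Applies the Landweber inversion to each split component against its
#' carrier-scaled transfer matrix (`diag(c) M`, rows at carrier nulls
#' down-weighted to zero).
#'
#' @param split A [split_signal()] result, or a list with `phi`/`psi`
#'   [scan_signal()]s.
#' @param Tm A [build_transfer_matrix()] result.
#' @param n_iter,tau Landweber controls, see [landweber()].
#' @param null_guard Carrier magnitude below which samples are ignored.
#' @return List with `phi`, `psi` [moment_field()]s and the per-component
#'   Landweber diagnostics in `info`.
#' @export
invert_components <- function(split, Tm, n_iter = 1000, tau = NULL,
                              null_guard = 0.05) {
  stopifnot(inherits(Tm, "transfer_matrix"))
  out <- list()
  info <- list()
  for (cc in c("phi", "psi")) {
    w <- carrier_weights(Tm, cc, null_guard)
    s <- stack_signal(split[[cc]])
    s[w == 0] <- 0
    fit <- landweber(w * Tm$M, s, n_iter = n_iter, tau = tau)
    out[[cc]] <- moment_field(matrix(fit$m, Tm$ny, Tm$nx),
                              Tm$cell_size, Tm$origin, basis = cc)
    info[[cc]] <- fit[c("residuals", "tau", "sigma_max")]
  }
  list(phi = out$phi, psi = out$psi, info = info)
}
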