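# Stage 1: decompose a measured scan signal S into its two carrier
# components.  S(x_s) = P(x_s) cos(2 pi x_s / D) + Q(x_s) sin(2 pi x_s / D)
# with slowly varying (bandwidth-limited) envelopes P, Q.  At the carrier
# zeros of one component the other is isolated, giving sparse exact
# envelope samples; interpolation plus a weighted residual correction
# yields components whose sum matches S exactly at every sample.

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Interpolate sparse envelope samples (xk, pk) onto positions x.
interp_envelope <- function(xk, pk, x, method = c("spline", "sinc"),
                            spacing = NULL) {
  method <- match.arg(method)
  if (length(xk) < 2) return(rep(if (length(xk)) pk else 0, length(x)))
  if (method == "spline") {
    stats::spline(xk, pk, xout = x, method = "natural")$y
  } else {
    h <- if (is.null(spacing)) stats::median(diff(xk)) else spacing
    as.vector(outer(x, xk, function(a, b) sinc((a - b) / h)) %*% pk)
  }
}

#' Sample a scan signal at the carrier zeros of one component
#'
#' At positions where the other component's carrier vanishes (spacing `D/2`
#' per component, the two combs interleaved at `D/4`), the measured signal
#' equals the wanted component's envelope up to the sign of its own carrier
#' (+-1).  The signal is read at these positions by natural-spline
#' interpolation of the scan samples.
#'
#' @param S A [scan_signal()].
#' @param geometry A [scan_geometry()].
#' @param gamma Basis shift in `[0, D/4)` (m).
#' @param component `"phi"` (samples where the psi carrier is zero) or
#'   `"psi"`.
#' @return List with `positions` (the carrier-zero x values) and `samples`
#'   (matrix `[n_positions x n_receivers]` of sign-corrected envelope
#'   values).
#' @export
sample_at_carrier_zeros <- function(S, geometry, gamma = 0,
                                    component = c("phi", "psi")) {
  component <- match.arg(component)
  D <- geometry$D
  xs <- S$x_s
  if (diff(range(xs)) < D)
    stop("scan range must cover at least one undulator period")
  # phi component: sin(2 pi (x+gamma)/D) = 0  ->  x = -gamma + k D/2
  # psi component: cos(...) = 0               ->  x = -gamma + D/4 + k D/2
  off <- if (component == "phi") -gamma else -gamma + D / 4
  eps <- 1e-9 * D
  kmin <- ceiling((min(xs) - off - eps) / (D / 2))
  kmax <- floor((max(xs) - off + eps) / (D / 2))
  pos <- off + (kmin:kmax) * (D / 2)
  pos <- pmin(pmax(pos, min(xs)), max(xs))
  th <- 2 * pi * (pos + gamma) / D
  sgn <- if (component == "phi") sign(cos(th)) else sign(sin(th))
  samples <- matrix(0, length(pos), ncol(S$values))
  for (r in seq_len(ncol(S$values))) {
    f <- stats::splinefun(xs, S$values[, r], method = "natural")
    samples[, r] <- f(pos) * sgn
  }
  list(positions = pos, samples = samples)
}

# First-estimate components at shift gamma: envelope interpolation of the
# carrier-zero samples, re-modulated with the shifted carriers.  Returns
# matrices [n_scan x n_recv] for both components.
first_estimates <- function(S, geometry, gamma, interp = "spline") {
  D <- geometry$D
  xs <- S$x_s
  th <- 2 * pi * (xs + gamma) / D
  ephi <- sample_at_carrier_zeros(S, geometry, gamma, "phi")
  epsi <- sample_at_carrier_zeros(S, geometry, gamma, "psi")
  nr <- ncol(S$values)
  Sphi <- matrix(0, length(xs), nr)
  Spsi <- matrix(0, length(xs), nr)
  for (r in seq_len(nr)) {
    P <- interp_envelope(ephi$positions, ephi$samples[, r], xs, interp,
                         spacing = D / 2)
    Q <- interp_envelope(epsi$positions, epsi$samples[, r], xs, interp,
                         spacing = D / 2)
    Sphi[, r] <- P * cos(th)
    Spsi[, r] <- Q * sin(th)
  }
  list(phi = Sphi, psi = Spsi)
}

#' Split a scan signal into its carrier components
#'
#' The splitting proceeds in four steps: (1) a grid search over the basis
#' shift `gamma` in `[0, D/4)` picks the shift that makes the energies of
#' the two first-estimate components as different as possible (the
#' residual correction is then maximally informed); (2) first estimates are
#' formed per receiver by envelope interpolation of the carrier-zero
#' samples, re-modulated with the shifted carriers; (3) the residual
#' `e = S - S_phi_E1 - S_psi_E1` is distributed onto the components with
#' energy-proportional weights, enforcing the exact sum constraint;
#' (4) the shifted-basis result is rotated back to the phi/psi basis by the
#' 2x2 trigonometric rotation with angle `2 pi gamma / D` (envelopes are
#' re-extracted on the well-conditioned half of each carrier before
#' rotating, and the sum constraint is re-imposed exactly).
#'
#' When either true component vanishes, the recovered other component
#' equals `S` exactly.  `gamma` is chosen jointly over all receivers.
#'
#' @param S A [scan_signal()] (typically a differential signal).
#' @param geometry A [scan_geometry()].
#' @param n_gamma Number of gamma grid steps across `[0, D/4)`.
#' @param interp Envelope interpolation: `"spline"` (natural cubic) or
#'   `"sinc"` (band-limited).
#' @param gamma Optional fixed shift; skips the grid search.
#' @return Object of class `split_result`: list with `phi`, `psi`
#'   (second-estimate [scan_signal()]s in the phi/psi basis), `gamma`
#'   (chosen shift), `energy_ratio`, `weights`, and the first estimates
#'   `phi_E1`, `psi_E1` in the shifted basis.
#' @export
split_signal <- function(S, geometry, n_gamma = 16, interp = "spline",
                         gamma = NULL) {
  D <- geometry$D
  xs <- S$x_s
  if (is.null(gamma)) {
    gammas <- seq(0, D / 4, length.out = n_gamma + 1)[seq_len(n_gamma)]
    best <- list(ratio = -1, gamma = 0, est = NULL)
    for (g in gammas) {
      est <- first_estimates(S, geometry, g, interp)
      Ephi <- sum(est$phi^2); Epsi <- sum(est$psi^2)
      ratio <- if (Ephi + Epsi > 0) abs(Ephi - Epsi) / (Ephi + Epsi) else 0
      if (ratio > best$ratio) best <- list(ratio = ratio, gamma = g, est = est)
    }
    gamma <- best$gamma
    est <- best$est
    energy_ratio <- best$ratio
  } else {
    est <- first_estimates(S, geometry, gamma, interp)
    Ephi <- sum(est$phi^2); Epsi <- sum(est$psi^2)
    energy_ratio <- if (Ephi + Epsi > 0) abs(Ephi - Epsi) / (Ephi + Epsi) else 0
  }
  Ephi <- sum(est$phi^2); Epsi <- sum(est$psi^2)
  if (Ephi + Epsi > 0) {
    wphi <- Ephi / (Ephi + Epsi); wpsi <- Epsi / (Ephi + Epsi)
  } else {
    wphi <- 0.5; wpsi <- 0.5
  }
  e <- S$values - est$phi - est$psi
  SphiG <- est$phi + wphi * e
  SpsiG <- est$psi + wpsi * e

  if (gamma == 0) {
    Sphi <- SphiG; Spsi <- SpsiG
  } else {
    # envelope extraction on the well-conditioned half of each carrier,
    # then the 2x2 basis rotation back to gamma = 0
    g2 <- 2 * pi * gamma / D
    thg <- 2 * pi * (xs + gamma) / D
    th <- 2 * pi * xs / D
    cg <- cos(thg); sg <- sin(thg)
    okc <- abs(cg) >= 0.5; oks <- abs(sg) >= 0.5
    nr <- ncol(S$values)
    Sphi <- matrix(0, length(xs), nr)
    Spsi <- matrix(0, length(xs), nr)
    for (r in seq_len(nr)) {
      Pg <- interp_envelope(xs[okc], SphiG[okc, r] / cg[okc], xs, interp)
      Qg <- interp_envelope(xs[oks], SpsiG[oks, r] / sg[oks], xs, interp)
      P <- Pg * cos(g2) + Qg * sin(g2)
      Q <- -Pg * sin(g2) + Qg * cos(g2)
      Sphi[, r] <- P * cos(th)
      Spsi[, r] <- Q * sin(th)
    }
    e2 <- S$values - Sphi - Spsi
    Sphi <- Sphi + wphi * e2
    Spsi <- Spsi + wpsi * e2
  }
  structure(list(
    phi = scan_signal(Sphi, xs, "phi"),
    psi = scan_signal(Spsi, xs, "psi"),
    gamma = gamma,
    energy_ratio = energy_ratio,
    weights = c(phi = wphi, psi = wpsi),
    phi_E1 = scan_signal(est$phi, xs, "phi_E1"),
    psi_E1 = scan_signal(est$psi, xs, "psi_E1")
  ), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Signal split: gamma* = %.4f m, energy ratio %.3f, weights (%.2f, %.2f)\n",
              x$gamma, x$energy_ratio, x$weights[1], x$weights[2]))
  invisible(x)
}
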