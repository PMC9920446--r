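# Synthetic conductivity phantoms and signal noise injection.  The default
# phantom set mirrors the study conditions: a 40 cm x 40 cm sheet in
# 2 cm pixels, 0.5 S/m background, one 1 S/m and one 0.25 S/m rectangular
# perturbation, and additive white Gaussian signal noise at 40 dB SNR on
# the differential signals.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Reference conductivity phantoms
#'
#' `"two_contrast"`: 20 x 20 grid, 0.5 S/m background with a rectangular
#' 1 S/m region (rows 4-7, cols 4-7) and a rectangular 0.25 S/m region
#' (rows 13-16, cols 12-15).  The region positions are package defaults;
#' only the three conductivity levels and the grid metric are prescribed
#' by the scenario the phantom emulates.
#' `"homogeneous"`: uniform 0.5 S/m reference body.
#' `"structured"`: a larger 46 cm sheet (23 x 23 pixels) with several
#' pronounced inhomogeneities concentrated on its right half, useful as a
#' prior-knowledge reference body.
#'
#' @param which Phantom name.
#' @param cell_size Pixel size (m).
#' @param thickness Sheet thickness (m).
#' @return A [conductivity_grid()]; all values within `[0, 1]` S/m.
#' @export
#' @examples
#' table(make_phantom("two_contrast")$values)
make_phantom <- function(which = c("two_contrast", "homogeneous",
                                   "structured"),
                         cell_size = 0.02, thickness = 0.01) {
  which <- match.arg(which)
  if (which == "structured") {
    v <- matrix(0.5, 23, 23)
    v[4:9, 15:20] <- 1.0
    v[13:18, 16:19] <- 0.25
    v[16:19, 4:6] <- 0.25
  } else {
    v <- matrix(0.5, 20, 20)
    if (which == "two_contrast") {
      v[4:7, 4:7] <- 1.0
      v[13:16, 12:15] <- 0.25
    }
  }
  conductivity_grid(v, cell_size, thickness = thickness)
}

#' Seeded random rectangular-perturbation phantom
#'
#' Background 0.5 S/m with `n_perturbations` non-overlapping rectangular
#' regions; sizes (in pixels) and conductivity values drawn uniformly from
#' the given ranges.  Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_perturbations Number of rectangles.
#' @param n Grid side length in pixels.
#' @param size_range Integer range of rectangle side lengths (pixels).
#' @param value_range Conductivity range (S/m) for the perturbations.
#' @param cell_size,thickness Grid metric.
#' @param max_tries Placement retries before giving up.
#' @return A [conductivity_grid()].
#' @export
random_phantom <- function(seed, n_perturbations = 2, n = 20,
                           size_range = c(3, 6),
                           value_range = c(0.1, 1.0),
                           cell_size = 0.02, thickness = 0.01,
                           max_tries = 200) {
  with_seed(seed, {
    v <- matrix(0.5, n, n)
    occupied <- matrix(FALSE, n, n)
    placed <- 0
    tries <- 0
    while (placed < n_perturbations) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place non-overlapping perturbations within retry budget")
      h <- sample(size_range[1]:size_range[2], 1)
      w <- sample(size_range[1]:size_range[2], 1)
      i0 <- sample(seq_len(n - h + 1), 1)
      j0 <- sample(seq_len(n - w + 1), 1)
      ri <- i0:(i0 + h - 1); rj <- j0:(j0 + w - 1)
      if (any(occupied[ri, rj])) next
      val <- stats::runif(1, value_range[1], value_range[2])
      v[ri, rj] <- val
      occupied[ri, rj] <- TRUE
      placed <- placed + 1
    }
    conductivity_grid(v, cell_size, thickness = thickness)
  })
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Scales an additive white Gaussian noise realisation so the power ratio
#' over the stacked trace satisfies
#' `10 log10(signal power / noise power) = snr_db`.
#'
#' @param S A [scan_signal()].
#' @param snr_db Target SNR in dB; `Inf` returns the input unchanged.
#' @param seed Integer seed for the noise realisation.
#' @return A [scan_signal()] with the same dimensions.
#' @export
add_noise <- function(S, snr_db, seed = NULL) {
  if (is.infinite(snr_db)) return(S)
  p_sig <- mean(S$values^2)
  if (p_sig == 0)
    stop("cannot set a finite SNR on a zero-power signal")
  with_seed(seed, {
    noise <- stats::rnorm(length(S$values))
    noise <- noise / sqrt(mean(noise^2)) * sqrt(p_sig / 10^(snr_db / 10))
    scan_signal(S$values + matrix(noise, nrow(S$values)), S$x_s, S$component)
  })
}
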