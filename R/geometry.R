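#' Scanner geometry for the planar undulator MIT system
#'
#' Bundles everything fixed about the scanner: the undulator period, the
#' conductivity sheet discretisation, the two z-distances (undulator-to-sheet
#' and sheet-to-receivers), the receiver segments, and the mechanical scan
#' trajectory.  All downstream field maps, forward solves and inverse stages
#' take a `scan_geometry` as their first structural argument.
#'
#' The sheet is centred at the origin of the body frame: a `sheet_size` of
#' 40 cm with 2 cm cells gives a 20 x 20 pixel grid spanning
#' \[-0.2, 0.2\] m in x and y.  The undulator lies a distance `z_exciter`
#' below the sheet plane, the receivers `z_receiver` above it.  Scanning
#' moves the body along x, so body coordinates map to lab coordinates as
#' `x_lab = x + x_s`.
#'
#' @param D Undulator field period in metres (stripe spacing is `D/2`).
#' @param sheet_size Numeric of length 1 or 2; sheet extent in metres.
#' @param cell_size Pixel edge length in metres; must divide `sheet_size`.
#' @param z_exciter Distance from undulator plane to sheet plane (m), > 0.
#' @param z_receiver Distance from sheet plane to receiver plane (m); 0 is
#'   allowed and denotes the contacting-measurement diagnostic mode.
#' @param receivers Data frame with columns `x`, `y` (segment centre, m),
#'   `length` (m) and `orient` (`"x"` or `"y"`).  Default: 6 segments of
#'   10 cm length oriented along y, centres evenly spaced over the sheet's
#'   y-extent, all at x = 0.
#' @param scan List with `min`, `max`, `n`: uniform scan positions in metres.
#' @param gamma Carrier phase shift in metres, in `[0, D/4)`.
#' @param y0 Fixed lateral offset between body and receiver frames (m).
#' @param thickness Effective sheet thickness (m); a global signal scale.
#'
#' @return An object of class `scan_geometry`.
#' @export
#' @examples
#' geom <- scan_geometry()
#' geom$nx            # 20 pixels per side
#' length(geom$scan_positions)
scan_geometry <- function(D = 0.16,
                          sheet_size = 0.40,
                          cell_size = 0.02,
                          z_exciter = 0.10,
                          z_receiver = 0.10,
                          receivers = NULL,
                          scan = list(min = -0.40, max = 0.40, n = 200),
                          gamma = 0,
                          y0 = 0,
                          thickness = 0.01) {
  if (length(sheet_size) == 1) sheet_size <- rep(sheet_size, 2)
  stopifnot(D > 0, cell_size > 0, all(sheet_size > 0), thickness > 0)
  nx <- sheet_size[1] / cell_size
  ny <- sheet_size[2] / cell_size
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("cell_size must divide sheet_size exactly")
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  if (z_exciter <= 0)
    stop("z_exciter must be > 0 (contactless excitation)")
  if (z_receiver < 0)
    stop("z_receiver must be >= 0 (0 = contacting measurement mode)")
  if (gamma < 0 || gamma >= D / 4)
    stop("gamma must lie in [0, D/4)")
  if (is.null(receivers)) {
    receivers <- data.frame(
      x = rep(0, 6),
      y = seq(-sheet_size[2] / 2, sheet_size[2] / 2, length.out = 6),
      length = rep(0.10, 6),
      orient = rep("y", 6),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(receivers),
            all(c("x", "y", "length", "orient") %in% names(receivers)),
            all(receivers$orient %in% c("x", "y")),
            all(receivers$length > 0))
  stopifnot(is.list(scan), scan$n >= 2, scan$max > scan$min)
  scan_positions <- seq(scan$min, scan$max, length.out = scan$n)

  structure(list(
    D = D,
    sheet_size = sheet_size,
    cell_size = cell_size,
    nx = nx, ny = ny,
    origin = c(-sheet_size[1] / 2, -sheet_size[2] / 2),
    z_exciter = z_exciter,
    z_receiver = z_receiver,
    receivers = receivers,
    scan = scan,
    scan_positions = scan_positions,
    gamma = gamma,
    y0 = y0,
    thickness = thickness
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("Planar MIT scan geometry\n")
  cat(sprintf("  undulator period D: %.3f m (stripe spacing %.3f m)\n",
              x$D, x$D / 2))
  cat(sprintf("  sheet: %.2f x %.2f m, %d x %d pixels of %.3f m\n",
              x$sheet_size[1], x$sheet_size[2], x$nx, x$ny, x$cell_size))
  cat(sprintf("  z: undulator->sheet %.3f m, sheet->receivers %.3f m%s\n",
              x$z_exciter, x$z_receiver,
              if (x$z_receiver == 0) " (contacting)" else ""))
  cat(sprintf("  receivers: %d segments; scan: %d positions in [%.2f, %.2f] m\n",
              nrow(x$receivers), length(x$scan_positions),
              x$scan$min, x$scan$max))
  invisible(x)
}

#' Pixel centre coordinates of the sheet grid
#'
#' @param geometry A `scan_geometry`.
#' @return List with vectors `x` (length `nx`), `y` (length `ny`) and the
#'   full grid `xc`, `yc` (length `nx*ny`, column-major with y fastest,
#'   matching `as.vector()` of an `ny x nx` pixel matrix).
#' @export
pixel_centers <- function(geometry) {
  dx <- geometry$cell_size
  x <- geometry$origin[1] + (seq_len(geometry$nx) - 0.5) * dx
  y <- geometry$origin[2] + (seq_len(geometry$ny) - 0.5) * dx
  list(x = x, y = y,
       xc = rep(x, each = geometry$ny),
       yc = rep(y, times = geometry$nx))
}

#' Read or write a scanner geometry configuration file
#'
#' The configuration is a flat key-value document (YAML or JSON, chosen by
#' file extension) with keys `D`, `cell_size`, `sheet_size`, `z_exciter`,
#' `z_receiver`, `receivers` (list of `{x, y, length, orient}`),
#' `scan` (`{min, max, n}`) and `gamma`.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_geometry()` returns a `scan_geometry`.
#' @export
read_geometry <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  rec <- cfg$receivers
  if (!is.null(rec) && !is.data.frame(rec)) {
    rec <- do.call(rbind, lapply(rec, function(r)
      data.frame(x = r$x, y = r$y, length = r$length, orient = r$orient,
                 stringsAsFactors = FALSE)))
  }
  args <- cfg[intersect(names(cfg),
                        c("D", "sheet_size", "cell_size", "z_exciter",
                          "z_receiver", "scan", "gamma", "y0", "thickness"))]
  args$receivers <- rec
  args$sheet_size <- unlist(args$sheet_size)
  do.call(scan_geometry, args)
}

#' @rdname read_geometry
#' @param geometry A `scan_geometry` to serialize.
#' @export
write_geometry <- function(geometry, path) {
  cfg <- list(
    D = geometry$D,
    sheet_size = geometry$sheet_size,
    cell_size = geometry$cell_size,
    z_exciter = geometry$z_exciter,
    z_receiver = geometry$z_receiver,
    receivers = lapply(seq_len(nrow(geometry$receivers)), function(i)
      as.list(geometry$receivers[i, ])),
    scan = geometry$scan,
    gamma = geometry$gamma,
    y0 = geometry$y0,
    thickness = geometry$thickness
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
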