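#' Conductivity grid
#'
#' A 2D array of pixel conductivities on a uniform rectangular grid, the
#' unknown of the tomographic problem.  Values are stored as an
#' `ny x nx` matrix with row 1 the bottom (lowest y) pixel row; element
#' `[i, j]` is the pixel in y-row `i`, x-column `j`.
#'
#' @param values Numeric matrix of conductivities (S/m), all `>= 0`.
#' @param cell_size Pixel edge length (m).
#' @param origin Length-2 numeric: `(x, y)` of the lower-left grid corner.
#' @param thickness Effective sheet thickness (m).
#' @return Object of class `conductivity_grid`.
#' @export
#' @examples
#' g <- conductivity_grid(matrix(0.5, 20, 20))
#' range(g$values)
conductivity_grid <- function(values, cell_size = 0.02,
                              origin = NULL, thickness = 0.01) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("conductivities must be >= 0")
  if (is.null(origin))
    origin <- c(-ncol(values) * cell_size / 2, -nrow(values) * cell_size / 2)
  structure(list(values = values,
                 cell_size = cell_size,
                 origin = as.numeric(origin),
                 thickness = thickness),
            class = "conductivity_grid")
}

#' @export
print.conductivity_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("Conductivity grid: %d x %d pixels of %.3f m (thickness %.3f m)\n",
              nrow(v), ncol(v), x$cell_size, x$thickness))
  cat(sprintf("  sigma in [%.3g, %.3g] S/m, %d distinct values\n",
              min(v), max(v), length(unique(as.vector(v)))))
  invisible(x)
}

#' Read and write conductivity grids
#'
#' CSV layout: comment header lines `# cell_size`, `# origin`, `# thickness`
#' followed by the row-major value matrix (top row first, so the file reads
#' like a map).  JSON stores the same fields verbatim.
#'
#' @param grid A `conductivity_grid`.
#' @param path Output path (`.csv` or `.json`).
#' @export
write_grid <- function(grid, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(values = grid$values,
                              cell_size = grid$cell_size,
                              origin = grid$origin,
                              thickness = grid$thickness),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# cell_size %.17g", grid$cell_size),
                 sprintf("# origin %.17g %.17g", grid$origin[1], grid$origin[2]),
                 sprintf("# thickness %.17g", grid$thickness)), con)
    write_matrix_rows(grid$values, con)   # top row first, full precision
  }
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(conductivity_grid(obj$values, obj$cell_size, obj$origin,
                             obj$thickness))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getnum <- function(key) {
    ln <- grep(paste0("^# ", key), hdr, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub(paste0("^# ", key), "", ln)), "\\s+")[[1]])
  }
  vals <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                          header = FALSE)
  m <- as.matrix(vals)
  dimnames(m) <- NULL
  conductivity_grid(m[rev(seq_len(nrow(m))), , drop = FALSE],
                    getnum("cell_size"), getnum("origin"), getnum("thickness"))
}

# Full-precision matrix rows, top row first (so the file reads like a map).
write_matrix_rows <- function(v, con) {
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  writeLines(apply(v, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), con)
}

# Same matrix/CSV format reused for per-pixel moment arrays.

#' Per-pixel magnetic dipole moment field
#'
#' z-directed magnetic dipole moments on the pixel grid (A m^2), the vector
#' potential of the discrete eddy-current field.  Implicitly zero outside
#' the grid support.
#'
#' @param values `ny x nx` numeric matrix of moments.
#' @param cell_size Pixel edge length (m).
#' @param origin Lower-left grid corner.
#' @param basis Optional label, e.g. `"phi"` or `"psi"`.
#' @return Object of class `moment_field`.
#' @export
moment_field <- function(values, cell_size = 0.02, origin = NULL,
                         basis = NA_character_) {
  values <- as.matrix(values)
  if (is.null(origin))
    origin <- c(-ncol(values) * cell_size / 2, -nrow(values) * cell_size / 2)
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin), basis = basis),
            class = "moment_field")
}

#' Write / read a moment field in the shared grid CSV format
#'
#' Same matrix layout as [write_grid()] (header comments, top row first),
#' with a `basis` header line instead of `thickness`.
#'
#' @param m A [moment_field()].
#' @param path CSV path.
#' @export
write_moments <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell_size %.17g", m$cell_size),
               sprintf("# origin %.17g %.17g", m$origin[1], m$origin[2]),
               sprintf("# basis %s", ifelse(is.na(m$basis), "NA", m$basis))),
             con)
  write_matrix_rows(m$values, con)
  invisible(path)
}

#' @rdname write_moments
#' @export
read_moments <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getval <- function(key) {
    ln <- grep(paste0("^# ", key), hdr, value = TRUE)[1]
    strsplit(trimws(sub(paste0("^# ", key), "", ln)), "\\s+")[[1]]
  }
  vals <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                          header = FALSE)
  v <- as.matrix(vals)
  dimnames(v) <- NULL
  basis <- getval("basis")
  if (identical(basis, "NA")) basis <- NA_character_
  moment_field(v[rev(seq_len(nrow(v))), , drop = FALSE],
               as.numeric(getval("cell_size")),
               as.numeric(getval("origin")), basis)
}

#' @export
print.moment_field <- function(x, ...) {
  cat(sprintf("Moment field (%s): %d x %d pixels, |m| max %.3g A m^2\n",
              ifelse(is.na(x$basis), "unlabelled", x$basis),
              nrow(x$values), ncol(x$values), max(abs(x$values))))
  invisible(x)
}
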