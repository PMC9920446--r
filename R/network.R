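# Resistor-network discretisation of the conductivity sheet and the
# eddy-current forward solve.
#
# The sheet is lumped onto a lattice: nodes at pixel corners, edges along
# pixel boundaries.  For an nx x ny cell grid there are (nx+1)(ny+1) nodes
# and nx(ny+1) + ny(nx+1) edges; the cycle-space dimension k - n + 1 equals
# the pixel count, which is exactly the number of independent elementary
# current vortices (one z-moment per pixel).
#
# Edge ordering convention (fixed, so CSV outputs are bit-comparable):
#   x-edges first, indexed by (line l = 0..ny, column j = 1..nx), j fastest;
#   then y-edges, indexed by (vline v = 0..nx, row i = 1..ny), i fastest.

node_id <- function(ix, iy, nx) iy * (nx + 1L) + ix + 1L

grid_edge_table <- function(nx, ny, cell_size, origin) {
  h <- cell_size
  # x-directed edges on horizontal node lines
  lx <- rep(0:ny, each = nx)
  jx <- rep(seq_len(nx), times = ny + 1)
  ex <- data.frame(
    type = "x", i = lx, j = jx,
    from = node_id(jx - 1L, lx, nx), to = node_id(jx, lx, nx),
    mx = origin[1] + (jx - 0.5) * h, my = origin[2] + lx * h,
    dirx = 1, diry = 0, stringsAsFactors = FALSE)
  # y-directed edges on vertical node lines
  vy <- rep(0:nx, each = ny)
  iy <- rep(seq_len(ny), times = nx + 1)
  ey <- data.frame(
    type = "y", i = iy, j = vy,
    from = node_id(vy, iy - 1L, nx), to = node_id(vy, iy, nx),
    mx = origin[1] + vy * h, my = origin[2] + (iy - 0.5) * h,
    dirx = 0, diry = 1, stringsAsFactors = FALSE)
  e <- rbind(ex, ey)
  e$dl <- h
  e
}

#' Build the resistor network of a conductivity grid
#'
#' Discretises the sheet into a lattice of lumped resistors: nodes at pixel
#' corners, one conductance per edge.  The edge conductance is the
#' arithmetic mean of the adjacent pixel conductivities (one pixel at the
#' sheet boundary) times the sheet thickness; for square cells the edge
#' length and width cancel.
#'
#' @param grid A [conductivity_grid()].
#' @return Object of class `resistor_network` with fields `nodes` (count),
#'   `edges` (edge table incl. conductance `g`), `nx`, `ny`, `cell_size`,
#'   `origin`, `thickness`.
#' @export
#' @examples
#' net <- build_network(conductivity_grid(matrix(0.5, 3, 3)))
#' net$n_nodes                     # 16
#' nrow(net$edges)                 # 24
#' nrow(net$edges) - net$n_nodes + 1  # 9 independent loops
build_network <- function(grid) {
  sig <- grid$values
  ny <- nrow(sig); nx <- ncol(sig)
  e <- grid_edge_table(nx, ny, grid$cell_size, grid$origin)
  g <- numeric(nrow(e))
  isx <- e$type == "x"
  # x-edge on line l: pixel row l below, row l+1 above
  l <- e$i[isx]; j <- e$j[isx]
  below <- ifelse(l >= 1, sig[cbind(pmax(l, 1), j)], NA)
  above <- ifelse(l + 1 <= ny, sig[cbind(pmin(l + 1, ny), j)], NA)
  g[isx] <- rowMeans(cbind(below, above), na.rm = TRUE)
  # y-edge on vline v: pixel column v left, v+1 right
  i <- e$i[!isx]; v <- e$j[!isx]
  left <- ifelse(v >= 1, sig[cbind(i, pmax(v, 1))], NA)
  right <- ifelse(v + 1 <= nx, sig[cbind(i, pmin(v + 1, nx))], NA)
  g[!isx] <- rowMeans(cbind(left, right), na.rm = TRUE)
  e$g <- g * grid$thickness
  structure(list(n_nodes = (nx + 1L) * (ny + 1L),
                 edges = e,
                 nx = nx, ny = ny,
                 cell_size = grid$cell_size,
                 origin = grid$origin,
                 thickness = grid$thickness),
            class = "resistor_network")
}

#' @export
print.resistor_network <- function(x, ...) {
  k <- nrow(x$edges)
  cat(sprintf(
    "Resistor network: %d nodes, %d edges, %d independent loops (pixels)\n",
    x$n_nodes, k, k - x$n_nodes + 1))
  invisible(x)
}

#' Induced EMFs along the network edges
#'
#' Applies the excitation vector potential at each edge midpoint:
#' `U = (A_E . direction) * dl`, the real amplitude at the eddy-current
#' phase (the 90-degree phase and the time-derivative factor are absorbed
#' into a unit scale).  Edges perpendicular to A_E carry no EMF; for the
#' ideal undulator only y-directed edges are driven.
#'
#' @param network A [build_network()] result.
#' @param geometry A [scan_geometry()].
#' @param x_s Scan position (m).
#' @param mode Undulator mode, see [undulator_potential()].
#' @param n_stripes Stripe count for `"stripes"` mode.
#' @return Numeric vector of per-edge EMFs in edge-table order.
#' @export
induced_emfs <- function(network, geometry, x_s = 0,
                         mode = "ideal", n_stripes = 11) {
  e <- network$edges
  A <- undulator_potential(geometry, list(x = e$mx, y = e$my),
                           mode = mode, x_s = x_s, n_stripes = n_stripes)
  (A$Ax * e$dirx + A$Ay * e$diry) * e$dl
}

#' Per-edge eddy currents
#'
#' Container for the solved (or curl-derived) currents along the directed
#' network edges.
#'
#' @param I Numeric vector of edge currents (A), in edge-table order.
#' @param edges Edge table (from the network or [grid_edge_table] layout).
#' @param nx,ny Grid dimensions (cells).
#' @param cell_size,origin Grid metric.
#' @param basis Label: `"phi"`, `"psi"` or a scan position.
#' @return Object of class `current_field`.
#' @export
current_field <- function(I, edges, nx, ny, cell_size, origin,
                          basis = NA_character_) {
  stopifnot(length(I) == nrow(edges))
  structure(list(I = I, edges = edges, nx = nx, ny = ny,
                 cell_size = cell_size, origin = origin, basis = basis),
            class = "current_field")
}

#' @export
print.current_field <- function(x, ...) {
  cat(sprintf("Current field (%s): %d edges on %d x %d cells, |I| max %.3g A\n",
              ifelse(is.na(x$basis), "unlabelled", x$basis),
              length(x$I), x$nx, x$ny, max(abs(x$I))))
  invisible(x)
}

# Signed net outflow at every node (Kirchhoff residual).
node_residuals <- function(I, edges, n_nodes) {
  r <- numeric(n_nodes)
  out <- tapply(I, edges$from, sum)
  inn <- tapply(I, edges$to, sum)
  r[as.integer(names(out))] <- r[as.integer(names(out))] + out
  r[as.integer(names(inn))] <- r[as.integer(names(inn))] - inn
  r
}

#' Solve the eddy currents of the network under given EMFs
#'
#' Nodal analysis: with each edge modelled as a conductance `g` in series
#' with an EMF `U` (driving from `from` to `to`), the node potentials solve
#' the sparse symmetric system `L V = -B' (g U)` with `L` the weighted graph
#' Laplacian.  One reference node per connected conducting component is
#' grounded (lowest node index), removing the gauge freedom
#' deterministically; disconnected conducting islands are therefore handled
#' in a single solve.  Edge currents follow as `I = g (V_from - V_to + U)`.
#'
#' @param network A [build_network()] result.
#' @param emfs Per-edge EMF vector from [induced_emfs()].
#' @param basis Label carried into the result.
#' @return A [current_field()]; attribute `node_residual` holds the maximum
#'   absolute Kirchhoff residual (guaranteed `<= 1e-10 * max|I|`).
#' @export
solve_eddy_currents <- function(network, emfs, basis = NA_character_) {
  e <- network$edges
  stopifnot(length(emfs) == nrow(e))
  n <- network$n_nodes
  cond <- e$g > 0
  I <- numeric(nrow(e))
  if (!any(cond)) {
    cf <- current_field(I, e, network$nx, network$ny,
                        network$cell_size, network$origin, basis)
    attr(cf, "node_residual") <- 0
    return(cf)
  }
  ec <- e[cond, ]
  gU <- ec$g * emfs[cond]
  # connected components of the conducting subgraph
  gr <- igraph::graph_from_edgelist(cbind(ec$from, ec$to), directed = FALSE)
  if (igraph::vcount(gr) < n) gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
  comp <- igraph::components(gr)$membership
  active <- sort(unique(c(ec$from, ec$to)))
  ground <- vapply(split(active, comp[active]), min, integer(1))
  free <- setdiff(active, ground)
  V <- numeric(n)
  if (length(free) > 0) {
    k <- nrow(ec)
    B <- Matrix::sparseMatrix(i = rep(seq_len(k), 2L),
                              j = c(ec$from, ec$to),
                              x = rep(c(1, -1), each = k),
                              dims = c(k, n))
    L <- Matrix::t(B) %*% (ec$g * B)
    rhs <- -as.numeric(Matrix::t(B) %*% gU)
    Vf <- Matrix::solve(L[free, free, drop = FALSE], rhs[free])
    V[free] <- as.numeric(Vf)
  }
  I[cond] <- ec$g * (V[ec$from] - V[ec$to] + emfs[cond])
  cf <- current_field(I, e, network$nx, network$ny,
                      network$cell_size, network$origin, basis)
  res <- max(abs(node_residuals(I, e, n)))
  if (max(abs(I)) > 0 && res > 1e-10 * max(abs(I)))
    warning(sprintf("Kirchhoff residual %.3g exceeds 1e-10 * max|I|", res))
  attr(cf, "node_residual") <- res
  cf
}

#' Basis eddy-current fields of the two carrier positions
#'
#' Solves the forward problem at the two reference scan positions of the
#' sinusoidal excitation: the symmetric position (body centred on a stripe,
#' `x_s = 0`, label `phi`) and the antisymmetric position a quarter period
#' away (`x_s = D/4`, label `psi`).  Any scan position's current field is
#' the superposition `J(x_s) = J_phi cos(2 pi x_s / D) + J_psi sin(2 pi x_s / D)`.
#'
#' @param grid A [conductivity_grid()].
#' @param geometry A [scan_geometry()].
#' @param mode,n_stripes Undulator options.
#' @return List with elements `phi` and `psi`, each a [current_field()].
#' @export
basis_currents <- function(grid, geometry, mode = "ideal", n_stripes = 11) {
  net <- build_network(grid)
  J <- lapply(c(phi = 0, psi = geometry$D / 4), function(xs) {
    solve_eddy_currents(net, induced_emfs(net, geometry, x_s = xs,
                                          mode = mode,
                                          n_stripes = n_stripes))
  })
  J$phi$basis <- "phi"
  J$psi$basis <- "psi"
  J
}

#' Write / read a current field as CSV
#'
#' Columns `edge_type` (`x`/`y`), `i`, `j` (line/column indices per the edge
#' ordering convention) and `current` (A).
#'
#' @param cf A [current_field()].
#' @param path CSV path.
#' @export
write_currents <- function(cf, path) {
  df <- data.frame(edge_type = cf$edges$type, i = cf$edges$i, j = cf$edges$j,
                   current = cf$I)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nx %d ny %d cell_size %.17g origin %.17g %.17g basis %s",
                     cf$nx, cf$ny, cf$cell_size, cf$origin[1], cf$origin[2],
                     ifelse(is.na(cf$basis), "NA", cf$basis)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_currents
#' @export
read_currents <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), "\\s+")[[1]]
  val <- function(key) hdr[which(hdr == key) + 1]
  nx <- as.integer(val("nx")); ny <- as.integer(val("ny"))
  cs <- as.numeric(val("cell_size"))
  org <- as.numeric(c(hdr[which(hdr == "origin") + 1],
                      hdr[which(hdr == "origin") + 2]))
  basis <- val("basis"); if (basis == "NA") basis <- NA_character_
  df <- utils::read.csv(textConnection(lines[-1]))
  e <- grid_edge_table(nx, ny, cs, org)
  stopifnot(nrow(df) == nrow(e),
            all(df$edge_type == e$type), all(df$i == e$i), all(df$j == e$j))
  current_field(df$current, e, nx, ny, cs, org, basis)
}
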